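#' Kaplan-Meier curve
#'
#' Product-limit estimate of a survival function, stored at the distinct
#' event times only (censorings shrink the risk set but add no step).
#'
#' @slot eventTimes strictly increasing distinct event times.
#' @slot atRisk number at risk at each event time.
#' @slot events number of events at each event time.
#' @slot survival the estimate S(t) at each event time; non-increasing,
#'   in \[0, 1\].
#' @seealso [kmEstimate()], [kmMedian()]
#' @export
setClass("KMCurve",
  representation(eventTimes = "numeric", atRisk = "integer",
                 events = "integer", survival = "numeric"))

setValidity("KMCurve", function(object) {
  msg <- character()
  d <- length(object@eventTimes)
  if (length(object@atRisk) != d || length(object@events) != d ||
      length(object@survival) != d)
    msg <- c(msg, "slots must have equal length")
  if (d > 1 && any(diff(object@eventTimes) <= 0))
    msg <- c(msg, "eventTimes must be strictly increasing")
  if (d > 0) {
    if (any(object@survival < -1e-12 | object@survival > 1 + 1e-12))
      msg <- c(msg, "survival must lie in [0, 1]")
    if (d > 1 && any(diff(object@survival) > 1e-12))
      msg <- c(msg, "survival must be non-increasing")
    if (d > 1 && any(diff(object@atRisk) > 0L))
      msg <- c(msg, "atRisk must be non-increasing across event times")
    if (any(object@events < 1L) || any(object@events > object@atRisk))
      msg <- c(msg, "events must satisfy 1 <= d_i <= n_i")
  }
  if (length(msg)) msg else TRUE
})

#' Two-sample log-rank test result
#'
#' The standardized log-rank statistic Z = sum(O - E) / sqrt(sum(V)) and its
#' square, with the per-event-time hypergeometric terms.
#'
#' @slot statistic the standardized statistic Z.
#' @slot score Z squared (chi-square(1) under the null).
#' @slot obsMinusExp sum over event times of d_1i - E_1i.
#' @slot variance sum of the hypergeometric variances V_i.
#' @slot perTime data.frame with columns time, d1, d2, n1, n2, E1, V.
#' @seealso [logRank()]
#' @export
setClass("LogRankResult",
  representation(statistic = "numeric", score = "numeric",
                 obsMinusExp = "numeric", variance = "numeric",
                 perTime = "data.frame"))

setValidity("LogRankResult", function(object) {
  msg <- character()
  if (object@variance < 0) msg <- c(msg, "variance must be >= 0")
  if (nrow(object@perTime) && any(object@perTime$V < -1e-12))
    msg <- c(msg, "per-time variances must be >= 0")
  if (is.finite(object@statistic) &&
      abs(object@score - object@statistic^2) > 1e-8 * (1 + object@score))
    msg <- c(msg, "score must equal statistic^2")
  if (length(msg)) msg else TRUE
})

#' Multilocus genotype cell classification
#'
#' High/low-risk map over the 3^q genotype cells of a q-SNP combination,
#' with per-cell provenance recording how each label was reached.
#'
#' @slot q interaction order.
#' @slot labels integer vector of length 3^q, 1 = HIGH, 0 = LOW, named by
#'   cell key (genotype codes joined by ":").
#' @slot provenance character vector: one of "cell_median",
#'   "complement_rule", "empty_default", "score_sum", "logrank_sign",
#'   "degenerate_default".
#' @slot overallMedian overall training-sample KM median (KM-MDR only;
#'   `NA` for score-based classifiers).
#' @seealso [classifyKM()], [classifySurv()], [classifyScores()],
#'   [assignGroups()]
#' @export
setClass("CellClassification",
  representation(q = "integer", labels = "integer", provenance = "character",
                 overallMedian = "numeric"))

setValidity("CellClassification", function(object) {
  msg <- character()
  nc <- 3L^object@q
  if (length(object@labels) != nc)
    msg <- c(msg, sprintf("labels must have length 3^q = %d", nc))
  if (!all(object@labels %in% c(0L, 1L)))
    msg <- c(msg, "labels must be 0 (LOW) or 1 (HIGH)")
  if (length(object@provenance) != nc)
    msg <- c(msg, "provenance must have length 3^q")
  if (length(msg)) msg else TRUE
})

#' Genotype + survival container
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding a complete
#' 0/1/2-coded SNP genotype matrix (SNPs as rows, subjects as columns, assay
#' `"genotype"`) with the survival phenotype in `colData`: `time`
#' (non-negative follow-up time), `status` (1 = event, 0 = censored) and any
#' number of numeric covariate columns.
#'
#' @param genotypes integer matrix, subjects x SNPs, entries in \{0, 1, 2\}.
#' @param time non-negative follow-up times, one per subject.
#' @param status event indicators in \{0, 1\}.
#' @param covariates optional numeric matrix/data.frame of per-subject
#'   covariates.
#' @param x a `MdrSurvData` object.
#' @param ... unused.
#' @return `MdrSurvData()` returns the container; `genotypes()` the
#'   subjects-x-SNPs integer matrix; `survTime()`/`survStatus()` numeric
#'   vectors; `covariateMatrix()` a numeric matrix or `NULL`.
#' @examples
#' g <- matrix(rbinom(40, 2, 0.3), 20, 2,
#'             dimnames = list(paste0("S", 1:20), c("rs1", "rs2")))
#' d <- MdrSurvData(g, time = rexp(20), status = rbinom(20, 1, 0.7))
#' survTime(d)[1:3]
#' @aliases MdrSurvData genotypes survTime survStatus covariateMatrix
#' @export MdrSurvData
#' @exportClass MdrSurvData
setClass("MdrSurvData", contains = "SummarizedExperiment")

setValidity("MdrSurvData", function(object) {
  msg <- character()
  if (!"genotype" %in% SummarizedExperiment::assayNames(object))
    return("assay 'genotype' is required")
  g <- SummarizedExperiment::assay(object, "genotype")
  if (!all(g %in% c(0L, 1L, 2L)))
    msg <- c(msg, "genotype entries must be 0, 1 or 2 (no missing values)")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("time", "status") %in% colnames(cd)))
    return("colData must contain 'time' and 'status'")
  if (ncol(object) < 1) msg <- c(msg, "at least one subject is required")
  if (any(cd$time < 0)) msg <- c(msg, "time must be non-negative")
  if (!all(cd$status %in% c(0, 1))) msg <- c(msg, "status must be 0 or 1")
  if (anyDuplicated(colnames(object))) msg <- c(msg, "subject ids must be unique")
  if (anyDuplicated(rownames(object))) msg <- c(msg, "SNP ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Cross-validated interaction search report
#'
#' Results of an exhaustive q-way MDR search: per-combination mean training
#' score, pooled testing score, cross-validation consistency (CVC) and
#' optional permutation p-value, plus the selected best model.
#'
#' @slot method one of "km", "surv", "cox", "aft".
#' @slot q interaction order searched.
#' @slot results ranked data.frame: model, trainingScore, testingScore, cvc,
#'   pValue, failedFolds.
#' @slot best list describing the selected best combination.
#' @slot folds integer fold assignment used.
#' @slot settings list snapshot (k, selectionOrder, seed, cvRepeats).
#' @slot perFold per-fold detail (winner index and, when requested,
#'   the per-fold [CellClassification-class] objects).
#' @param x a `MdrSearchReport`.
#' @param ... unused.
#' @aliases bestModel resultsTable
#' @seealso [runCV()], [selectBest()], [permutationTest()]
#' @export
setClass("MdrSearchReport",
  representation(method = "character", q = "integer", results = "data.frame",
                 best = "list", folds = "integer", settings = "list",
                 perFold = "list"))

setValidity("MdrSearchReport", function(object) {
  msg <- character()
  if (!object@method %in% c("km", "surv", "cox", "aft"))
    msg <- c(msg, "unknown method")
  if (nrow(object@results)) {
    if (any(object@results$cvc < 0 | object@results$cvc > max(object@folds)))
      msg <- c(msg, "cvc must lie in 0..k")
    if (any(object@results$trainingScore < -1e-9, na.rm = TRUE))
      msg <- c(msg, "scores must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Epistatic penetrance model
#'
#' A 3x3 penetrance table f\[i, j\] = P(high risk | SNP1 = i, SNP2 = j) with
#' no marginal effects under Hardy-Weinberg genotype weights and a target
#' heritability.
#'
#' @slot f 3x3 penetrance matrix, entries in \[0, 1\].
#' @slot maf minor allele frequency used for the HWE weights.
#' @slot h2 target heritability Var(f) / (K (1 - K)).
#' @slot K population prevalence of high-risk status under the model.
#' @slot modelId identifier (records the generating seed).
#' @seealso [generatePenetrance()], [penetranceSummary()]
#' @export
setClass("PenetranceModel",
  representation(f = "matrix", maf = "numeric", h2 = "numeric",
                 K = "numeric", modelId = "character"))

setValidity("PenetranceModel", function(object) {
  msg <- character()
  if (!all(dim(object@f) == c(3L, 3L))) msg <- c(msg, "f must be 3x3")
  if (any(object@f < -1e-12 | object@f > 1 + 1e-12))
    msg <- c(msg, "penetrances must lie in [0, 1]")
  if (object@maf <= 0 || object@maf > 0.5)
    msg <- c(msg, "maf must lie in (0, 0.5]")
  if (length(msg)) msg else TRUE
})
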