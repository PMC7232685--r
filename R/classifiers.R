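.PROV <- c("cell_median", "complement_rule", "empty_default",
           "degenerate_default")

.cellIndex <- function(geno) {
  # base-3 encoding of a subjects x q genotype matrix -> 0 .. 3^q - 1
  geno <- as.matrix(geno)
  q <- ncol(geno)
  as.integer(geno %*% 3L^((q - 1L):0L))
}

.cellKeys <- function(q) {
  grid <- expand.grid(rev(replicate(q, 0:2, simplify = FALSE)))[, q:1,
                                                                drop = FALSE]
  apply(grid, 1L, paste, collapse = ":")
}

.newClassification <- function(q, labels, provCodes, overallMedian) {
  prov <- c("cell_median", "complement_rule", "empty_default",
            "degenerate_default")[provCodes + 1L]
  names(labels) <- .cellKeys(q)
  new("CellClassification", q = as.integer(q), labels = labels,
      provenance = prov, overallMedian = overallMedian)
}

.checkGenoMatrix <- function(geno, n) {
  geno <- as.matrix(geno)
  if (nrow(geno) != n)
    stop("genotype rows must align with the survival sample", call. = FALSE)
  if (!all(geno %in% c(0L, 1L, 2L)))
    stop("genotypes must be coded 0/1/2 with no missing values",
         call. = FALSE)
  storage.mode(geno) <- "integer"
  geno
}

#' KM-MDR cell classifier
#'
#' Classifies each multilocus genotype cell of a q-SNP combination as
#' high or low risk by comparing the cell's Kaplan-Meier median survival
#' time with the overall median of the training sample: a cell is HIGH
#' exactly when its median is strictly smaller than the overall median.
#' When a cell's median is not estimable (heavy censoring or sparsity),
#' the complement sample — all training subjects outside the cell — is
#' used instead: a complement median that is estimable and larger than the
#' overall median marks the cell HIGH; any other outcome, and empty cells,
#' default to LOW.
#'
#' @param geno integer matrix, subjects x q, genotype codes 0/1/2 for the
#'   q SNPs of the candidate combination.
#' @param time,status training-sample follow-up times and event indicators.
#' @return A [CellClassification-class].
#' @examples
#' set.seed(1)
#' g <- matrix(rbinom(200, 2, 0.4), 100, 2)
#' cl <- classifyKM(g, time = rexp(100), status = rbinom(100, 1, 0.8))
#' table(riskLabels(cl))
#' @export
classifyKM <- function(geno, time, status) {
  .checkSurvInput(time, status)
  geno <- .checkGenoMatrix(geno, length(time))
  q <- ncol(geno)
  o <- order(time)
  tt <- as.numeric(time[o]); ss <- as.integer(status[o])
  tm <- .cppKmMedian(tt, ss)
  if (is.na(tm))
    stop("overall median survival time is not estimable; ",
         "the KM-MDR classifier is not applicable to this sample",
         call. = FALSE)
  cellv <- .cellIndex(geno)[o]
  res <- .cppClassifyKm(tt, ss, cellv, 3L^q, tm)
  .newClassification(q, res$labels, res$provenance, tm)
}

#' Surv-MDR cell classifier
#'
#' Labels each multilocus genotype cell by the sign of the log-rank
#' statistic comparing subjects inside the cell against all other
#' subjects: Z > 0 (cell dies earlier than its complement) marks the cell
#' HIGH. Empty cells and cells whose statistic is undefined default LOW.
#'
#' @inheritParams classifyKM
#' @return A [CellClassification-class] with `overallMedian = NA`.
#' @export
classifySurv <- function(geno, time, status) {
  .checkSurvInput(time, status)
  if (sum(status) == 0L)
    stop("at least one event is required", call. = FALSE)
  geno <- .checkGenoMatrix(geno, length(time))
  q <- ncol(geno)
  o <- order(time)
  cellv <- .cellIndex(geno)[o]
  res <- .cppClassifySurv(as.numeric(time[o]), as.integer(status[o]),
                          cellv, 3L^q)
  # provenance codes from C++: 0 logrank sign, 2 empty, 3 degenerate
  prov <- res$provenance
  cl <- .newClassification(q, res$labels, ifelse(prov == 0L, 0L, prov),
                           NA_real_)
  cl@provenance[prov == 0L] <- "logrank_sign"
  cl
}

#' Null-model subject scores for the regression-based comparators
#'
#' `coxNullScores()` returns martingale residuals of the genotype-free null
#' Cox model: status_i minus the Breslow cumulative hazard at the subject's
#' observed time (times `exp(z gamma)` when covariates are present). With no
#' covariates this is the Nelson-Aalen-based residual. `aftNullScores()`
#' returns the negated standardized residual of a null log-normal
#' accelerated failure time model, -(log t_i - mu - z gamma) / sigma, so
#' that in both scores larger values mean higher risk (earlier death than
#' the null model predicts). Censored subjects enter with their observed
#' censored time.
#'
#' @param time,status follow-up times and event indicators.
#' @param covariates optional numeric matrix of adjusting covariates (the
#'   null model never includes genotypes).
#' @return Numeric vector of per-subject scores.
#' @examples
#' s <- coxNullScores(time = rexp(50), status = rep(1, 50))
#' abs(sum(s)) < 1e-8  # martingale residuals sum to zero
#' @export
coxNullScores <- function(time, status, covariates = NULL) {
  .checkSurvInput(time, status)
  df <- data.frame(time = time, status = status)
  if (is.null(covariates) || NCOL(covariates) == 0L) {
    fit <- survival::coxph(survival::Surv(time, status) ~ 1, data = df,
                           ties = "breslow")
  } else {
    z <- as.matrix(covariates)
    if (nrow(z) != length(time))
      stop("covariates must have one row per subject", call. = FALSE)
    fit <- tryCatch(
      survival::coxph(survival::Surv(time, status) ~ z, data = df,
                      ties = "breslow"),
      error = function(e) stop("null Cox model failed to fit: ",
                               conditionMessage(e), call. = FALSE),
      warning = function(w) stop("null Cox model did not converge cleanly: ",
                                 conditionMessage(w), call. = FALSE))
  }
  unname(stats::residuals(fit, type = "martingale"))
}

#' @rdname coxNullScores
#' @export
aftNullScores <- function(time, status, covariates = NULL) {
  .checkSurvInput(time, status)
  if (any(time <= 0))
    stop("AFT residuals require strictly positive times", call. = FALSE)
  df <- data.frame(time = time, status = status)
  fml <- if (is.null(covariates) || NCOL(covariates) == 0L) {
    survival::Surv(time, status) ~ 1
  } else {
    z <- as.matrix(covariates)
    if (nrow(z) != length(time))
      stop("covariates must have one row per subject", call. = FALSE)
    survival::Surv(time, status) ~ z
  }
  fit <- tryCatch(
    survival::survreg(fml, data = df, dist = "lognormal"),
    error = function(e) stop("null AFT model failed to fit: ",
                             conditionMessage(e), call. = FALSE))
  lp <- as.numeric(fit$linear.predictors)
  unname(-(log(time) - lp) / fit$scale)
}

#' Score-sum cell classifier (GMDR family)
#'
#' Labels a multilocus genotype cell HIGH exactly when the sum of its
#' subjects' scores is strictly positive. Used with [coxNullScores()]
#' (Cox-MDR) and [aftNullScores()] (AFT-MDR). Empty cells and zero sums
#' are LOW.
#'
#' @param geno integer matrix, subjects x q, genotype codes 0/1/2.
#' @param scores numeric per-subject scores, aligned with `geno` rows.
#' @return A [CellClassification-class] with `overallMedian = NA`.
#' @export
classifyScores <- function(geno, scores) {
  geno <- .checkGenoMatrix(geno, length(scores))
  if (any(!is.finite(scores)))
    stop("scores must be finite", call. = FALSE)
  q <- ncol(geno)
  ncells <- 3L^q
  cellv <- .cellIndex(geno)
  sums <- rep(0, ncells)
  agg <- rowsum(scores, cellv)
  sums[as.integer(rownames(agg)) + 1L] <- agg[, 1L]
  counts <- tabulate(cellv + 1L, ncells)
  labels <- as.integer(sums > 0)
  cl <- .newClassification(q, labels, ifelse(counts == 0L, 2L, 3L), NA_real_)
  cl@provenance[counts > 0L] <- "score_sum"
  cl
}

#' Pool subjects into high/low-risk groups
#'
#' Applies a trained [CellClassification-class] to (possibly new) subjects:
#' each subject receives the label of its multilocus genotype cell. Cells
#' never observed in training keep the LOW default (with a warning when a
#' genuinely unseen cell — `empty_default` provenance — is hit).
#'
#' @param classification a [CellClassification-class].
#' @param geno integer matrix, subjects x q.
#' @return Integer vector: 1 = HIGH, 0 = LOW per subject.
#' @export
assignGroups <- function(classification, geno) {
  geno <- .checkGenoMatrix(geno, NROW(geno))
  if (ncol(geno) != classification@q)
    stop("genotype matrix must have q = ", classification@q, " columns",
         call. = FALSE)
  cellv <- .cellIndex(geno)
  unseen <- classification@provenance[cellv + 1L] == "empty_default"
  if (any(unseen))
    warning(sum(unseen), " subject(s) fall in genotype cells unseen in ",
            "training; defaulted to LOW", call. = FALSE)
  unname(classification@labels[cellv + 1L])
}

#' @rdname CellClassification-class
#' @export
setMethod("riskLabels", "CellClassification", function(x) {
  f <- factor(ifelse(x@labels == 1L, "HIGH", "LOW"),
              levels = c("HIGH", "LOW"))
  names(f) <- names(x@labels)
  f
})

#' @describeIn CellClassification-class compact display of the cell map.
#' @param object a `CellClassification`.
#' @export
setMethod("show", "CellClassification", function(object) {
  cat("CellClassification: q =", object@q, "(", 3L^object@q, "cells )\n")
  cat("  HIGH:", sum(object@labels == 1L),
      " LOW:", sum(object@labels == 0L), "\n")
  if (!is.na(object@overallMedian))
    cat("  overall training median:", format(object@overallMedian), "\n")
  tb <- table(object@provenance)
  cat("  provenance:", paste(names(tb), tb, sep = "=", collapse = ", "),
      "\n")
})
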