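#' @rdname MdrSurvData-class
#' @export
MdrSurvData <- function(genotypes, time, status, covariates = NULL) {
  g <- as.matrix(genotypes)
  if (is.null(rownames(g))) rownames(g) <- paste0("subject", seq_len(nrow(g)))
  if (is.null(colnames(g))) colnames(g) <- paste0("SNP", seq_len(ncol(g)))
  if (!all(g %in% c(0L, 1L, 2L)))
    stop("genotypes must be coded 0/1/2 with no missing values",
         call. = FALSE)
  storage.mode(g) <- "integer"
  n <- nrow(g)
  if (length(time) != n || length(status) != n)
    stop("time and status must have one value per genotype row",
         call. = FALSE)
  cd <- S4Vectors::DataFrame(time = as.numeric(time),
                             status = as.integer(status),
                             row.names = rownames(g))
  if (!is.null(covariates)) {
    z <- as.data.frame(covariates)
    if (nrow(z) != n)
      stop("covariates must have one row per subject", call. = FALSE)
    if (is.null(colnames(z)) || any(colnames(z) == ""))
      colnames(z) <- paste0("z", seq_len(ncol(z)))
    for (nm in colnames(z)) cd[[nm]] <- as.numeric(z[[nm]])
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(genotype = t(g)), colData = cd)
  new("MdrSurvData", se)
}

#' @rdname MdrSurvData-class
#' @export
setMethod("genotypes", "MdrSurvData", function(x, ...) {
  t(SummarizedExperiment::assay(x, "genotype"))
})

#' @rdname MdrSurvData-class
#' @export
setMethod("survTime", "MdrSurvData", function(x) {
  as.numeric(SummarizedExperiment::colData(x)$time)
})

#' @rdname MdrSurvData-class
#' @export
setMethod("survStatus", "MdrSurvData", function(x) {
  as.integer(SummarizedExperiment::colData(x)$status)
})

#' @rdname MdrSurvData-class
#' @export
setMethod("covariateMatrix", "MdrSurvData", function(x) {
  cd <- SummarizedExperiment::colData(x)
  extra <- setdiff(colnames(cd), c("time", "status"))
  if (!length(extra)) return(NULL)
  m <- as.matrix(as.data.frame(cd[, extra, drop = FALSE]))
  rownames(m) <- colnames(x)
  m
})

#' @describeIn MdrSurvData-class one-line summary on top of the
#'   SummarizedExperiment display.
#' @param object a `MdrSurvData`.
#' @export
setMethod("show", "MdrSurvData", function(object) {
  cat(sprintf(
    "MdrSurvData: %d subjects x %d SNPs, %d events (%.1f%% censored)\n",
    ncol(object), nrow(object), sum(survStatus(object)),
    100 * mean(survStatus(object) == 0L)))
  cv <- covariateMatrix(object)
  if (!is.null(cv))
    cat("  covariates:", paste(colnames(cv), collapse = ", "), "\n")
  callNextMethod()
})
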