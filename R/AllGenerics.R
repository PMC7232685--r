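#' @import methods
NULL

#' Kaplan-Meier median survival time
#'
#' Smallest time at which the product-limit survival estimate drops to 0.5
#' or below. Returns `NA` when the curve never reaches 0.5 (heavy censoring
#' or a cure fraction).
#'
#' @param x a [KMCurve-class] object, or a numeric vector of follow-up times.
#' @param ... for the numeric method, `status`: an event indicator vector
#'   (1 = event, 0 = censored).
#' @return A single numeric time, or `NA_real_` when not estimable.
#' @examples
#' kmMedian(kmEstimate(c(1, 2, 3, 4), c(1, 1, 1, 1)))
#' @export
setGeneric("kmMedian", function(x, ...) standardGeneric("kmMedian"))

#' @rdname MdrSurvData-class
#' @export
setGeneric("genotypes", function(x, ...) standardGeneric("genotypes"))

#' @rdname MdrSurvData-class
#' @export
setGeneric("survTime", function(x) standardGeneric("survTime"))

#' @rdname MdrSurvData-class
#' @export
setGeneric("survStatus", function(x) standardGeneric("survStatus"))

#' @rdname MdrSurvData-class
#' @export
setGeneric("covariateMatrix", function(x) standardGeneric("covariateMatrix"))

#' @rdname CellClassification-class
#' @export
setGeneric("riskLabels", function(x) standardGeneric("riskLabels"))

#' @rdname MdrSearchReport-class
#' @export
setGeneric("bestModel", function(x, ...) standardGeneric("bestModel"))

#' @rdname MdrSearchReport-class
#' @export
setGeneric("resultsTable", function(x) standardGeneric("resultsTable"))
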