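#' @useDynLib kmmdr, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

.checkSurvInput <- function(time, status) {
  if (length(time) == 0L) stop("empty sample: no subjects", call. = FALSE)
  if (length(time) != length(status))
    stop("time and status must have equal length", call. = FALSE)
  if (any(!is.finite(time)) || any(time < 0))
    stop("times must be finite and non-negative", call. = FALSE)
  if (!all(status %in% c(0, 1)))
    stop("status must be 0 (censored) or 1 (event)", call. = FALSE)
  invisible(TRUE)
}

#' Kaplan-Meier product-limit estimate
#'
#' Estimates the survival function S(t) = prod over event times t_i <= t of
#' (1 - d_i / n_i), where d_i is the number of events and n_i the number at
#' risk at t_i. Censored subjects leave the risk set without contributing a
#' step; a subject censored exactly at an event time remains at risk for
#' that event time.
#'
#' @param time non-negative follow-up times.
#' @param status event indicators, 1 = event, 0 = censored.
#' @return A [KMCurve-class] object (empty when there are no events, in
#'   which case S(t) is identically 1).
#' @examples
#' kmEstimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
#' @export
kmEstimate <- function(time, status) {
  .checkSurvInput(time, status)
  o <- order(time)
  res <- .cppKmCurve(as.numeric(time[o]), as.integer(status[o]))
  new("KMCurve",
      eventTimes = as.numeric(res$eventTimes),
      atRisk = as.integer(res$atRisk),
      events = as.integer(res$events),
      survival = as.numeric(res$survival))
}

#' @rdname kmMedian
#' @export
setMethod("kmMedian", "KMCurve", function(x, ...) {
  hit <- which(x@survival <= 0.5 + 1e-9)
  if (length(hit)) x@eventTimes[hit[1L]] else NA_real_
})

#' @rdname kmMedian
#' @export
setMethod("kmMedian", "numeric", function(x, status, ...) {
  .checkSurvInput(x, status)
  o <- order(x)
  .cppKmMedian(as.numeric(x[o]), as.integer(status[o]))
})

#' Two-sample log-rank test
#'
#' Standardized log-rank statistic between the two groups defined by
#' `group`: Z = sum_i (d_1i - E_1i) / sqrt(sum_i V_i), with
#' E_1i = d_i n_1i / n_i and
#' V_i = (n_i - d_i) d_i n_1i n_2i / ((n_i - 1) n_i^2) accumulated over the
#' distinct event times of the pooled sample. Its square is the score used
#' throughout the MDR search. Event times where only one subject is at risk
#' contribute zero variance.
#'
#' @param time non-negative follow-up times.
#' @param status event indicators, 1 = event, 0 = censored.
#' @param group binary group labels (logical, or any two-valued vector);
#'   `TRUE`/1/the higher level is "group 1" of the statistic.
#' @return A [LogRankResult-class] object.
#' @examples
#' lr <- logRank(c(1, 2, 3, 4), c(1, 1, 1, 1), c(1, 1, 0, 0))
#' lr@statistic  # 7 / sqrt(17)
#' @export
logRank <- function(time, status, group) {
  .checkSurvInput(time, status)
  if (length(group) != length(time))
    stop("group must have one label per subject", call. = FALSE)
  g <- as.integer(as.factor(group)) - 1L
  if (any(is.na(g))) stop("group labels must not be missing", call. = FALSE)
  if (all(g == 0L) || all(g == 1L))
    stop("degenerate groups: both groups must be non-empty", call. = FALSE)
  o <- order(time)
  tt <- as.numeric(time[o]); ss <- as.integer(status[o]); gg <- g[o]
  acc <- .cppLogrank(tt, ss, gg)
  if (acc$events == 0L)
    stop("no events: log-rank statistic undefined", call. = FALSE)
  if (acc$var <= 0)
    stop("zero total variance: log-rank statistic undefined", call. = FALSE)
  z <- acc$oe / sqrt(acc$var)
  new("LogRankResult",
      statistic = z, score = z * z,
      obsMinusExp = acc$oe, variance = acc$var,
      perTime = .logRankPerTime(tt, ss, gg))
}

# Per-event-time hypergeometric table; plain R, used for reporting and as a
# readable statement of the same accumulation the C++ kernel performs.
.logRankPerTime <- function(tt, ss, gg) {
  et <- unique(tt[ss == 1L])
  if (!length(et))
    return(data.frame(time = numeric(0), d1 = integer(0), d2 = integer(0),
                      n1 = integer(0), n2 = integer(0), E1 = numeric(0),
                      V = numeric(0)))
  rows <- lapply(et, function(u) {
    at <- tt >= u
    n1 <- sum(at & gg == 1L); n2 <- sum(at & gg == 0L)
    d1 <- sum(tt == u & ss == 1L & gg == 1L)
    d2 <- sum(tt == u & ss == 1L & gg == 0L)
    n <- n1 + n2; d <- d1 + d2
    V <- if (n > 1) (n - d) * d * n1 * n2 / ((n - 1) * n^2) else 0
    data.frame(time = u, d1 = d1, d2 = d2, n1 = n1, n2 = n2,
               E1 = d * n1 / n, V = V)
  })
  do.call(rbind, rows)
}

#' @describeIn KMCurve-class display the number of event times and the
#'   median.
#' @param object a `KMCurve`.
#' @export
setMethod("show", "KMCurve", function(object) {
  cat("KMCurve with", length(object@eventTimes), "distinct event times\n")
  if (length(object@eventTimes)) {
    med <- kmMedian(object)
    cat("  median survival:",
        if (is.na(med)) "not estimable" else format(med), "\n")
    cat("  S(t) range: [", format(min(object@survival)), ", ",
        format(max(object@survival)), "]\n", sep = "")
  } else cat("  no events: S(t) = 1 everywhere\n")
})

#' @describeIn LogRankResult-class display the statistic and score.
#' @param object a `LogRankResult`.
#' @export
setMethod("show", "LogRankResult", function(object) {
  cat("Two-sample log-rank test\n")
  cat("  Z      =", format(object@statistic), "\n")
  cat("  Z^2    =", format(object@score), "\n")
  cat("  O - E  =", format(object@obsMinusExp),
      " Var =", format(object@variance), "\n")
  cat("  event times used:", nrow(object@perTime), "\n")
})
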