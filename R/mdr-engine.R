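# RNG discipline: every stochastic entry point takes an integer seed, runs
# under a locally restored RNG state, and derives any sub-seeds it needs
# with .subSeeds(). Fixed seed => bit-identical output.

.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      stats::runif(1L)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
  }
  expr
}

.subSeeds <- function(seed, n) {
  .withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Stratified cross-validation folds
#'
#' Randomly partitions subjects into `k` folds, stratified by event status
#' so that each fold's censoring fraction matches the overall fraction as
#' closely as an integer partition allows: within each status stratum the
#' fold sizes differ by at most one.
#'
#' @param status event indicators (1 = event, 0 = censored), one per
#'   subject; an [MdrSurvData-class] object is also accepted.
#' @param k number of folds (default 10).
#' @param seed integer seed; the assignment is deterministic given the seed.
#' @return Integer vector of fold ids in 1..k, one per subject, with
#'   attributes `k` and `seed`.
#' @examples
#' f <- makeFolds(rep(c(0, 1), 50), k = 10, seed = 7)
#' table(f)
#' @export
makeFolds <- function(status, k = 10L, seed = NULL) {
  if (is(status, "MdrSurvData")) status <- survStatus(status)
  n <- length(status)
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (n < k) stop("need at least k subjects to make k folds", call. = FALSE)
  if (!all(status %in% c(0, 1)))
    stop("status must be 0 or 1", call. = FALSE)
  fold <- integer(n)
  .withSeed(seed, {
    for (s in unique(status)) {
      idx <- which(status == s)
      m <- length(idx)
      # random fold order, cycled: per-stratum sizes differ by at most 1
      fold[sample(idx)] <- rep_len(sample.int(k), m)
    }
  })
  attr(fold, "k") <- k
  attr(fold, "seed") <- seed
  fold
}

# Balanced accuracy of predicted cell labels against score-sign
# pseudo-labels; an absent class contributes the chance value 0.5.
.balancedAccuracy <- function(pseudo, pred) {
  sens <- if (any(pseudo)) mean(pred[pseudo] == 1L) else 0.5
  spec <- if (any(!pseudo)) mean(pred[!pseudo] == 0L) else 0.5
  0.5 * (sens + spec)
}

# Core exhaustive q-way search over pre-sorted data.
# tt, ss, Gs, ff: time/status/genotypes/folds sorted by time; scores:
# per-subject null-model scores (cox/aft), aligned with tt.
.cvSearchOnce <- function(tt, ss, Gs, ff, k, q, method, scores = NULL) {
  n <- length(tt)
  p <- ncol(Gs)
  combos <- utils::combn(p, q)        # lexicographic order
  nc <- ncol(combos)
  ncells <- 3L^q
  pow <- 3L^((q - 1L):0L)
  cellAll <- matrix(0L, n, nc)
  for (cc in seq_len(nc))
    cellAll[, cc] <- as.integer(Gs[, combos[, cc], drop = FALSE] %*% pow)
  trainScore <- matrix(NA_real_, nc, k)
  testLab <- matrix(NA_integer_, n, nc)
  foldFailed <- logical(k)
  winners <- rep(NA_integer_, k)
  scoreBased <- method %in% c("cox", "aft")
  for (f in seq_len(k)) {
    trw <- which(ff != f)
    tew <- which(ff == f)
    t_tr <- tt[trw]
    s_tr <- ss[trw]
    if (method == "km") {
      tm <- .cppKmMedian(t_tr, s_tr)
      if (is.na(tm)) { foldFailed[f] <- TRUE; next }
    } else if (sum(s_tr) == 0L) { foldFailed[f] <- TRUE; next }
    if (scoreBased) ps_tr <- scores[trw] > 0
    for (cc in seq_len(nc)) {
      cellv <- cellAll[trw, cc]
      labs <- if (method == "km") {
        .cppClassifyKm(t_tr, s_tr, cellv, ncells, tm)$labels
      } else if (method == "surv") {
        .cppClassifySurv(t_tr, s_tr, cellv, ncells)$labels
      } else {
        sums <- numeric(ncells)
        ag <- rowsum(scores[trw], cellv)
        sums[as.integer(rownames(ag)) + 1L] <- ag[, 1L]
        as.integer(sums > 0)
      }
      g_tr <- labs[cellv + 1L]
      trainScore[cc, f] <- if (scoreBased) .balancedAccuracy(ps_tr, g_tr)
                           else .cppLogrankScore(t_tr, s_tr, g_tr)
      testLab[tew, cc] <- labs[cellAll[tew, cc] + 1L]
    }
    winners[f] <- which.max(trainScore[, f])  # ties -> lexicographic first
  }
  nFailed <- sum(foldFailed)
  cvc <- tabulate(winners[!is.na(winners)], nc)
  skipped <- nFailed > k / 2
  testScore <- rep(NA_real_, nc)
  if (!skipped) {
    psAll <- if (scoreBased) scores > 0
    for (cc in seq_len(nc)) {
      ok <- which(!is.na(testLab[, cc]))
      testScore[cc] <- if (scoreBased)
        .balancedAccuracy(psAll[ok], testLab[ok, cc])
      else .cppLogrankScore(tt[ok], ss[ok], testLab[ok, cc])
    }
  }
  trainMean <- rowMeans(trainScore[, !foldFailed, drop = FALSE])
  if (all(foldFailed)) trainMean <- rep(NA_real_, nc)
  list(combos = combos, trainingScore = trainMean, testingScore = testScore,
       cvc = cvc, winners = winners, foldFailed = foldFailed,
       skipped = rep(skipped, nc))
}

.unpackData <- function(data) {
  if (is(data, "MdrSurvData")) {
    list(time = survTime(data), status = survStatus(data),
         covariates = covariateMatrix(data), G = genotypes(data),
         snpIds = rownames(data))
  } else if (is.list(data)) {
    G <- .checkGenoMatrix(data$genotypes, length(data$time))
    list(time = data$time, status = as.integer(data$status),
         covariates = data$covariates, G = G,
         snpIds = colnames(G) %||% paste0("SNP", seq_len(ncol(G))))
  } else stop("data must be an MdrSurvData or a list", call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.nullScoresFor <- function(method, time, status, covariates) {
  switch(method,
         cox = coxNullScores(time, status, covariates),
         aft = aftNullScores(time, status, covariates),
         NULL)
}

.orderResults <- function(res, selectionOrder) {
  if (selectionOrder == "cvc_first")
    order(res$skipped, -res$cvc, -res$testingScore, seq_len(nrow(res)))
  else
    order(res$skipped, -res$testingScore, -res$cvc, seq_len(nrow(res)))
}

#' Exhaustive cross-validated q-way interaction search
#'
#' For every combination of q SNPs, trains the chosen cell classifier on
#' each of k training folds, scores it on the training fold (squared
#' log-rank of pooled HIGH vs LOW for the "km" and "surv" methods; balanced
#' accuracy against score-sign pseudo-labels for "cox" and "aft"), labels
#' the held-out fold with the trained rule, and computes one pooled testing
#' score on the union of all held-out folds. Cross-validation consistency
#' (CVC) counts the folds in which a combination attains the maximum
#' training score (ties broken toward the lexicographically smallest SNP
#' tuple). Training folds where a method is not applicable (e.g. the overall
#' KM median is not estimable) are marked failed; a search in which more
#' than half the folds fail yields no scored models.
#'
#' @param data an [MdrSurvData-class], or a list with elements `time`,
#'   `status`, `genotypes` (subjects x SNPs), optionally `covariates`.
#' @param q interaction order (number of SNPs per combination).
#' @param method one of `"km"`, `"surv"`, `"cox"`, `"aft"`.
#' @param folds fold assignment from [makeFolds()]; built from `seed` when
#'   omitted.
#' @param k fold count used when `folds` is omitted.
#' @param seed integer seed for fold construction (and repeats).
#' @param selectionOrder `"test_score_first"` (maximum testing score, CVC as
#'   tie-break) or `"cvc_first"` (maximum CVC, testing score as tie-break).
#' @param cvRepeats number of independent cross-validation repetitions;
#'   testing and training scores are averaged and CVC summed over repeats.
#' @return A [MdrSearchReport-class].
#' @examples
#' sim <- buildDataset(simConfig(n = 150, p = 4, seed = 11))
#' rep1 <- runCV(sim$data, q = 2, method = "km", seed = 3)
#' bestModel(rep1)$model
#' @export
runCV <- function(data, q, method = c("km", "surv", "cox", "aft"),
                  folds = NULL, k = 10L, seed = NULL,
                  selectionOrder = c("test_score_first", "cvc_first"),
                  cvRepeats = 1L) {
  method <- match.arg(method)
  selectionOrder <- match.arg(selectionOrder)
  d <- .unpackData(data)
  p <- ncol(d$G)
  if (q < 1L || q > p) stop("need 1 <= q <= p", call. = FALSE)
  n <- length(d$time)
  if (is.null(folds)) {
    if (is.null(seed) && cvRepeats == 1L)
      stop("provide folds or a seed", call. = FALSE)
    foldSeeds <- .subSeeds(seed, cvRepeats)
    foldsList <- lapply(foldSeeds, function(s) makeFolds(d$status, k, s))
  } else {
    if (length(folds) != n)
      stop("folds must assign every subject", call. = FALSE)
    k <- max(attr(folds, "k") %||% max(folds))
    foldsList <- list(folds)
    if (cvRepeats > 1L)
      foldsList <- c(foldsList,
                     lapply(.subSeeds(seed %||% 1L, cvRepeats - 1L),
                            function(s) makeFolds(d$status, k, s)))
  }
  scores <- .nullScoresFor(method, d$time, d$status, d$covariates)
  ord <- order(d$time)
  tt <- as.numeric(d$time[ord])
  ss <- as.integer(d$status[ord])
  Gs <- d$G[ord, , drop = FALSE]
  sc <- if (!is.null(scores)) scores[ord]
  runs <- lapply(foldsList, function(fl)
    .cvSearchOnce(tt, ss, Gs, fl[ord], k, q, method, sc))
  r1 <- runs[[1L]]
  nc <- ncol(r1$combos)
  agg <- function(field) {
    m <- vapply(runs, `[[`, numeric(nc), field)
    rowMeans(matrix(m, nrow = nc))
  }
  modelNames <- apply(r1$combos, 2L,
                      function(ix) paste(d$snpIds[ix], collapse = ","))
  res <- data.frame(
    model = modelNames,
    trainingScore = agg("trainingScore"),
    testingScore = agg("testingScore"),
    cvc = as.integer(Reduce(`+`, lapply(runs, `[[`, "cvc"))),
    pValue = NA_real_,
    failedFolds = as.integer(Reduce(`+`, lapply(runs,
                               function(r) rep(sum(r$foldFailed), nc)))),
    skipped = Reduce(`|`, lapply(runs, `[[`, "skipped")),
    stringsAsFactors = FALSE)
  ranked <- res[.orderResults(res, selectionOrder), , drop = FALSE]
  best <- if (nrow(ranked) && !ranked$skipped[1L] &&
              is.finite(ranked$testingScore[1L])) {
    i <- rownames(ranked)[1L]
    list(model = ranked$model[1L],
         snpIndices = r1$combos[, as.integer(i)],
         trainingScore = ranked$trainingScore[1L],
         testingScore = ranked$testingScore[1L],
         cvc = ranked$cvc[1L], q = as.integer(q), method = method,
         pValue = NA_real_)
  } else list()
  new("MdrSearchReport", method = method, q = as.integer(q),
      results = ranked, best = best, folds = as.integer(foldsList[[1L]]),
      settings = list(k = k, selectionOrder = selectionOrder,
                      seed = seed, cvRepeats = cvRepeats),
      perFold = list(winners = lapply(runs, `[[`, "winners"),
                     foldFailed = lapply(runs, `[[`, "foldFailed")))
}

#' Per-fold detail for one SNP combination
#'
#' Recomputes, for a single combination, the k per-fold training
#' classifications and training scores underlying a [runCV()] report.
#'
#' @param data as in [runCV()].
#' @param snpIndices integer vector of q SNP column indices.
#' @param method classifier method.
#' @param folds fold assignment used in the original search.
#' @return List of k entries: `fold`, `trainingScore`,
#'   `classification` (a [CellClassification-class], or `NULL` for a failed
#'   fold).
#' @export
perFoldDetail <- function(data, snpIndices, method = "km", folds) {
  d <- .unpackData(data)
  k <- attr(folds, "k") %||% max(folds)
  scores <- .nullScoresFor(method, d$time, d$status, d$covariates)
  lapply(seq_len(k), function(f) {
    tr <- folds != f
    g_tr <- d$G[tr, snpIndices, drop = FALSE]
    cl <- tryCatch(switch(method,
            km = classifyKM(g_tr, d$time[tr], d$status[tr]),
            surv = classifySurv(g_tr, d$time[tr], d$status[tr]),
            classifyScores(g_tr, scores[tr])),
          error = function(e) NULL)
    sc <- if (is.null(cl)) NA_real_ else {
      g <- assignGroups(cl, g_tr)
      if (method %in% c("km", "surv")) {
        o <- order(d$time[tr])
        .cppLogrankScore(as.numeric(d$time[tr][o]),
                         as.integer(d$status[tr][o]), g[o])
      } else .balancedAccuracy(scores[tr] > 0, g)
    }
    list(fold = f, trainingScore = sc, classification = cl)
  })
}

#' Select the overall best model across interaction orders
#'
#' Applies the selection rule to a list of [runCV()] reports (one per q):
#' maximum testing score, ties broken by higher CVC, then by the more
#' parsimonious model (smaller q), then by lexicographic SNP tuple. With
#' `selectionOrder = "cvc_first"` CVC is primary and the testing score
#' breaks ties.
#'
#' @param reports list of [MdrSearchReport-class] objects.
#' @param selectionOrder see [runCV()].
#' @return The best model description (list, as in `bestModel()`), with a
#'   `q` element.
#' @export
selectBest <- function(reports,
                       selectionOrder = c("test_score_first", "cvc_first")) {
  selectionOrder <- match.arg(selectionOrder)
  cands <- Filter(function(b) length(b) > 0, lapply(reports, bestModel))
  if (!length(cands)) stop("no model could be fit in any report",
                           call. = FALSE)
  ts <- vapply(cands, `[[`, numeric(1), "testingScore")
  cvc <- vapply(cands, `[[`, numeric(1), "cvc")
  qs <- vapply(cands, `[[`, integer(1), "q")
  o <- if (selectionOrder == "cvc_first") order(-cvc, -ts, qs)
       else order(-ts, -cvc, qs)
  cands[[o[1L]]]
}

#' Permutation p-value for the selected model
#'
#' Permutes the (time, status) pairs jointly against the genotype rows and
#' reruns the cross-validated pipeline for each permutation. With
#' `nullStatistic = "max"` (the default) the null statistic is the maximum
#' testing score over all q-way combinations — a family-wise calibrated
#' reference for a model selected by exhaustive search. With
#' `nullStatistic = "model"` the pipeline is rerun for one fixed SNP
#' combination only (by default the observed best model) and its testing
#' score is the null statistic — the cheaper per-model reference, markedly
#' less conservative because it ignores the selection step.
#' p = (1 + #\{null >= observed\}) / (1 + B).
#'
#' @inheritParams runCV
#' @param B number of permutations (default 1000).
#' @param nullStatistic `"max"` (family-wise) or `"model"` (per-model).
#' @param snpIndices SNP column indices of the fixed combination for
#'   `nullStatistic = "model"`; defaults to the observed best model.
#' @return List: `observed` (the observed value of the chosen statistic),
#'   `pValue`, `nullScores` (length B), and `report` (the observed-data
#'   [MdrSearchReport-class]).
#' @export
permutationTest <- function(data, q, method = "km", B = 1000L, seed = NULL,
                            k = 10L,
                            selectionOrder = "test_score_first",
                            nullStatistic = c("max", "model"),
                            snpIndices = NULL) {
  if (B < 1L) stop("B must be >= 1", call. = FALSE)
  nullStatistic <- match.arg(nullStatistic)
  d <- .unpackData(data)
  n <- length(d$time)
  seeds <- .subSeeds(seed, 2L * B + 1L)
  obsRep <- runCV(list(time = d$time, status = d$status,
                       covariates = d$covariates, genotypes = d$G),
                  q, method, k = k, seed = seeds[1L],
                  selectionOrder = selectionOrder)
  if (nullStatistic == "model") {
    if (is.null(snpIndices)) snpIndices <- bestModel(obsRep)$snpIndices
    G <- d$G[, snpIndices, drop = FALSE]
    q <- length(snpIndices)
  } else G <- d$G
  oneScore <- function(time, status, covariates, foldSeed) {
    r <- runCV(list(time = time, status = status, covariates = covariates,
                    genotypes = G),
               q, method, k = k, seed = foldSeed,
               selectionOrder = selectionOrder)
    if (nrow(r@results)) max(r@results$testingScore, na.rm = TRUE) else 0
  }
  obs <- if (nullStatistic == "model")
    oneScore(d$time, d$status, d$covariates, seeds[1L])
  else max(obsRep@results$testingScore, na.rm = TRUE)
  nullScores <- vapply(seq_len(B), function(b) {
    perm <- .withSeed(seeds[b + 1L], sample.int(n))
    oneScore(d$time[perm], d$status[perm],
             if (!is.null(d$covariates)) d$covariates[perm, , drop = FALSE],
             seeds[B + 1L + b])
  }, numeric(1))
  list(observed = obs,
       pValue = (1 + sum(nullScores >= obs)) / (1 + B),
       nullScores = nullScores, report = obsRep)
}

#' One-call MDR analysis
#'
#' Runs the exhaustive search for each interaction order in
#' `qMin:qMax` (folds shared across orders), selects the overall best model,
#' and optionally attaches a permutation p-value to it.
#'
#' @inheritParams runCV
#' @param qMin,qMax range of interaction orders to search.
#' @param B permutations for the best model's p-value (0 = skip).
#' @return List: `reports` (one [MdrSearchReport-class] per q), `best`, and
#'   `groups` — the pooled cross-validated high/low assignment of every
#'   subject under the best model (for survival-curve plotting).
#' @export
runMdr <- function(data, qMin = 2L, qMax = 2L,
                   method = c("km", "surv", "cox", "aft"),
                   k = 10L, B = 0L, seed = NULL,
                   selectionOrder = c("test_score_first", "cvc_first"),
                   cvRepeats = 1L) {
  method <- match.arg(method)
  selectionOrder <- match.arg(selectionOrder)
  d <- .unpackData(data)
  seeds <- .subSeeds(seed, 2L)
  folds <- makeFolds(d$status, k, seeds[1L])
  reports <- lapply(qMin:qMax, function(q)
    runCV(data, q, method, folds = folds, selectionOrder = selectionOrder,
          cvRepeats = cvRepeats, seed = seeds[2L]))
  names(reports) <- paste0("q", qMin:qMax)
  best <- selectBest(reports, selectionOrder)
  if (B > 0L) {
    pt <- permutationTest(data, best$q, method, B = B, seed = seeds[2L],
                          k = k, selectionOrder = selectionOrder)
    best$pValue <- pt$pValue
  }
  groups <- .pooledGroups(d, best$snpIndices, method, folds)
  list(reports = reports, best = best, groups = groups, folds = folds)
}

# Pooled cross-validated H/L assignment of all subjects for one model.
.pooledGroups <- function(d, snpIndices, method, folds) {
  k <- attr(folds, "k") %||% max(folds)
  scores <- .nullScoresFor(method, d$time, d$status, d$covariates)
  out <- rep(NA_integer_, length(d$time))
  for (f in seq_len(k)) {
    tr <- folds != f
    cl <- tryCatch(switch(method,
            km = classifyKM(d$G[tr, snpIndices, drop = FALSE],
                            d$time[tr], d$status[tr]),
            surv = classifySurv(d$G[tr, snpIndices, drop = FALSE],
                                d$time[tr], d$status[tr]),
            classifyScores(d$G[tr, snpIndices, drop = FALSE], scores[tr])),
          error = function(e) NULL)
    if (!is.null(cl))
      out[!tr] <- suppressWarnings(
        assignGroups(cl, d$G[!tr, snpIndices, drop = FALSE]))
  }
  out
}

#' @rdname MdrSearchReport-class
#' @export
setMethod("bestModel", "MdrSearchReport", function(x, ...) x@best)

#' @rdname MdrSearchReport-class
#' @export
setMethod("resultsTable", "MdrSearchReport", function(x) {
  x@results[, c("model", "trainingScore", "testingScore", "cvc", "pValue",
                "failedFolds")]
})

#' @describeIn MdrSearchReport-class display the top-ranked models.
#' @param object a `MdrSearchReport`.
#' @export
setMethod("show", "MdrSearchReport", function(object) {
  cat(sprintf("MdrSearchReport: method = %s, q = %d, %d combinations\n",
              object@method, object@q, nrow(object@results)))
  if (length(object@best))
    cat("  best:", object@best$model,
        sprintf("(testing score %.4f, CVC %d/%d)\n",
                object@best$testingScore, object@best$cvc,
                object@settings$k))
  print(utils::head(resultsTable(object), 5L))
})
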