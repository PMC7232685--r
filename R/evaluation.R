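# Monte-Carlo operating characteristics: type-I error (designated-pair
# selection rate under null data) and power (causal-pair selection rate),
# estimated over independently simulated datasets with per-dataset seeds
# derived deterministically from one master seed.

.operatingPoint <- function(method, maf, h2, survivalModel, gamma,
                            censoringFraction, nDatasets, hits, nFailed) {
  est <- hits / nDatasets
  data.frame(method = method, maf = maf, h2 = h2,
             survivalModel = survivalModel, gamma = gamma,
             censoringFraction = censoringFraction, nDatasets = nDatasets,
             estimate = est,
             mcStderr = sqrt(est * (1 - est) / nDatasets),
             nFailed = nFailed, stringsAsFactors = FALSE)
}

.sameModel <- function(best, pair) {
  length(best) > 0 && identical(sort(as.integer(best$snpIndices)),
                                sort(as.integer(pair)))
}

#' Type-I error of the two-way interaction search
#'
#' Simulates null datasets (no SNP affects survival), runs the full 2-way
#' cross-validated search on each, and estimates the probability that a
#' pre-designated pair (SNPs 1 and 2 by default) is selected as the best
#' model. Under exchangeability of the p null SNPs, the uniform reference
#' rate is 1 / choose(p, 2) — 1/28 = 0.03577 with 8 SNPs; datasets in which
#' no model can be selected (e.g. overall medians not estimable under heavy
#' censoring) lower the rate.
#'
#' @param method classifier method passed to [runCV()].
#' @param maf minor allele frequency of all (non-causal) SNPs.
#' @param censoringFraction target expected censored fraction.
#' @param nDatasets number of null datasets.
#' @param seed master seed.
#' @param n,p subjects and SNPs per dataset.
#' @param pair the designated pair whose selection is counted.
#' @param survivalModel generator of the null survival times ("cox" =
#'   Weibull baseline; the null has no genotype effect either way).
#' @param k,selectionOrder cross-validation settings, see [runCV()].
#' @return One-row data.frame (an operating point): the estimate, its
#'   binomial Monte-Carlo standard error, and the number of datasets in
#'   which no model was selected.
#' @examples
#' estimateType1(maf = 0.3, censoringFraction = 0, nDatasets = 5, seed = 1)
#' @export
estimateType1 <- function(method = "km", maf, censoringFraction,
                          nDatasets, seed = NULL, n = 400L, p = 8L,
                          pair = c(1L, 2L), survivalModel = "cox",
                          k = 10L, selectionOrder = "test_score_first") {
  cfg0 <- simConfig(survivalModel, n = n, p = p, maf = maf,
                    censoringFraction = censoringFraction)
  cb <- if (censoringFraction > 0)
    calibrateCensoring(censoringFraction,
                       .latentSamplerFor(cfg0, function(m) rep(0L, m)),
                       seed = .subSeeds(seed, 1L))
  seeds <- matrix(.subSeeds(seed, 2L * nDatasets), ncol = 2L)
  hits <- 0L; nFailed <- 0L
  for (i in seq_len(nDatasets)) {
    cfg <- simConfig(survivalModel, n = n, p = p, maf = maf,
                     censoringFraction = censoringFraction,
                     censorBound = cb, seed = seeds[i, 1L])
    sim <- buildDataset(cfg)
    best <- tryCatch(
      bestModel(runCV(sim$data, q = 2L, method = method, k = k,
                      seed = seeds[i, 2L],
                      selectionOrder = selectionOrder)),
      error = function(e) list())
    if (!length(best)) nFailed <- nFailed + 1L
    else if (.sameModel(best, pair)) hits <- hits + 1L
  }
  .operatingPoint(method, maf, NA_real_, survivalModel,
                  gamma = 0, censoringFraction, nDatasets, hits, nFailed)
}

#' Power of the two-way interaction search
#'
#' Simulates datasets with a purely epistatic causal pair and estimates,
#' for each requested method, the probability that the causal pair is
#' selected as the best two-way model. All methods are evaluated on
#' identical datasets and identical folds (a paired design that removes
#' between-method Monte-Carlo noise from power contrasts).
#'
#' @param methods character vector of classifier methods.
#' @param scenario list with elements `maf`, `h2`, `modelSeed` (penetrance
#'   model seed), `survivalModel`, `gamma`, `censoringFraction`, and
#'   optionally `n` (400) and `p` (10).
#' @param nDatasets datasets per operating point.
#' @param seed master seed.
#' @param k,selectionOrder cross-validation settings.
#' @return data.frame with one operating-point row per method.
#' @examples
#' sc <- list(maf = 0.2, h2 = 0.4, modelSeed = 3, survivalModel = "cox",
#'            gamma = 0, censoringFraction = 0)
#' estimatePower("km", sc, nDatasets = 3, seed = 2)
#' @export
estimatePower <- function(methods = c("km", "surv", "cox", "aft"),
                          scenario, nDatasets, seed = NULL, k = 10L,
                          selectionOrder = "test_score_first") {
  n <- scenario$n %||% 400L
  p <- scenario$p %||% 10L
  pm <- generatePenetrance(scenario$maf, scenario$h2, scenario$modelSeed)
  cfg0 <- simConfig(scenario$survivalModel, n = n, p = p,
                    maf = scenario$maf, causalPair = c(1L, 2L),
                    penetrance = pm, gamma = scenario$gamma,
                    censoringFraction = scenario$censoringFraction)
  cb <- if (scenario$censoringFraction > 0)
    calibrateCensoring(scenario$censoringFraction,
                       .latentSamplerFor(cfg0, function(m)
                         assignRisk(sampleGenotypes(m, 2L, scenario$maf),
                                    pm)),
                       seed = .subSeeds(seed, 1L))
  seeds <- matrix(.subSeeds(seed, 2L * nDatasets), ncol = 2L)
  hits <- stats::setNames(integer(length(methods)), methods)
  nFailed <- stats::setNames(integer(length(methods)), methods)
  for (i in seq_len(nDatasets)) {
    cfg <- simConfig(scenario$survivalModel, n = n, p = p,
                     maf = scenario$maf, causalPair = c(1L, 2L),
                     penetrance = pm, gamma = scenario$gamma,
                     censoringFraction = scenario$censoringFraction,
                     censorBound = cb, seed = seeds[i, 1L])
    sim <- buildDataset(cfg)
    folds <- makeFolds(survStatus(sim$data), k, seeds[i, 2L])
    for (m in methods) {
      best <- tryCatch(
        bestModel(runCV(sim$data, q = 2L, method = m, folds = folds,
                        selectionOrder = selectionOrder)),
        error = function(e) list())
      if (!length(best)) nFailed[m] <- nFailed[m] + 1L
      else if (.sameModel(best, c(1L, 2L))) hits[m] <- hits[m] + 1L
    }
  }
  do.call(rbind, lapply(methods, function(m)
    .operatingPoint(m, scenario$maf, scenario$h2, scenario$survivalModel,
                    scenario$gamma, scenario$censoringFraction, nDatasets,
                    hits[m], nFailed[m])))
}

#' The full simulation design grid
#'
#' Enumerates (without executing) the Cartesian simulation design: 5
#' penetrance models for each of 14 (MAF, heritability) combinations — 70
#' epistatic models — crossed with 2 survival models, 2 covariate effects
#' and 4 censoring fractions: 1,120 cells.
#'
#' @param mafs,h2s,modelSeeds,survivalModels,gammas,censoringFractions
#'   grid axes; defaults are the package's study conditions.
#' @return data.frame with one row per grid cell.
#' @examples
#' nrow(fullSimulationGrid())  # 1120
#' @export
fullSimulationGrid <- function(mafs = c(0.2, 0.4),
                               h2s = c(0.01, 0.025, 0.05, 0.1, 0.2, 0.3,
                                       0.4),
                               modelSeeds = 1:5,
                               survivalModels = c("cox", "aft"),
                               gammas = c(0, 1),
                               censoringFractions = c(0, 0.1, 0.3, 0.5)) {
  g <- expand.grid(maf = mafs, h2 = h2s, modelSeed = modelSeeds,
                   survivalModel = survivalModels, gamma = gammas,
                   censoringFraction = censoringFractions,
                   stringsAsFactors = FALSE)
  g[order(g$survivalModel, g$gamma, g$censoringFraction, g$maf, g$h2,
          g$modelSeed), , drop = FALSE]
}

#' Execute a grid of power operating points
#'
#' Runs [estimatePower()] for every row of a design grid (as produced by
#' [fullSimulationGrid()] or any subset), with per-cell seeds derived
#' deterministically from the master seed. Failures in a cell are recorded
#' and the sweep continues.
#'
#' @param grid data.frame with columns maf, h2, modelSeed, survivalModel,
#'   gamma, censoringFraction.
#' @param nDatasets datasets per cell.
#' @param seed master seed.
#' @param methods classifier methods evaluated per cell.
#' @param ... further arguments to [estimatePower()].
#' @return Tidy data.frame of operating points (one row per cell x method);
#'   failed cells yield a row with `NA` estimate and the error message in
#'   attribute `errors`.
#' @export
runSweep <- function(grid, nDatasets, seed = NULL,
                     methods = c("km", "surv", "cox", "aft"), ...) {
  seeds <- .subSeeds(seed, nrow(grid))
  errs <- character()
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sc <- as.list(grid[i, , drop = FALSE])
    tryCatch(estimatePower(methods, sc, nDatasets, seed = seeds[i], ...),
             error = function(e) {
               errs[[length(errs) + 1L]] <<- conditionMessage(e)
               .operatingPoint(paste(methods, collapse = "/"), sc$maf,
                               sc$h2, sc$survivalModel, sc$gamma,
                               sc$censoringFraction, nDatasets, NA_integer_,
                               NA_integer_)
             })
  })
  out <- do.call(rbind, rows)
  attr(out, "errors") <- errs
  out
}
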