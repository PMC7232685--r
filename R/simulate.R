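# Simulation of survival datasets with a purely epistatic two-locus effect.
#
# Latent high-risk status x is Bernoulli(f at the subject's two-locus cell);
# survival times then follow either a proportional-hazards model with
# Weibull baseline, lambda(t | x, z) = lambda0(t) exp(x beta + z gamma)
# with S0(t) = exp(-(t/b)^a) (a = shape, b = scale), or a log-normal
# accelerated failure time model log T = mu + x beta + z gamma + sigma eps.
# Censoring times are Uniform(0, c) with c calibrated by Monte-Carlo
# bisection to hit a target expected censored fraction.

#' Simulation configuration
#'
#' Bundles and validates the parameters of one simulated dataset. Defaults
#' are the package's study conditions: 400 subjects, 10 SNPs, causal pair
#' (1, 2), Cox model with beta = 1.2 on the latent risk indicator and a
#' Weibull(shape 5, scale 2) baseline, or AFT with mu = 0, beta = -1,
#' sigma = 1; covariate effect gamma 0 or 1; censoring fraction in
#' \{0, 0.1, 0.3, 0.5\}.
#'
#' @param survivalModel `"cox"` or `"aft"`.
#' @param n number of subjects.
#' @param p number of SNPs.
#' @param maf minor allele frequency, recycled across SNPs.
#' @param causalPair integer pair of causal SNP indices, or `NULL` for a
#'   null (no-effect) dataset.
#' @param penetrance a [PenetranceModel-class]; required when `causalPair`
#'   is non-NULL.
#' @param beta effect of the latent high-risk indicator x.
#' @param gamma effect of the standard-normal covariate z (0 = no
#'   covariate).
#' @param sigma AFT error scale.
#' @param mu AFT intercept.
#' @param shape,scale Weibull baseline parameters of the Cox model.
#' @param censoringFraction target expected censored fraction in \[0, 1).
#' @param censorBound optional pre-calibrated upper bound of the
#'   Uniform(0, c) censoring distribution; when `NULL` and censoring is
#'   requested, [calibrateCensoring()] is run inside [buildDataset()].
#' @param seed integer seed.
#' @return A validated list of class `kmmdr_sim_config`.
#' @examples
#' cfg <- simConfig(n = 200, p = 6, seed = 1)
#' @export
simConfig <- function(survivalModel = c("cox", "aft"), n = 400L, p = 10L,
                      maf = 0.2, causalPair = NULL, penetrance = NULL,
                      beta = NULL, gamma = 0, sigma = 1, mu = 0,
                      shape = 5, scale = 2, censoringFraction = 0,
                      censorBound = NULL, seed = NULL) {
  survivalModel <- match.arg(survivalModel)
  if (is.null(beta)) beta <- if (survivalModel == "cox") 1.2 else -1.0
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (censoringFraction < 0 || censoringFraction >= 1)
    stop("censoringFraction must lie in [0, 1)", call. = FALSE)
  if (!is.null(causalPair)) {
    causalPair <- as.integer(causalPair)
    if (length(causalPair) != 2L || anyDuplicated(causalPair) ||
        any(causalPair < 1L) || any(causalPair > p))
      stop("causalPair must be two distinct SNP indices <= p", call. = FALSE)
    if (is.null(penetrance))
      stop("a penetrance model is required with a causal pair",
           call. = FALSE)
  }
  structure(list(survivalModel = survivalModel, n = as.integer(n),
                 p = as.integer(p), maf = maf, causalPair = causalPair,
                 penetrance = penetrance, beta = beta, gamma = gamma,
                 sigma = sigma, mu = mu, shape = shape, scale = scale,
                 censoringFraction = censoringFraction,
                 censorBound = censorBound, seed = seed),
            class = "kmmdr_sim_config")
}

#' Sample genotypes under Hardy-Weinberg and linkage equilibrium
#'
#' Each SNP column is an independent Binomial(2, maf) draw per subject.
#'
#' @param n subjects.
#' @param p SNPs.
#' @param maf minor allele frequency, scalar or length p.
#' @param seed integer seed.
#' @return Integer matrix n x p with column names SNP1..SNPp.
#' @export
sampleGenotypes <- function(n, p, maf, seed = NULL) {
  maf <- rep_len(maf, p)
  if (any(maf <= 0 | maf > 0.5))
    stop("each maf must lie in (0, 0.5]", call. = FALSE)
  .withSeed(seed, {
    g <- vapply(maf, function(m) stats::rbinom(n, 2L, m), integer(n))
    g <- matrix(as.integer(g), n, p,
                dimnames = list(paste0("subject", seq_len(n)),
                                paste0("SNP", seq_len(p))))
    g
  })
}

#' Latent high-risk status from a penetrance model
#'
#' Draws x_i ~ Bernoulli(f at subject i's two-locus genotype cell).
#'
#' @param geno2 integer matrix n x 2: genotypes at the causal pair.
#' @param penetrance a [PenetranceModel-class].
#' @param seed integer seed.
#' @return Integer 0/1 vector of latent risk indicators.
#' @export
assignRisk <- function(geno2, penetrance, seed = NULL) {
  geno2 <- .checkGenoMatrix(geno2, NROW(geno2))
  if (ncol(geno2) != 2L) stop("geno2 must have two columns", call. = FALSE)
  pr <- penetrance@f[cbind(geno2[, 1L] + 1L, geno2[, 2L] + 1L)]
  .withSeed(seed, stats::rbinom(nrow(geno2), 1L, pr))
}

.latentCox <- function(n, eta, shape, scale) {
  u <- stats::runif(n)
  scale * (-log(u) / exp(eta))^(1 / shape)
}

.latentAft <- function(n, eta, mu, sigma) {
  exp(mu + eta + sigma * stats::rnorm(n))
}

.applyCensoring <- function(latent, censorBound, seed = NULL) {
  n <- length(latent)
  if (is.null(censorBound))
    return(list(time = latent, status = rep(1L, n)))
  .withSeed(seed, {
    cens <- stats::runif(n, 0, censorBound)
    list(time = pmin(latent, cens), status = as.integer(latent <= cens))
  })
}

#' Simulate survival outcomes from the Cox (Weibull-baseline) model
#'
#' Latent times are inverse-transform draws from
#' S(t | x, z) = exp(-(t / scale)^shape * exp(x beta + z gamma)); observed
#' time and status come from independent Uniform(0, censorBound) censoring
#' (none when `censorBound` is `NULL`).
#'
#' @param x 0/1 latent risk indicator per subject.
#' @param z covariate per subject (0 allowed).
#' @param cfg a [simConfig()] with `survivalModel = "cox"`.
#' @param censorBound Uniform censoring upper bound, or `NULL`.
#' @param seed integer seed.
#' @return List with `time` and `status`.
#' @export
simulateCox <- function(x, z = 0, cfg = simConfig("cox"),
                        censorBound = NULL, seed = NULL) {
  n <- length(x)
  z <- rep_len(z, n)
  .withSeed(seed, {
    latent <- .latentCox(n, x * cfg$beta + z * cfg$gamma, cfg$shape,
                         cfg$scale)
    .applyCensoring(latent, censorBound)
  })
}

#' Simulate survival outcomes from the log-normal AFT model
#'
#' log T = mu + x beta + z gamma + sigma eps with standard-normal eps.
#'
#' @inheritParams simulateCox
#' @param cfg a [simConfig()] with `survivalModel = "aft"`.
#' @export
simulateAft <- function(x, z = 0, cfg = simConfig("aft"),
                        censorBound = NULL, seed = NULL) {
  n <- length(x)
  z <- rep_len(z, n)
  .withSeed(seed, {
    latent <- .latentAft(n, x * cfg$beta + z * cfg$gamma, cfg$mu, cfg$sigma)
    .applyCensoring(latent, censorBound)
  })
}

#' Calibrate the uniform censoring bound for a target censored fraction
#'
#' For Uniform(0, c) censoring the expected censored fraction is
#' E\[min(T, c)\] / c, a decreasing function of c; given a Monte-Carlo
#' sample of latent times the bound achieving a target fraction is found by
#' bisection.
#'
#' @param targetFraction target expected censored fraction in \[0, 1).
#' @param latentSampler function(n) returning latent event times, or a
#'   numeric vector of pre-drawn latent times.
#' @param nDraws Monte-Carlo draws used in the calibration.
#' @param seed integer seed for the draws.
#' @param tol absolute tolerance on the achieved expected fraction.
#' @return The censoring bound c (`NULL` for target 0: no censoring).
#' @examples
#' cfg <- simConfig("cox")
#' cb <- calibrateCensoring(0.3, function(n) {
#'   u <- runif(n); cfg$scale * (-log(u))^(1 / cfg$shape)
#' }, seed = 1)
#' @export
calibrateCensoring <- function(targetFraction, latentSampler,
                               nDraws = 100000L, seed = NULL, tol = 0.005) {
  if (targetFraction < 0 || targetFraction >= 1)
    stop("targetFraction must lie in [0, 1)", call. = FALSE)
  if (targetFraction == 0) return(NULL)
  latent <- if (is.function(latentSampler))
    .withSeed(seed, latentSampler(nDraws)) else as.numeric(latentSampler)
  frac <- function(c) mean(pmin(latent, c)) / c
  lo <- min(latent) * 1e-3
  hi <- max(latent) * 2
  if (frac(hi) > targetFraction) {
    # even the widest bound censors too much only if target below reach
    while (frac(hi) > targetFraction && hi < max(latent) * 1e6) hi <- hi * 10
    if (frac(hi) > targetFraction)
      stop(sprintf("target fraction %.3f unreachable; achievable < %.3f",
                   targetFraction, frac(hi)), call. = FALSE)
  }
  for (it in seq_len(200L)) {
    mid <- sqrt(lo * hi)
    fm <- frac(mid)
    if (abs(fm - targetFraction) <= tol * 0.5) break
    if (fm > targetFraction) lo <- mid else hi <- mid
  }
  mid
}

.latentSamplerFor <- function(cfg, penetranceDraw) {
  # latent-time generator marginal over genotypes/x/z for calibration
  function(n) {
    x <- penetranceDraw(n)
    z <- if (cfg$gamma != 0) stats::rnorm(n) else numeric(n)
    eta <- x * cfg$beta + z * cfg$gamma
    if (cfg$survivalModel == "cox") .latentCox(n, eta, cfg$shape, cfg$scale)
    else .latentAft(n, eta, cfg$mu, cfg$sigma)
  }
}

#' Build one simulated dataset
#'
#' Composes the full generative chain: HWE/LE genotypes, latent risk from
#' the penetrance model at the causal pair (x = 0 for null datasets), a
#' standard-normal covariate when `gamma != 0`, survival outcomes from the
#' configured model, and calibrated uniform censoring.
#'
#' @param cfg a [simConfig()].
#' @return List: `data` (an [MdrSurvData-class]), and `truth` (causal pair,
#'   latent x, realized censored fraction, the censoring bound used, and
#'   the config).
#' @examples
#' pm <- generatePenetrance(0.2, 0.4, seed = 5)
#' sim <- buildDataset(simConfig(n = 100, p = 5, causalPair = c(1, 2),
#'                               penetrance = pm, seed = 9))
#' sim$truth$causalPair
#' @export
buildDataset <- function(cfg) {
  stopifnot(inherits(cfg, "kmmdr_sim_config"))
  seeds <- .subSeeds(cfg$seed, 5L)
  G <- sampleGenotypes(cfg$n, cfg$p, cfg$maf, seeds[1L])
  x <- if (is.null(cfg$causalPair)) rep(0L, cfg$n)
       else assignRisk(G[, cfg$causalPair, drop = FALSE], cfg$penetrance,
                       seeds[2L])
  z <- if (cfg$gamma != 0) .withSeed(seeds[3L], stats::rnorm(cfg$n))
       else numeric(cfg$n)
  cb <- cfg$censorBound
  if (is.null(cb) && cfg$censoringFraction > 0) {
    draw <- if (is.null(cfg$causalPair)) function(n) rep(0L, n)
            else function(n) {
              gg <- sampleGenotypes(n, 2L, cfg$maf)
              assignRisk(gg, cfg$penetrance)
            }
    cb <- calibrateCensoring(cfg$censoringFraction,
                             .latentSamplerFor(cfg, draw), seed = seeds[4L])
  }
  sim <- if (cfg$survivalModel == "cox")
    simulateCox(x, z, cfg, censorBound = cb, seed = seeds[5L])
  else simulateAft(x, z, cfg, censorBound = cb, seed = seeds[5L])
  data <- MdrSurvData(G, sim$time, sim$status,
                      covariates = if (cfg$gamma != 0)
                        data.frame(z = z))
  list(data = data,
       truth = list(causalPair = cfg$causalPair, x = x,
                    censorBound = cb,
                    censoredFraction = mean(sim$status == 0L),
                    config = cfg))
}
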