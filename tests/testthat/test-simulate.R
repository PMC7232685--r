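test_that("penetrance models have exactly null marginals and the target heritability", {
  # independent direct-summation oracle over the nine cells
  oracle <- function(f, maf) {
    p <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
    K <- 0; v <- 0
    for (i in 1:3) for (j in 1:3) K <- K + p[i] * p[j] * f[i, j]
    for (i in 1:3) for (j in 1:3) v <- v + p[i] * p[j] * (f[i, j] - K)^2
    rowm <- sapply(1:3, function(i) sum(p * f[i, ]))
    colm <- sapply(1:3, function(j) sum(p * f[, j]))
    list(K = K, h2 = v / (K * (1 - K)),
         dev = max(abs(c(rowm, colm) - K)))
  }
  grid <- expand.grid(maf = c(0.2, 0.4),
                      h2 = c(0.01, 0.025, 0.05, 0.1, 0.2, 0.3, 0.4))
  for (i in seq_len(nrow(grid))) {
    for (s in 1:7) {
      pm <- generatePenetrance(grid$maf[i], grid$h2[i], seed = s)
      o <- oracle(pm@f, grid$maf[i])
      expect_lt(o$dev, 1e-6)
      expect_equal(o$h2, grid$h2[i], tolerance = 1e-10)
      expect_true(all(pm@f >= 0 & pm@f <= 1))
      expect_equal(o$K, penetranceSummary(pm)$K, tolerance = 1e-12)
    }
  }
  # determinism and distinctness of the per-cell model seeds
  a <- generatePenetrance(0.2, 0.1, seed = 3)
  expect_identical(a@f, generatePenetrance(0.2, 0.1, seed = 3)@f)
  expect_false(identical(a@f, generatePenetrance(0.2, 0.1, seed = 4)@f))
  # a constant table is the degenerate h2 = 0 model with null marginals
  flat <- new("PenetranceModel", f = matrix(0.3, 3, 3), maf = 0.2,
              h2 = 0, K = 0.3, modelId = "flat")
  expect_equal(penetranceSummary(flat)$h2, 0)
  expect_lt(penetranceSummary(flat)$maxMarginalDeviation, 1e-12)
})

test_that("genotypes follow HWE frequencies and linkage equilibrium", {
  g <- sampleGenotypes(100000, 3, c(0.5, 0.2, 0.2), seed = 2)
  fr <- table(factor(g[, 1], 0:2)) / nrow(g)
  expect_lt(max(abs(as.numeric(fr) - c(0.25, 0.5, 0.25))), 0.01)
  expect_lt(abs(mean(g[, 2] == 2) - 0.04), 0.002)
  expect_lt(abs(cor(g[, 2], g[, 3])), 0.02)   # independent columns
  expect_identical(g, sampleGenotypes(100000, 3, c(0.5, 0.2, 0.2),
                                      seed = 2))
  expect_error(sampleGenotypes(10, 2, 0.6), "maf")
})

test_that("risk assignment is Bernoulli in the subject's penetrance cell", {
  pm <- generatePenetrance(0.2, 0.2, seed = 6)
  g <- sampleGenotypes(100000, 2, 0.2, seed = 7)
  one <- pm; one@f[] <- 1
  zero <- pm; zero@f[] <- 0
  expect_true(all(assignRisk(g[1:100, ], one, seed = 1) == 1L))
  expect_true(all(assignRisk(g[1:100, ], zero, seed = 1) == 0L))
  x <- assignRisk(g, pm, seed = 8)
  K <- penetranceSummary(pm)$K
  expect_lt(abs(mean(x) - K), 3 * sqrt(K * (1 - K) / 1e5))
})

test_that("Cox generator matches the closed-form Weibull baseline", {
  cfg <- simConfig("cox", n = 100000)
  sim <- simulateCox(rep(0L, 100000), cfg = cfg, seed = 3)
  expect_true(all(sim$status == 1L))            # no censoring configured
  # S0(t) = exp(-(t/2)^5): sup-norm of the empirical survival
  ts <- seq(0.1, 3.5, by = 0.05)
  emp <- vapply(ts, function(u) mean(sim$time > u), numeric(1))
  expect_lt(max(abs(emp - exp(-(ts / 2)^5))), 0.01)
  expect_equal(median(sim$time), 2 * log(2)^(1 / 5), tolerance = 0.005)
  # proportional hazards: the x = 1 group dies earlier
  simx <- simulateCox(rep(1L, 100000), cfg = cfg, seed = 3)
  expect_lt(median(simx$time), median(sim$time))
  expect_equal(median(simx$time),
               2 * (log(2) / exp(1.2))^(1 / 5), tolerance = 0.005)
})

test_that("AFT generator produces standard log-normal log-times with AFT scaling", {
  cfg <- simConfig("aft", n = 100000)
  sim <- simulateAft(rep(0L, 100000), cfg = cfg, seed = 4)
  lt <- log(sim$time)
  expect_equal(mean(lt), 0, tolerance = 0.01)
  expect_equal(sd(lt), 1, tolerance = 0.01)
  expect_equal(median(sim$time), 1, tolerance = 0.02)
  simx <- simulateAft(rep(1L, 100000), cfg = cfg, seed = 4)
  expect_equal(median(simx$time) / median(sim$time), exp(-1),
               tolerance = 0.02)
  expect_identical(simulateAft(rep(1L, 10), cfg = cfg, seed = 5)$time,
                   simulateAft(rep(1L, 10), cfg = cfg, seed = 5)$time)
})

test_that("censoring calibration hits targets and is monotone", {
  sampler <- function(n) 2 * (-log(runif(n)))^(1 / 5)  # null Weibull
  expect_null(calibrateCensoring(0, sampler, seed = 1))
  bounds <- vapply(c(0.1, 0.3, 0.5), function(f)
    calibrateCensoring(f, sampler, seed = 1), numeric(1))
  expect_true(all(diff(bounds) < 0))   # heavier censoring, smaller bound
  # independent validation at 10^6 draws
  set.seed(2)
  latent <- sampler(1e6)
  for (i in 1:3) {
    realized <- mean(latent > runif(1e6, 0, bounds[i]))
    expect_lt(abs(realized - c(0.1, 0.3, 0.5)[i]), 0.01)
  }
  # realized fractions at study scale, n = 400 over 100 replicates
  set.seed(3)
  fr <- replicate(100, {
    tt <- sampler(400)
    mean(tt > runif(400, 0, bounds[2]))
  })
  expect_lt(abs(mean(fr) - 0.3), 0.02)
})

test_that("dataset builder composes the chain with the declared shapes and determinism", {
  pm <- generatePenetrance(0.2, 0.3, seed = 1)
  cfg <- simConfig("cox", n = 400, p = 10, maf = 0.2, causalPair = c(1, 2),
                   penetrance = pm, censoringFraction = 0.3, seed = 11)
  sim <- buildDataset(cfg)
  expect_s4_class(sim$data, "MdrSurvData")
  expect_equal(dim(genotypes(sim$data)), c(400L, 10L))
  expect_length(survTime(sim$data), 400)
  expect_equal(sim$truth$causalPair, c(1L, 2L))
  expect_lt(abs(sim$truth$censoredFraction - 0.3), 0.08)
  # byte-identical reproduction from the same config
  sim2 <- buildDataset(cfg)
  expect_identical(genotypes(sim$data), genotypes(sim2$data))
  expect_identical(survTime(sim$data), survTime(sim2$data))
  # null datasets carry no effect: x is identically zero, all events at C=0
  null <- buildDataset(simConfig("cox", n = 200, p = 8, maf = 0.1,
                                 seed = 12))
  expect_true(all(null$truth$x == 0L))
  expect_true(all(survStatus(null$data) == 1L))
  # and survival is unrelated to a designated SNP's dichotomization
  g1 <- genotypes(null$data)[, 1] > 0
  expect_lt(logRank(survTime(null$data), survStatus(null$data), g1)@score,
            qchisq(0.999, 1))
  # covariate present only when gamma != 0
  expect_null(covariateMatrix(null$data))
  withZ <- buildDataset(simConfig("cox", n = 50, p = 3, maf = 0.2,
                                  gamma = 1, seed = 13))
  expect_equal(dim(covariateMatrix(withZ$data)), c(50L, 1L))
})
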