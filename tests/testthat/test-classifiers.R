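# One-SNP (q = 1) layouts give direct control over the three cells.

test_that("KM-MDR labels cells by median comparison, with ties going LOW", {
  # cell 0 dies at 1, cell 2 at 5, cell 1 at 10; overall median 5
  g <- matrix(rep(c(0L, 2L, 1L), each = 4), ncol = 1)
  time <- c(rep(1, 4), rep(5, 4), rep(10, 4))
  status <- rep(1L, 12)
  expect_equal(kmMedian(time, status), 5)
  cl <- classifyKM(g, time, status)
  expect_equal(unname(cl@labels), c(1L, 0L, 0L))   # 1 < 5; 10 > 5; 5 == 5
  expect_equal(cl@provenance, rep("cell_median", 3))
  expect_equal(cl@overallMedian, 5)
})

test_that("KM-MDR complement rule: an early-censored cell with unreached median is HIGH", {
  # cell 0: 4 early events then censoring -> its own median unreachable,
  # but it drags overall survival down, so its complement outlives the
  # overall sample
  g <- matrix(c(rep(0L, 10), rep(1L, 10), rep(2L, 10)), ncol = 1)
  time <- c(rep(1, 4), rep(2, 6), 5:24)
  status <- c(rep(1, 4), rep(0, 6), rep(1, 20))
  cl <- classifyKM(g, time, status)
  expect_identical(cl@provenance[1], "complement_rule")
  expect_identical(unname(cl@labels[1]), 1L)
  # the rule's inputs, recomputed with the exported primitives
  inCell <- g[, 1] == 0L
  expect_true(is.na(kmMedian(time[inCell], status[inCell])))
  expect_gt(kmMedian(time[!inCell], status[!inCell]),
            kmMedian(time, status))
})

test_that("KM-MDR empty cells default LOW and inapplicability raises", {
  g <- matrix(rep(c(0L, 1L), each = 6), ncol = 1)  # cell 2 unobserved
  time <- c(1:6, 7:12)
  cl <- classifyKM(g, time, rep(1L, 12))
  expect_identical(cl@provenance[3], "empty_default")
  expect_identical(unname(cl@labels[3]), 0L)
  expect_error(classifyKM(g, time, rep(0L, 12)), "not applicable")
})

test_that("KM-MDR classification is invariant under monotone time rescaling", {
  set.seed(21)
  g <- matrix(rbinom(160, 2, 0.4), ncol = 2)
  time <- rexp(80)
  status <- rbinom(80, 1, 0.8)
  base <- classifyKM(g, time, status)
  for (f in list(function(t) t^3, function(t) exp(t), function(t) 10 * t)) {
    tr <- classifyKM(g, f(time), status)
    expect_identical(tr@labels, base@labels)
    expect_identical(tr@provenance, base@provenance)
  }
})

test_that("Surv-MDR labels cells by log-rank sign, defaults degenerate cells LOW", {
  # cell 0 dies before anyone else -> positive O - E -> HIGH
  g <- matrix(rep(c(0L, 1L), each = 6), ncol = 1)
  time <- c(1:6, 101:106)
  cl <- classifySurv(g, time, rep(1L, 12))
  expect_identical(unname(cl@labels[1]), 1L)
  expect_identical(unname(cl@labels[2]), 0L)
  expect_identical(cl@provenance[3], "empty_default")
  expect_identical(unname(cl@labels[3]), 0L)
  # duplication of every subject preserves the labels
  cl2 <- classifySurv(rbind(g, g), rep(time, 2), rep(1L, 24))
  expect_identical(cl2@labels, cl@labels)
})

test_that("KM-MDR and Surv-MDR decisions coincide on well-populated cells of a strong epistatic pair", {
  # under a pure two-locus effect (h2 = 0.4), the two classifiers are
  # near-interchangeable on cells large enough for a stable median
  # (>= 5% of n); sparse cells may legitimately differ
  pm <- generatePenetrance(0.2, 0.4, seed = 1)
  perCell <- c()
  for (i in 1:50) {
    sim <- buildDataset(simConfig(n = 400, p = 2, maf = 0.2,
                                  causalPair = c(1, 2), penetrance = pm,
                                  seed = 1000 + i))
    g <- genotypes(sim$data)
    tt <- survTime(sim$data)
    ss <- survStatus(sim$data)
    ck <- classifyKM(g, tt, ss)
    cs <- classifySurv(g, tt, ss)
    cnt <- tabulate(3 * g[, 1] + g[, 2] + 1, 9)
    perCell <- c(perCell, (ck@labels == cs@labels)[cnt >= 20])
  }
  expect_gt(mean(perCell), 0.95)
})

test_that("Cox null-model scores are martingale residuals of the genotype-free fit", {
  set.seed(31)
  time <- rexp(100)
  status <- rbinom(100, 1, 0.8)
  s <- coxNullScores(time, status)
  expect_lt(abs(sum(s)), 1e-6)           # residuals of a fitted null sum to 0
  expect_equal(s[which(time == min(time))[1]],
               status[which(time == min(time))[1]],
               tolerance = 0.05)          # Lambda(t) ~ 0 at the earliest time
  # a subject censored at time 0 has residual exactly 0
  s0 <- coxNullScores(c(0, time), c(0L, status))
  expect_equal(s0[1], 0)
  # with covariates the null fit adjusts: scores still sum to ~0
  z <- rnorm(100)
  sz <- coxNullScores(time, status, cbind(z = z))
  expect_lt(abs(sum(sz)), 1e-6)
})

test_that("Cox scores separate true risk groups in simulated PH data", {
  set.seed(32)
  n <- 2000
  x <- rbinom(n, 1, 0.3)
  sim <- simulateCox(x, cfg = simConfig("cox", n = n))
  s <- coxNullScores(sim$time, sim$status)
  expect_gt(mean(s[x == 1]), mean(s[x == 0]))
})

test_that("AFT null-model scores are negated standardized log-normal residuals", {
  set.seed(33)
  time <- exp(rnorm(200))
  status <- rbinom(200, 1, 0.8)
  s <- aftNullScores(time, status)
  fit <- survival::survreg(survival::Surv(time, status) ~ 1,
                           dist = "lognormal")
  expect_equal(s, -(log(time) - fit$linear.predictors) / fit$scale,
               tolerance = 1e-10)
  # monotone: earlier observed times score higher
  o <- order(time)
  expect_true(all(diff(s[o]) <= 0))
  # larger = higher risk: true accelerated group scores higher
  x <- rbinom(2000, 1, 0.3)
  sim <- simulateAft(x, cfg = simConfig("aft", n = 2000), seed = 8)
  sa <- aftNullScores(sim$time, sim$status)
  expect_gt(mean(sa[x == 1]), mean(sa[x == 0]))  # beta = -1: earlier deaths
})

test_that("score-sum classifier thresholds cells at strictly positive sums", {
  g <- matrix(c(0L, 0L, 1L, 2L, 2L), ncol = 1)
  expect_true(all(classifyScores(g, rep(0, 5))@labels == 0L))  # ties -> LOW
  cl <- classifyScores(g, c(-1, 2, 3, -1, 0.5))
  expect_equal(unname(cl@labels), c(1L, 1L, 0L))   # sums 1, 3, -0.5
  # single-subject positive cell is HIGH
  expect_identical(unname(classifyScores(matrix(1L), 0.2)@labels[2]), 1L)
  # negating scores flips every non-tied cell
  set.seed(34)
  g2 <- matrix(rbinom(20, 2, 0.5), ncol = 1)
  sc <- rnorm(20)
  a <- classifyScores(g2, sc)@labels
  b <- classifyScores(g2, -sc)@labels
  sums <- vapply(0:2, function(c) sum(sc[g2[, 1] == c]), numeric(1))
  nonTied <- abs(sums) > 1e-12 & tabulate(g2[, 1] + 1, 3) > 0
  expect_true(all((a != b)[nonTied]))
  # conservation: cell sums add up to the total score mass
  expect_equal(sum(sums), sum(sc))
})

test_that("group assignment maps subjects through their cells, warning on unseen cells", {
  g <- matrix(rep(c(0L, 1L), each = 6), ncol = 1)
  cl <- classifyKM(g, c(1:6, 101:106), rep(1L, 12))
  expect_equal(assignGroups(cl, g), unname(cl@labels[g[, 1] + 1]))
  expect_warning(out <- assignGroups(cl, matrix(2L)), "unseen")
  expect_identical(out, 0L)
  allHigh <- new("CellClassification", q = 1L,
                 labels = stats::setNames(rep(1L, 3), c("0", "1", "2")),
                 provenance = rep("cell_median", 3),
                 overallMedian = 1)
  expect_equal(assignGroups(allHigh, g), rep(1L, 12))
})
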