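# Independent brute-force oracles, deliberately written as naive loops over
# the defining formulas, not sharing code with the package internals.

# Log-rank: accumulate O - E and hypergeometric variance at each distinct
# event time of the pooled sample; group 1 is group == 1.
bruteLogRank <- function(time, status, group) {
  et <- sort(unique(time[status == 1]))
  oe <- 0
  v <- 0
  for (u in et) {
    n1 <- sum(time >= u & group == 1)
    n2 <- sum(time >= u & group == 0)
    d1 <- sum(time == u & status == 1 & group == 1)
    d2 <- sum(time == u & status == 1 & group == 0)
    n <- n1 + n2
    d <- d1 + d2
    oe <- oe + d1 - d * n1 / n
    if (n > 1) v <- v + (n - d) * d * n1 * n2 / ((n - 1) * n^2)
  }
  z <- oe / sqrt(v)
  list(z = z, score = z^2, oe = oe, v = v)
}

# Product-limit estimate evaluated at the distinct event times.
bruteKm <- function(time, status) {
  et <- sort(unique(time[status == 1]))
  s <- 1
  out <- numeric(length(et))
  for (i in seq_along(et)) {
    u <- et[i]
    n <- sum(time >= u)
    d <- sum(time == u & status == 1)
    s <- s * (1 - d / n)
    out[i] <- s
  }
  list(eventTimes = et, survival = out)
}

bruteKmMedian <- function(time, status) {
  km <- bruteKm(time, status)
  hit <- which(km$survival <= 0.5 + 1e-9)
  if (length(hit)) km$eventTimes[hit[1]] else NA_real_
}

# Random small survival instance with ties and censoring.
randomInstance <- function(n, tieProb = 0.3, censProb = 0.3) {
  time <- sample(1:5, n, replace = TRUE) +
    ifelse(runif(n) < tieProb, 0, runif(n))
  status <- as.integer(runif(n) >= censProb)
  g <- integer(n)
  g[sample(n, max(1, floor(n / 2)))] <- 1L
  list(time = time, status = status, group = g)
}

# Small complete dataset with a strong single-locus effect on survival.
effectDataset <- function(n = 120, seed = 99) {
  set.seed(seed)
  g <- cbind(SNPa = rbinom(n, 2, 0.4), SNPb = rbinom(n, 2, 0.4))
  rate <- ifelse(g[, 1] == 2, 4, 1)   # code-2 carriers die much earlier
  list(genotypes = g, time = rexp(n, rate), status = rep(1L, n))
}
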