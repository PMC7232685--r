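# Purely epistatic two-locus penetrance models.
#
# A table f[i, j] = P(high risk | g1 = i, g2 = j) has "no marginal effects"
# when every HWE-weighted row and column marginal equals the prevalence K.
# Writing f = K + delta, that condition is linear in delta: the feasible
# deltas form a 4-dimensional null space of the 6 marginal constraints
# (rank 5). We draw a random direction in that space and scale it
# analytically so that the heritability
#   h2 = sum_ij p_i p_j delta_ij^2 / (K (1 - K))
# hits the target exactly, rejecting draws that leave [0, 1] penetrances.

.hweWeights <- function(maf) {
  # genotype code = count of minor alleles
  c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
}

.marginalNullBasis <- function(p) {
  # constraints: sum_j p_j delta[i, j] = 0 (rows), sum_i p_i delta[i, j] = 0
  C <- matrix(0, 6L, 9L)
  for (i in 1:3) C[i, (i - 1L) * 3L + 1:3] <- p          # row i marginal
  for (j in 1:3) C[3L + j, j + c(0L, 3L, 6L)] <- p       # column j marginal
  ns <- svd(C, nu = 0L, nv = 9L)$v[, 6:9, drop = FALSE]  # rank(C) = 5
  ns
}

#' Generate a purely epistatic penetrance model
#'
#' Draws a 3x3 penetrance table with exactly zero marginal effects under
#' Hardy-Weinberg genotype weights for the given minor allele frequency and
#' exactly the target heritability, by sampling a random direction in the
#' linear subspace of zero-marginal tables and scaling it analytically.
#' Rejection sampling keeps all penetrances in \[0, 1\].
#'
#' @param maf minor allele frequency in (0, 0.5].
#' @param h2 target heritability in (0, 1).
#' @param seed integer seed; the model is deterministic given the seed.
#' @param maxTries rejection budget before giving up.
#' @return A [PenetranceModel-class].
#' @examples
#' pm <- generatePenetrance(maf = 0.2, h2 = 0.1, seed = 42)
#' penetranceSummary(pm)$h2
#' @export
generatePenetrance <- function(maf, h2, seed = NULL, maxTries = 100000L) {
  if (maf <= 0 || maf > 0.5) stop("maf must lie in (0, 0.5]", call. = FALSE)
  if (h2 <= 0 || h2 >= 1) stop("h2 must lie in (0, 1)", call. = FALSE)
  p <- .hweWeights(maf)
  W <- as.vector(outer(p, p))  # cell probabilities, column-major 3x3
  B <- .marginalNullBasis(p)
  .withSeed(seed, {
    for (try in seq_len(maxTries)) {
      K <- stats::runif(1L, 0.1, 0.9)
      v <- stats::rnorm(4L)
      u <- as.vector(B %*% v)
      varU <- sum(W * u^2)
      if (varU < 1e-12) next
      delta <- u * sqrt(h2 * K * (1 - K) / varU)
      f <- K + delta
      if (all(f >= 0 & f <= 1)) {
        fm <- matrix(f, 3L, 3L,
                     dimnames = list(paste0("g1=", 0:2), paste0("g2=", 0:2)))
        return(new("PenetranceModel", f = fm, maf = maf, h2 = h2, K = K,
                   modelId = sprintf("maf%s_h%s_seed%s", maf, h2,
                                     seed %||% "NA")))
      }
    }
  })
  stop(sprintf(paste0("no feasible penetrance table found in %d tries ",
                      "(maf = %g, h2 = %g)"), maxTries, maf, h2),
       call. = FALSE)
}

#' Recompute prevalence, heritability and marginal effects of a model
#'
#' Direct summation over the nine genotype cells under HWE weights:
#' prevalence K = sum p_i p_j f_ij, heritability
#' sum p_i p_j (f_ij - K)^2 / (K (1 - K)), and the maximum absolute
#' deviation of any row/column marginal penetrance from K.
#'
#' @param model a [PenetranceModel-class].
#' @return List with elements `K`, `h2`, `maxMarginalDeviation`.
#' @export
penetranceSummary <- function(model) {
  p <- .hweWeights(model@maf)
  W <- outer(p, p)
  K <- sum(W * model@f)
  h2 <- sum(W * (model@f - K)^2) / (K * (1 - K))
  rowMarg <- as.vector(model@f %*% p)      # E[f | g1 = i]
  colMarg <- as.vector(t(model@f) %*% p)   # E[f | g2 = j]
  list(K = K, h2 = h2,
       maxMarginalDeviation = max(abs(c(rowMarg, colMarg) - K)))
}

#' @describeIn PenetranceModel-class display the table and its summaries.
#' @param object a `PenetranceModel`.
#' @export
setMethod("show", "PenetranceModel", function(object) {
  s <- penetranceSummary(object)
  cat(sprintf("PenetranceModel %s: maf = %g, h2 = %.4g, K = %.4g\n",
              object@modelId, object@maf, s$h2, s$K))
  print(round(object@f, 4))
})
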