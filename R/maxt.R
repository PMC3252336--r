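# Step-down (free step-down) maxT permutation adjustment, the step-3
# multiple-testing correction of MB-MDR.

# Core computation from an observed statistic vector and a P x B matrix of
# permutation statistics.  Hypotheses are ranked by decreasing observed
# statistic (ties broken by original order, so results are reproducible);
# for each permutation, successive maxima are taken from the bottom of the
# ranking upward; adjusted p for rank i is (1 + #{b : u_i^b >= T_(i)})/(B+1),
# then monotonicity is enforced down the ranking.
maxt_from_matrix <- function(observed, permstats) {
  P <- length(observed)
  permstats <- as.matrix(permstats)
  stopifnot(nrow(permstats) == P)
  B <- ncol(permstats)
  ord <- order(-observed, seq_len(P), method = "radix")
  To <- observed[ord]
  cnt <- numeric(P)
  for (b in seq_len(B)) {
    u <- rev(cummax(rev(permstats[ord, b])))
    cnt <- cnt + (u >= To)
  }
  p <- cummax((1 + cnt) / (B + 1))
  out <- numeric(P)
  out[ord] <- p
  out
}

# The B permutation index rows used by every maxT run with a given master
# seed: permutation b draws from sub-seed (seed, "maxt", b), so any scan is
# reproducible in isolation.
maxt_permutations <- function(n, B, seed) {
  t(vapply(seq_len(B), function(b) {
    set.seed(derive_seed(seed, "maxt", b))
    sample.int(n)
  }, integer(n)))
}

#' Step-down maxT adjusted p-values
#'
#' Monte Carlo free step-down maxT: the whole trait vector is permuted `B`
#' times, the complete statistic vector is recomputed on each permuted
#' trait, and adjusted p-values are formed from successive maxima down the
#' observed ranking with enforced monotonicity.  The smallest attainable
#' adjusted p-value is `1/(B + 1)`.
#'
#' @param observed numeric vector of observed statistics (one per
#'   hypothesis, larger = more extreme).
#' @param trait the trait vector the statistics were computed from.
#' @param recompute function mapping a permuted trait vector to the full
#'   statistic vector (same length and order as `observed`).  It must
#'   reapply any adjustment step, with designs fixed functions of the
#'   genotypes.
#' @param B number of random permutations (ignored when `permutations` is
#'   given).
#' @param seed master seed for the permutation stream.
#' @param permutations optional explicit `B x n` matrix of permutation
#'   index rows (e.g. an exhaustive enumeration, excluding the identity,
#'   for exact small-sample computations).
#' @return adjusted p-values in the original hypothesis order, each in
#'   `[1/(B+1), 1]`.
#' @export
maxt_adjust <- function(observed, trait, recompute, B = 999L, seed = 1L,
                        permutations = NULL) {
  trait <- unname(as.double(trait))  # a permuted trait has no meaningful
                                     # sample alignment left
  n <- length(trait)
  if (is.null(permutations)) {
    if (B < 19L) stop_named("B must be >= 19")
    permutations <- maxt_permutations(n, B, seed)
  } else {
    permutations <- as.matrix(permutations)
    if (ncol(permutations) != n) stop_named("permutation rows must have length n")
    B <- nrow(permutations)
  }
  P <- length(observed)
  permstats <- matrix(0, P, B)
  for (b in seq_len(B)) {
    st <- recompute(trait[permutations[b, ]])
    if (length(st) != P) {
      stop_named("recompute returned %d statistics, expected %d",
                 length(st), P)
    }
    permstats[, b] <- st
  }
  maxt_from_matrix(observed, permstats)
}
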