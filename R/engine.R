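# Vectorised scan engines.
#
# A full MB-MDR scan evaluates steps 1-2 for every SNP pair on the observed
# trait and on B permuted traits.  Everything steps 1-2 need reduces to
# per-cell counts (fixed across permutations) and per-cell trait sums, so a
# scan over all pairs collapses to one cell-indicator matrix product per
# trait vector plus elementwise arithmetic:
#
#   * unadjusted: pooled t-statistics from group size/sum and the global
#     trait sum / sum of squares (both permutation-invariant);
#   * on-the-fly adjusted: Wald t-statistics from cell indicators
#     residualised on each pair's fixed main-effect design (the Gram matrix
#     of residualised indicators is permutation-invariant, and a pooled
#     H/L indicator residualises to the sum of its cell residuals).
#
# Each engine exposes stats(ymat): an n x k matrix of trait vectors in, a
# P x k matrix of pair statistics out, column by column identical to the
# per-pair functions in mbmdr_core.R.

D_TOL <- 1e-10  # squared-norm threshold below which an indicator is
                # treated as collinear with the adjustment design

# n x 3m indicator matrix; column 3(s-1) + g + 1 is 1(genotype of SNP s == g)
snp_indicator_matrix <- function(genotypes) {
  n <- nrow(genotypes)
  m <- ncol(genotypes)
  M <- matrix(0, n, 3L * m)
  i <- rep(seq_len(n), times = m)
  j <- 3L * (rep(seq_len(m), each = n) - 1L) + as.vector(genotypes) + 1L
  M[cbind(i, j)] <- 1
  M
}

# n x 9P matrix of two-locus cell indicators, pair-major, cell order
# c = 3 g_a + g_b within each pair block.
cell_indicator_matrix <- function(M, pairs) {
  P <- nrow(pairs)
  iidx <- rep(0:2, each = 3L)   # g_a per cell 0..8
  jidx <- rep(0:2, times = 3L)  # g_b per cell
  acol <- rep(3L * (pairs[, 1L] - 1L), each = 9L) + rep(iidx, P) + 1L
  bcol <- rep(3L * (pairs[, 2L] - 1L), each = 9L) + rep(jidx, P) + 1L
  M[, acol, drop = FALSE] * M[, bcol, drop = FALSE]
}

# Steps 1-2 from cell counts N (c x P) and cell sums S (c x P), pooled-t
# (unadjusted) flavour.  Returns the P pair statistics.
step12_pooled <- function(N, S, n, sy, syy, tcrit, valid) {
  tt <- pooled_t_stat(N, S, n, sy, syy)
  H <- valid & !is.na(tt) & tt > tcrit
  L <- valid & !is.na(tt) & tt < -tcrit
  group_stat <- function(mask) {
    ng <- .colSums(N * mask, nrow(N), ncol(N))
    sg <- .colSums(S * mask, nrow(S), ncol(S))
    tg <- pooled_t_stat(ng, sg, n, sy, syy)
    ifelse(ng > 0 & ng < n, tg, 0)
  }
  pmax(group_stat(H), -group_stat(L), 0)
}

build_unadjusted_engine <- function(genotypes, alpha1, min_cell) {
  n <- nrow(genotypes)
  pairs <- pair_grid(ncol(genotypes))
  P <- nrow(pairs)
  M <- snp_indicator_matrix(genotypes)
  W <- cell_indicator_matrix(M, pairs)
  N9 <- matrix(.colSums(W, n, ncol(W)), 9L, P)
  valid <- N9 >= min_cell & N9 <= n - min_cell
  tcrit <- stats::qt(1 - alpha1 / 2, n - 2L)
  stats_fun <- function(ymat) {
    ymat <- as.matrix(ymat)
    k <- ncol(ymat)
    SS <- crossprod(W, ymat)
    sy <- .colSums(ymat, n, k)
    syy <- .colSums(ymat^2, n, k)
    out <- matrix(0, P, k)
    for (b in seq_len(k)) {
      out[, b] <- step12_pooled(N9, matrix(SS[, b], 9L, P), n,
                                sy[b], syy[b], tcrit, valid)
    }
    out
  }
  list(stats = stats_fun, pairs = pairs, cell_sizes = N9)
}

# Single-locus (MB-MDR 1D) engine: 3 genotype cells per SNP.
build_1d_engine <- function(genotypes, alpha1, min_cell) {
  n <- nrow(genotypes)
  m <- ncol(genotypes)
  M <- snp_indicator_matrix(genotypes)
  N3 <- matrix(.colSums(M, n, 3L * m), 3L, m)
  valid <- N3 >= min_cell & N3 <= n - min_cell
  tcrit <- stats::qt(1 - alpha1 / 2, n - 2L)
  stats_fun <- function(ymat) {
    ymat <- as.matrix(ymat)
    k <- ncol(ymat)
    SS <- crossprod(M, ymat)
    sy <- .colSums(ymat, n, k)
    syy <- .colSums(ymat^2, n, k)
    out <- matrix(0, m, k)
    for (b in seq_len(k)) {
      out[, b] <- step12_pooled(N3, matrix(SS[, b], 3L, m), n,
                                sy[b], syy[b], tcrit, valid)
    }
    out
  }
  list(stats = stats_fun, pairs = matrix(seq_len(m), ncol = 1L))
}

# On-the-fly adjusted engine.  `designs` is a list of P (possibly 0-column)
# main-effect design matrices, one per pair, fixed functions of genotypes.
build_adjusted_engine <- function(genotypes, alpha1, min_cell, designs) {
  n <- nrow(genotypes)
  pairs <- pair_grid(ncol(genotypes))
  P <- nrow(pairs)
  stopifnot(length(designs) == P)
  M <- snp_indicator_matrix(genotypes)
  W <- cell_indicator_matrix(M, pairs)
  N9 <- matrix(.colSums(W, n, ncol(W)), 9L, P)

  Eall <- matrix(0, n, 9L * P)   # residualised cell indicators
  G81 <- matrix(0, 81L, P)       # per-pair Gram of residualised indicators
  ranks <- integer(P)
  qlist <- vector("list", P)
  for (p in seq_len(P)) {
    X0 <- cbind(1, designs[[p]])
    qr0 <- qr(X0)
    r0 <- qr0$rank
    Q0 <- qr.Q(qr0)[, seq_len(r0), drop = FALSE]
    C <- W[, (9L * (p - 1L) + 1L):(9L * p), drop = FALSE]
    E <- C - Q0 %*% crossprod(Q0, C)
    Eall[, (9L * (p - 1L) + 1L):(9L * p)] <- E
    G81[, p] <- as.vector(crossprod(E))
    ranks[p] <- r0
    qlist[[p]] <- Q0
  }
  Qall <- do.call(cbind, qlist)
  qblock <- rep.int(seq_len(P), ranks)
  D9 <- matrix(G81[(0:8) * 9L + 1:9, ], 9L, P)  # diagonal entries
  dfp <- n - ranks - 1L
  tcritp <- stats::qt(1 - alpha1 / 2, dfp)
  tcrit9 <- matrix(rep(tcritp, each = 9L), 9L, P)
  sdf9 <- matrix(rep(sqrt(dfp), each = 9L), 9L, P)
  valid <- N9 >= min_cell & N9 <= n - min_cell & D9 > D_TOL
  i81 <- rep(1:9, times = 9L)
  j81 <- rep(1:9, each = 9L)

  stats_fun <- function(ymat) {
    ymat <- as.matrix(ymat)
    k <- ncol(ymat)
    Aall <- crossprod(Eall, ymat)          # 9P x k
    QY <- crossprod(Qall, ymat)            # sum(ranks) x k
    yy <- .colSums(ymat^2, n, k)
    out <- matrix(0, P, k)
    for (b in seq_len(k)) {
      A <- matrix(Aall[, b], 9L, P)
      yPy <- as.vector(rowsum(QY[, b]^2, qblock))
      yR <- yy[b] - yPy                    # per-pair residual SS of y on X0
      rtol <- 1e-12 * max(yy[b], 1)
      yR9 <- matrix(rep(yR, each = 9L), 9L, P)
      RSS1 <- pmax(yR9 - A^2 / D9, 0)
      tt <- A * sdf9 / sqrt(D9 * RSS1)
      deg <- valid & RSS1 <= rtol
      if (any(deg)) tt[deg] <- sign(A)[deg] * Inf
      H <- valid & !is.na(tt) & tt > tcrit9
      L <- valid & !is.na(tt) & tt < -tcrit9
      group_stat <- function(mask) {
        ag <- .colSums(A * mask, 9L, P)
        dg <- .colSums(G81 * (mask[i81, , drop = FALSE] *
                              mask[j81, , drop = FALSE]), 81L, P)
        any_g <- .colSums(mask, 9L, P) > 0
        ok <- any_g & dg > D_TOL
        rssg <- pmax(yR - ag^2 / ifelse(dg > D_TOL, dg, 1), 0)
        tg <- ag * sqrt(dfp) / sqrt(dg * rssg)
        degg <- ok & rssg <= rtol
        if (any(degg)) tg[degg] <- sign(ag)[degg] * Inf
        ifelse(ok, tg, 0)
      }
      out[, b] <- pmax(group_stat(H), -group_stat(L), 0)
    }
    out
  }
  list(stats = stats_fun, pairs = pairs, cell_sizes = N9,
       ranks = ranks, df = dfp)
}
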