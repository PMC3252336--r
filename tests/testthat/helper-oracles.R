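# Shared fixtures and independent oracles.  Oracles deliberately use a
# different computational route (t.test, lm, explicit enumeration) than the
# package internals.

random_genotypes <- function(n, m, seed, maf_range = c(0.15, 0.5)) {
  set.seed(seed)
  mafs <- runif(m, maf_range[1], maf_range[2])
  genotype_matrix(vapply(mafs, function(p) rbinom(n, 2L, p), integer(n)))
}

# Per-pair MB-MDR statistic recomputed from raw trait groups with t.test /
# lm, independent of the package's sufficient-statistic engine.
oracle_pair_stat <- function(g1, g2, y, alpha1, min_cell,
                             adjust = NULL) {
  n <- length(y)
  cell <- 3L * g1 + g2
  lab <- rep("O", 9L)
  for (c in 0:8) {
    nc <- sum(cell == c)
    if (nc < min_cell || nc > n - min_cell) next
    ind <- as.numeric(cell == c)
    if (is.null(adjust)) {
      tst <- t.test(y[ind == 1], y[ind == 0], var.equal = TRUE)
      stat <- unname(tst$statistic)
      p <- tst$p.value
    } else {
      fit <- lm(y ~ adjust + ind)
      cf <- summary(fit)$coefficients
      if (!"ind" %in% rownames(cf)) next  # collinear: untestable, stays O
      stat <- cf["ind", "t value"]
      p <- cf["ind", "Pr(>|t|)"]
    }
    if (p < alpha1) lab[c + 1L] <- if (stat > 0) "H" else "L"
  }
  side <- function(which_lab, sgn) {
    cells <- which(lab == which_lab) - 1L
    if (!length(cells)) return(0)
    ind <- as.numeric(cell %in% cells)
    if (all(ind == 0) || all(ind == 1)) return(0)
    if (is.null(adjust)) {
      sgn * unname(t.test(y[ind == 1], y[ind == 0],
                          var.equal = TRUE)$statistic)
    } else {
      cf <- summary(lm(y ~ adjust + ind))$coefficients
      if (!"ind" %in% rownames(cf)) return(0)
      sgn * cf["ind", "t value"]
    }
  }
  max(side("H", 1), side("L", -1), 0)
}

# All permutations of 1..n as an n! x n matrix (small n only).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

# Exhaustive free step-down maxT oracle: adjusted p-values computed by
# explicit enumeration over a full permutation set (identity included).
oracle_stepdown_maxt <- function(observed, permstats) {
  P <- length(observed)
  N <- ncol(permstats)
  ord <- order(-observed, seq_len(P))
  To <- observed[ord]
  cnt <- numeric(P)
  for (b in seq_len(N)) {
    u <- permstats[ord, b]
    for (i in P:1) {
      if (i < P) u[i] <- max(u[i], u[i + 1L])
      cnt[i] <- cnt[i] + (u[i] >= To[i])
    }
  }
  p <- cnt / N
  for (i in seq_len(P)[-1L]) p[i] <- max(p[i], p[i - 1L])
  out <- numeric(P)
  out[ord] <- p
  out
}
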