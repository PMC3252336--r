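# The elementary association test behind every MB-MDR step: a two-group
# comparison of trait means, either as a classical pooled-variance Student
# t-test (no adjustment) or as the Wald t-test of the group indicator in an
# ordinary least-squares model that also carries main-effect design columns.

# Pooled two-sample t from sufficient statistics; vectorised over group size
# n1 and group sum s1.  sy/syy are the overall trait sum and sum of squares
# (invariant under trait permutation, which the scan engines exploit).
# Degenerate zero-residual-variance splits give +/-Inf (p = 0 convention).
pooled_t_stat <- function(n1, s1, n, sy, syy) {
  n2 <- n - n1
  m1 <- s1 / n1
  m2 <- (sy - s1) / n2
  ssw <- syy - n1 * m1^2 - n2 * m2^2      # pooled within-group SS
  ssw[ssw < 0] <- 0                        # clip roundoff
  tt <- (m1 - m2) / sqrt(ssw / (n - 2) * (1 / n1 + 1 / n2))
  tol <- 1e-12 * max(syy, 1)
  deg <- is.finite(m1) & is.finite(m2) & ssw <= tol
  if (any(deg)) tt[deg] <- sign(m1 - m2)[deg] * Inf
  zz <- deg & m1 == m2                   # no mean difference, no variance:
  if (any(zz)) tt[zz] <- 0               # no evidence rather than p = 0
  tt
}

#' Two-group association test on a quantitative trait
#'
#' Compares trait means between the samples with `indicator == 1` and the
#' rest.  With no adjustment design this is the classical pooled-variance
#' Student t-test (`df = n - 2`); the sign is `mean(group 1) - mean(group 2)`.
#' With an adjustment design it is the Wald t-test of the indicator
#' coefficient in the OLS fit of the trait on intercept + design + indicator
#' (`df = n - q - 2` for a full-rank `n x q` design), the homoskedastic
#' regression analogue of the pooled t-test.
#'
#' A split with zero residual variance is degenerate: by convention the
#' statistic is `+/-Inf` and the p-value 0, with a warning.
#'
#' @param trait numeric trait vector.
#' @param indicator 0/1 membership vector with at least one 0 and one 1.
#' @param adjust_design optional `n x q` numeric matrix of main-effect
#'   columns (no intercept); `NULL` or 0 columns means unadjusted.
#' @return list with `statistic` (signed t), `p` (two-sided), `df`.
#' @export
association_test <- function(trait, indicator, adjust_design = NULL) {
  n <- length(trait)
  stopifnot(length(indicator) == n)
  indicator <- as.double(indicator)
  if (!all(indicator %in% c(0, 1))) stop_named("indicator must be 0/1")
  n1 <- sum(indicator)
  if (n1 == 0 || n1 == n) stop_named("indicator must split the sample")
  if (is.null(adjust_design) || NCOL(adjust_design) == 0L ||
      length(adjust_design) == 0L) {
    tt <- pooled_t_stat(n1, sum(trait[indicator == 1]), n,
                        sum(trait), sum(trait^2))
    df <- n - 2L
  } else {
    X0 <- cbind(1, adjust_design)
    qr0 <- qr(X0)
    r0 <- qr0$rank
    Q0 <- qr.Q(qr0)[, seq_len(r0), drop = FALSE]
    e <- indicator - Q0 %*% crossprod(Q0, indicator)
    d <- sum(e * e)
    df <- n - r0 - 1L
    if (d <= 1e-10 || df <= 0L) {
      stop_named("indicator is collinear with the adjustment design")
    }
    yres <- trait - Q0 %*% crossprod(Q0, trait)
    a <- sum(e * yres)
    rss <- sum(yres * yres) - a^2 / d
    rss <- max(rss, 0)
    if (rss <= 1e-12 * max(sum(trait^2), 1)) {
      tt <- sign(a) * Inf
    } else {
      tt <- a / d / sqrt(rss / df / d)
    }
  }
  if (!is.finite(tt)) {
    warning("degenerate association test: zero residual variance; p = 0")
    p <- 0
  } else {
    p <- 2 * stats::pt(-abs(tt), df)
  }
  list(statistic = as.double(tt), p = as.double(p), df = as.integer(df))
}
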