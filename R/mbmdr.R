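# The user-facing MB-MDR fits: the all-pairs epistasis scan (mbmdr) and the
# single-locus scan (mbmdr_1d), plus their S3 methods.

# Resolve a policy into the concrete scan inputs: the trait actually
# scanned (residualised for residual policies), the engine, and any
# selection / significant set involved.
prepare_scan <- function(genotypes, trait, settings) {
  policy <- settings$policy
  selection <- NULL
  significant_set <- character()
  y <- trait
  if (policy$kind == "residual") {
    scan <- single_snp_scan(trait, genotypes, policy$coding)
    selection <- switch(policy$selector,
      mr_aic = stepwise_aic_select(trait, genotypes, policy$coding),
      sr_perm = select_snps(scan, "sr_perm", B = settings$perms,
                            seed = derive_seed(settings$seed, "sr_perm"),
                            trait = trait, genotypes = genotypes,
                            coding = policy$coding),
      sr_alpha = select_snps(scan, "sr_alpha"),
      sr_topk = select_snps(scan, "sr_topk", k = policy$k))
    y <- residualize_trait(trait, genotypes, selection, policy$coding)
  }
  if (policy$kind == "on_the_fly") {
    if (policy$selector == "one_d_significant") {
      fit1d <- mbmdr_1d(genotypes, trait, alpha1 = settings$alpha1,
                        min_cell = settings$min_cell,
                        perms = settings$perms,
                        seed = derive_seed(settings$seed, "1d"))
      significant_set <- fit1d$snps$snp[fit1d$snps$p_adjusted <= 0.05]
    } else if (policy$selector == "list_significant") {
      scan <- single_snp_scan(trait, genotypes, policy$coding)
      sel <- select_snps(scan, "sr_perm", B = settings$perms,
                         seed = derive_seed(settings$seed, "sr_perm"),
                         trait = trait, genotypes = genotypes,
                         coding = policy$coding)
      significant_set <- sel$snp_ids
    }
    pairs <- pair_grid(ncol(genotypes))
    designs <- lapply(seq_len(nrow(pairs)), function(p) {
      resolve_adjust_design(policy, pairs[p, ], significant_set, genotypes)
    })
    engine <- build_adjusted_engine(genotypes, settings$alpha1,
                                    settings$min_cell, designs)
  } else {
    engine <- build_unadjusted_engine(genotypes, settings$alpha1,
                                      settings$min_cell)
  }
  list(engine = engine, y = y, selection = selection,
       significant_set = significant_set)
}

#' All-pairs MB-MDR statistics
#'
#' Runs MB-MDR steps 1-2 for every SNP pair under the policy in `settings`
#' (residual policies residualise the trait first; on-the-fly policies carry
#' per-pair Wald adjustment) and returns the pair statistics without
#' multiple-testing correction.
#'
#' @param genotypes genotype matrix.
#' @param trait numeric trait vector.
#' @param settings [scan_settings()].
#' @return numeric vector of non-negative statistics over all
#'   `choose(m, 2)` pairs in lexicographic order, with the pair index
#'   matrix as attribute `"pairs"`.
#' @export
scan_pairs <- function(genotypes, trait, settings = scan_settings()) {
  genotypes <- genotype_matrix(genotypes)
  trait <- trait_vector(trait)
  check_aligned(genotypes, trait)
  prep <- prepare_scan(genotypes, trait, settings)
  st <- prep$engine$stats(matrix(prep$y, ncol = 1L))[, 1L]
  attr(st, "pairs") <- prep$engine$pairs
  st
}

#' Fit an MB-MDR epistasis scan
#'
#' The full three-step MB-MDR analysis for a quantitative trait: (1) each of
#' the 9 two-locus genotype cells of every SNP pair is tested against the
#' pooled rest at level `alpha1` and labelled High/Low/No-evidence; (2) the
#' pair statistic is the larger of the pooled-H and pooled-L association
#' statistics; (3) familywise error is controlled by step-down maxT over
#' `perms` permutations of the trait.  Lower-order (main) effects are
#' handled according to `policy` — see [adjustment_policy()].
#'
#' @param genotypes genotype matrix (see [genotype_matrix()]).
#' @param trait numeric trait vector aligned with the genotype rows.
#' @param policy [adjustment_policy()].
#' @param alpha1,min_cell,perms,seed see [scan_settings()].
#' @param settings optional prebuilt [scan_settings()]; overrides the
#'   individual arguments.
#' @return object of class `mbmdr`: list with `pairs` (data frame
#'   `snp_a`, `snp_b`, `statistic`, `p_adjusted` in lexicographic pair
#'   order), `settings`, `selection` (residual policies), `significant_set`
#'   (on-the-fly policies), `n`, `m` and `call`.
#' @seealso [significant_pairs()], [mbmdr_1d()], [write_pair_results()]
#' @examples
#' sim <- simulate_replicate(simulation_config("alternative", "M27",
#'   maf = 0.25, g2 = 0.1, n = 400, m = 6, seed = 7), 1)
#' fit <- mbmdr(sim$genotypes, sim$trait, perms = 49)
#' summary(fit)
#' @export
mbmdr <- function(genotypes, trait, policy = adjustment_policy("none"),
                  alpha1 = 0.1, min_cell = 10L, perms = 999L, seed = 1L,
                  settings = NULL) {
  cl <- match.call()
  settings <- settings %||%
    scan_settings(alpha1, min_cell, perms, seed, policy)
  genotypes <- genotype_matrix(genotypes)
  trait <- trait_vector(trait)
  check_aligned(genotypes, trait)
  n <- nrow(genotypes)
  m <- ncol(genotypes)
  if (m < 2L) stop_named("need at least 2 SNPs for a pair scan")
  t0 <- proc.time()[["elapsed"]]
  prep <- prepare_scan(genotypes, trait, settings)
  obs <- prep$engine$stats(matrix(prep$y, ncol = 1L))[, 1L]
  B <- settings$perms
  perms_idx <- maxt_permutations(n, B, settings$seed)
  Y <- matrix(prep$y[t(perms_idx)], n, B)
  permstats <- prep$engine$stats(Y)
  padj <- maxt_from_matrix(obs, permstats)
  pairs <- prep$engine$pairs
  res <- data.frame(snp_a = colnames(genotypes)[pairs[, 1L]],
                    snp_b = colnames(genotypes)[pairs[, 2L]],
                    statistic = obs, p_adjusted = padj,
                    stringsAsFactors = FALSE)
  elapsed <- proc.time()[["elapsed"]] - t0
  message(sprintf(
    "mbmdr scan: %d SNPs, %d pairs, B=%d, policy=%s/%s/%s, %.1fs",
    m, nrow(res), B, settings$policy$kind, settings$policy$selector,
    settings$policy$coding$name, elapsed))
  structure(list(pairs = res, settings = settings,
                 selection = prep$selection,
                 significant_set = prep$significant_set,
                 n = n, m = m, elapsed = elapsed, call = cl),
            class = "mbmdr")
}

#' Single-locus MB-MDR scan (MB-MDR 1D)
#'
#' The same machinery as [mbmdr()] applied to the 3 one-locus genotype
#' cells of each SNP: cell-wise labelling at `alpha1`, pooled H/L statistic,
#' and step-down maxT over trait permutations.
#'
#' @inheritParams mbmdr
#' @return object of class `mbmdr_1d`: list with `snps` (data frame `snp`,
#'   `statistic`, `p_adjusted`), `settings`, `n`, `m`, `call`.
#' @export
mbmdr_1d <- function(genotypes, trait, alpha1 = 0.1, min_cell = 10L,
                     perms = 999L, seed = 1L) {
  cl <- match.call()
  settings <- scan_settings(alpha1, min_cell, perms, seed,
                            adjustment_policy("none"))
  genotypes <- genotype_matrix(genotypes)
  trait <- trait_vector(trait)
  check_aligned(genotypes, trait)
  n <- nrow(genotypes)
  engine <- build_1d_engine(genotypes, settings$alpha1, settings$min_cell)
  obs <- engine$stats(matrix(trait, ncol = 1L))[, 1L]
  B <- settings$perms
  perms_idx <- maxt_permutations(n, B, settings$seed)
  Y <- matrix(trait[t(perms_idx)], n, B)
  padj <- maxt_from_matrix(obs, engine$stats(Y))
  structure(list(snps = data.frame(snp = colnames(genotypes),
                                   statistic = obs, p_adjusted = padj,
                                   stringsAsFactors = FALSE),
                 settings = settings, n = n, m = ncol(genotypes),
                 call = cl),
            class = "mbmdr_1d")
}

#' Significant pairs of an MB-MDR fit
#'
#' @param object an `mbmdr` fit.
#' @param alpha familywise significance level on the maxT-adjusted
#'   p-values (default 0.05).
#' @return data frame of pairs with `p_adjusted <= alpha`, sorted by
#'   adjusted p then pair ids.
#' @export
significant_pairs <- function(object, alpha = 0.05) {
  stopifnot(inherits(object, "mbmdr"))
  res <- object$pairs[object$pairs$p_adjusted <= alpha, , drop = FALSE]
  res[order(res$p_adjusted, res$snp_a, res$snp_b, method = "radix"), ,
      drop = FALSE]
}

#' @export
print.mbmdr <- function(x, ...) {
  s <- x$settings
  cat(sprintf("MB-MDR epistasis scan: %d samples, %d SNPs, %d pairs\n",
              x$n, x$m, nrow(x$pairs)))
  cat(sprintf("  policy: %s / %s (%s coding); alpha1=%g, min_cell=%d, B=%d\n",
              s$policy$kind, s$policy$selector, s$policy$coding$name,
              s$alpha1, s$min_cell, s$perms))
  sig <- significant_pairs(x)
  cat(sprintf("  %d pair%s with maxT-adjusted p <= 0.05\n", nrow(sig),
              if (nrow(sig) == 1L) "" else "s"))
  invisible(x)
}

#' @export
summary.mbmdr <- function(object, alpha = 0.05, ...) {
  structure(list(fit = object, alpha = alpha,
                 significant = significant_pairs(object, alpha)),
            class = "summary.mbmdr")
}

#' @export
print.summary.mbmdr <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$fit$selection)) {
    cat("  residual adjustment for: ",
        if (length(x$fit$selection$snp_ids)) {
          paste(x$fit$selection$snp_ids, collapse = ", ")
        } else "(no SNP selected; original trait used)", "\n", sep = "")
  }
  if (length(x$fit$significant_set)) {
    cat("  significant main-effect set: ",
        paste(x$fit$significant_set, collapse = ", "), "\n", sep = "")
  }
  if (nrow(x$significant)) {
    cat(sprintf("\nPairs significant at FWER %g:\n", x$alpha))
    print(x$significant, row.names = FALSE, digits = 4)
  } else {
    cat(sprintf("\nNo pair significant at FWER %g.\n", x$alpha))
  }
  invisible(x)
}

#' Plot maxT-adjusted significance over the pair scan
#'
#' Draws `-log10` adjusted p-values against pair index with the familywise
#' 0.05 threshold marked.
#'
#' @param x an `mbmdr` fit.
#' @param alpha threshold line (default 0.05).
#' @param ... passed to [graphics::plot()].
#' @export
plot.mbmdr <- function(x, alpha = 0.05, ...) {
  p <- x$pairs$p_adjusted
  graphics::plot(seq_along(p), -log10(p), xlab = "pair index",
                 ylab = expression(-log[10](p[adj])),
                 main = "MB-MDR pair scan", pch = 20, ...)
  graphics::abline(h = -log10(alpha), lty = 2)
  invisible(x)
}

#' @export
print.mbmdr_1d <- function(x, ...) {
  cat(sprintf("MB-MDR single-locus scan: %d samples, %d SNPs, B=%d\n",
              x$n, x$m, x$settings$perms))
  sig <- x$snps[x$snps$p_adjusted <= 0.05, , drop = FALSE]
  cat(sprintf("  %d SNP%s with maxT-adjusted p <= 0.05\n", nrow(sig),
              if (nrow(sig) == 1L) "" else "s"))
  if (nrow(sig)) print(sig, row.names = FALSE, digits = 4)
  invisible(x)
}
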