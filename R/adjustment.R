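# Main-effect screening, SNP selection, trait residualisation, and
# construction of per-pair on-the-fly adjustment designs.

# Precomputed sufficient statistics for fast single-SNP F scans under
# either coding, reusable across trait permutations.
build_main_effect_engine <- function(genotypes, coding) {
  coding <- as_coding(coding)
  n <- nrow(genotypes)
  m <- ncol(genotypes)
  if (coding$name == "additive") {
    X <- matrix(as.double(genotypes), n, m)
    xbar <- .colMeans(X, n, m)
    Xc <- sweep(X, 2L, xbar)
    sxx <- .colSums(Xc^2, n, m)
    stats_fun <- function(y) {
      yc <- y - mean(y)
      syy <- sum(yc^2)
      sxy <- as.vector(crossprod(Xc, yc))
      ssr <- ifelse(sxx > 0, sxy^2 / ifelse(sxx > 0, sxx, 1), 0)
      f <- ifelse(sxx > 0, ssr / ((syy - ssr) / (n - 2L)), 0)
      f[!is.finite(f)] <- 0
      f
    }
    df1 <- ifelse(sxx > 0, 1L, 0L)
    df2 <- rep(n - 2L, m)
  } else {
    M <- snp_indicator_matrix(genotypes)
    N3 <- matrix(.colSums(M, n, 3L * m), 3L, m)
    klev <- .colSums(N3 > 0, 3L, m)
    stats_fun <- function(y) {
      sy <- sum(y)
      syy0 <- sum(y^2) - sy^2 / n               # total SS
      S3 <- matrix(crossprod(M, y), 3L, m)
      ssb <- .colSums(ifelse(N3 > 0, S3^2 / pmax(N3, 1), 0), 3L, m) -
        sy^2 / n
      ssb <- pmax(ssb, 0)
      sse <- pmax(syy0 - ssb, 0)
      f <- ifelse(klev > 1, (ssb / pmax(klev - 1, 1)) /
                    (sse / (n - klev)), 0)
      f[!is.finite(f)] <- 0
      f
    }
    df1 <- klev - 1L
    df2 <- n - klev
  }
  list(stats = stats_fun, df1 = df1, df2 = df2, n = n, m = m,
       coding = coding)
}

#' Single-SNP main-effect regression scan
#'
#' For every SNP, ordinary least squares of the trait on intercept plus the
#' coded genotype column(s); the statistic is the overall F for the coded
#' columns (under additive coding the squared slope t; under codominant
#' coding the 2-df one-way genotype ANOVA F).  Monomorphic SNPs carry no
#' information: statistic 0, p 1.
#'
#' @param trait numeric trait vector.
#' @param genotypes genotype matrix.
#' @param coding [coding_scheme()] or its name.
#' @return object of class `main_effect_scan`: data frame with columns
#'   `snp`, `statistic`, `p`, `df1`, `df2`.
#' @export
single_snp_scan <- function(trait, genotypes, coding = coding_scheme()) {
  genotypes <- genotype_matrix(genotypes)
  trait <- trait_vector(trait)
  check_aligned(genotypes, trait)
  if (stats::var(trait) == 0) stop_named("trait is constant")
  eng <- build_main_effect_engine(genotypes, coding)
  f <- eng$stats(trait)
  p <- ifelse(eng$df1 > 0,
              stats::pf(f, pmax(eng$df1, 1), eng$df2, lower.tail = FALSE), 1)
  out <- data.frame(snp = colnames(genotypes), statistic = f, p = p,
                    df1 = eng$df1, df2 = eng$df2,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "coding") <- eng$coding$name
  class(out) <- c("main_effect_scan", "data.frame")
  out
}

#' Select main-effect SNPs for adjustment
#'
#' * `sr_perm`: SNPs whose step-down maxT adjusted p-value (over `B` trait
#'   permutations of the single-SNP F scan) is below 0.05.
#' * `sr_alpha`: SNPs with raw p below 0.05 (no multiplicity correction).
#' * `sr_topk`: the `k` SNPs with the smallest raw p-values (ties broken by
#'   SNP order).
#'
#' An empty selection is a valid result.
#'
#' @param scan a [single_snp_scan()] result.
#' @param method `"sr_perm"`, `"sr_alpha"` or `"sr_topk"`.
#' @param k number of SNPs for `sr_topk`.
#' @param B,seed permutation count and master seed for `sr_perm`.
#' @param trait,genotypes,coding the data behind `scan` (needed to permute
#'   for `sr_perm`).
#' @return object of class `selection_result`: list with `method` and
#'   `snp_ids` ordered by increasing raw p-value.
#' @export
select_snps <- function(scan, method = c("sr_perm", "sr_alpha", "sr_topk"),
                        k = 10L, B = 999L, seed = 1L, trait = NULL,
                        genotypes = NULL, coding = NULL) {
  method <- match.arg(method)
  ord <- order(scan$p, seq_len(nrow(scan)), method = "radix")
  ids <- switch(method,
    sr_alpha = scan$snp[ord][scan$p[ord] < 0.05],
    sr_topk = {
      if (!(is_count(k) && k >= 1 && k <= nrow(scan))) {
        stop_named("k must be in 1..%d", nrow(scan))
      }
      scan$snp[ord][seq_len(k)]
    },
    sr_perm = {
      if (is.null(trait) || is.null(genotypes)) {
        stop_named("sr_perm needs trait and genotypes to permute")
      }
      coding <- as_coding(coding %||% attr(scan, "coding"))
      eng <- build_main_effect_engine(genotype_matrix(genotypes), coding)
      padj <- maxt_adjust(scan$statistic, trait, eng$stats, B = B,
                          seed = seed)
      scan$snp[ord][padj[ord] < 0.05]
    })
  selection_result(method, ids)
}

selection_result <- function(method, snp_ids) {
  structure(list(method = method,
                 snp_ids = as.character(snp_ids)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result: %s, %d SNP%s%s>\n", x$method,
              length(x$snp_ids), if (length(x$snp_ids) == 1L) "" else "s",
              if (length(x$snp_ids)) {
                paste0(": ", paste(x$snp_ids, collapse = ", "))
              } else ""))
  invisible(x)
}

#' Bidirectional stepwise AIC selection of main-effect SNPs
#'
#' Gaussian stepwise search over SNP blocks (a SNP enters or leaves with all
#' its coded columns at once; under codominant coding a SNP is a 3-level
#' factor term).  AIC is `n log(RSS/n) + 2 * edf` up to an additive
#' constant, the scale used by [stats::step()].  At each iteration the
#' single add-or-drop move with the largest AIC decrease is applied; the
#' search stops when no move decreases AIC.
#'
#' @param trait numeric trait vector.
#' @param genotypes genotype matrix.
#' @param coding [coding_scheme()] or its name.
#' @param start `"null"` (intercept-only, the default) or `"full"`.
#' @return a `selection_result` with method `"mr_aic"`.
#' @export
stepwise_aic_select <- function(trait, genotypes, coding = coding_scheme(),
                                start = c("null", "full")) {
  start <- match.arg(start)
  coding <- as_coding(coding)
  genotypes <- genotype_matrix(genotypes)
  trait <- trait_vector(trait)
  check_aligned(genotypes, trait)
  n <- nrow(genotypes)
  m <- ncol(genotypes)
  poly <- which(apply(genotypes, 2L, function(g) length(unique(g))) > 1L)
  vnames <- paste0("S", poly)
  df <- data.frame(.y = as.vector(trait))
  for (i in seq_along(poly)) {
    g <- genotypes[, poly[i]]
    df[[vnames[i]]] <- if (coding$name == "additive") as.double(g)
                       else factor(g, levels = sort(unique(g)))
  }
  max_cols <- 1L + coding$n_columns * length(poly)
  if (start == "full" && n <= max_cols) {
    stop_named("full-start model needs n > %d coded columns", max_cols)
  }
  if (length(poly) == 0L) return(selection_result("mr_aic", character()))
  upper <- stats::reformulate(vnames, response = ".y")
  init <- if (start == "null") stats::lm(.y ~ 1, data = df)
          else stats::lm(upper, data = df)
  fit <- stats::step(init, scope = list(lower = ~1, upper = upper),
                     direction = "both", trace = 0)
  kept <- attr(stats::terms(fit), "term.labels")
  selection_result("mr_aic", colnames(genotypes)[poly[match(kept, vnames)]])
}

#' Residualise the trait on selected main-effect SNPs
#'
#' OLS of the trait on intercept plus the concatenated coded columns of the
#' selected SNPs; the residuals become the new trait.  With an empty
#' selection the original trait is returned unchanged.  A rank-deficient
#' design is handled by pivoting (dependent columns dropped) with a
#' warning.
#'
#' @param trait numeric trait vector.
#' @param genotypes genotype matrix.
#' @param selection a `selection_result` (or character vector of SNP ids).
#' @param coding [coding_scheme()] or its name.
#' @return residual trait vector (same names as the input trait).
#' @export
residualize_trait <- function(trait, genotypes, selection,
                              coding = coding_scheme()) {
  trait <- trait_vector(trait)
  ids <- if (inherits(selection, "selection_result")) selection$snp_ids
         else as.character(selection)
  if (length(ids) == 0L) return(trait)
  genotypes <- genotype_matrix(genotypes)
  check_aligned(genotypes, trait)
  miss <- setdiff(ids, colnames(genotypes))
  if (length(miss)) stop_named("unknown SNP ids: %s",
                               paste(miss, collapse = ", "))
  X <- do.call(cbind, lapply(ids, function(id) {
    encode_genotypes(genotypes[, id], coding)
  }))
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), as.vector(trait))
  if (any(is.na(fit$coefficients))) {
    warning("rank-deficient adjustment design; dependent columns dropped")
  }
  trait_vector(fit$residuals, sample_ids = names(trait))
}

#' Resolve the on-the-fly adjustment design for one pair
#'
#' * `pair_always`: coded columns of both SNPs of the pair.
#' * `one_d_significant` / `list_significant`: coded columns of whichever of
#'   the two SNPs is in the precomputed significant set — none, one, or
#'   both may be adjusted for.
#' * residual or no-adjustment policies: an empty (0-column) design.
#'
#' @param policy [adjustment_policy()].
#' @param pair length-2 vector of SNP indices or names.
#' @param significant_set character vector of significant SNP ids
#'   (precomputed once per dataset; unused for `pair_always`).
#' @param genotypes genotype matrix.
#' @return `n x q` numeric design matrix (possibly `q = 0`).
#' @export
resolve_adjust_design <- function(policy, pair, significant_set = character(),
                                  genotypes) {
  stopifnot(inherits(policy, "adjustment_policy"))
  n <- nrow(genotypes)
  if (policy$kind != "on_the_fly") {
    return(matrix(numeric(0), nrow = n, ncol = 0L))
  }
  ids <- if (is.character(pair)) pair else colnames(genotypes)[pair]
  adj <- switch(policy$selector,
    pair_always = ids,
    one_d_significant = ,
    list_significant = intersect(ids, significant_set))
  if (length(adj) == 0L) {
    return(matrix(numeric(0), nrow = n, ncol = 0L))
  }
  cols <- lapply(adj, function(id) {
    x <- encode_genotypes(genotypes[, id], policy$coding)
    colnames(x) <- paste(id, colnames(x), sep = ".")
    x
  })
  do.call(cbind, cols)
}
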