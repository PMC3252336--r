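# Two-locus binary-mean epistasis models and their exact variance
# decomposition under Hardy-Weinberg and linkage equilibrium.

#' Hardy-Weinberg genotype frequencies
#'
#' @param p minor allele frequency in `(0, 0.5]`.
#' @return frequencies `((1-p)^2, 2p(1-p), p^2)` of genotypes 0/1/2.
#' @export
hwe_freqs <- function(p) {
  if (!(is.numeric(p) && length(p) == 1L && p > 0 && p <= 0.5)) {
    stop_named("MAF must be in (0, 0.5]")
  }
  c((1 - p)^2, 2 * p * (1 - p), p^2)
}

#' Binary mean patterns of the two-locus epistasis models
#'
#' `M27`: the phenotypic mean is high iff the individual carries at least
#' one minor allele at both loci.  `M170`: high iff exactly one of the two
#' loci is heterozygous.  Rows index the genotype (minor-allele count) of
#' the first locus, columns that of the second; 0 = homozygous major.
#'
#' @param model `"M27"` or `"M170"`.
#' @return 3x3 binary matrix.
#' @export
epistasis_pattern <- function(model = c("M27", "M170")) {
  model <- match.arg(model)
  g <- 0:2
  pat <- if (model == "M27") {
    outer(g, g, function(i, j) as.numeric(i >= 1 & j >= 1))
  } else {
    outer(g, g, function(i, j) as.numeric((i == 1) + (j == 1) == 1))
  }
  dimnames(pat) <- list(paste0("g1=", g), paste0("g2=", g))
  pat
}

#' Exact variance decomposition of a two-locus genotypic mean pattern
#'
#' With both loci at MAF `p`, in Hardy-Weinberg and linkage equilibrium,
#' the 9 genotype-cell means decompose the total genetic variance into main
#' effects (per-locus variance of the marginal conditional means) and
#' epistasis (the remainder), and each locus's main-effect variance into an
#' additive part — the squared frequency-weighted covariance of the
#' marginal means with the allele count divided by the allele-count
#' variance (the frequency-weighted least-squares line) — and a dominance
#' remainder.
#'
#' A constant pattern is degenerate: all components are 0 and the ratios
#' are undefined (`NaN`, with `degenerate = TRUE`).  The same applies to
#' the additive/dominance ratios of a pattern whose main-effect variance
#' vanishes.
#'
#' @param pattern 3x3 numeric matrix of genotypic means (rows = locus 1
#'   genotype 0/1/2, columns = locus 2), or a model name for
#'   [epistasis_pattern()].
#' @param p shared minor allele frequency.
#' @return object of class `variance_decomposition`: list with the variance
#'   components (`sigma2_gen`, `sigma2_main`, `sigma2_add`, `sigma2_dom`,
#'   `sigma2_epi`, plus per-locus breakdowns) and the ratios
#'   `main_over_gen`, `add_over_main`, `dom_over_main`, `epi_over_gen`.
#' @examples
#' variance_components("M27", 0.25)
#' @export
variance_components <- function(pattern, p) {
  if (is.character(pattern)) pattern <- epistasis_pattern(pattern)
  stopifnot(is.matrix(pattern), all(dim(pattern) == c(3L, 3L)))
  f <- hwe_freqs(p)
  joint <- outer(f, f)
  mu <- sum(joint * pattern)
  sigma2_gen <- sum(joint * (pattern - mu)^2)
  g <- 0:2
  cg <- sum(f * g)
  vg <- sum(f * (g - cg)^2)
  locus <- function(marg) {
    main <- sum(f * (marg - mu)^2)
    cv <- sum(f * (g - cg) * (marg - mu))
    add <- cv^2 / vg
    c(main = main, add = add, dom = main - add)
  }
  l1 <- locus(as.vector(pattern %*% f))
  l2 <- locus(as.vector(crossprod(pattern, f)))
  sigma2_main <- l1[["main"]] + l2[["main"]]
  sigma2_add <- l1[["add"]] + l2[["add"]]
  sigma2_dom <- sigma2_main - sigma2_add
  sigma2_epi <- sigma2_gen - sigma2_main
  ratio <- function(num, den) if (den > 1e-15) num / den else NaN
  structure(list(
    p = p,
    sigma2_gen = sigma2_gen, sigma2_main = sigma2_main,
    sigma2_add = sigma2_add, sigma2_dom = sigma2_dom,
    sigma2_epi = sigma2_epi,
    locus1 = l1, locus2 = l2,
    main_over_gen = ratio(sigma2_main, sigma2_gen),
    add_over_main = ratio(sigma2_add, sigma2_main),
    dom_over_main = ratio(sigma2_dom, sigma2_main),
    epi_over_gen = ratio(sigma2_epi, sigma2_gen),
    degenerate = sigma2_gen <= 1e-15), class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, digits = 3, ...) {
  cat(sprintf("Two-locus variance decomposition (MAF p = %g)\n", x$p))
  if (x$degenerate) {
    cat("  degenerate pattern: no genetic variance\n")
    return(invisible(x))
  }
  cat(sprintf("  main/gen = %.*f  add/main = %.*f  dom/main = %.*f  epi/gen = %.*f\n",
              digits, x$main_over_gen, digits, x$add_over_main,
              digits, x$dom_over_main, digits, x$epi_over_gen))
  cat(sprintf("  (per unit squared mean offset: gen %.4g, main %.4g, epi %.4g)\n",
              x$sigma2_gen, x$sigma2_main, x$sigma2_epi))
  invisible(x)
}

#' Mean offset scaling a binary pattern to a target genetic variance
#'
#' The high-cell mean offset `d` (with the low mean fixed at 0) such that
#' the two-locus genotypic means `d * pattern` have variance `g2` under
#' HWE and linkage equilibrium: `d = sqrt(g2 / Var(pattern))`.
#'
#' @param pattern 3x3 binary matrix or model name.
#' @param p shared minor allele frequency.
#' @param g2 target total genetic variance (broad-sense heritability when
#'   the phenotypic variance is 1).
#' @return scalar `d` (0 when `g2 = 0`).
#' @export
scaled_offset <- function(pattern, p, g2) {
  stopifnot(is.numeric(g2), length(g2) == 1L, g2 >= 0)
  if (g2 == 0) return(0)
  if (is.character(pattern)) pattern <- epistasis_pattern(pattern)
  vc <- variance_components(pattern, p)
  if (vc$degenerate) stop_named("constant pattern cannot carry g2 > 0")
  sqrt(g2 / vc$sigma2_gen)
}
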