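# Adjustment policies and scan settings.

#' Lower-order effect adjustment policy
#'
#' Describes how SNP main effects are handled during an epistasis scan:
#'
#' * `kind = "none"` — no adjustment (selector `not_applicable`).
#' * `kind = "residual"` — main effects are screened first, the trait is
#'   residualised on the selected SNPs, and the scan runs on the residual
#'   trait.  Selectors: `sr_perm` (single-SNP regression, step-down maxT
#'   adjusted p < 0.05), `sr_alpha` (raw p < 0.05), `sr_topk` (the `k`
#'   smallest raw p-values), `mr_aic` (bidirectional stepwise AIC).
#' * `kind = "on_the_fly"` — adjustment columns enter the MB-MDR test for
#'   each pair directly, replacing the Student t-test by a Wald test.
#'   Selectors: `pair_always` (always adjust for both SNPs of the pair),
#'   `one_d_significant` (adjust for whichever of the pair is significant in
#'   a prior single-locus MB-MDR scan), `list_significant` (likewise, with
#'   significance from a single-SNP regression + maxT screen).
#'
#' @param kind adjustment kind, see above.
#' @param selector SNP selector consistent with `kind`; defaults to the
#'   natural choice (`not_applicable`, `sr_perm`, `pair_always`).
#' @param k number of SNPs kept by `sr_topk`.
#' @param coding [coding_scheme()] (or its name) used for every screening /
#'   adjustment regression under this policy.
#' @return object of class `adjustment_policy`.
#' @examples
#' adjustment_policy("on_the_fly", "pair_always", coding = "codominant")
#' @export
adjustment_policy <- function(kind = c("none", "residual", "on_the_fly"),
                              selector = NULL, k = 10L,
                              coding = coding_scheme("codominant")) {
  kind <- match.arg(kind)
  allowed <- switch(kind,
    none = "not_applicable",
    residual = c("sr_perm", "sr_alpha", "sr_topk", "mr_aic"),
    on_the_fly = c("pair_always", "one_d_significant", "list_significant"))
  selector <- selector %||% allowed[1L]
  if (!selector %in% allowed) {
    stop_named("selector '%s' not valid for kind '%s' (allowed: %s)",
               selector, kind, paste(allowed, collapse = ", "))
  }
  if (selector == "sr_topk" && !(is_count(k) && k >= 1)) {
    stop_named("k must be a positive integer for sr_topk")
  }
  structure(list(kind = kind, selector = selector, k = as.integer(k),
                 coding = as_coding(coding)),
            class = "adjustment_policy")
}

#' @export
print.adjustment_policy <- function(x, ...) {
  cat(sprintf("<adjustment_policy: kind=%s selector=%s coding=%s%s>\n",
              x$kind, x$selector, x$coding$name,
              if (x$selector == "sr_topk") paste0(" k=", x$k) else ""))
  invisible(x)
}

#' Scan settings for MB-MDR
#'
#' @param alpha1 step-1 significance level for labelling the multilocus
#'   genotype cells High/Low (default 0.1).
#' @param min_cell minimum cell size for a cell to be testable; smaller
#'   cells are labelled `O` (default 10).  A cell must also leave at least
#'   `min_cell` samples in its complement.
#' @param perms number of maxT trait permutations `B` (default 999); the
#'   smallest attainable adjusted p-value is `1/(B + 1)`.
#' @param seed master seed; all permutations derive sub-seeds from it.
#' @param policy [adjustment_policy()].
#' @return object of class `scan_settings`.
#' @export
scan_settings <- function(alpha1 = 0.1, min_cell = 10L, perms = 999L,
                          seed = 1L, policy = adjustment_policy("none")) {
  if (!(is.numeric(alpha1) && length(alpha1) == 1L &&
        alpha1 > 0 && alpha1 < 1)) {
    stop_named("alpha1 must be in (0, 1)")
  }
  if (!(is_count(min_cell) && min_cell >= 2)) {
    stop_named("min_cell must be an integer >= 2")
  }
  if (!(is_count(perms) && perms >= 19)) {
    stop_named("perms must be an integer >= 19")
  }
  if (!is_count(seed)) stop_named("seed must be an integer")
  stopifnot(inherits(policy, "adjustment_policy"))
  structure(list(alpha1 = alpha1, min_cell = as.integer(min_cell),
                 perms = as.integer(perms), seed = as.integer(seed),
                 policy = policy),
            class = "scan_settings")
}
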