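# Aggregation of scan results across simulation replicates into power,
# familywise error and false-positive metrics.

#' Classify one replicate's significant pairs against the simulated truth
#'
#' @param significant_pairs data frame (or 2-column matrix) of significant
#'   pair ids, e.g. from [significant_pairs()]; order within a pair does
#'   not matter.
#' @param truth the `truth` record of [simulate_replicate()] (needs fields
#'   `snp1..snp4`).
#' @return named logical vector: `causal` ((SNP1, SNP2) significant),
#'   `any_noncausal` (any significant pair other than the causal one),
#'   `snp3_other` (SNP3 paired with anything but SNP4), `snp3_snp4` (the
#'   (SNP3, SNP4) pair), `snp4_other` (SNP4 paired with anything but SNP3).
#' @export
classify_outcome <- function(significant_pairs, truth) {
  if (is.matrix(significant_pairs)) {
    significant_pairs <- as.data.frame(significant_pairs,
                                       stringsAsFactors = FALSE)
  }
  if (!is.null(significant_pairs$snp_a)) {
    a <- as.character(significant_pairs$snp_a)
    b <- as.character(significant_pairs$snp_b)
  } else if (ncol(significant_pairs) >= 2L) {
    a <- as.character(significant_pairs[[1L]])
    b <- as.character(significant_pairs[[2L]])
  } else {
    a <- b <- character()
  }
  has_pair <- function(x, y) any((a == x & b == y) | (a == y & b == x))
  with_other <- function(x, excl) {
    any((a == x & b != excl & b != x) | (b == x & a != excl & a != x))
  }
  causal <- has_pair(truth$snp1, truth$snp2)
  c(causal = causal,
    any_pair = length(a) > 0L,
    any_noncausal = (length(a) - as.integer(causal)) > 0L,
    snp3_other = with_other(truth$snp3, truth$snp4),
    snp3_snp4 = has_pair(truth$snp3, truth$snp4),
    snp4_other = with_other(truth$snp4, truth$snp3))
}

#' Summarise replicate outcomes into study metrics
#'
#' Fractions of replicates in which: the causal pair (SNP1, SNP2) is
#' significant (`power`); at least one non-causal pair is significant
#' (`fp_any`, the type-I error under a null scenario where no causal pair
#' exists); SNP3 or SNP4 pair up falsely (`fp_snp3_other`, `fp_snp3_snp4`,
#' `fp_snp4_other`).
#'
#' @param outcomes list of [classify_outcome()] records (or a matrix with
#'   one row per replicate).
#' @param causal_exists whether the setting has a true epistatic pair.
#'   Under a null scenario (`FALSE`) there is no causal pair and `fp_any`
#'   counts replicates with any significant pair at all; under the
#'   alternative (`TRUE`, default) it counts pairs other than
#'   (SNP1, SNP2).
#' @return object of class `study_summary`: one-row data frame with the
#'   metric fractions and `replicates`.
#' @export
summarize_outcomes <- function(outcomes, causal_exists = TRUE) {
  if (is.list(outcomes)) outcomes <- do.call(rbind, outcomes)
  if (is.null(dim(outcomes)) || nrow(outcomes) < 1L) {
    stop_named("need at least one replicate outcome")
  }
  frac <- colMeans(outcomes)
  out <- data.frame(replicates = nrow(outcomes),
                    power = frac[["causal"]],
                    fp_any = if (causal_exists) frac[["any_noncausal"]]
                             else frac[["any_pair"]],
                    fp_snp3_other = frac[["snp3_other"]],
                    fp_snp3_snp4 = frac[["snp3_snp4"]],
                    fp_snp4_other = frac[["snp4_other"]])
  class(out) <- c("study_summary", "data.frame")
  out
}

#' Bradley's liberal robustness criterion
#'
#' An empirical type-I error rate is adequately controlled at nominal level
#' `alpha` if it lies in the open interval `(alpha/2, 3*alpha/2)` — for
#' `alpha = 0.05`, `(0.025, 0.075)`.
#'
#' @param rate empirical rate in `[0, 1]`.
#' @param alpha nominal level (default 0.05).
#' @return logical.
#' @export
bradley_robust <- function(rate, alpha = 0.05) {
  stopifnot(all(rate >= 0 & rate <= 1), alpha > 0, alpha < 1)
  eps <- 1e-10  # endpoints are excluded even under roundoff (3*alpha/2
                # is not exactly representable)
  (rate - alpha / 2 > eps) & (3 * alpha / 2 - rate > eps)
}

#' Run a simulate-scan-summarise study for one setting
#'
#' Simulates `replicates` datasets under `config`, runs the MB-MDR scan
#' with the given policy on each (per-replicate scan seeds derive from the
#' study seed), classifies significant pairs at FWER `alpha`, and
#' summarises.
#'
#' @param config [simulation_config()].
#' @param policy [adjustment_policy()].
#' @param alpha1,min_cell,perms see [scan_settings()].
#' @param alpha familywise significance level applied to the adjusted
#'   p-values (default 0.05).
#' @param replicates number of replicates (default `config$replicates`).
#' @param verbose print one progress line per replicate to standard error.
#' @return a `study_summary` (see [summarize_outcomes()]) with the setting
#'   columns (`scenario`, `model`, `maf`, `g2`, `policy`, `selector`,
#'   `coding`, `perms`) prepended and `bradley_ok` appended.
#' @export
run_study <- function(config, policy = adjustment_policy("none"),
                      alpha1 = 0.1, min_cell = 10L, perms = 999L,
                      alpha = 0.05, replicates = config$replicates,
                      verbose = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  outcomes <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    rep_data <- simulate_replicate(config, r)
    fit <- suppressMessages(mbmdr(
      rep_data$genotypes, rep_data$trait, policy = policy,
      alpha1 = alpha1, min_cell = min_cell, perms = perms,
      seed = derive_seed(config$seed, "scan", r)))
    sig <- significant_pairs(fit, alpha)
    outcomes[[r]] <- classify_outcome(sig, rep_data$truth)
    if (verbose) {
      message(sprintf("replicate %d/%d: %d significant pair(s)",
                      r, replicates, nrow(sig)))
    }
  }
  summ <- summarize_outcomes(outcomes,
                             causal_exists = config$scenario == "alternative")
  cbind(data.frame(scenario = config$scenario, model = config$model,
                   maf = config$maf, g2 = config$g2,
                   policy = policy$kind, selector = policy$selector,
                   coding = policy$coding$name, perms = as.integer(perms),
                   stringsAsFactors = FALSE),
        summ,
        data.frame(bradley_ok = bradley_robust(summ$fp_any, alpha)))
}
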