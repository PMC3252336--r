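# MB-MDR steps 1-2 for a single SNP pair, in the direct (per-pair) form.
# These functions define the method; the scan engines in engine.R compute
# the same quantities vectorised across all pairs and permutations.

#' Partition samples into the 9 two-locus genotype cells
#'
#' Two bi-allelic markers give rise to nine multilocus genotype cells; cell
#' index `3 * g_a + g_b` in `0..8` (genotypes are minor-allele counts).
#'
#' @param genotypes genotype matrix.
#' @param a,b distinct SNP column indices (or names).
#' @return object of class `cell_partition`: list with `pair` (indices),
#'   `cell_index` (length-n vector in 0..8) and `cell_sizes` (9 counts).
#' @export
partition_pair <- function(genotypes, a, b) {
  if (is.character(a)) a <- match(a, colnames(genotypes))
  if (is.character(b)) b <- match(b, colnames(genotypes))
  m <- ncol(genotypes)
  if (anyNA(c(a, b)) || a < 1 || b < 1 || a > m || b > m) {
    stop_named("invalid SNP index")
  }
  if (a == b) stop_named("a pair needs two distinct SNPs")
  idx <- 3L * genotypes[, a] + genotypes[, b]
  structure(list(pair = c(a = as.integer(a), b = as.integer(b)),
                 cell_index = as.integer(idx),
                 cell_sizes = tabulate(idx + 1L, nbins = 9L)),
            class = "cell_partition")
}

#' Label the 9 genotype cells High / Low / No-evidence (MB-MDR steps 1-2)
#'
#' Each cell with at least `min_cell` members (and at least `min_cell`
#' members outside it) is tested against the pooled remaining cells with
#' [association_test()].  Cells with two-sided p below `alpha1` are labelled
#' `H` (positive statistic) or `L` (negative statistic); everything else —
#' non-significant, too small, or untestable — is `O` (no evidence).
#'
#' @param partition a [partition_pair()] result (or any object with a
#'   `cell_index` field; a single-locus partition has cells `0..2`).
#' @param trait numeric trait vector.
#' @param adjust_design optional main-effect design passed through to
#'   [association_test()].
#' @param settings [scan_settings()].
#' @return object of class `hlo_labels`: list with `labels` (factor H/L/O
#'   per cell), `step1_stats` (signed statistics, 0 for untested cells) and
#'   `step1_pvalues` (`NA` for untested cells).
#' @export
hlo_classify <- function(partition, trait, adjust_design = NULL,
                         settings = scan_settings()) {
  idx <- partition$cell_index
  n <- length(trait)
  stopifnot(length(idx) == n)
  ncell <- if (max(idx) > 2L || inherits(partition, "cell_partition")) 9L
           else 3L
  sizes <- tabulate(idx + 1L, nbins = ncell)
  labels <- rep("O", ncell)
  stats <- numeric(ncell)
  pvals <- rep(NA_real_, ncell)
  for (c in seq_len(ncell)) {
    nc <- sizes[c]
    if (nc < settings$min_cell || nc > n - settings$min_cell) next
    res <- tryCatch(
      association_test(trait, as.double(idx == c - 1L), adjust_design),
      error = function(e) NULL)  # collinear with design: untestable, O
    if (is.null(res)) next
    stats[c] <- res$statistic
    pvals[c] <- res$p
    if (res$p < settings$alpha1) {
      labels[c] <- if (res$statistic > 0) "H" else "L"
    }
  }
  structure(list(labels = factor(labels, levels = c("H", "L", "O")),
                 step1_stats = stats, step1_pvalues = pvals,
                 cell_sizes = sizes),
            class = "hlo_labels")
}

#' MB-MDR pair statistic (step 2)
#'
#' The pair statistic is `max(T_H, T_L, 0)` where `T_H` is the
#' [association_test()] statistic of the pooled `H` cells against all other
#' samples (0 if no `H` cells) and `T_L` is minus the statistic of the pooled
#' `L` cells against the rest (0 if no `L` cells).  Only the H/L/O sets
#' matter, so the statistic is invariant under any relabelling of cell
#' indices that preserves them.
#'
#' @param labels an [hlo_classify()] result.
#' @param partition the matching partition.
#' @param trait numeric trait vector.
#' @param adjust_design optional design, as used for the labels.
#' @return non-negative scalar statistic.
#' @export
pair_statistic <- function(labels, partition, trait, adjust_design = NULL) {
  idx <- partition$cell_index
  lab <- as.character(labels$labels)
  one_side <- function(which_lab) {
    cells <- which(lab == which_lab) - 1L
    if (length(cells) == 0L) return(0)
    ind <- as.double(idx %in% cells)
    if (all(ind == 1) || all(ind == 0)) return(0)
    st <- tryCatch(
      suppressWarnings(association_test(trait, ind, adjust_design)$statistic),
      error = function(e) 0)
    if (which_lab == "H") st else -st
  }
  max(one_side("H"), one_side("L"), 0)
}
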