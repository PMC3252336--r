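# Genotype / trait containers, validation, codings, and the delimited-text
# readers and writers used by the scan tools.
#
# Orientation is fixed throughout the package: a genotype value is the minor
# allele count, 0 = homozygous major, 1 = heterozygote, 2 = homozygous minor.

#' Construct a validated genotype matrix
#'
#' A genotype matrix is an `n_samples x n_snps` integer matrix of minor-allele
#' counts in `{0, 1, 2}` with unique SNP identifiers as column names and
#' unique sample identifiers as row names.  Missing values are rejected:
#' the simulator produces complete data and silent imputation would
#' contaminate downstream test statistics.
#'
#' @param values numeric or integer matrix with entries in `{0, 1, 2}`.
#' @param snp_ids character vector of unique SNP identifiers (defaults to
#'   existing column names, else `snp1, snp2, ...`).
#' @param sample_ids character vector of unique sample identifiers (defaults
#'   to existing row names, else `s1, s2, ...`).
#' @return the validated integer matrix with `snp_ids` as column names and
#'   `sample_ids` as row names.
#' @examples
#' genotype_matrix(matrix(c(0L, 1L, 2L, 0L, 1L, 1L), nrow = 3))
#' @export
genotype_matrix <- function(values, snp_ids = NULL, sample_ids = NULL) {
  if (!is.matrix(values)) stop_named("genotypes must be a matrix")
  n <- nrow(values)
  m <- ncol(values)
  if (n < 2L) stop_named("need at least 2 samples, got %d", n)
  if (m < 1L) stop_named("need at least 1 SNP")
  snp_ids <- snp_ids %||% colnames(values) %||% paste0("snp", seq_len(m))
  sample_ids <- sample_ids %||% rownames(values) %||% paste0("s", seq_len(n))
  if (length(snp_ids) != m) stop_named("snp_ids length %d != %d SNP columns",
                                       length(snp_ids), m)
  if (length(sample_ids) != n) stop_named(
    "sample_ids length %d != %d sample rows", length(sample_ids), n)
  if (anyDuplicated(snp_ids)) stop_named("duplicate SNP ids")
  if (anyDuplicated(sample_ids)) stop_named("duplicate sample ids")
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop_named("missing genotype at sample '%s', SNP '%s' (not supported)",
               sample_ids[bad[1L]], snp_ids[bad[2L]])
  }
  ok <- values == 0 | values == 1 | values == 2
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1L, ]
    stop_named(
      "invalid genotype value '%s' at sample '%s', SNP '%s' (must be 0/1/2)",
      format(values[bad[1L], bad[2L]]), sample_ids[bad[1L]], snp_ids[bad[2L]])
  }
  storage.mode(values) <- "integer"
  dimnames(values) <- list(as.character(sample_ids), as.character(snp_ids))
  values
}

#' Construct a validated quantitative trait vector
#'
#' @param values numeric vector of finite trait values.
#' @param sample_ids optional sample identifiers (defaults to existing names).
#' @return named numeric vector.
#' @export
trait_vector <- function(values, sample_ids = NULL) {
  if (!is.numeric(values)) stop_named("trait must be numeric")
  if (length(values) < 2L) stop_named("trait needs at least 2 values")
  if (!all(is.finite(values))) stop_named("trait contains non-finite values")
  sample_ids <- sample_ids %||% names(values) %||%
    paste0("s", seq_along(values))
  if (length(sample_ids) != length(values)) {
    stop_named("sample_ids length mismatch")
  }
  if (anyDuplicated(sample_ids)) stop_named("duplicate sample ids in trait")
  values <- as.double(values)
  names(values) <- as.character(sample_ids)
  values
}

check_aligned <- function(genotypes, trait) {
  if (length(trait) != nrow(genotypes)) {
    stop_named("trait length %d != %d genotype rows",
               length(trait), nrow(genotypes))
  }
  tn <- names(trait)
  gn <- rownames(genotypes)
  if (!is.null(tn) && !is.null(gn) && !identical(tn, gn)) {
    stop_named("trait sample ids do not match genotype sample ids")
  }
  invisible(TRUE)
}

#' Genotype coding schemes
#'
#' `additive` codes a genotype as a single column equal to the minor-allele
#' count (one degree of freedom).  `codominant` codes it as the two indicator
#' columns `1(g == 1)` and `1(g == 2)` which, with an intercept, span the full
#' 3-level genotype factor (two degrees of freedom).  Codominant adjustment
#' therefore removes every genotype-mean difference of a SNP, additive
#' adjustment only the best-fitting linear-in-allele-count part.
#'
#' @param name `"additive"` or `"codominant"`.
#' @return an object of class `coding_scheme` with fields `name` and
#'   `n_columns`.
#' @export
coding_scheme <- function(name = c("codominant", "additive")) {
  name <- match.arg(name)
  structure(list(name = name,
                 n_columns = if (name == "additive") 1L else 2L),
            class = "coding_scheme")
}

#' @export
print.coding_scheme <- function(x, ...) {
  cat(sprintf("<coding_scheme: %s (%d column%s)>\n", x$name, x$n_columns,
              if (x$n_columns > 1L) "s" else ""))
  invisible(x)
}

as_coding <- function(coding) {
  if (inherits(coding, "coding_scheme")) return(coding)
  coding_scheme(coding)
}

#' Encode a genotype column as regression design columns
#'
#' @param g vector of genotypes in `{0, 1, 2}`.
#' @param coding a [coding_scheme()] or its name.
#' @return `length(g) x n_columns` numeric matrix; one column equal to `g`
#'   for additive coding, indicator columns `1(g == 1)`, `1(g == 2)` for
#'   codominant coding.
#' @examples
#' encode_genotypes(c(0, 1, 2), "codominant")
#' @export
encode_genotypes <- function(g, coding = coding_scheme("codominant")) {
  coding <- as_coding(coding)
  if (anyNA(g) || !all(g == 0 | g == 1 | g == 2)) {
    stop_named("genotype values must be 0/1/2 with no missing values")
  }
  g <- as.double(g)
  if (coding$name == "additive") {
    matrix(g, ncol = 1L, dimnames = list(NULL, "add"))
  } else {
    cbind(het = as.double(g == 1), hom = as.double(g == 2))
  }
}

# ---------------------------------------------------------------------------
# File formats.  Genotype file: TSV, header `sample_id<TAB>snp...`, one row
# per sample.  Trait file: TSV with columns sample_id, trait.  Result file:
# TSV snp_a, snp_b, statistic, p_adjusted sorted by p_adjusted then pair ids.

#' Read a genotype matrix from delimited text
#'
#' Two dialects are supported: `matrix_tsv` (tab-separated, header row of SNP
#' ids, first column the sample id) and `plink_raw_like` (whitespace
#' separated, same layout; a convenience reader for allele-count exports, not
#' a full PLINK parser).
#'
#' @param path file path.
#' @param dialect `"matrix_tsv"` or `"plink_raw_like"`.
#' @return validated genotype matrix (see [genotype_matrix()]).
#' @export
read_genotypes <- function(path, dialect = c("matrix_tsv", "plink_raw_like")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_named("genotype file not found: %s", path)
  df <- utils::read.table(path, header = TRUE,
                          sep = if (dialect == "matrix_tsv") "\t" else "",
                          colClasses = "character", check.names = FALSE,
                          comment.char = "", quote = "")
  if (ncol(df) < 2L) stop_named("genotype file needs sample id + >=1 SNP")
  sample_ids <- df[[1L]]
  snp_ids <- colnames(df)[-1L]
  vals <- suppressWarnings(
    vapply(df[-1L], as.numeric, numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop_named("non-numeric genotype at sample '%s', SNP '%s' in %s",
               sample_ids[bad[1L]], snp_ids[bad[2L]], path)
  }
  genotype_matrix(vals, snp_ids = snp_ids, sample_ids = sample_ids)
}

#' Write a genotype matrix as TSV
#'
#' @param genotypes genotype matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(genotypes, path) {
  genotypes <- genotype_matrix(genotypes)
  df <- data.frame(sample_id = rownames(genotypes), genotypes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a quantitative trait from TSV
#'
#' Expects columns `sample_id` and `trait`.
#'
#' @param path file path.
#' @return named numeric trait vector.
#' @export
read_trait <- function(path) {
  if (!file.exists(path)) stop_named("trait file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, quote = "")
  if (!all(c("sample_id", "trait") %in% colnames(df))) {
    stop_named("trait file must have columns sample_id and trait")
  }
  trait_vector(as.numeric(df$trait), sample_ids = as.character(df$sample_id))
}

#' Write a quantitative trait as TSV
#'
#' @param trait named numeric vector (see [trait_vector()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trait <- function(trait, path) {
  trait <- trait_vector(trait)
  df <- data.frame(sample_id = names(trait), trait = trait,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write pair-scan results as TSV
#'
#' Columns `snp_a`, `snp_b`, `statistic`, `p_adjusted`, sorted by adjusted
#' p-value ascending, ties broken by `(snp_a, snp_b)` lexicographically.
#'
#' @param results data frame with those columns (e.g. `fit$pairs` from
#'   [mbmdr()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pair_results <- function(results, path) {
  need <- c("snp_a", "snp_b", "statistic", "p_adjusted")
  if (!all(need %in% colnames(results))) {
    stop_named("results must have columns %s", paste(need, collapse = ", "))
  }
  results <- results[need]
  ord <- order(results$p_adjusted, results$snp_a, results$snp_b,
               method = "radix")
  utils::write.table(results[ord, ], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
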