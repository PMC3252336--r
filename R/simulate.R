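# Two-locus quantitative-trait simulator.
#
# Each replicate draws m independent SNPs in HWE and linkage equilibrium:
# SNP1/SNP2 (the functional pair, MAF p), SNP3 (additive main effect) and
# SNP4 (over-dominant main effect) at U(0.05, 0.5) MAFs, and m - 4 noise
# SNPs at U(0.05, 0.5) MAFs.  The trait is
#
#   y = d * pattern(g1, g2) + beta3 * g3 + beta4 * 1(g4 == 1) + e,
#
# with d scaling the binary epistasis pattern to genetic variance g2,
# beta3/beta4 scaling the main effects to population variances sigma2_3,
# sigma2_4 ~ U(0, 0.06), and e ~ N(0, 1 - g2 - sigma2_3 - sigma2_4) so the
# total phenotypic variance is 1.  The null scenarios switch effects off:
# H01 keeps only the SNP3/SNP4 main effects (d = 0); H02 has no genetic
# contribution at all (e ~ N(0, 1)).

#' Simulation configuration
#'
#' @param scenario `"alternative"` (epistatic pair plus main-effect loci),
#'   `"H01"` (main-effect loci only) or `"H02"` (no genetic effects).
#' @param model epistasis model `"M27"` or `"M170"` (pattern of the
#'   functional pair; irrelevant under the nulls but retained so SNP1/SNP2
#'   keep their designated MAF).
#' @param maf shared minor allele frequency of SNP1 and SNP2.
#' @param g2 total genetic variance of the two-locus model (0 under the
#'   nulls).
#' @param n samples per replicate (default 2000).
#' @param m SNPs per replicate, at least 4 (default 100: the 4 functional /
#'   main-effect loci plus 96 noise markers).
#' @param replicates number of replicates (default 500).
#' @param seed master seed; replicate `r` derives its own sub-seed.
#' @param noise_maf_range range of the uniform MAF draw for noise SNPs and
#'   for SNP3/SNP4 (default `c(0.05, 0.5)`).
#' @param main_var_max upper bound of the uniform draw for the SNP3/SNP4
#'   main-effect variances (default 0.06).
#' @param maf3,maf4 optional fixed MAFs for SNP3/SNP4 (default: drawn per
#'   replicate from `noise_maf_range`).
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(scenario = c("alternative", "H01", "H02"),
                              model = c("M27", "M170"), maf = 0.25,
                              g2 = 0.05, n = 2000L, m = 100L,
                              replicates = 500L, seed = 1L,
                              noise_maf_range = c(0.05, 0.5),
                              main_var_max = 0.06,
                              maf3 = NULL, maf4 = NULL) {
  scenario <- match.arg(scenario)
  model <- match.arg(model)
  if (scenario != "alternative") {
    if (!missing(g2) && g2 != 0) {
      stop_named("null scenario %s requires g2 = 0", scenario)
    }
    g2 <- 0
  } else if (!(is.numeric(g2) && length(g2) == 1L && g2 > 0)) {
    stop_named("alternative scenario requires g2 > 0")
  }
  hwe_freqs(maf)  # validates maf
  if (!(is_count(n) && n >= 10)) stop_named("n must be an integer >= 10")
  if (!(is_count(m) && m >= 4)) stop_named("m must be an integer >= 4")
  if (!(is_count(replicates) && replicates >= 1)) {
    stop_named("replicates must be a positive integer")
  }
  if (!is_count(seed)) stop_named("seed must be an integer")
  stopifnot(length(noise_maf_range) == 2L,
            noise_maf_range[1] > 0, noise_maf_range[2] <= 0.5,
            noise_maf_range[1] < noise_maf_range[2])
  if (!(is.numeric(main_var_max) && main_var_max >= 0 &&
        g2 + 2 * main_var_max < 1)) {
    stop_named("main_var_max inconsistent with unit phenotypic variance")
  }
  for (mm in list(maf3, maf4)) if (!is.null(mm)) hwe_freqs(mm)
  structure(list(scenario = scenario, model = model, maf = maf, g2 = g2,
                 n = as.integer(n), m = as.integer(m),
                 replicates = as.integer(replicates),
                 seed = as.integer(seed),
                 noise_maf_range = as.double(noise_maf_range),
                 main_var_max = as.double(main_var_max),
                 maf3 = maf3, maf4 = maf4),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "<simulation_config: %s %s p=%g g2=%g n=%d m=%d replicates=%d seed=%d>\n",
    x$scenario, x$model, x$maf, x$g2, x$n, x$m, x$replicates, x$seed))
  invisible(x)
}

#' Simulate one replicate dataset
#'
#' Reproducible in isolation: replicate `r` is generated from the sub-seed
#' derived from `(config$seed, "replicate", r)`.
#'
#' @param config [simulation_config()].
#' @param replicate_index replicate number `r >= 1`.
#' @return list with `genotypes` (n x m genotype matrix; SNP1..SNP4 are the
#'   first four columns, named `SNP1..SNP4`, noise SNPs `N5..`), `trait`
#'   (named numeric vector) and `truth` (list of the causal/main-effect SNP
#'   ids and every drawn parameter).
#' @export
simulate_replicate <- function(config, replicate_index = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  if (!(is_count(replicate_index) && replicate_index >= 1)) {
    stop_named("replicate_index must be a positive integer")
  }
  set.seed(derive_seed(config$seed, "replicate", replicate_index))
  n <- config$n
  m <- config$m
  rng <- config$noise_maf_range
  maf3 <- config$maf3 %||% stats::runif(1, rng[1], rng[2])
  maf4 <- config$maf4 %||% stats::runif(1, rng[1], rng[2])
  var3 <- stats::runif(1, 0, config$main_var_max)
  var4 <- stats::runif(1, 0, config$main_var_max)
  noise_mafs <- stats::runif(m - 4L, rng[1], rng[2])
  mafs <- c(config$maf, config$maf, maf3, maf4, noise_mafs)
  G <- vapply(mafs, function(p) stats::rbinom(n, 2L, p), integer(n))
  snp_ids <- c("SNP1", "SNP2", "SNP3", "SNP4",
               if (m > 4L) paste0("N", 5L:m))
  G <- genotype_matrix(G, snp_ids = snp_ids,
                       sample_ids = paste0("s", seq_len(n)))

  if (config$scenario == "H02") {
    var3 <- 0
    var4 <- 0
  }
  d <- if (config$scenario == "alternative") {
    scaled_offset(config$model, config$maf, config$g2)
  } else 0
  beta3 <- if (var3 > 0) sqrt(var3 / (2 * maf3 * (1 - maf3))) else 0
  q4 <- 2 * maf4 * (1 - maf4)           # heterozygote frequency
  beta4 <- if (var4 > 0) sqrt(var4 / (q4 * (1 - q4))) else 0
  sigma2_e <- 1 - config$g2 - var3 - var4
  if (sigma2_e <= 0) stop_named("environmental variance <= 0")

  pat <- epistasis_pattern(config$model)
  mu <- d * pat[cbind(G[, 1L] + 1L, G[, 2L] + 1L)] +
    beta3 * G[, 3L] + beta4 * (G[, 4L] == 1L)
  y <- mu + stats::rnorm(n, 0, sqrt(sigma2_e))
  trait <- trait_vector(y, sample_ids = rownames(G))

  truth <- list(replicate = as.integer(replicate_index),
                snp1 = "SNP1", snp2 = "SNP2", snp3 = "SNP3", snp4 = "SNP4",
                scenario = config$scenario, model = config$model,
                maf = config$maf, g2 = config$g2, d = d,
                maf3 = maf3, maf4 = maf4, var3 = var3, var4 = var4,
                beta3 = beta3, beta4 = beta4, sigma2_e = sigma2_e)
  list(genotypes = G, trait = trait, truth = truth)
}

#' Lazy stream of simulation replicates
#'
#' @param config [simulation_config()].
#' @return object of class `simulation_study`: list with `config` and
#'   `replicate(r)`, a function returning replicate `r` (see
#'   [simulate_replicate()]); the stream is deterministic given the master
#'   seed and each replicate is reproducible in isolation.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  structure(list(config = config,
                 replicate = function(r) simulate_replicate(config, r)),
            class = "simulation_study")
}

#' @export
print.simulation_study <- function(x, ...) {
  cat("<simulation_study>\n  ")
  print(x$config)
  invisible(x)
}
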