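table1_expected <- list(
  # model, MAF, main/gen, add/main, dom/main, epi/gen (3-decimal values;
  # the M170 p=0.5 additive/dominance split is undefined because the
  # main-effects variance is exactly zero there)
  list("M27", 0.10, 0.319, 0.947, 0.053, 0.681),
  list("M27", 0.25, 0.609, 0.857, 0.143, 0.391),
  list("M27", 0.50, 0.857, 0.667, 0.333, 0.143),
  list("M170", 0.10, 0.581, 0.780, 0.220, 0.419),
  list("M170", 0.25, 0.118, 0.400, 0.600, 0.882),
  list("M170", 0.50, 0.000, NA, NA, 1.000))

test_that("analytic variance decomposition reproduces the model table", {
  for (row in table1_expected) {
    vc <- variance_components(row[[1]], row[[2]])
    expect_equal(round(vc$main_over_gen, 3), row[[3]],
                 info = paste(row[[1]], row[[2]]))
    expect_equal(round(vc$epi_over_gen, 3), row[[6]],
                 info = paste(row[[1]], row[[2]]))
    if (is.na(row[[4]])) {
      expect_true(is.nan(vc$add_over_main))
      expect_true(is.nan(vc$dom_over_main))
      expect_lt(vc$sigma2_main, 1e-15)
    } else {
      expect_equal(round(vc$add_over_main, 3), row[[4]],
                   info = paste(row[[1]], row[[2]]))
      expect_equal(round(vc$dom_over_main, 3), row[[5]],
                   info = paste(row[[1]], row[[2]]))
    }
    # components are a decomposition
    expect_equal(vc$sigma2_main + vc$sigma2_epi, vc$sigma2_gen,
                 tolerance = 1e-12)
    expect_equal(vc$sigma2_add + vc$sigma2_dom, vc$sigma2_main,
                 tolerance = 1e-12)
    expect_true(all(c(vc$sigma2_add, vc$sigma2_dom, vc$sigma2_epi,
                      vc$sigma2_gen) >= -1e-12))
    expect_equal(vc$main_over_gen + vc$epi_over_gen, 1, tolerance = 1e-12)
  }
  # closed form at p = 0.5: per-locus main 27/256, additive 18/256
  vc5 <- variance_components("M27", 0.5)
  expect_equal(vc5$locus1[["main"]], 27 / 256, tolerance = 1e-12)
  expect_equal(vc5$locus1[["add"]], 18 / 256, tolerance = 1e-12)
})

test_that("Hardy-Weinberg frequencies and the mean offset scale correctly", {
  expect_equal(hwe_freqs(0.5), c(0.25, 0.5, 0.25))
  expect_equal(hwe_freqs(0.1), c(0.81, 0.18, 0.01))
  expect_equal(sum(hwe_freqs(0.3127)), 1, tolerance = 1e-12)
  expect_error(hwe_freqs(0.6), "MAF")
  expect_error(hwe_freqs(0), "MAF")

  expect_identical(scaled_offset("M27", 0.25, 0), 0)
  # the scaled pattern recovers the target variance under enumeration
  for (model in c("M27", "M170")) {
    for (g2 in c(0.01, 0.05, 0.1)) {
      d <- scaled_offset(model, 0.25, g2)
      f <- hwe_freqs(0.25)
      mu <- d * epistasis_pattern(model)
      jp <- outer(f, f)
      expect_equal(sum(jp * mu^2) - sum(jp * mu)^2, g2, tolerance = 1e-12)
    }
  }
  expect_error(scaled_offset(matrix(1, 3, 3), 0.25, 0.05), "constant")
})

test_that("pattern definitions match the two-locus models", {
  p27 <- epistasis_pattern("M27")
  expect_equal(unname(p27), outer(0:2, 0:2,
                                  function(i, j) as.numeric(i >= 1 & j >= 1)))
  p170 <- epistasis_pattern("M170")
  expect_equal(unname(p170[2, ]), c(1, 0, 1))  # het x hom is high
  expect_equal(unname(p170[, 2]), c(1, 0, 1))
  expect_equal(unname(diag(p170)), c(0, 0, 0))
})

test_that("simulated replicates respect the configured moments", {
  cfg <- simulation_config("H02", "M27", maf = 0.25, n = 2000, m = 10,
                           seed = 7)
  rep1 <- simulate_replicate(cfg, 1)
  expect_identical(dim(rep1$genotypes), c(2000L, 10L))
  expect_equal(var(rep1$trait), 1, tolerance = 0.15)
  expect_identical(rep1$truth$d, 0)
  expect_identical(rep1$truth$beta3, 0)

  # SNP1 genotype frequencies within binomial sampling error of HWE
  freq <- tabulate(rep1$genotypes[, 1] + 1L, 3L) / 2000
  exp_freq <- hwe_freqs(0.25)
  expect_true(all(abs(freq - exp_freq) <
                    4 * sqrt(exp_freq * (1 - exp_freq) / 2000)))

  # over-dominance of SNP4: heterozygote trait mean exceeds both
  # homozygote means by ~beta4 under H01
  cfg1 <- simulation_config("H01", "M27", maf = 0.25, n = 2000, m = 10,
                            seed = 8, maf4 = 0.4)
  r <- simulate_replicate(cfg1, 2)
  cls <- tapply(as.vector(r$trait), r$genotypes[, "SNP4"], mean)
  expect_gt(cls[["1"]], cls[["0"]])
  expect_gt(cls[["1"]], cls[["2"]])
  expect_equal(cls[["1"]] - cls[["0"]], r$truth$beta4, tolerance = 0.25)
  expect_identical(r$truth$d, 0)

  # epistatic component variance matches g2 on average
  cfg_a <- simulation_config("alternative", "M27", maf = 0.25, g2 = 0.1,
                             n = 2000, m = 4, seed = 9)
  pat <- epistasis_pattern("M27")
  v <- vapply(1:60, function(r) {
    s <- simulate_replicate(cfg_a, r)
    mu <- s$truth$d * pat[cbind(s$genotypes[, 1] + 1L,
                                s$genotypes[, 2] + 1L)]
    var(mu)
  }, numeric(1))
  expect_equal(mean(v), 0.1, tolerance = 0.05)
})

test_that("simulation streams are reproducible and replicates distinct", {
  cfg <- simulation_config("alternative", "M170", maf = 0.1, g2 = 0.05,
                           n = 100, m = 6, seed = 77)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  r1 <- s1$replicate(3)
  r2 <- s2$replicate(3)
  expect_identical(r1$genotypes, r2$genotypes)
  expect_identical(r1$trait, r2$trait)
  expect_false(identical(r1$genotypes, s1$replicate(4)$genotypes))

  expect_error(simulation_config("H01", "M27", maf = 0.25, g2 = 0.1),
               "g2 = 0")
  expect_error(simulation_config("alternative", "M27", maf = 0.25, g2 = 0),
               "g2 > 0")
})
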