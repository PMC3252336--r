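test_that("single-SNP F statistics match per-SNP linear model fits", {
  G <- random_genotypes(150, 8, seed = 81)
  set.seed(82)
  y <- rnorm(150) + 0.4 * G[, 2]
  for (cod in c("additive", "codominant")) {
    scan <- single_snp_scan(y, G, cod)
    for (j in c(1, 2, 5)) {
      x <- if (cod == "additive") cbind(G[, j]) else
        encode_genotypes(G[, j], "codominant")
      an <- anova(lm(y ~ x))
      expect_equal(scan$statistic[j], an[1, "F value"], tolerance = 1e-10)
      expect_equal(scan$p[j], an[1, "Pr(>F)"], tolerance = 1e-10)
    }
  }
  # additive F is the squared slope t
  scan_a <- single_snp_scan(y, G, "additive")
  tslope <- summary(lm(y ~ G[, 2]))$coefficients[2, "t value"]
  expect_equal(scan_a$statistic[2], tslope^2, tolerance = 1e-10)

  # a monomorphic SNP carries no information
  Gm <- genotype_matrix(cbind(mono = rep(0L, 150), poly = G[, 1]))
  sm <- single_snp_scan(y, Gm, "codominant")
  expect_equal(sm$statistic[1], 0)
  expect_equal(sm$p[1], 1)
})

test_that("codominant coding detects over-dominance that additive misses", {
  # heterozygote advantage at MAF 0.5: the additive (allele-count) slope is
  # orthogonal to the effect, the 2-df genotype test is not
  set.seed(91)
  g <- rbinom(600, 2, 0.5)
  y <- rnorm(600) + 0.5 * (g == 1)
  G <- genotype_matrix(cbind(od = g))
  p_add <- single_snp_scan(y, G, "additive")$p
  p_cod <- single_snp_scan(y, G, "codominant")$p
  expect_lt(p_cod, 1e-6)
  expect_gt(p_add, 0.01)
})

test_that("selection rules reproduce their defining order statistics", {
  G <- random_genotypes(200, 12, seed = 101)
  set.seed(102)
  y <- rnorm(200) + 0.5 * G[, 4]
  scan <- single_snp_scan(y, G, "codominant")

  top5 <- select_snps(scan, "sr_topk", k = 5)
  expect_length(top5$snp_ids, 5L)
  expect_identical(top5$snp_ids,
                   scan$snp[order(scan$p, seq_len(nrow(scan)))][1:5])

  # invariant to affine trait transformations
  scan2 <- single_snp_scan(3 * y - 7, G, "codominant")
  expect_identical(select_snps(scan2, "sr_topk", k = 5)$snp_ids,
                   top5$snp_ids)

  alpha_sel <- select_snps(scan, "sr_alpha")
  expect_identical(sort(alpha_sel$snp_ids), sort(scan$snp[scan$p < 0.05]))

  perm_sel <- select_snps(scan, "sr_perm", B = 99, seed = 5, trait = y,
                          genotypes = G, coding = "codominant")
  expect_true(scan$snp[4] %in% perm_sel$snp_ids)
  expect_error(select_snps(scan, "sr_topk", k = 99), "k must be")
})

test_that("null-trait selection behaves like its nominal level", {
  # sr_alpha picks ~5% of SNPs on average; maxT-based sr_perm is almost
  # always empty under the global null
  set.seed(111)
  frac <- numeric(25)
  n_empty <- 0L
  for (r in 1:25) {
    G <- random_genotypes(150, 20, seed = 1000 + r)
    y <- rnorm(150)
    scan <- single_snp_scan(y, G, "additive")
    frac[r] <- length(select_snps(scan, "sr_alpha")$snp_ids) / 20
    if (r <= 12) {
      sel <- select_snps(scan, "sr_perm", B = 99, seed = r, trait = y,
                         genotypes = G, coding = "additive")
      n_empty <- n_empty + (length(sel$snp_ids) == 0L)
    }
  }
  expect_gt(mean(frac), 0.005)
  expect_lt(mean(frac), 0.15)
  expect_gte(n_empty, 10L)
})

test_that("stepwise AIC keeps strong main effects and little else", {
  set.seed(121)
  G <- random_genotypes(800, 15, seed = 122)
  y <- rnorm(800, sd = sqrt(0.9)) +
    sqrt(0.1 / (2 * 0.35 * 0.65)) * G[, 7]
  sel <- stepwise_aic_select(y, G, "additive")
  expect_true(colnames(G)[7] %in% sel$snp_ids)
  expect_identical(sel$method, "mr_aic")

  y0 <- rnorm(800)
  sel0 <- stepwise_aic_select(y0, G, "additive")
  expect_lte(length(sel0$snp_ids), 5L)

  # block stepping: a codominant SNP enters with both columns or not at all
  sel_c <- stepwise_aic_select(y, G, "codominant")
  expect_true(colnames(G)[7] %in% sel_c$snp_ids)
})

test_that("residualisation removes exactly the modelled main effects", {
  G <- random_genotypes(300, 6, seed = 131)
  set.seed(132)
  y <- rnorm(300) + 0.8 * G[, 2] + 0.7 * (G[, 3] == 1)

  # empty selection: trait passes through untouched
  expect_identical(residualize_trait(y, G, character(), "codominant"),
                   trait_vector(y, rownames(G)))

  sel <- selection_ids <- c(colnames(G)[2], colnames(G)[3])
  res <- residualize_trait(y, G, sel, "codominant")
  expect_equal(mean(res), 0, tolerance = 1e-10)
  for (id in sel) {
    X <- encode_genotypes(G[, id], "codominant")
    expect_lt(max(abs(crossprod(X, res))), 1e-8)
    # all genotype-class means vanish under codominant residualisation
    cls <- tapply(as.vector(res), G[, id], mean)
    expect_lt(max(abs(cls)), 1e-10)
  }

  # idempotence
  res2 <- residualize_trait(res, G, sel, "codominant")
  expect_equal(as.vector(res2), as.vector(res), tolerance = 1e-10)

  # additive residualisation leaves the over-dominant pattern behind
  res_add <- residualize_trait(y, G, colnames(G)[3], "additive")
  cls3 <- tapply(as.vector(res_add), G[, 3], mean)
  expect_gt(max(abs(cls3)), 0.05)
})

test_that("on-the-fly designs cover the none/one/both adjustment cases", {
  G <- random_genotypes(50, 4, seed = 141)
  pol <- adjustment_policy("on_the_fly", "pair_always",
                           coding = "codominant")
  D <- resolve_adjust_design(pol, c(1, 2), character(), G)
  expect_identical(ncol(D), 4L)

  pol1d <- adjustment_policy("on_the_fly", "one_d_significant",
                             coding = "additive")
  expect_identical(ncol(resolve_adjust_design(pol1d, c(1, 2),
                                              character(), G)), 0L)
  D1 <- resolve_adjust_design(pol1d, c(1, 2), colnames(G)[1], G)
  expect_identical(ncol(D1), 1L)
  expect_equal(unname(D1[, 1]), as.double(G[, 1]))
  expect_identical(
    ncol(resolve_adjust_design(pol1d, c(1, 2), colnames(G)[1:2], G)), 2L)

  # residual / none policies contribute no design columns
  expect_identical(
    ncol(resolve_adjust_design(adjustment_policy("none"), c(1, 2),
                               character(), G)), 0L)
})

test_that("policy constructors enforce selector consistency", {
  expect_error(adjustment_policy("residual", "pair_always"), "not valid")
  expect_error(adjustment_policy("on_the_fly", "sr_perm"), "not valid")
  expect_identical(adjustment_policy("residual")$selector, "sr_perm")
  expect_error(scan_settings(alpha1 = 1.5), "alpha1")
  expect_error(scan_settings(perms = 5), "perms")
})
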