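test_that("pair partitions index the 9 two-locus cells", {
  G <- genotype_matrix(cbind(a = c(0L, 1L, 2L), b = c(0L, 1L, 2L)),
                       sample_ids = c("x", "y", "z"))
  part <- partition_pair(G, 1, 2)
  expect_identical(part$cell_index, c(0L, 4L, 8L))
  expect_identical(sum(part$cell_sizes), 3L)
  expect_error(partition_pair(G, 1, 1), "distinct")

  # monomorphic second locus occupies only cells 0, 3, 6
  G2 <- genotype_matrix(cbind(a = c(0L, 1L, 2L, 1L), b = c(0L, 0L, 0L, 0L)))
  p2 <- partition_pair(G2, "a", "b")
  expect_true(all(which(p2$cell_sizes > 0) %in% c(1L, 4L, 7L)))

  sim <- simulate_replicate(
    simulation_config("H02", "M27", maf = 0.25, n = 2000, m = 5, seed = 3), 1)
  expect_identical(sum(partition_pair(sim$genotypes, 1, 2)$cell_sizes), 2000L)
})

test_that("H/L/O labels follow the cell-wise tests and the size rule", {
  st <- scan_settings(alpha1 = 0.1, min_cell = 10, perms = 19)
  set.seed(21)
  g1 <- rbinom(400, 2, 0.5)
  g2 <- rbinom(400, 2, 0.5)
  G <- genotype_matrix(cbind(s1 = g1, s2 = g2))
  part <- partition_pair(G, 1, 2)

  # constant trait: every cell is no-evidence
  lab0 <- hlo_classify(part, rep(1.5, 400), NULL, st)
  expect_true(all(lab0$labels == "O"))

  # one strongly shifted cell becomes H; verify every label against a
  # cell-wise pooled t-test oracle
  y <- rnorm(400)
  y[part$cell_index == 4L] <- y[part$cell_index == 4L] + 5
  lab <- hlo_classify(part, y, NULL, st)
  expect_identical(as.character(lab$labels)[5], "H")
  n <- 400
  for (c in 0:8) {
    nc <- sum(part$cell_index == c)
    expected <- "O"
    if (nc >= 10 && nc <= n - 10) {
      tt <- t.test(y[part$cell_index == c], y[part$cell_index != c],
                   var.equal = TRUE)
      if (tt$p.value < 0.1) expected <- if (tt$statistic > 0) "H" else "L"
    }
    expect_identical(as.character(lab$labels)[c + 1L], expected)
  }

  # an undersized cell stays O no matter how extreme its trait values
  g_rare <- c(rep(0L, 397), 1L, 1L, 1L)
  Gr <- genotype_matrix(cbind(s1 = g1, s2 = g_rare))
  pr <- partition_pair(Gr, 1, 2)
  yr <- rnorm(400)
  yr[g_rare == 1L] <- 50
  labr <- hlo_classify(pr, yr, NULL, st)
  small_cells <- which(pr$cell_sizes > 0 & pr$cell_sizes < 10)
  expect_true(all(as.character(labr$labels)[small_cells] == "O"))
})

test_that("the pair statistic pools H and L cells as the oracle does", {
  st <- scan_settings(alpha1 = 0.2, min_cell = 5, perms = 19)
  set.seed(31)
  for (rep in 1:3) {
    G <- random_genotypes(60, 2, seed = 31 + rep)
    y <- rnorm(60) + 0.8 * (G[, 1] == 1) * (G[, 2] == 1)
    part <- partition_pair(G, 1, 2)
    lab <- hlo_classify(part, y, NULL, st)
    stat <- pair_statistic(lab, part, y, NULL)
    expect_gte(stat, 0)
    expect_equal(stat,
                 oracle_pair_stat(G[, 1], G[, 2], y, 0.2, 5),
                 tolerance = 1e-10)
  }

  # all-O labelling yields 0
  lab0 <- hlo_classify(partition_pair(random_genotypes(50, 2, 99), 1, 2),
                       rep(0, 50), NULL, st)
  expect_equal(pair_statistic(lab0,
                              partition_pair(random_genotypes(50, 2, 99),
                                             1, 2),
                              rep(0, 50), NULL), 0)
})

test_that("the vectorised scan equals per-pair computation, both codings", {
  st <- scan_settings(alpha1 = 0.2, min_cell = 5, perms = 19)
  G <- random_genotypes(80, 6, seed = 41)
  set.seed(42)
  y <- rnorm(80)
  fast <- scan_pairs(G, y, st)
  pairs <- attr(fast, "pairs")
  expect_identical(nrow(pairs), 15L)
  ref <- vapply(seq_len(nrow(pairs)), function(k) {
    oracle_pair_stat(G[, pairs[k, 1]], G[, pairs[k, 2]], y, 0.2, 5)
  }, numeric(1))
  expect_equal(as.vector(fast), ref, tolerance = 1e-10)

  for (cod in c("additive", "codominant")) {
    pol <- adjustment_policy("on_the_fly", "pair_always", coding = cod)
    sta <- scan_settings(alpha1 = 0.2, min_cell = 5, perms = 19,
                         policy = pol)
    fasta <- scan_pairs(G, y, sta)
    refa <- vapply(seq_len(nrow(pairs)), function(k) {
      D <- resolve_adjust_design(pol, pairs[k, ], character(), G)
      oracle_pair_stat(G[, pairs[k, 1]], G[, pairs[k, 2]], y, 0.2, 5,
                       adjust = D)
    }, numeric(1))
    expect_equal(as.vector(fasta), refa, tolerance = 1e-10)
  }
})

test_that("scan statistics permute consistently with SNP relabelling", {
  st <- scan_settings(alpha1 = 0.2, min_cell = 5, perms = 19)
  G <- random_genotypes(70, 5, seed = 51)
  set.seed(52)
  y <- rnorm(70)
  base <- scan_pairs(G, y, st)
  pairs <- attr(base, "pairs")
  perm <- c(3L, 1L, 5L, 2L, 4L)
  Gp <- genotype_matrix(G[, perm], snp_ids = colnames(G)[perm])
  swapped <- scan_pairs(Gp, y, st)
  pairs_p <- attr(swapped, "pairs")
  key <- function(p, ids) {
    apply(cbind(ids[p[, 1]], ids[p[, 2]]), 1,
          function(r) paste(sort(r), collapse = "|"))
  }
  expect_equal(
    unname(swapped[order(key(pairs_p, colnames(Gp)))]),
    unname(base[order(key(pairs, colnames(G)))]),
    tolerance = 1e-12)
})

test_that("single-locus scan statistics ignore the other SNPs", {
  G <- random_genotypes(500, 6, seed = 61)
  set.seed(62)
  y <- rnorm(500) + 0.6 * G[, 3]
  fit <- mbmdr_1d(G, y, min_cell = 5, perms = 99, seed = 5)
  # statistics are per-SNP: dropping an unrelated column changes nothing
  fit2 <- mbmdr_1d(G[, -6], y, min_cell = 5, perms = 99, seed = 5)
  expect_equal(fit$snps$statistic[1:5], fit2$snps$statistic,
               tolerance = 1e-12)
  # the strong additive SNP is found
  expect_lte(fit$snps$p_adjusted[3], 0.05)
})
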