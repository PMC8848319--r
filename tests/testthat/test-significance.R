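test_that("the FWER threshold is the floor(level*n_perm)-th smallest minimum p-value", {
  # synthetic threshold_result path: feed a dataset whose permutation minima
  # are checked against the order-statistic rule via direct reconstruction
  cfg <- simulation_config(n_samples = 120, n_snps = 20, ld_block_size = 1,
                           n_genes = 4, n_gene_edges = 6, seed = 61)
  sim <- simulate_dataset(cfg)
  y_adj <- adjust_phenotype(sim$dataset$phenotype)
  gm <- filter_gene_models(sim$network)
  mods <- enumerate_snp_models(gm, sim$mapping)
  th <- fwer_threshold(sim$dataset, y_adj, mods, n_perm = 40, level = 0.1,
                       seed = 3)
  expect_length(th$min_p_per_permutation, 40L)
  expect_identical(th$threshold, sort(th$min_p_per_permutation)[4])
  # determinism under the seed
  th2 <- fwer_threshold(sim$dataset, y_adj, mods, n_perm = 40, level = 0.1,
                        seed = 3)
  expect_identical(th$min_p_per_permutation, th2$min_p_per_permutation)
  # k = 0 falls back to the smallest minimum with a warning
  expect_warning(
    th0 <- fwer_threshold(sim$dataset, y_adj, mods, n_perm = 20, level = 0.01,
                          seed = 3),
    "smallest")
  expect_identical(th0$threshold, min(th0$min_p_per_permutation))
  empty <- mods[0, , drop = FALSE]
  class(empty) <- class(mods)
  expect_error(fwer_threshold(sim$dataset, y_adj, empty, seed = 1),
               class = "netepi_validation")
})

test_that("significance selection is inclusive at the threshold and monotone", {
  res <- data.frame(snp_a = c("a", "b", "c"), snp_b = c("x", "y", "z"),
                    p = c(0.01, 0.05, 0.2))
  expect_identical(nrow(select_significant(res, 0.05)), 2L)  # p == threshold kept
  expect_identical(nrow(select_significant(res[0, ], 0.05)), 0L)
  lo <- select_significant(res, 0.01)
  hi <- select_significant(res, 0.05)
  expect_true(all(paste(lo$snp_a, lo$snp_b) %in% paste(hi$snp_a, hi$snp_b)))
})

test_that("truncated product multiplies only p-values at or below tau", {
  p <- c(0.0005, 0.02, 0.2)
  expect_equal(exp(truncated_product(p, 0.01)), 0.0005, tolerance = 1e-12)
  expect_equal(exp(truncated_product(p, 0.05)), 1e-5, tolerance = 1e-12)
  expect_identical(truncated_product(c(0.2, 0.9), 0.05), 0)  # empty product
  expect_error(truncated_product(c(0.1, 1.2), 0.05), class = "netepi_validation")
  expect_error(truncated_product(p, 1.5), class = "netepi_validation")

  # monotone non-increasing in tau; log-space equals direct product
  set.seed(71)
  for (i in 1:20) {
    pv <- stats::runif(8)
    taus <- sort(stats::runif(5))
    w <- vapply(taus, function(t) truncated_product(pv, t), 0)
    expect_true(all(diff(w) <= 1e-12))
    direct <- vapply(taus, function(t) prod(pv[pv <= t]), 0)
    expect_equal(exp(w), direct, tolerance = 1e-10)
  }
})

test_that("ATPM handles the rank-1 and total-tie cases exactly", {
  B <- 19
  # observed W strictly smallest at every tau
  pmat <- rbind(rep(1e-6, 2), matrix(stats::runif(B * 2, 0.2, 0.9), B, 2))
  pmat[pmat > 0.05] <- NA  # storage convention
  pmat[1, ] <- 1e-6
  r <- atpm_test(pmat, taus = c(0.001, 0.01, 0.05))
  expect_equal(r$pi_0, rep(1 / (B + 1), 3))
  expect_equal(r$p0, 1 / (B + 1))
  expect_true(r$significant)

  # all rows identical: everything ties, all pi = 1, P0 = 1
  pmat2 <- matrix(0.002, 10, 3)
  r2 <- atpm_test(pmat2)
  expect_equal(r2$pi_0, rep(1, 3))
  expect_equal(r2$p0, 1)
  expect_false(r2$significant)

  expect_error(atpm_test(matrix(0.5, 1, 2)), class = "netepi_validation")
})

test_that("ATPM matches the exhaustive brute-force oracle on a hand-checkable toy", {
  # B = 3, 2 SNP models: small enough to verify by hand
  pmat <- rbind(c(0.004, 0.030),
                c(0.200, 0.008),
                c(0.001, 0.600),
                c(0.047, 0.049))
  r <- atpm_test(pmat, taus = c(0.001, 0.01, 0.05))
  o <- oracle_atpm(pmat, taus = c(0.001, 0.01, 0.05))
  expect_equal(exp(r$w0), o$W[1, ], tolerance = 1e-12)
  expect_identical(r$pi_0, o$pi[1, ])
  expect_identical(r$pi_star_0, o$pi_star[1])
  expect_identical(r$p0, o$p0)
  # hand check of the first truncation point: only row 3 has p <= 0.001,
  # so W(0.001) = 1 for rows 1, 2, 4 (ties) and 0.001 for row 3
  expect_equal(exp(r$w0[1]), 1)
  expect_equal(r$pi_0[1], 1)
})

test_that("ATPM is invariant to the order of SNP models and of permutations", {
  set.seed(81)
  pmat <- matrix(stats::runif(20 * 4, 0.0005, 0.06), 20, 4)
  r <- atpm_test(pmat)
  r_cols <- atpm_test(pmat[, c(3, 1, 4, 2)])
  expect_identical(r$p0, r_cols$p0)
  expect_identical(r$pi_star_0, r_cols$pi_star_0)
  # permutation rows (2..B+1) may be reordered freely
  r_rows <- atpm_test(pmat[c(1, sample(2:20)), ])
  expect_identical(r$p0, r_rows$p0)
})

test_that("empirical ATPM p-values live on the permutation grid", {
  set.seed(91)
  B <- 49
  pmat <- matrix(stats::runif((B + 1) * 3, 0.001, 0.9), B + 1, 3)
  pmat[pmat > 0.05] <- NA
  r <- atpm_test(pmat)
  grid <- seq_len(B + 1) / (B + 1)
  expect_true(all(r$pi_0 %in% grid))
  expect_true(r$p0 %in% grid)
  expect_gte(r$p0, 1 / (B + 1))
})

test_that("gene-level analysis tests exactly the parents of significant pairs, sharing permutations", {
  cfg <- simulation_config(n_samples = 500, n_snps = 24, ld_block_size = 2,
                           within_block_corr = 0.2, n_genes = 6,
                           n_gene_edges = 10,
                           planted_models = list(list(gene_a = "G001",
                                                      gene_b = "G004",
                                                      gamma = 1.0)),
                           seed = 101)
  sim <- simulate_dataset(cfg)
  y_adj <- adjust_phenotype(sim$dataset$phenotype, sim$dataset$covariates)
  gm <- filter_gene_models(sim$network)
  mods <- enumerate_snp_models(gm, sim$mapping)
  qc <- apply_snp_model_qc(mods, sim$dataset)
  scan <- scan_pairs(qc$kept, sim$dataset, y_adj)

  # no significant pairs -> no gene models tested
  expect_length(gene_level_analysis(scan[0, ], qc$kept, sim$dataset, y_adj,
                                    B = 19, seed = 1), 0L)

  # force two parents to share one significant pair
  shared <- qc$kept[1, , drop = FALSE]
  shared$parents <- list(c("G001|G004", "G002|G003"))
  rest <- qc$kept[-1, , drop = FALSE]
  mods2 <- rbind(shared, rest)
  class(mods2) <- class(qc$kept)
  sig <- data.frame(snp_a = shared$snp_a, snp_b = shared$snp_b, p = 1e-6)
  gr <- gene_level_analysis(sig, mods2, sim$dataset, y_adj, B = 19, seed = 2)
  keys <- vapply(gr, function(r) paste(r$gene_a, r$gene_b, sep = "|"), "")
  expect_setequal(keys, c("G001|G004", "G002|G003"))
  ns <- stats::setNames(vapply(gr, `[[`, 0L, "n_snp_models"), keys)
  n_g1g4 <- sum(vapply(mods2$parents, function(p) "G001|G004" %in% p, TRUE))
  n_g2g3 <- sum(vapply(mods2$parents, function(p) "G002|G003" %in% p, TRUE))
  expect_identical(unname(ns["G001|G004"]), n_g1g4)
  expect_identical(unname(ns["G002|G003"]), n_g2g3)

  # determinism under the seed
  gr2 <- gene_level_analysis(sig, mods2, sim$dataset, y_adj, B = 19, seed = 2)
  expect_identical(vapply(gr, `[[`, 0, "p0"), vapply(gr2, `[[`, 0, "p0"))
})

test_that("a planted gene-pair interaction is recovered end to end", {
  # regression frozen from a 25-seed oracle run of the full stage chain
  recovered <- 0L
  seeds <- 101:104
  for (s in seeds) {
    cfg <- simulation_config(n_samples = 2000, n_snps = 40, ld_block_size = 5,
                             within_block_corr = 0.2, maf_range = c(0.2, 0.4),
                             n_genes = 8, n_gene_edges = 14,
                             planted_models = list(list(gene_a = "G001",
                                                        gene_b = "G003",
                                                        gamma = 0.6)),
                             seed = s)
    sim <- simulate_dataset(cfg)
    y_adj <- adjust_phenotype(sim$dataset$phenotype, sim$dataset$covariates)
    gm <- filter_gene_models(sim$network)
    mods <- enumerate_snp_models(gm, sim$mapping)
    qc <- apply_snp_model_qc(mods, sim$dataset)
    th <- fwer_threshold(sim$dataset, y_adj, qc$kept, n_perm = 100,
                         seed = netepi:::derive_seed(s, 1))
    scan <- scan_pairs(qc$kept, sim$dataset, y_adj)
    sig <- select_significant(scan, th$threshold)
    gr <- gene_level_analysis(sig, qc$kept, sim$dataset, y_adj, B = 199,
                              seed = netepi:::derive_seed(s, 2))
    sig_keys <- vapply(Filter(function(r) r$significant, gr),
                       function(r) paste(r$gene_a, r$gene_b, sep = "|"), "")
    if ("G001|G003" %in% sig_keys) recovered <- recovered + 1L
  }
  expect_gte(recovered, 3L)
})
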