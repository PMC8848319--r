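test_that("gene-model filtering applies the evidence threshold and drops self-loops", {
  net <- gene_network(data.frame(gene_a = c("A", "A", "B", "D"),
                                 gene_b = c("B", "C", "C", "D"),
                                 evidence_count = c(2L, 1L, 3L, 5L)))
  gm <- filter_gene_models(net)
  expect_identical(paste(gm$gene_a, gm$gene_b), c("A B", "B C"))
  gm1 <- filter_gene_models(net, min_evidence = 1L)
  expect_identical(paste(gm1$gene_a, gm1$gene_b), c("A B", "A C", "B C"))
  empty <- gene_network(data.frame(gene_a = character(0),
                                   gene_b = character(0),
                                   evidence_count = integer(0)))
  expect_identical(nrow(filter_gene_models(empty)), 0L)
})

test_that("mapping combination is a source-restricted union with tissue filtering", {
  pos <- snp_gene_map(data.frame(snp_id = "s1", gene_id = "G1",
                                 source = "positional"))
  eq <- snp_gene_map(data.frame(snp_id = c("s1", "s2"),
                                gene_id = c("G1", "G2"), source = "eqtl",
                                tissue = c("colon", "blood")))
  comb <- combine_mappings(list(pos, eq), sources = c("positional", "eqtl"))
  expect_identical(nrow(unique(as.data.frame(comb)[, c("snp_id", "gene_id")])), 2L)

  # idempotence
  expect_identical(as.data.frame(combine_mappings(list(eq, eq), sources = "eqtl")),
                   as.data.frame(eq))

  colon <- combine_mappings(list(pos, eq), sources = c("positional", "eqtl"),
                            tissues = "colon")
  expect_identical(as.data.frame(colon)$tissue, "colon")

  expect_warning(combine_mappings(list(pos), sources = c("positional", "chromatin")),
                 "absent")
})

test_that("SNP-model enumeration crosses gene SNP sets, excludes self-pairs and merges parents", {
  gm <- filter_gene_models(gene_network(data.frame(
    gene_a = c("A", "C"), gene_b = c("B", "D"), evidence_count = 2L)))
  map <- snp_gene_map(data.frame(
    snp_id = c("s1", "s2", "s2", "s3", "s1", "s5"),
    gene_id = c("A", "A", "B", "B", "C", "D"),
    source = "positional"))
  mods <- enumerate_snp_models(gm, map)
  expect_setequal(paste(mods$snp_a, mods$snp_b),
                  c("s1 s2", "s1 s3", "s2 s3", "s1 s5"))

  # pair shared between two gene models appears once with both parents
  gm2 <- filter_gene_models(gene_network(data.frame(
    gene_a = c("A", "C"), gene_b = c("B", "D"), evidence_count = 2L)))
  map2 <- snp_gene_map(data.frame(
    snp_id = c("s1", "s5", "s1", "s5"), gene_id = c("A", "B", "C", "D"),
    source = "positional"))
  mods2 <- enumerate_snp_models(gm2, map2)
  expect_identical(nrow(mods2), 1L)
  expect_setequal(mods2$parents[[1]], c("A|B", "C|D"))

  # gene with no mapped SNPs produces no pairs and is listed as empty
  gm3 <- filter_gene_models(gene_network(data.frame(
    gene_a = "A", gene_b = "Z", evidence_count = 2L)))
  mods3 <- enumerate_snp_models(gm3, map)
  expect_identical(nrow(mods3), 0L)
  expect_identical(attr(mods3, "empty_gene_models"), "A|Z")
})

test_that("enumeration size matches the brute-force cross product on random instances", {
  for (seed in 1:10) {
    set.seed(seed)
    n_genes <- sample(3:6, 1)
    genes <- sprintf("g%d", seq_len(n_genes))
    # disjoint SNP sets per gene
    sizes <- sample(0:4, n_genes, replace = TRUE)
    snp_ids <- sprintf("r%03d", seq_len(sum(sizes)))
    gene_of <- rep(genes, sizes)
    map <- snp_gene_map(data.frame(snp_id = snp_ids, gene_id = gene_of,
                                   source = "eqtl"))
    pairs <- t(utils::combn(genes, 2))
    keep <- sample(nrow(pairs), sample(nrow(pairs), 1))
    gm <- filter_gene_models(gene_network(data.frame(
      gene_a = pairs[keep, 1], gene_b = pairs[keep, 2], evidence_count = 2L)))
    mods <- enumerate_snp_models(gm, map)
    expected <- sum(vapply(seq_len(nrow(gm)), function(i) {
      sum(gene_of == gm$gene_a[i]) * sum(gene_of == gm$gene_b[i])
    }, 0))
    expect_identical(nrow(mods), as.integer(expected))
  }
})

test_that("minor allele frequency folds and handles missingness", {
  expect_equal(snp_maf(c(0, 0, 1, 2, 2, 1)), 0.5)
  expect_equal(snp_maf(c(0, 2, NA, 1)), 0.5)
  expect_equal(snp_maf(c(0, 0, 0, 1)), 0.125)
  expect_error(snp_maf(c(NA_integer_, NA_integer_)), class = "netepi_validation")
})

test_that("exact Hardy-Weinberg test matches the enumeration oracle", {
  expect_equal(hwe_exact_test(50, 0, 0), 1)
  expect_equal(hwe_exact_test(25, 50, 25), oracle_hwe_enum(25, 50, 25),
               tolerance = 1e-12)
  p_extreme <- hwe_exact_test(50, 0, 50)
  expect_equal(p_extreme, oracle_hwe_enum(50, 0, 50), tolerance = 1e-12)
  expect_lt(p_extreme, 1e-3)
  expect_error(hwe_exact_test(-1, 2, 3), class = "netepi_validation")

  # sweep: all tables with total <= 25, plus random larger tables (n <= 200)
  for (n in c(1:25)) {
    for (n_ab in 0:n) {
      for (n_bb in 0:(n - n_ab)) {
        n_aa <- n - n_ab - n_bb
        expect_equal(hwe_exact_test(n_aa, n_ab, n_bb),
                     oracle_hwe_enum(n_aa, n_ab, n_bb), tolerance = 1e-12)
      }
    }
  }
  set.seed(3)
  for (i in 1:50) {
    n <- sample(26:200, 1)
    n_ab <- sample(0:n, 1)
    n_bb <- sample(0:(n - n_ab), 1)
    expect_equal(hwe_exact_test(n - n_ab - n_bb, n_ab, n_bb),
                 oracle_hwe_enum(n - n_ab - n_bb, n_ab, n_bb),
                 tolerance = 1e-12)
  }
})

test_that("dosage r-squared captures perfect, inverse and independent LD", {
  g <- c(0L, 1L, 2L, 1L, 0L, 2L)
  expect_equal(pairwise_r2(g, g), 1)
  expect_equal(pairwise_r2(g, 2L - g), 1)
  set.seed(8)
  a <- stats::rbinom(10000, 2, 0.3)
  b <- stats::rbinom(10000, 2, 0.3)
  expect_lt(pairwise_r2(a, b), 0.01)
  expect_true(is.na(pairwise_r2(rep(1L, 5), g[1:5])))
})

test_that("SNP-model QC applies MAF, HWE, whitelist, HLA and LD rules with the stated boundaries", {
  set.seed(12)
  n <- 400
  common <- function() stats::rbinom(n, 2, 0.3)
  rare <- stats::rbinom(n, 2, 0.01)
  g1 <- common(); g2 <- common(); g3 <- common()
  g_ld <- g1
  flip <- sample(n, 10)  # r2 well above 0.75 but not 1
  g_ld[flip] <- sample(0:2, 10, replace = TRUE)
  G <- cbind(s1 = g1, s2 = g2, s3 = g3, s_rare = rare, s_ld = g_ld,
             h1 = common(), h2 = common())
  ds <- make_dataset(G, chromosome = c(rep("1", 5), "6", "6"),
                     positions = c(1:5 * 10000L, 26000000L, 27000000L))
  mods <- data.frame(
    snp_a = c("s1", "s1", "s1", "h1", "s1"),
    snp_b = c("s2", "s_rare", "s_ld", "h2", "h1"),
    stringsAsFactors = FALSE)
  mods$parents <- rep(list("X|Y"), nrow(mods))
  class(mods) <- c("snp_models", "data.frame")

  res <- apply_snp_model_qc(mods, ds)
  kept_keys <- paste(res$kept$snp_a, res$kept$snp_b)
  expect_true("s1 s2" %in% kept_keys)
  expect_false("s1 s_rare" %in% kept_keys)   # MAF rule
  expect_false("s1 s_ld" %in% kept_keys)     # LD rule
  expect_false("h1 h2" %in% kept_keys)       # both in HLA
  expect_true("s1 h1" %in% kept_keys)        # only one in HLA
  expect_setequal(res$rejections$rule, c("MAF", "LD", "HLA"))

  # whitelist exempts MAF/HWE failures
  res_wl <- apply_snp_model_qc(mods, ds, qc_config(whitelist = "s_rare"))
  expect_true("s1 s_rare" %in% paste(res_wl$kept$snp_a, res_wl$kept$snp_b))

  # boundary: r2 exactly at the threshold is retained (strict inequality)
  G2 <- cbind(a = c(0L, 0L, 1L, 2L, 1L, 2L, 0L, 1L),
              b = c(0L, 1L, 0L, 2L, 1L, 2L, 1L, 0L))
  r2 <- pairwise_r2(G2[, 1], G2[, 2])
  ds2 <- make_dataset(G2)
  mods2 <- data.frame(snp_a = "a", snp_b = "b")
  mods2$parents <- list("X|Y")
  class(mods2) <- c("snp_models", "data.frame")
  res2 <- apply_snp_model_qc(mods2, ds2,
                             qc_config(maf_min = 0.01, hwe_alpha = 1e-6,
                                       ld_r2_max = r2))
  expect_identical(nrow(res2$kept), 1L)
  res3 <- apply_snp_model_qc(mods2, ds2,
                             qc_config(maf_min = 0.01, hwe_alpha = 1e-6,
                                       ld_r2_max = r2 - 1e-9))
  expect_identical(nrow(res3$kept), 0L)
})

test_that("QC is order-independent and monotone in its thresholds", {
  cfg <- simulation_config(n_samples = 250, n_snps = 30, n_genes = 6,
                           n_gene_edges = 12, maf_range = c(0.02, 0.5),
                           within_block_corr = 0.8, seed = 77)
  sim <- simulate_dataset(cfg)
  gm <- filter_gene_models(sim$network)
  mods <- enumerate_snp_models(gm, sim$mapping)
  base <- apply_snp_model_qc(mods, sim$dataset)

  perm <- mods[sample(nrow(mods)), , drop = FALSE]
  class(perm) <- class(mods)
  shuffled <- apply_snp_model_qc(perm, sim$dataset)
  key <- function(df) sort(paste(df$snp_a, df$snp_b))
  expect_identical(key(shuffled$kept), key(base$kept))

  relaxed <- apply_snp_model_qc(mods, sim$dataset,
                                qc_config(maf_min = 0.01, hwe_alpha = 1e-5,
                                          ld_r2_max = 0.95))
  expect_true(all(key(base$kept) %in% key(relaxed$kept)))
})
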