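# Programmatic fixtures shared across test files.

# Minimal dataset wrapper around a raw genotype matrix.
make_dataset <- function(G, phenotype = NULL, chromosome = "1",
                         positions = NULL, covariates = NULL) {
  G <- as.matrix(G)
  n <- nrow(G)
  m <- ncol(G)
  snps <- data.frame(
    snp_id = if (!is.null(colnames(G))) colnames(G) else sprintf("s%03d", seq_len(m)),
    chromosome = rep_len(chromosome, m),
    position = positions %||% (seq_len(m) * 10000L),
    allele_a1 = "A", allele_a2 = "G", stringsAsFactors = FALSE)
  genotype_dataset(sprintf("i%04d", seq_len(n)), snps, G,
                   phenotype %||% rep(c(0L, 1L), length.out = n),
                   covariates = covariates)
}

write_tsv_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Haplotype-coupled trio for phantom-epistasis scenarios: the causal SNP's
# minor allele rides almost exclusively on haplotypes carrying the minor
# alleles of BOTH flanking SNPs, so its additive effect masquerades as an
# interaction of the flankers.
make_phantom_trio <- function(n, pa = 0.45, couple = 0.9, seed) {
  set.seed(seed)
  hap <- function() {
    h_a <- stats::rbinom(n, 1, pa)
    h_b <- stats::rbinom(n, 1, pa)
    h_causal <- ifelse(h_a * h_b == 1, stats::rbinom(n, 1, couple),
                       stats::rbinom(n, 1, 0.02))
    cbind(h_causal, h_a, h_b)
  }
  m <- hap() + hap()
  list(g_causal = m[, 1], g_a = m[, 2], g_b = m[, 3])
}

# Random small gene-model graph for neighborhood tests.
random_gene_graph <- function(n_genes, n_edges, seed) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(n_genes))
  pairs <- t(utils::combn(genes, 2))
  idx <- sample(nrow(pairs), min(n_edges, nrow(pairs)))
  data.frame(gene_a = pairs[idx, 1], gene_b = pairs[idx, 2],
             evidence_count = 2L, stringsAsFactors = FALSE)
}
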