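# Self-contained generator for genotypes with LD-block structure, a
# many-to-many SNP-gene annotation, a co-function gene network, gene sets,
# and binary phenotypes with optional planted main effects, planted
# gene-pair interactions, and a latent ancestry confounder. Emits exactly
# the containers (and, via write_plink, the files) the readers consume.

#' Simulation configuration
#'
#' Defines one synthetic study. Genotypes are generated per LD block from a
#' latent Gaussian with exchangeable within-block correlation: two
#' independent draws per sample are thresholded at the allele-frequency
#' quantile and summed, so each SNP is marginally in Hardy-Weinberg
#' proportions at its allele frequency while within-block dosages are
#' correlated. The phenotype follows a logistic model
#' `logit P(case) = prevalence_intercept + sum(beta * g) +
#' sum(gamma * gA * gB) + confounder_effect * u`, with `u` standard normal
#' per sample and emitted as covariate column 1 (standing in for an
#' ancestry principal component).
#'
#' @param n_samples,n_snps dataset dimensions.
#' @param ld_block_size SNPs per LD block (default 5).
#' @param within_block_corr latent exchangeable correlation in `[0, 1)`
#'   (default 0.3).
#' @param maf_range allele-frequency range, drawn uniformly per SNP
#'   (default `c(0.05, 0.5)`).
#' @param n_genes number of genes; genes tile the SNP axis in order.
#' @param snps_per_gene SNPs per gene; default `n_snps / n_genes` (must then
#'   divide evenly).
#' @param n_gene_edges number of network edges (includes all planted models).
#' @param evidence_counts integer vector the per-edge evidence count is
#'   sampled from (default `1:4`); planted model edges always get at least 2.
#' @param planted_models list of `list(gene_a=, gene_b=, gamma=)` gene-pair
#'   interactions on the log-odds scale; one representative SNP pair (the
#'   first mapped SNP of each gene) carries each planted interaction.
#' @param main_effects list of `list(snp_id=, beta=)` log-odds main effects.
#' @param confounder_effect log-odds effect per unit of the latent ancestry
#'   axis (default 0).
#' @param prevalence_intercept logistic intercept (default 0: balanced
#'   case/control, as in large case-control panels).
#' @param sources mapping sources sampled per SNP-gene entry (default all
#'   three: positional, eqtl, chromatin).
#' @param seed mandatory integer seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_samples, n_snps, ld_block_size = 5L,
                              within_block_corr = 0.3,
                              maf_range = c(0.05, 0.5),
                              n_genes = NULL, snps_per_gene = NULL,
                              n_gene_edges = NULL,
                              evidence_counts = 1:4,
                              planted_models = list(),
                              main_effects = list(),
                              confounder_effect = 0,
                              prevalence_intercept = 0,
                              sources = VALID_SOURCES,
                              seed) {
  if (missing(seed)) stop_netepi("validation", "seed is mandatory")
  if (n_samples < 1 || n_snps < 1) stop_netepi("validation", "sizes must be positive")
  if (within_block_corr < 0 || within_block_corr >= 1) {
    stop_netepi("validation", "within_block_corr must be in [0, 1)")
  }
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    stop_netepi("validation", "maf_range must lie in (0, 0.5]")
  }
  n_genes <- n_genes %||% max(1L, n_snps %/% 5L)
  snps_per_gene <- snps_per_gene %||% (n_snps %/% n_genes)
  if (snps_per_gene < 1 || n_genes * snps_per_gene > n_snps) {
    stop_netepi("validation", "n_genes * snps_per_gene must be <= n_snps")
  }
  n_gene_edges <- n_gene_edges %||% min(2L * n_genes, n_genes * (n_genes - 1L) %/% 2L)
  structure(list(n_samples = as.integer(n_samples), n_snps = as.integer(n_snps),
                 ld_block_size = as.integer(ld_block_size),
                 within_block_corr = within_block_corr, maf_range = maf_range,
                 n_genes = as.integer(n_genes),
                 snps_per_gene = as.integer(snps_per_gene),
                 n_gene_edges = as.integer(n_gene_edges),
                 evidence_counts = as.integer(evidence_counts),
                 planted_models = planted_models, main_effects = main_effects,
                 confounder_effect = confounder_effect,
                 prevalence_intercept = prevalence_intercept,
                 sources = sources, seed = as.integer(seed)),
            class = "simulation_config")
}

gene_id_of <- function(i) sprintf("G%03d", i)
snp_id_of <- function(j) sprintf("rs%05d", j)

#' Simulate a complete synthetic study
#'
#' Generates genotypes, annotation, network and phenotype per the
#' configuration, together with a truth record of planted effects.
#'
#' @param config a [simulation_config()].
#' @return A list with elements `dataset` ([genotype_dataset()]), `mapping`
#'   ([snp_gene_map()]), `network` ([gene_network()]) and `truth` (planted
#'   gene models with their representative SNP pairs, main-effect SNPs, and
#'   the latent confounder values).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    n <- config$n_samples
    m <- config$n_snps
    bs <- config$ld_block_size
    rho <- config$within_block_corr

    maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    thr <- stats::qnorm(1 - maf)  # latent > thr  <=>  carry one A1 allele

    geno <- matrix(0L, n, m)
    block_of <- (seq_len(m) - 1L) %/% bs
    for (b in unique(block_of)) {
      cols <- which(block_of == b)
      k <- length(cols)
      for (draw in 1:2) {
        shared <- stats::rnorm(n)
        z <- sqrt(rho) * matrix(shared, n, k) +
          sqrt(1 - rho) * matrix(stats::rnorm(n * k), n, k)
        geno[, cols] <- geno[, cols] +
          (z > matrix(thr[cols], n, k, byrow = TRUE))
      }
    }
    storage.mode(geno) <- "integer"

    snps <- data.frame(
      snp_id = snp_id_of(seq_len(m)),
      chromosome = "1",
      position = seq_len(m) * 5000L,
      allele_a1 = "A", allele_a2 = "G",
      stringsAsFactors = FALSE
    )

    # Genes tile the SNP axis.
    gene_ids <- gene_id_of(seq_len(config$n_genes))
    spg <- config$snps_per_gene
    map_rows <- data.frame(
      snp_id = snps$snp_id[seq_len(config$n_genes * spg)],
      gene_id = rep(gene_ids, each = spg),
      source = sample(config$sources, config$n_genes * spg, replace = TRUE),
      tissue = NA_character_, stringsAsFactors = FALSE
    )
    mapping <- snp_gene_map(map_rows)

    # Network: planted edges first (evidence >= 2), then random distinct pairs.
    planted_pairs <- lapply(config$planted_models, function(pm) {
      if (!pm$gene_a %in% gene_ids || !pm$gene_b %in% gene_ids) {
        stop_netepi("config", "planted model gene not in annotation: %s-%s",
                    pm$gene_a, pm$gene_b)
      }
      sort(c(pm$gene_a, pm$gene_b))
    })
    edge_keys <- vapply(planted_pairs, paste, "", collapse = "\r")
    edges <- data.frame(
      gene_a = vapply(planted_pairs, `[`, "", 1L),
      gene_b = vapply(planted_pairs, `[`, "", 2L),
      evidence_count = if (length(planted_pairs)) {
        pmax(2L, sample(config$evidence_counts, length(planted_pairs), replace = TRUE))
      } else integer(0),
      stringsAsFactors = FALSE
    )
    while (nrow(edges) < config$n_gene_edges) {
      pair <- sort(sample(gene_ids, 2L))
      key <- paste(pair, collapse = "\r")
      if (key %in% edge_keys) next
      edge_keys <- c(edge_keys, key)
      edges <- rbind(edges, data.frame(
        gene_a = pair[1], gene_b = pair[2],
        evidence_count = sample(config$evidence_counts, 1L),
        stringsAsFactors = FALSE))
    }
    network <- gene_network(edges)

    # Phenotype: logistic model with planted effects and latent confounder.
    u <- stats::rnorm(n)
    eta <- rep(config$prevalence_intercept, n)
    for (me in config$main_effects) {
      j <- match(me$snp_id, snps$snp_id)
      if (is.na(j)) stop_netepi("config", "main-effect SNP not found: %s", me$snp_id)
      eta <- eta + me$beta * geno[, j]
    }
    rep_pairs <- data.frame(gene_a = character(0), gene_b = character(0),
                            snp_a = character(0), snp_b = character(0),
                            gamma = numeric(0), stringsAsFactors = FALSE)
    for (pm in config$planted_models) {
      snps_a <- map_rows$snp_id[map_rows$gene_id == pm$gene_a]
      snps_b <- map_rows$snp_id[map_rows$gene_id == pm$gene_b]
      shared_only <- length(intersect(snps_a, snps_b)) == length(union(snps_a, snps_b))
      if (!length(snps_a) || !length(snps_b) || shared_only) {
        stop_netepi("config", "planted model %s-%s has no usable SNP pair",
                    pm$gene_a, pm$gene_b)
      }
      sa <- snps_a[1]
      sb <- setdiff(snps_b, sa)[1]
      eta <- eta + pm$gamma * geno[, match(sa, snps$snp_id)] *
        geno[, match(sb, snps$snp_id)]
      rep_pairs <- rbind(rep_pairs, data.frame(
        gene_a = min(pm$gene_a, pm$gene_b), gene_b = max(pm$gene_a, pm$gene_b),
        snp_a = min(sa, sb), snp_b = max(sa, sb), gamma = pm$gamma,
        stringsAsFactors = FALSE))
    }
    eta <- eta + config$confounder_effect * u
    y <- stats::rbinom(n, 1L, stats::plogis(eta))

    dataset <- genotype_dataset(sprintf("S%05d", seq_len(n)), snps, geno, y,
                                covariates = matrix(u, ncol = 1,
                                                    dimnames = list(NULL, "PC1")))
    truth <- list(
      planted_gene_models = rep_pairs,
      main_effect_snps = if (length(config$main_effects)) {
        data.frame(snp_id = vapply(config$main_effects, `[[`, "", "snp_id"),
                   beta = vapply(config$main_effects, `[[`, 0, "beta"),
                   stringsAsFactors = FALSE)
      } else data.frame(snp_id = character(0), beta = numeric(0)),
      confounder = u
    )
    list(dataset = dataset, mapping = mapping, network = network, truth = truth)
  })
}

#' Per-SNP empirical allele frequency
#'
#' Mean allele count divided by 2 for each SNP (frequency of the counted
#' A1 allele, not folded to minor).
#'
#' @param dataset a [genotype_dataset()] with no missing entries.
#' @return Named numeric vector, one frequency per SNP.
#' @export
empirical_maf_check <- function(dataset) {
  if (anyNA(dataset$genotypes)) {
    stop_netepi("validation", "empirical_maf_check expects a complete matrix")
  }
  colMeans(dataset$genotypes) / 2
}

#' Simulate a gene-set collection
#'
#' Background sets are sampled uniformly from the network's gene universe;
#' optionally one extra set is built around a chosen neighborhood (its genes
#' are guaranteed members) so the pathway stage has a planted enrichment.
#'
#' @param network a [gene_network()] giving the gene universe.
#' @param n_sets number of background sets.
#' @param set_size genes per background set (capped at the universe size).
#' @param enriched_genes optional character vector; if given, a set named
#'   `"ENRICHED"` containing these genes (padded with random genes up to
#'   `set_size`) is prepended.
#' @param seed integer seed.
#' @return A `gene_set_collection`.
#' @export
simulate_gene_sets <- function(network, n_sets = 10L, set_size = 15L,
                               enriched_genes = NULL, seed) {
  if (missing(seed)) stop_netepi("validation", "seed is mandatory")
  universe <- sort(unique(c(network$gene_a, network$gene_b)))
  if (!length(universe)) stop_netepi("validation", "network has no genes")
  set_size <- min(set_size, length(universe))
  with_seed(seed, {
    sets <- list()
    if (!is.null(enriched_genes)) {
      extra <- setdiff(universe, enriched_genes)
      pad <- if (set_size > length(enriched_genes)) {
        sample(extra, min(length(extra), set_size - length(enriched_genes)))
      } else character(0)
      sets[["ENRICHED"]] <- unique(c(enriched_genes, pad))
    }
    for (i in seq_len(n_sets)) {
      sets[[sprintf("SET%03d", i)]] <- sample(universe, set_size)
    }
    attr(sets, "descriptions") <- stats::setNames(
      rep("simulated", length(sets)), names(sets))
    class(sets) <- "gene_set_collection"
    sets
  })
}
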