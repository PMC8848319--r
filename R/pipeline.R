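# End-to-end orchestration of the detection protocol, plus the type-I-error
# and subsample-robustness harnesses.

#' Protocol configuration
#'
#' Collects every tunable of the full protocol. All sub-seeds (threshold
#' permutations, ATPM permutations, outer permutations) are derived
#' deterministically from the master seed with a counter scheme, so a run
#' is reproducible end to end.
#'
#' @param mode `"biofiltered"` (test only SNP pairs spanning a network gene
#'   model) or `"standard"` (exhaustive scan of all SNP pairs, gene pairs
#'   assigned post hoc by positional mapping).
#' @param sources mapping sources to combine (default all three).
#' @param tissues optional tissue filter applied to the mapping.
#' @param min_evidence minimum evidence count for a gene model (default 2).
#' @param qc a [qc_config()].
#' @param n_perm_threshold permutations for the SNP-level threshold
#'   (default 400).
#' @param fwer SNP-level family-wise error rate (default 0.05).
#' @param taus ATPM truncation points (default `c(0.001, 0.01, 0.05)`).
#' @param B ATPM permutations (default 999).
#' @param alpha gene-level significance cutoff (default 0.05).
#' @param store_threshold scan storage threshold (default 0.05 =
#'   `max(taus)`, so the truncated products are exact).
#' @param prs list: `enabled`, `window_kb`, `p_max`, `r2_max` for the
#'   clumping + scoring stage.
#' @param pathway list: `enabled`, `alpha`, `scope`, `size_range`.
#' @param seed master seed (mandatory).
#' @return A `protocol_config` list.
#' @export
protocol_config <- function(mode = c("biofiltered", "standard"),
                            sources = VALID_SOURCES, tissues = NULL,
                            min_evidence = 2L, qc = qc_config(),
                            n_perm_threshold = 400L, fwer = 0.05,
                            taus = c(0.001, 0.01, 0.05), B = 999L,
                            alpha = 0.05, store_threshold = max(taus),
                            prs = list(enabled = TRUE, window_kb = 250,
                                       p_max = 1, r2_max = 0.1),
                            pathway = list(enabled = TRUE, alpha = 0.05,
                                           scope = "global",
                                           size_range = NULL),
                            seed) {
  mode <- match.arg(mode)
  if (missing(seed)) stop_netepi("validation", "seed is mandatory")
  if (store_threshold < max(taus)) {
    stop_netepi("validation", "store_threshold must be >= max(taus)")
  }
  structure(list(mode = mode, sources = sources, tissues = tissues,
                 min_evidence = as.integer(min_evidence), qc = qc,
                 n_perm_threshold = as.integer(n_perm_threshold),
                 fwer = fwer, taus = taus, B = as.integer(B), alpha = alpha,
                 store_threshold = store_threshold, prs = prs,
                 pathway = pathway, seed = as.integer(seed)),
            class = "protocol_config")
}

# Post-hoc gene-pair parents via the positional mapping (Standard mode).
assign_positional_parents <- function(snp_models, mapping) {
  pos <- as.data.frame(mapping)
  pos <- pos[pos$source == "positional", c("snp_id", "gene_id")]
  genes_of <- split(pos$gene_id, pos$snp_id)
  snp_models$parents <- lapply(seq_len(nrow(snp_models)), function(i) {
    ga <- unique(genes_of[[snp_models$snp_a[i]]])
    gb <- unique(genes_of[[snp_models$snp_b[i]]])
    if (!length(ga) || !length(gb)) return(character(0))
    grid <- expand.grid(a = ga, b = gb, stringsAsFactors = FALSE)
    grid <- grid[grid$a != grid$b, , drop = FALSE]
    unique(paste(pmin(grid$a, grid$b), pmax(grid$a, grid$b), sep = "|"))
  })
  snp_models
}

#' Run the full detection protocol
#'
#' Stages, in order: gene-model filtering, mapping combination, SNP-pair
#' enumeration (or the exhaustive Standard scan), quality control,
#' phenotype adjustment, permutation threshold, interaction scan, selection
#' of significant pairs, gene-level ATPM, polygenic-score diagnostics of
#' the significant pairs, and pathway enrichment of the significant gene
#' models' network neighborhoods.
#'
#' @param dataset a [genotype_dataset()].
#' @param mapping a [snp_gene_map()] (or list of them).
#' @param network a [gene_network()].
#' @param gene_sets optional `gene_set_collection` for the pathway stage.
#' @param config a [protocol_config()].
#' @param out_dir optional directory for [write_results()].
#' @return A `run_bundle` list carrying every stage's output (and the
#'   inputs, so the error harnesses can re-run stages).
#' @export
run_protocol <- function(dataset, mapping, network, gene_sets = NULL,
                         config, out_dir = NULL) {
  stopifnot(inherits(config, "protocol_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_netepi("stage", "[stage %s] %s", name, conditionMessage(e))
    })
  }
  gene_models <- stage("gene_models",
                       filter_gene_models(network, config$min_evidence))
  mapping_c <- stage("mapping",
                     combine_mappings(mapping, sources = config$sources,
                                      tissues = config$tissues))
  snp_models <- stage("enumerate", {
    if (config$mode == "biofiltered") {
      enumerate_snp_models(gene_models, mapping_c)
    } else {
      all_snp_pairs(dataset$snps$snp_id)
    }
  })
  qc_res <- stage("qc", apply_snp_model_qc(snp_models, dataset, config$qc))
  kept <- qc_res$kept
  if (config$mode == "standard") {
    kept <- stage("posthoc_mapping", assign_positional_parents(kept, mapping_c))
  }
  y_adj <- stage("adjust_phenotype",
                 adjust_phenotype(dataset$phenotype, dataset$covariates))
  threshold <- stage("fwer_threshold",
                     fwer_threshold(dataset, y_adj, kept,
                                    n_perm = config$n_perm_threshold,
                                    level = config$fwer,
                                    seed = derive_seed(config$seed, 1L)))
  scan <- stage("scan",
                scan_pairs(kept, dataset, y_adj,
                           store_threshold = config$store_threshold))
  significant <- stage("select", select_significant(scan, threshold$threshold))
  gene_results <- stage("gene_level",
                        gene_level_analysis(significant, kept, dataset, y_adj,
                                            B = config$B, taus = config$taus,
                                            alpha = config$alpha,
                                            seed = derive_seed(config$seed, 2L)))

  prs_diag <- NULL
  if (isTRUE(config$prs$enabled) && nrow(significant)) {
    prs_diag <- stage("prs", {
      sumstats <- snp_summary_stats(dataset, y_adj)
      usable <- sumstats[!is.na(sumstats$p), , drop = FALSE]
      kept_ids <- clump(usable, dataset, window_kb = config$prs$window_kb,
                        p_max = config$prs$p_max, r2_max = config$prs$r2_max)
      prs <- compute_prs(dataset, kept_ids,
                         stats::setNames(usable$beta, usable$snp_id))
      adj <- lapply(seq_len(nrow(significant)), function(i) {
        ja <- match(significant$snp_a[i], dataset$snps$snp_id)
        jb <- match(significant$snp_b[i], dataset$snps$snp_id)
        r <- interaction_test(dataset$genotypes[, ja], dataset$genotypes[, jb],
                              y_adj, extra_covariates = matrix(prs$score, ncol = 1),
                              snp_a = significant$snp_a[i],
                              snp_b = significant$snp_b[i])
        data.frame(snp_a = r$snp_a, snp_b = r$snp_b,
                   p_unadjusted = significant$p[i], p_prs_adjusted = r$p,
                   beta3_unadjusted = significant$beta3[i],
                   beta3_prs_adjusted = r$beta3, stringsAsFactors = FALSE)
      })
      list(table = do.call(rbind, adj), prs = prs, n_clumped = length(kept_ids))
    })
  }

  neighborhoods <- list()
  enrichments <- NULL
  sig_gene_models <- Filter(function(r) isTRUE(r$significant), gene_results)
  if (isTRUE(config$pathway$enabled) && length(sig_gene_models) &&
      !is.null(gene_sets) && nrow(gene_models)) {
    enr <- stage("pathway", {
      sig_df <- data.frame(
        gene_a = vapply(sig_gene_models, `[[`, "", "gene_a"),
        gene_b = vapply(sig_gene_models, `[[`, "", "gene_b"),
        stringsAsFactors = FALSE)
      nbs <- lapply(seq_len(nrow(sig_df)), function(i) {
        build_neighborhood(c(sig_df$gene_a[i], sig_df$gene_b[i]),
                           gene_models, sig_df)
      })
      universe <- build_universe(gene_sets, mapping_c, gene_models,
                                 mode = if (config$mode == "standard")
                                   "standard" else "biofiltered")
      list(neighborhoods = nbs,
           table = hypergeom_enrich(nbs, gene_sets, universe,
                                    alpha = config$pathway$alpha,
                                    pathway_scope = config$pathway$scope,
                                    size_range = config$pathway$size_range))
    })
    neighborhoods <- enr$neighborhoods
    enrichments <- enr$table
  }

  bundle <- structure(list(
    config = config, dataset = dataset, mapping = mapping_c,
    network = network, gene_sets = gene_sets, gene_models = gene_models,
    snp_models = kept, rejections = qc_res$rejections, y_adj = y_adj,
    threshold = threshold, scan = scan, significant = significant,
    gene_results = gene_results, prs = prs_diag,
    neighborhoods = neighborhoods, enrichments = enrichments
  ), class = "run_bundle")
  if (!is.null(out_dir)) write_results(bundle, out_dir)
  bundle
}

#' @export
print.run_bundle <- function(x, ...) {
  n_sig_gm <- sum(vapply(x$gene_results, `[[`, TRUE, "significant"))
  cat(sprintf(paste0(
    "run_bundle (%s mode)\n",
    "  SNP models tested: %d (threshold %.3g)\n",
    "  significant SNP models: %d\n",
    "  gene models tested: %d, significant: %d\n"),
    x$config$mode, nrow(x$snp_models), x$threshold$threshold,
    nrow(x$significant), length(x$gene_results), n_sig_gm))
  invisible(x)
}

#' Empirical type-I-error rate of the full protocol
#'
#' Permutes the adjusted phenotype `n_outer` times; for each permutation the
#' scan, the selection at the (observed-data) threshold, and the gene-level
#' ATPM are re-run. A permutation yielding at least one significant gene
#' model is a false positive; the rate is `#FP / n_outer` with an exact
#' binomial 95% confidence interval. The SNP-level threshold is computed
#' once from the observed data and reused: under the global null its
#' distribution is the same for every permutation.
#'
#' @param bundle a `run_bundle` from [run_protocol()].
#' @param n_outer number of outer permutations (default 1000; below 50 a
#'   warning is raised, the interval is very wide).
#' @param B ATPM permutations per outer permutation (default: the bundle's).
#' @param seed integer seed for the outer permutation stream.
#' @return list with `rate`, `n_fp`, `n_outer`, `ci` (95% exact),
#'   `mean_significant` (mean number of significant gene models per
#'   permutation).
#' @export
estimate_type1_error <- function(bundle, n_outer = 1000L, B = NULL, seed) {
  if (missing(seed)) stop_netepi("validation", "seed is mandatory")
  if (n_outer < 50L) warning("n_outer < 50: confidence interval will be very wide")
  B <- B %||% bundle$config$B
  cfg <- bundle$config
  y <- as_y_values(bundle$y_adj)
  Y <- permute_phenotypes(y, n_outer, derive_seed(seed, 0L))
  res <- scan_pairs_multi(bundle$snp_models, bundle$dataset, Y)
  thr <- bundle$threshold$threshold
  n_fp <- 0L
  n_sig_total <- 0L
  for (b in seq_len(n_outer)) {
    hit <- which(res$p[, b] <= thr)
    if (!length(hit)) next
    sig <- data.frame(snp_a = bundle$snp_models$snp_a[hit],
                      snp_b = bundle$snp_models$snp_b[hit],
                      p = res$p[hit, b], stringsAsFactors = FALSE)
    gm <- gene_level_analysis(sig, bundle$snp_models, bundle$dataset, Y[, b],
                              B = B, taus = cfg$taus, alpha = cfg$alpha,
                              seed = derive_seed(seed, b))
    n_sig <- sum(vapply(gm, `[[`, TRUE, "significant"))
    n_sig_total <- n_sig_total + n_sig
    if (n_sig > 0L) n_fp <- n_fp + 1L
  }
  ci <- as.numeric(stats::binom.test(n_fp, n_outer)$conf.int)
  list(rate = n_fp / n_outer, n_fp = n_fp, n_outer = as.integer(n_outer),
       ci = ci, mean_significant = n_sig_total / n_outer)
}

#' Subsample robustness of the detected gene models
#'
#' Repeatedly draws a stratified subsample (preserving the case fraction),
#' re-runs the scan, the selection — conservatively at the full-data SNP
#' threshold — and the gene-level ATPM, and reports which full-data
#' significant gene models are recovered.
#'
#' @param bundle a `run_bundle`.
#' @param fraction sampling fraction in (0, 1]; default 0.8.
#' @param reps number of repetitions (default 10).
#' @param seed integer seed.
#' @return list with `per_rep` (data.frame: rep, n_significant, recovery
#'   percentage), `mean_recovery`, `se_recovery`, `full_models` (the
#'   full-data significant gene-model keys); recovery is `NA` (reported as
#'   not applicable) when the full-data result is empty.
#' @export
robustness_subsample <- function(bundle, fraction = 0.8, reps = 10L, seed) {
  if (missing(seed)) stop_netepi("validation", "seed is mandatory")
  if (fraction <= 0 || fraction > 1) {
    stop_netepi("validation", "fraction must be in (0, 1]")
  }
  cfg <- bundle$config
  ds <- bundle$dataset
  y <- as_y_values(bundle$y_adj)
  full_sig <- Filter(function(r) isTRUE(r$significant), bundle$gene_results)
  full_keys <- vapply(full_sig, function(r) paste(r$gene_a, r$gene_b, sep = "|"), "")
  per_rep <- data.frame(rep = integer(0), n_significant = integer(0),
                        recovery = numeric(0))
  for (r in seq_len(reps)) {
    idx <- with_seed(derive_seed(seed, r), {
      cases <- which(ds$phenotype == 1L)
      controls <- which(ds$phenotype == 0L)
      sort(c(sample(cases, round(fraction * length(cases))),
             sample(controls, round(fraction * length(controls)))))
    })
    sub <- genotype_dataset(ds$sample_ids[idx], ds$snps,
                            ds$genotypes[idx, , drop = FALSE],
                            ds$phenotype[idx],
                            if (is.null(ds$covariates)) NULL else
                              ds$covariates[idx, , drop = FALSE])
    y_sub <- adjust_phenotype(sub$phenotype, sub$covariates)
    scan <- scan_pairs(bundle$snp_models, sub, y_sub,
                       store_threshold = cfg$store_threshold)
    sig <- select_significant(scan, bundle$threshold$threshold)
    gm <- gene_level_analysis(sig, bundle$snp_models, sub, y_sub,
                              B = cfg$B, taus = cfg$taus, alpha = cfg$alpha,
                              seed = derive_seed(seed, 10000L + r))
    sig_gm <- Filter(function(x) isTRUE(x$significant), gm)
    keys <- vapply(sig_gm, function(x) paste(x$gene_a, x$gene_b, sep = "|"), "")
    recovery <- if (length(full_keys)) {
      100 * mean(full_keys %in% keys)
    } else NA_real_
    per_rep <- rbind(per_rep, data.frame(rep = r, n_significant = length(keys),
                                         recovery = recovery))
  }
  rec <- per_rep$recovery
  list(per_rep = per_rep,
       mean_recovery = if (all(is.na(rec))) NA_real_ else mean(rec),
       se_recovery = if (all(is.na(rec)) || reps < 2) NA_real_ else
         stats::sd(rec) / sqrt(reps),
       full_models = full_keys)
}
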