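# Permutation-based family-wise error control at the SNP-pair level, and
# aggregation of SNP-pair p-values into gene-pair significance with the
# adaptive truncated product method (ATPM). Following Becker & Knapp, every
# permutation null distribution here includes the observed statistic, so
# empirical p-values live on the grid {1/(B+1), ..., 1} and can never be 0.

# Matrix of permuted phenotype columns (first column = identity if
# include_observed). Permutations are uniform, drawn under `seed`.
permute_phenotypes <- function(y, n_perm, seed, include_observed = FALSE) {
  n <- length(y)
  with_seed(seed, {
    cols <- lapply(seq_len(n_perm), function(b) y[sample.int(n)])
    Y <- do.call(cbind, cols)
    if (include_observed) Y <- cbind(y, Y)
    Y
  })
}

#' Permutation threshold for SNP-pair significance
#'
#' The number of tested SNP pairs varies between analyses, so the
#' significance threshold is dataset-dependent: the phenotype is permuted
#' `n_perm` times, the full pair scan is re-run on each permutation, and the
#' minimum p-value per permutation is recorded. The threshold controlling
#' the family-wise error rate at `level` is the k-th smallest of these
#' minima with `k = floor(level * n_perm)`.
#'
#' @param dataset a [genotype_dataset()].
#' @param y_adj adjusted phenotype.
#' @param snp_models QC-passed `snp_models`.
#' @param n_perm number of permutations (default 400; at least 20).
#' @param level FWER level (default 0.05).
#' @param seed integer seed for the permutation stream.
#' @return A `threshold_result`: list with `min_p_per_permutation`,
#'   `threshold`, `fwer_level`, `n_perm`, `seed`.
#' @export
fwer_threshold <- function(dataset, y_adj, snp_models, n_perm = 400L,
                           level = 0.05, seed) {
  if (missing(seed)) stop_netepi("validation", "seed is mandatory")
  if (!nrow(snp_models)) stop_netepi("validation", "no SNP models to scan")
  if (n_perm < 20L) stop_netepi("validation", "n_perm must be >= 20")
  y <- as_y_values(y_adj)
  Y <- permute_phenotypes(y, n_perm, seed)
  res <- scan_pairs_multi(snp_models, dataset, Y)
  min_p <- apply(res$p, 2L, min)
  k <- floor(level * n_perm)
  sorted <- sort(min_p)
  if (k < 1L) {
    warning("floor(level * n_perm) = 0; using the smallest minimum p-value")
    threshold <- sorted[1]
  } else {
    threshold <- sorted[k]
  }
  structure(list(min_p_per_permutation = min_p, threshold = threshold,
                 fwer_level = level, n_perm = as.integer(n_perm),
                 seed = as.integer(seed)),
            class = "threshold_result")
}

#' Select significant SNP-pair results
#'
#' Keeps scan results with `p <= threshold` (inclusive), ordered by p-value
#' then SNP ids.
#'
#' @param results data.frame from [scan_pairs()].
#' @param threshold numeric threshold (typically
#'   `fwer_threshold(...)$threshold`).
#' @return The significant subset of `results`.
#' @export
select_significant <- function(results, threshold) {
  out <- results[!is.na(results$p) & results$p <= threshold, , drop = FALSE]
  out <- out[order(out$p, out$snp_a, out$snp_b), ]
  rownames(out) <- NULL
  out
}

#' Truncated product statistic
#'
#' `W(tau) = prod p_i^{I(p_i <= tau)}`: the product of the p-values at or
#' below the truncation point; an empty product is 1. Computed and returned
#' in log space to avoid underflow (`W = exp(log_w)`).
#'
#' @param pvals p-values in `(0, 1]`; `NA` entries stand for p-values above
#'   the storage threshold and contribute nothing.
#' @param tau truncation point in `(0, 1)`.
#' @return `log(W)` (0 for the empty product).
#' @export
truncated_product <- function(pvals, tau) {
  if (tau <= 0 || tau >= 1) stop_netepi("validation", "tau must be in (0, 1)")
  keep <- !is.na(pvals)
  if (any(pvals[keep] <= 0 | pvals[keep] > 1)) {
    stop_netepi("validation", "p-values must lie in (0, 1]")
  }
  use <- keep & pvals <= tau
  sum(log(pvals[use]))
}

#' Permuted p-value store for a set of SNP pairs
#'
#' Scans every SNP pair against the observed adjusted phenotype (row 1,
#' b = 0) and against `B` seeded permutations of it (rows 2..B+1), keeping
#' p-values at or below `store_threshold`; entries above it are stored as
#' `NA` (the sparse-storage convention: an absent entry is known to lie in
#' `(store_threshold, 1]`). This is the input [atpm_test()] consumes.
#'
#' @param snp_models a `snp_models` data.frame.
#' @param dataset a [genotype_dataset()].
#' @param y_adj adjusted phenotype.
#' @param B number of permutations.
#' @param seed integer seed.
#' @param store_threshold storage cutoff (must be at least the largest
#'   truncation point used downstream; default 0.05).
#' @return Numeric matrix `(B + 1) x nrow(snp_models)`, columns named by
#'   `"snp_a|snp_b"`.
#' @export
permuted_pval_store <- function(snp_models, dataset, y_adj, B, seed,
                                store_threshold = 0.05) {
  if (missing(seed)) stop_netepi("validation", "seed is mandatory")
  y <- as_y_values(y_adj)
  Y <- permute_phenotypes(y, B, seed, include_observed = TRUE)
  res <- scan_pairs_multi(snp_models, dataset, Y)
  P <- t(res$p)
  P[P > store_threshold] <- NA_real_
  colnames(P) <- paste(snp_models$snp_a, snp_models$snp_b, sep = "|")
  P
}

#' Adaptive truncated product test for one gene pair
#'
#' Combines the p-values of the N SNP pairs mapped to a gene pair across
#' the observed dataset (b = 0) and B phenotype permutations. For each
#' truncation point tau and each b, the truncated product `W_b(tau)` is
#' computed; its empirical p-value is
#' `pi_b(tau) = sum_l I(W_b(tau) >= W_l(tau)) / (B + 1)` (the observed
#' dataset is part of its own null, so values lie on the grid
#' `{1/(B+1), ..., 1}`). The adaptive step takes
#' `pi*_b = min_tau pi_b(tau)`, and the gene-level p-value is
#' `P0 = sum_l I(pi*_0 >= pi*_l) / (B + 1)`; the gene pair is significant
#' when `P0 <= alpha`. All comparisons use the inclusive inequalities.
#'
#' @param pmat numeric matrix `(B + 1) x N`: row 1 is the observed dataset,
#'   rows 2..B+1 the permutations; `NA` entries are p-values above the
#'   storage threshold (which must be at least `max(taus)`).
#' @param taus truncation points (default `c(0.001, 0.01, 0.05)`).
#' @param alpha significance level (default 0.05).
#' @param gene_a,gene_b optional gene ids carried into the result.
#' @return A `gene_model_result`: list with `gene_a`, `gene_b`,
#'   `n_snp_models`, `taus`, `w0` (log-scale observed statistics), `pi_0`,
#'   `pi_star_0`, `p0`, `significant`, `b`.
#' @export
atpm_test <- function(pmat, taus = c(0.001, 0.01, 0.05), alpha = 0.05,
                      gene_a = NA_character_, gene_b = NA_character_) {
  pmat <- as.matrix(pmat)
  B1 <- nrow(pmat)
  if (B1 < 2L) stop_netepi("validation", "need the observed row plus >= 1 permutation")
  vals <- pmat[!is.na(pmat)]
  if (length(vals) && any(vals <= 0 | vals > 1)) {
    stop_netepi("validation", "p-values must lie in (0, 1]")
  }
  # log W_b(tau) for every b and tau: sum of log p over entries <= tau.
  logw <- vapply(taus, function(tau) {
    ind <- !is.na(pmat) & pmat <= tau
    lp <- matrix(0, nrow(pmat), ncol(pmat))
    lp[ind] <- log(pmat[ind])
    rowSums(lp)
  }, numeric(B1))
  logw <- matrix(logw, nrow = B1)
  # pi_b(tau): inclusive rank of W_b among all W_l (self included);
  # rank with ties.method = "max" is exactly sum_l I(W_l <= W_b).
  pi_mat <- apply(logw, 2L, function(w) rank(w, ties.method = "max") / B1)
  pi_mat <- matrix(pi_mat, nrow = B1)
  pi_star <- apply(pi_mat, 1L, min)
  p0 <- sum(pi_star <= pi_star[1]) / B1
  structure(list(gene_a = gene_a, gene_b = gene_b,
                 n_snp_models = ncol(pmat), taus = taus,
                 w0 = logw[1, ], pi_0 = pi_mat[1, ],
                 pi_star_0 = pi_star[1], p0 = p0,
                 significant = p0 <= alpha, b = B1 - 1L),
            class = "gene_model_result")
}

#' @export
print.gene_model_result <- function(x, ...) {
  cat(sprintf("gene model %s-%s: N = %d SNP models, P0 = %.4g%s\n",
              x$gene_a, x$gene_b, x$n_snp_models, x$p0,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Gene-level ATPM analysis of all candidate gene models
#'
#' Candidate gene pairs are those parenting at least one significant SNP
#' pair. A single set of `B` seeded phenotype permutations is shared across
#' all candidates (preserving the dependence between gene models); all SNP
#' pairs of all candidates are re-scanned per permutation with a storage
#' threshold of `max(taus)`, and [atpm_test()] is applied per candidate.
#'
#' @param significant data.frame of significant SNP-pair results (from
#'   [select_significant()]).
#' @param snp_models the full QC-passed `snp_models` (with `parents`).
#' @param dataset a [genotype_dataset()].
#' @param y_adj adjusted phenotype.
#' @param B number of permutations (default 999).
#' @param taus truncation points (default `c(0.001, 0.01, 0.05)`).
#' @param alpha gene-level significance cutoff (default 0.05).
#' @param seed integer seed for the permutation stream (independent of the
#'   threshold-stage stream).
#' @return List of `gene_model_result`, sorted by `p0` then gene ids; empty
#'   when there is no significant SNP pair.
#' @export
gene_level_analysis <- function(significant, snp_models, dataset, y_adj,
                                B = 999L, taus = c(0.001, 0.01, 0.05),
                                alpha = 0.05, seed) {
  if (missing(seed)) stop_netepi("validation", "seed is mandatory")
  if (is.null(significant) || !nrow(significant)) return(list())
  sig_key <- paste(significant$snp_a, significant$snp_b, sep = "\r")
  all_key <- paste(snp_models$snp_a, snp_models$snp_b, sep = "\r")
  sig_rows <- match(sig_key, all_key)
  if (anyNA(sig_rows)) {
    stop_netepi("validation", "significant pair missing from snp_models")
  }
  candidates <- sort(unique(unlist(snp_models$parents[sig_rows])))
  if (!length(candidates)) return(list())

  # Rows (SNP pairs) needed: every SNP model of every candidate gene model.
  needed <- which(vapply(snp_models$parents,
                         function(p) any(p %in% candidates), TRUE))
  sub <- snp_models[needed, , drop = FALSE]

  P <- permuted_pval_store(sub, dataset, y_adj, B = B, seed = seed,
                           store_threshold = max(taus))

  out <- lapply(candidates, function(gm) {
    cols <- which(vapply(sub$parents, function(p) gm %in% p, TRUE))
    parts <- strsplit(gm, "|", fixed = TRUE)[[1]]
    atpm_test(P[, cols, drop = FALSE], taus = taus, alpha = alpha,
              gene_a = parts[1], gene_b = parts[2])
  })
  ord <- order(vapply(out, `[[`, 0, "p0"),
               vapply(out, `[[`, "", "gene_a"),
               vapply(out, `[[`, "", "gene_b"))
  out[ord]
}
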