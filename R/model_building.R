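# From prior knowledge to the tested hypothesis space: filter gene models
# by evidence, combine mappings, enumerate candidate SNP pairs, and apply
# the SNP-model quality-control rules (MAF, Hardy-Weinberg, HLA region,
# linkage disequilibrium).

#' Filter the co-function network into gene models
#'
#' Keeps edges supported by at least `min_evidence` databases and removes
#' self-interactions (within-gene epistasis needs special handling and is
#' out of scope). Output is sorted lexicographically.
#'
#' @param network a [gene_network()].
#' @param min_evidence minimum evidence count (default 2).
#' @return data.frame of class `gene_models` with columns `gene_a`,
#'   `gene_b` (sorted pairs) and `evidence_count`.
#' @export
filter_gene_models <- function(network, min_evidence = 2L) {
  keep <- network$evidence_count >= min_evidence & !network$self_loop
  out <- as.data.frame(network)[keep, c("gene_a", "gene_b", "evidence_count")]
  out <- out[order(out$gene_a, out$gene_b), ]
  rownames(out) <- NULL
  class(out) <- c("gene_models", "data.frame")
  out
}

#' Combine SNP-gene mappings
#'
#' Set union of mapping entries restricted to the requested sources and,
#' optionally, tissues (entries with no tissue tag are dropped by a tissue
#' filter). Requesting a source absent from every input raises a warning,
#' not an error.
#'
#' @param maps list of [snp_gene_map()] objects (a single map is accepted).
#' @param sources subset of `positional`, `eqtl`, `chromatin`.
#' @param tissues optional character vector of tissue tags to keep.
#' @return A [snp_gene_map()].
#' @export
combine_mappings <- function(maps, sources = VALID_SOURCES, tissues = NULL) {
  if (inherits(maps, "snp_gene_map")) maps <- list(maps)
  bad <- setdiff(sources, VALID_SOURCES)
  if (length(bad)) stop_netepi("validation", "unknown source(s): %s",
                               paste(bad, collapse = ", "))
  all_rows <- do.call(rbind, lapply(maps, as.data.frame))
  present <- unique(all_rows$source)
  missing_src <- setdiff(sources, present)
  if (length(missing_src)) {
    warning(sprintf("requested source(s) absent from all maps: %s",
                    paste(missing_src, collapse = ", ")))
  }
  rows <- all_rows[all_rows$source %in% sources, , drop = FALSE]
  if (!is.null(tissues)) {
    rows <- rows[!is.na(rows$tissue) & rows$tissue %in% tissues, , drop = FALSE]
  }
  snp_gene_map(rows)
}

# Projection of a mapping to the bare (snp, gene) relation.
project_mapping <- function(mapping) {
  unique(as.data.frame(mapping)[, c("snp_id", "gene_id")])
}

#' Enumerate candidate SNP pairs from gene models
#'
#' For each gene model (A, B), forms all unordered SNP pairs with one SNP
#' mapped to A and the other to B (self-pairs excluded). A pair arising from
#' several gene models appears once, with all parent gene models recorded.
#' Gene models that produce no SNP pair are returned in the
#' `"empty_gene_models"` attribute (they can never reach significance).
#'
#' @param gene_models output of [filter_gene_models()].
#' @param mapping a [snp_gene_map()]; source/tissue tags are ignored here.
#' @return data.frame of class `snp_models` with columns `snp_a`, `snp_b`
#'   (sorted pairs) and list-column `parents` of `"A|B"` gene-model keys.
#' @export
enumerate_snp_models <- function(gene_models, mapping) {
  proj <- project_mapping(mapping)
  snps_of <- split(proj$snp_id, proj$gene_id)
  acc <- new.env(parent = emptyenv())
  empty <- character(0)
  for (i in seq_len(nrow(gene_models))) {
    ga <- gene_models$gene_a[i]
    gb <- gene_models$gene_b[i]
    sa <- snps_of[[ga]]
    sb <- snps_of[[gb]]
    parent <- paste(ga, gb, sep = "|")
    n_pairs <- 0L
    if (length(sa) && length(sb)) {
      grid <- expand.grid(a = sa, b = sb, stringsAsFactors = FALSE)
      grid <- grid[grid$a != grid$b, , drop = FALSE]
      if (nrow(grid)) {
        key <- paste(pmin(grid$a, grid$b), pmax(grid$a, grid$b), sep = "\r")
        for (k in unique(key)) {
          acc[[k]] <- c(acc[[k]], parent)
        }
        n_pairs <- length(unique(key))
      }
    }
    if (n_pairs == 0L) empty <- c(empty, parent)
  }
  keys <- sort(ls(acc))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(snp_a = vapply(parts, `[`, "", 1L),
                    snp_b = vapply(parts, `[`, "", 2L),
                    stringsAsFactors = FALSE)
  out$parents <- lapply(keys, function(k) unique(acc[[k]]))
  attr(out, "empty_gene_models") <- empty
  class(out) <- c("snp_models", "data.frame")
  out
}

# All C(m,2) SNP pairs of a dataset, as used by the exhaustive Standard scan.
all_snp_pairs <- function(snp_ids) {
  m <- length(snp_ids)
  if (m < 2L) {
    out <- data.frame(snp_a = character(0), snp_b = character(0))
  } else {
    idx <- utils::combn(m, 2L)
    out <- data.frame(snp_a = snp_ids[idx[1, ]], snp_b = snp_ids[idx[2, ]],
                      stringsAsFactors = FALSE)
    swap <- out$snp_a > out$snp_b
    tmp <- out$snp_a[swap]; out$snp_a[swap] <- out$snp_b[swap]; out$snp_b[swap] <- tmp
    out <- out[order(out$snp_a, out$snp_b), ]
    rownames(out) <- NULL
  }
  out$parents <- rep(list(character(0)), nrow(out))
  class(out) <- c("snp_models", "data.frame")
  out
}

#' Minor allele frequency of a dosage column
#'
#' `min(f, 1 - f)` where `f` is the A1 allele frequency over non-missing
#' entries (complete-case).
#'
#' @param g integer dosages in `{0, 1, 2, NA}`.
#' @return MAF in `[0, 0.5]`.
#' @export
snp_maf <- function(g) {
  g <- g[!is.na(g)]
  if (!length(g)) stop_netepi("validation", "all-missing genotype column")
  f <- sum(g) / (2 * length(g))
  min(f, 1 - f)
}

#' Exact test of Hardy-Weinberg proportions
#'
#' Conditional on the observed allele counts, sums the probabilities of all
#' heterozygote counts whose conditional probability does not exceed that of
#' the observed table (two-sided exact test). Probabilities are computed by
#' the standard recurrence over heterozygote counts.
#'
#' @param n_aa,n_ab,n_bb genotype counts (major hom, het, minor hom).
#' @return Exact p-value in `(0, 1]`.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  if (any(c(n_aa, n_ab, n_bb) < 0)) stop_netepi("validation", "negative counts")
  n <- n_aa + n_ab + n_bb
  if (n < 1) stop_netepi("validation", "empty table")
  n_rare <- 2 * min(n_aa, n_bb) + n_ab  # minor allele count
  # possible heterozygote counts share the parity of n_rare
  hets <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  if (length(hets) == 1L) return(1)
  # Recurrence on the conditional distribution of the het count h given the
  # allele counts: P(h+2)/P(h) = 4 * n_hom_rare(h) * n_hom_common(h) /
  # ((h+2)(h+1)); run in log space (the unnormalized mass spans hundreds of
  # orders of magnitude at large n), then normalized.
  lp <- numeric(length(hets))
  for (i in seq_len(length(hets) - 1L)) {
    h <- hets[i]
    n_hom_rare <- (n_rare - h) / 2
    n_hom_com <- (2 * n - n_rare - h) / 2
    lp[i + 1] <- lp[i] + log(4 * n_hom_rare * n_hom_com) -
      log((h + 2) * (h + 1))
  }
  lp <- lp - max(lp)
  probs <- exp(lp)
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_ab, hets)]
  if (is.na(p_obs)) stop_netepi("validation", "inconsistent genotype counts")
  # relative tolerance so that mathematically tied tables (e.g. symmetric
  # distributions) are included regardless of floating-point rounding
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Composite linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of dosages over complete cases (phase-free
#' composite LD). If either column is monomorphic after complete-case
#' restriction the value is undefined: `NA` is returned and the caller is
#' expected to exempt the pair from LD filtering.
#'
#' @param g_a,g_b integer dosage columns.
#' @return r-squared in `[0, 1]`, or `NA` if undefined.
#' @export
pairwise_r2 <- function(g_a, g_b) {
  ok <- !is.na(g_a) & !is.na(g_b)
  if (sum(ok) < 2L) return(NA_real_)
  a <- g_a[ok]; b <- g_b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}

#' Quality-control configuration for SNP models
#'
#' @param maf_min drop SNPs with minor allele frequency strictly below this
#'   (default 0.05).
#' @param hwe_alpha drop SNPs departing from Hardy-Weinberg proportions at
#'   exact-test p strictly below this (default 0.001).
#' @param ld_r2_max drop pairs with dosage r-squared strictly above this
#'   (default 0.75).
#' @param hla_region optional `list(chromosome=, start=, end=)`; a pair is
#'   dropped only when BOTH SNPs fall inside the closed interval. Default
#'   `chr6:25e6-34e6` (GRCh37 convention).
#' @param whitelist SNP ids exempt from the MAF and HWE rules (known risk
#'   SNPs are retained even when those criteria fail).
#' @return A `qc_config` list.
#' @export
qc_config <- function(maf_min = 0.05, hwe_alpha = 0.001, ld_r2_max = 0.75,
                      hla_region = list(chromosome = "6",
                                        start = 25000000L, end = 34000000L),
                      whitelist = character(0)) {
  stopifnot(maf_min > 0, maf_min < 1, hwe_alpha > 0, hwe_alpha < 1,
            ld_r2_max > 0, ld_r2_max < 1)
  if (!is.null(hla_region) && hla_region$start > hla_region$end) {
    stop_netepi("validation", "hla_region start must be <= end")
  }
  structure(list(maf_min = maf_min, hwe_alpha = hwe_alpha,
                 ld_r2_max = ld_r2_max, hla_region = hla_region,
                 whitelist = as.character(whitelist)),
            class = "qc_config")
}

#' Apply SNP-model quality control
#'
#' Drops a candidate pair when (a) either SNP has MAF below `maf_min` or an
#' exact Hardy-Weinberg p-value below `hwe_alpha` — unless that SNP is
#' whitelisted; (b) both SNPs lie inside the HLA region (main and
#' non-additive effects are hard to separate there); or (c) the pair's
#' dosage r-squared exceeds `ld_r2_max`. MAF and HWE are computed on the
#' pooled cohort (cases and controls). Pairs with undefined r-squared are
#' exempt from the LD rule and flagged.
#'
#' @param models a `snp_models` data.frame.
#' @param dataset a [genotype_dataset()].
#' @param qc a [qc_config()].
#' @return list with `kept` (the surviving `snp_models`) and `rejections`
#'   (data.frame `snp_a`, `snp_b`, `rule`, `value`).
#' @export
apply_snp_model_qc <- function(models, dataset, qc = qc_config()) {
  snp_ids <- unique(c(models$snp_a, models$snp_b))
  col_of <- match(snp_ids, dataset$snps$snp_id)
  if (anyNA(col_of)) {
    stop_netepi("validation", "SNP model refers to SNP absent from dataset: %s",
                snp_ids[which(is.na(col_of))[1]])
  }
  maf <- vapply(col_of, function(j) snp_maf(dataset$genotypes[, j]), 0)
  hwe_p <- vapply(col_of, function(j) {
    g <- dataset$genotypes[, j]
    g <- g[!is.na(g)]
    hwe_exact_test(sum(g == 0L), sum(g == 1L), sum(g == 2L))
  }, 0)
  names(maf) <- names(hwe_p) <- snp_ids
  exempt <- snp_ids %in% qc$whitelist
  names(exempt) <- snp_ids
  snp_fails <- !exempt & (maf < qc$maf_min | hwe_p < qc$hwe_alpha)

  in_hla <- rep(FALSE, length(snp_ids))
  if (!is.null(qc$hla_region)) {
    pos <- dataset$snps$position[col_of]
    chr <- dataset$snps$chromosome[col_of]
    in_hla <- chr == as.character(qc$hla_region$chromosome) &
      pos >= qc$hla_region$start & pos <= qc$hla_region$end
  }
  names(in_hla) <- snp_ids

  keep <- rep(TRUE, nrow(models))
  rej <- list()
  flagged_ld <- character(0)
  for (i in seq_len(nrow(models))) {
    a <- models$snp_a[i]; b <- models$snp_b[i]
    if (snp_fails[a] || snp_fails[b]) {
      s <- if (snp_fails[a]) a else b
      rule <- if (!exempt[s] && maf[s] < qc$maf_min) "MAF" else "HWE"
      val <- if (rule == "MAF") maf[s] else hwe_p[s]
      rej[[length(rej) + 1L]] <- data.frame(snp_a = a, snp_b = b, rule = rule,
                                            value = val, stringsAsFactors = FALSE)
      keep[i] <- FALSE
      next
    }
    if (in_hla[a] && in_hla[b]) {
      rej[[length(rej) + 1L]] <- data.frame(snp_a = a, snp_b = b, rule = "HLA",
                                            value = NA_real_, stringsAsFactors = FALSE)
      keep[i] <- FALSE
      next
    }
    r2 <- pairwise_r2(dataset$genotypes[, match(a, dataset$snps$snp_id)],
                      dataset$genotypes[, match(b, dataset$snps$snp_id)])
    if (is.na(r2)) {
      flagged_ld <- c(flagged_ld, paste(a, b, sep = "|"))
    } else if (r2 > qc$ld_r2_max) {
      rej[[length(rej) + 1L]] <- data.frame(snp_a = a, snp_b = b, rule = "LD",
                                            value = r2, stringsAsFactors = FALSE)
      keep[i] <- FALSE
    }
  }
  kept <- models[keep, , drop = FALSE]
  rownames(kept) <- NULL
  class(kept) <- class(models)
  rejections <- if (length(rej)) do.call(rbind, rej) else {
    data.frame(snp_a = character(0), snp_b = character(0),
               rule = character(0), value = numeric(0))
  }
  attr(kept, "ld_undefined") <- flagged_ld
  list(kept = kept, rejections = rejections)
}
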