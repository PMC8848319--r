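# Shared domain containers and readers/writers for the external formats the
# pipeline touches: PLINK 1 binary genotypes, SNP-gene mapping tables,
# gene-gene network edge lists, and GMT gene-set collections.

VALID_SOURCES <- c("positional", "eqtl", "chromatin")

#' Construct a genotype dataset
#'
#' The central container of the pipeline: an additive-coded genotype matrix
#' (samples x SNPs, entries 0/1/2 counting copies of allele A1, `NA` for
#' missing), SNP metadata, a binary phenotype (0 control / 1 case) and an
#' optional covariate matrix (e.g. principal components of ancestry).
#'
#' @param sample_ids character vector of unique sample identifiers.
#' @param snps data.frame with columns `snp_id`, `chromosome`, `position`
#'   (1-based bp), `allele_a1`, `allele_a2`; `snp_id` must be unique.
#' @param genotypes integer matrix `length(sample_ids)` x `nrow(snps)` with
#'   entries in `{0, 1, 2, NA}`; A1 is the counted allele.
#' @param phenotype integer vector in `{0, 1, NA}`, one per sample.
#' @param covariates optional numeric matrix, one row per sample.
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(sample_ids, snps, genotypes, phenotype,
                             covariates = NULL) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) {
    stop_netepi("validation", "duplicate sample ids")
  }
  req <- c("snp_id", "chromosome", "position", "allele_a1", "allele_a2")
  if (!all(req %in% names(snps))) {
    stop_netepi("validation", "snps table must have columns: %s",
                paste(req, collapse = ", "))
  }
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  snps$snp_id <- as.character(snps$snp_id)
  snps$chromosome <- as.character(snps$chromosome)
  snps$position <- as.integer(snps$position)
  if (anyDuplicated(snps$snp_id)) {
    stop_netepi("validation", "duplicate snp ids")
  }
  if (any(snps$position < 1L, na.rm = TRUE)) {
    stop_netepi("validation", "positions must be >= 1")
  }
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (nrow(genotypes) != length(sample_ids) || ncol(genotypes) != nrow(snps)) {
    stop_netepi("format", "genotype matrix is %d x %d but expected %d x %d",
                nrow(genotypes), ncol(genotypes), length(sample_ids), nrow(snps))
  }
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && !all(bad %in% 0:2)) {
    stop_netepi("validation", "genotype entries must be 0, 1, 2 or NA")
  }
  phenotype <- as.integer(phenotype)
  if (length(phenotype) != length(sample_ids)) {
    stop_netepi("format", "phenotype length does not match samples")
  }
  if (!all(phenotype[!is.na(phenotype)] %in% 0:1)) {
    stop_netepi("validation", "phenotype must be coded 0/1 (or NA)")
  }
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    storage.mode(covariates) <- "double"
    if (nrow(covariates) != length(sample_ids)) {
      stop_netepi("format", "covariate rows do not match samples")
    }
  }
  dimnames(genotypes) <- list(sample_ids, snps$snp_id)
  structure(list(sample_ids = sample_ids, snps = snps, genotypes = genotypes,
                 phenotype = phenotype, covariates = covariates),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d samples x %d SNPs (%d cases, %d controls)\n",
              length(x$sample_ids), nrow(x$snps),
              sum(x$phenotype == 1L, na.rm = TRUE),
              sum(x$phenotype == 0L, na.rm = TRUE)))
  if (!is.null(x$covariates)) {
    cat(sprintf("  covariates: %d column(s)\n", ncol(x$covariates)))
  }
  invisible(x)
}

#' Read a PLINK 1 binary fileset
#'
#' Decodes a SNP-major `.bed` (magic bytes `6c 1b 01`) together with its
#' `.bim`/`.fam` metadata. Genotypes count copies of the BIM A1 allele
#' (bed code `00` -> 2, `10` -> 1, `11` -> 0, `01` -> missing). The fam
#' phenotype is recoded 1 -> 0 (control), 2 -> 1 (case), `-9`/`0` -> `NA`.
#' File order of samples and SNPs is preserved.
#'
#' @param bed_path,bim_path,fam_path paths to the three files; `bim_path` and
#'   `fam_path` default to `bed_path` with the extension swapped.
#' @return A [genotype_dataset()].
#' @export
read_plink <- function(bed_path, bim_path = NULL, fam_path = NULL) {
  stem <- sub("\\.bed$", "", bed_path)
  bim_path <- bim_path %||% paste0(stem, ".bim")
  fam_path <- fam_path %||% paste0(stem, ".fam")
  for (p in c(bed_path, bim_path, fam_path)) {
    if (!file.exists(p)) stop_netepi("io", "file not found: %s", p)
  }
  fam <- utils::read.table(fam_path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("fid", "iid", "pid", "mid", "sex", "pheno"))
  bim <- utils::read.table(bim_path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chromosome", "snp_id", "cm", "position",
                                         "allele_a1", "allele_a2"))
  n <- nrow(fam)
  m <- nrow(bim)
  pheno_raw <- fam$pheno
  if (!all(pheno_raw %in% c(1, 2, 0, -9))) {
    stop_netepi("validation", "unknown fam phenotype code(s): %s",
                paste(unique(setdiff(pheno_raw, c(1, 2, 0, -9))), collapse = ", "))
  }
  phenotype <- ifelse(pheno_raw == 1, 0L, ifelse(pheno_raw == 2, 1L, NA_integer_))

  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop_netepi("format", "not a PLINK bed file (bad magic bytes): %s", bed_path)
  }
  if (raw[3] != as.raw(0x01)) {
    stop_netepi("format", "only SNP-major bed files are supported")
  }
  bytes_per_snp <- ceiling(n / 4)
  expected <- 3 + bytes_per_snp * m
  if (length(raw) != expected) {
    stop_netepi("format",
                "bed payload is %d bytes but %d expected for %d samples x %d SNPs",
                length(raw) - 3, expected - 3, n, m)
  }
  payload <- as.integer(raw[-(1:3)])
  # Expand each byte into 4 two-bit codes (sample-little-endian within byte).
  codes <- matrix(0L, nrow = bytes_per_snp * 4L, ncol = m)
  byte_mat <- matrix(payload, nrow = bytes_per_snp, ncol = m)
  for (k in 0:3) {
    codes[seq_len(bytes_per_snp) * 4L - 3L + k, ] <- byte_mat %/% (4L^k) %% 4L
  }
  codes <- codes[seq_len(n), , drop = FALSE]
  # 00 -> 2 copies of A1, 10 -> 1, 11 -> 0, 01 -> missing
  geno <- matrix(NA_integer_, n, m)
  geno[codes == 0L] <- 2L
  geno[codes == 2L] <- 1L
  geno[codes == 3L] <- 0L

  snps <- bim[, c("snp_id", "chromosome", "position", "allele_a1", "allele_a2")]
  snps$chromosome <- as.character(snps$chromosome)
  snps$allele_a1 <- as.character(snps$allele_a1)
  snps$allele_a2 <- as.character(snps$allele_a2)
  genotype_dataset(fam$iid, snps, geno, phenotype)
}

#' Write a PLINK 1 binary fileset
#'
#' Inverse of [read_plink()]: emits SNP-major `.bed` plus `.bim`/`.fam`.
#' Covariates, if any, are written alongside as `<stem>.cov` (TSV).
#'
#' @param dataset a [genotype_dataset()].
#' @param stem output path without extension.
#' @return The stem, invisibly.
#' @export
write_plink <- function(dataset, stem) {
  n <- length(dataset$sample_ids)
  m <- nrow(dataset$snps)
  fam <- data.frame(fid = dataset$sample_ids, iid = dataset$sample_ids,
                    pid = 0L, mid = 0L, sex = 0L,
                    pheno = ifelse(is.na(dataset$phenotype), -9L,
                                   dataset$phenotype + 1L))
  utils::write.table(fam, paste0(stem, ".fam"), sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  bim <- data.frame(chromosome = dataset$snps$chromosome,
                    snp_id = dataset$snps$snp_id, cm = 0L,
                    position = dataset$snps$position,
                    allele_a1 = dataset$snps$allele_a1,
                    allele_a2 = dataset$snps$allele_a2)
  utils::write.table(bim, paste0(stem, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  bytes_per_snp <- ceiling(n / 4)
  code <- matrix(1L, nrow = bytes_per_snp * 4L, ncol = m)  # 01 = missing pad
  g <- dataset$genotypes
  cd <- matrix(1L, n, m)
  cd[!is.na(g) & g == 2L] <- 0L
  cd[!is.na(g) & g == 1L] <- 2L
  cd[!is.na(g) & g == 0L] <- 3L
  code[seq_len(n), ] <- cd
  idx <- seq_len(bytes_per_snp) * 4L
  bytes <- code[idx - 3L, , drop = FALSE] +
    4L * code[idx - 2L, , drop = FALSE] +
    16L * code[idx - 1L, , drop = FALSE] +
    64L * code[idx, , drop = FALSE]
  con <- file(paste0(stem, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)
  if (!is.null(dataset$covariates)) {
    cov <- data.frame(iid = dataset$sample_ids, dataset$covariates)
    utils::write.table(cov, paste0(stem, ".cov"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(stem)
}

#' Construct / validate a SNP-gene mapping
#'
#' A many-to-many relation between SNPs and genes, each entry tagged with the
#' mapping source (`positional`, `eqtl` or `chromatin`) and an optional
#' tissue. Exact duplicate entries are collapsed (set semantics).
#'
#' @param entries data.frame with columns `snp_id`, `gene_id`, `source` and
#'   optionally `tissue`.
#' @return An object of class `snp_gene_map` (a normalized data.frame).
#' @export
snp_gene_map <- function(entries) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  if (!all(c("snp_id", "gene_id", "source") %in% names(entries))) {
    stop_netepi("format", "mapping needs columns snp_id, gene_id, source")
  }
  if (!"tissue" %in% names(entries)) {
    entries$tissue <- rep(NA_character_, nrow(entries))
  }
  entries <- entries[, c("snp_id", "gene_id", "source", "tissue")]
  for (cn in names(entries)) entries[[cn]] <- as.character(entries[[cn]])
  entries$tissue[!is.na(entries$tissue) & entries$tissue == ""] <- NA_character_
  if (nrow(entries)) {
    if (any(!nzchar(entries$snp_id)) || any(!nzchar(entries$gene_id))) {
      stop_netepi("validation", "empty snp_id or gene_id in mapping")
    }
    bad <- setdiff(unique(entries$source), VALID_SOURCES)
    if (length(bad)) {
      stop_netepi("validation", "unknown mapping source(s): %s (allowed: %s)",
                  paste(bad, collapse = ", "), paste(VALID_SOURCES, collapse = "|"))
    }
    entries <- unique(entries)
  }
  rownames(entries) <- NULL
  class(entries) <- c("snp_gene_map", "data.frame")
  entries
}

#' Read a SNP-gene mapping table (TSV)
#'
#' Header columns `snp_id`, `gene_id`, `source` (one of
#' `positional|eqtl|chromatin`) and optional `tissue`. Duplicate rows are
#' collapsed.
#'
#' @param path TSV file path.
#' @return A [snp_gene_map()].
#' @export
read_mapping_table <- function(path) {
  if (!file.exists(path)) stop_netepi("io", "file not found: %s", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  snp_gene_map(tab)
}

#' Construct / validate a gene-gene co-function network
#'
#' Unordered gene pairs with an integer evidence count (number of databases
#' supporting the pair). `(A,B)` and `(B,A)` rows are merged keeping the
#' maximum evidence count; self-loops are retained but flagged.
#'
#' @param edges data.frame with columns `gene_a`, `gene_b`, `evidence_count`.
#' @return An object of class `gene_network` with a logical `self_loop` column.
#' @export
gene_network <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("gene_a", "gene_b", "evidence_count") %in% names(edges))) {
    stop_netepi("format", "network needs columns gene_a, gene_b, evidence_count")
  }
  edges$gene_a <- as.character(edges$gene_a)
  edges$gene_b <- as.character(edges$gene_b)
  ev <- suppressWarnings(as.numeric(edges$evidence_count))
  if (nrow(edges) && (anyNA(ev) || any(ev != round(ev)))) {
    stop_netepi("validation", "evidence_count must be integer")
  }
  edges$evidence_count <- as.integer(ev)
  if (nrow(edges) && any(edges$evidence_count < 1L)) {
    stop_netepi("validation", "evidence_count must be >= 1")
  }
  if (nrow(edges)) {
    a <- pmin(edges$gene_a, edges$gene_b)
    b <- pmax(edges$gene_a, edges$gene_b)
    key <- paste(a, b, sep = "\r")
    ev <- tapply(edges$evidence_count, key, max)
    parts <- strsplit(names(ev), "\r", fixed = TRUE)
    edges <- data.frame(gene_a = vapply(parts, `[`, "", 1L),
                        gene_b = vapply(parts, `[`, "", 2L),
                        evidence_count = as.integer(ev),
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$gene_a, edges$gene_b), ]
  }
  edges$self_loop <- if (nrow(edges)) edges$gene_a == edges$gene_b else logical(0)
  rownames(edges) <- NULL
  class(edges) <- c("gene_network", "data.frame")
  edges
}

#' Read a gene-gene network edge list (TSV)
#'
#' Header columns `gene_a`, `gene_b`, `evidence_count`. Reciprocal rows are
#' merged into one unordered edge keeping the maximum evidence count.
#'
#' @param path TSV file path.
#' @return A [gene_network()].
#' @export
read_network_table <- function(path) {
  if (!file.exists(path)) stop_netepi("io", "file not found: %s", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  gene_network(tab)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>gene...`.
#' Duplicate genes within a line are deduplicated; duplicate set names and
#' lines with fewer than three fields are rejected.
#'
#' @param path GMT file path.
#' @return A `gene_set_collection`: a named list of character vectors with a
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_netepi("io", "file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop_netepi("format", "GMT line %d has fewer than 3 fields",
                which(nf < 3L)[1])
  }
  names_ <- vapply(fields, `[`, "", 1L)
  if (anyDuplicated(names_)) {
    stop_netepi("validation", "duplicate gene set name: %s",
                names_[duplicated(names_)][1])
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- names_
  attr(sets, "descriptions") <- stats::setNames(vapply(fields, `[`, "", 2L), names_)
  class(sets) <- "gene_set_collection"
  sets
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets (sizes %s)\n", length(x),
              if (length(x)) paste(range(lengths(x)), collapse = "-") else "-"))
  invisible(x)
}

#' Write the result tables of a run
#'
#' Emits deterministic TSV files: `snp_models.tsv` (significant SNP pairs
#' with interaction coefficient and p-value), `gene_models.tsv` (per-tau
#' truncated-product p-values and the gene-level P0), `pathways.tsv` and
#' `threshold.tsv` (per-permutation minimum p-values and the derived
#' threshold). Rows are sorted by p-value then lexicographic ids, so two
#' runs with identical inputs produce byte-identical files.
#'
#' @param bundle a `run_bundle` from [run_protocol()], or a bare list with
#'   any of the elements `significant`, `gene_results`, `enrichments`,
#'   `threshold`.
#' @param out_dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(bundle, out_dir) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop_netepi("io", "cannot create directory %s", out_dir)
  paths <- character(0)

  snp_tab <- bundle$significant
  if (is.null(snp_tab)) {
    snp_tab <- data.frame(snp_a = character(0), snp_b = character(0),
                          beta3 = numeric(0), statistic = numeric(0),
                          p = numeric(0), n_used = integer(0))
  } else {
    snp_tab <- snp_tab[, c("snp_a", "snp_b", "beta3", "statistic", "p", "n_used")]
    snp_tab <- snp_tab[order(snp_tab$p, snp_tab$snp_a, snp_tab$snp_b), ]
  }
  p <- file.path(out_dir, "snp_models.tsv")
  utils::write.table(snp_tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)

  gm <- bundle$gene_results
  if (is.null(gm) || !length(gm)) {
    gm_tab <- data.frame(gene_a = character(0), gene_b = character(0),
                         n_snp_models = integer(0),
                         pi_tau_0.001 = numeric(0), pi_tau_0.01 = numeric(0),
                         pi_tau_0.05 = numeric(0), pi_star = numeric(0),
                         p0 = numeric(0), significant = logical(0))
  } else {
    gm_tab <- gene_results_table(gm)
    gm_tab <- gm_tab[order(gm_tab$p0, gm_tab$gene_a, gm_tab$gene_b), ]
  }
  p <- file.path(out_dir, "gene_models.tsv")
  utils::write.table(gm_tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)

  en <- bundle$enrichments
  if (is.null(en)) {
    en <- data.frame(neighborhood = character(0), set_name = character(0),
                     overlap = integer(0), set_size = integer(0),
                     neighborhood_size = integer(0), universe_size = integer(0),
                     p = numeric(0), threshold = numeric(0),
                     significant = logical(0))
  } else {
    en <- en[order(en$p, en$neighborhood, en$set_name), ]
  }
  p <- file.path(out_dir, "pathways.tsv")
  utils::write.table(en, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)

  th <- bundle$threshold
  if (is.null(th)) {
    th_tab <- data.frame(permutation = integer(0), min_p = numeric(0),
                         threshold = numeric(0), fwer_level = numeric(0),
                         seed = integer(0))
  } else {
    th_tab <- data.frame(permutation = seq_along(th$min_p_per_permutation),
                         min_p = th$min_p_per_permutation,
                         threshold = th$threshold, fwer_level = th$fwer_level,
                         seed = th$seed)
  }
  p <- file.path(out_dir, "threshold.tsv")
  utils::write.table(th_tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)

  invisible(paths)
}

# Flatten a list of gene_model_result objects to a data.frame.
gene_results_table <- function(gene_results) {
  do.call(rbind, lapply(gene_results, function(r) {
    row <- data.frame(gene_a = r$gene_a, gene_b = r$gene_b,
                      n_snp_models = r$n_snp_models, stringsAsFactors = FALSE)
    for (i in seq_along(r$taus)) {
      row[[paste0("pi_tau_", format(r$taus[i], trim = TRUE))]] <- r$pi_0[i]
    }
    row$pi_star <- r$pi_star_0
    row$p0 <- r$p0
    row$significant <- r$significant
    row
  }))
}
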