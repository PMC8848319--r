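# Network-neighborhood construction around significant gene pairs and
# hypergeometric gene-set enrichment with a Bonferroni rule over the tested
# neighborhoods and the gene sets they touch.

gene_model_keys <- function(df) paste(df$gene_a, df$gene_b, sep = "|")

#' Shortest-path neighborhood of a significant gene pair
#'
#' With the direct edge between the two genes removed, collects every gene
#' lying on any shortest path between them in the (unweighted, undirected)
#' gene-model graph. An intermediate gene is kept only if it forms a
#' significant gene model with at least one other gene on those paths; the
#' two endpoint genes are always members. The neighborhood is tested
#' downstream only when it has at least 3 genes.
#'
#' @param gene_model character vector `c(gene_a, gene_b)`.
#' @param gene_models data.frame of all filtered gene models (the graph).
#' @param significant_gene_models data.frame with columns `gene_a`,
#'   `gene_b` of the significant gene models of the current analysis.
#' @return A `neighborhood`: list with `gene_a`, `gene_b`, `members`
#'   (sorted), `tested`.
#' @export
build_neighborhood <- function(gene_model, gene_models,
                               significant_gene_models) {
  a <- gene_model[1]; b <- gene_model[2]
  g <- igraph::graph_from_data_frame(
    gene_models[, c("gene_a", "gene_b")], directed = FALSE)
  if (!a %in% igraph::V(g)$name || !b %in% igraph::V(g)$name) {
    stop_netepi("validation", "gene absent from the gene-model graph")
  }
  eid <- suppressWarnings(igraph::get_edge_ids(g, c(a, b)))
  if (length(eid) && eid > 0) g <- igraph::delete_edges(g, eid)

  finish <- function(members, tested) {
    structure(list(gene_a = min(a, b), gene_b = max(a, b),
                   members = sort(unique(members)), tested = tested),
              class = "neighborhood")
  }
  d <- igraph::distances(g, v = a, to = b)[1, 1]
  if (!is.finite(d)) return(finish(c(a, b), FALSE))
  paths <- igraph::all_shortest_paths(g, from = a, to = b)$vpaths
  path_genes <- unique(unlist(lapply(paths, function(p) igraph::V(g)$name[p])))

  sig_keys <- gene_model_keys(significant_gene_models)
  intermediates <- setdiff(path_genes, c(a, b))
  keep <- vapply(intermediates, function(x) {
    partners <- setdiff(path_genes, x)
    any(paste(pmin(x, partners), pmax(x, partners), sep = "|") %in% sig_keys)
  }, TRUE)
  members <- c(a, b, intermediates[keep])
  finish(members, length(members) >= 3L)
}

#' @export
print.neighborhood <- function(x, ...) {
  cat(sprintf("neighborhood %s-%s: %d gene(s)%s\n", x$gene_a, x$gene_b,
              length(x$members), if (x$tested) "" else " (not tested)"))
  invisible(x)
}

#' Gene universe for enrichment testing
#'
#' Intersection of the genes annotated in any gene set with the genes that
#' can be mapped to a SNP of the dataset; in `biofiltered` mode, further
#' restricted to genes participating in at least one filtered gene model.
#'
#' @param gene_sets a `gene_set_collection`.
#' @param mapping a [snp_gene_map()].
#' @param gene_models filtered gene models (used in `biofiltered` mode).
#' @param mode `"biofiltered"` (default) or `"standard"`.
#' @return Sorted character vector of gene ids.
#' @export
build_universe <- function(gene_sets, mapping, gene_models = NULL,
                           mode = c("biofiltered", "standard")) {
  mode <- match.arg(mode)
  in_sets <- unique(unlist(gene_sets, use.names = FALSE))
  mapped <- unique(as.data.frame(mapping)$gene_id)
  universe <- intersect(in_sets, mapped)
  if (mode == "biofiltered") {
    if (is.null(gene_models)) {
      stop_netepi("validation", "biofiltered mode needs gene_models")
    }
    universe <- intersect(universe, unique(c(gene_models$gene_a,
                                             gene_models$gene_b)))
  }
  if (!length(universe)) stop_netepi("validation", "empty gene universe")
  sort(universe)
}

#' Hypergeometric enrichment of neighborhoods in gene sets
#'
#' For each tested neighborhood and each gene set sharing at least one gene
#' with it, computes the upper-tail hypergeometric probability of the
#' observed overlap (population = universe, successes = set, draws =
#' neighborhood, everything intersected with the universe first). A single
#' Bonferroni threshold is shared across results:
#' `alpha / (n_pathways * n_tested_neighborhoods)`, where `n_pathways`
#' counts (globally, by default) the distinct sets containing at least one
#' gene of any tested neighborhood. Significance is strict (`p < threshold`).
#'
#' @param neighborhoods list of [build_neighborhood()] results (untested
#'   ones are ignored).
#' @param gene_sets a `gene_set_collection`.
#' @param universe gene universe from [build_universe()].
#' @param alpha numerator of the Bonferroni threshold (default 0.05).
#' @param pathway_scope `"global"` (default: one shared pathway count) or
#'   `"per_neighborhood"` (each neighborhood's threshold uses its own count
#'   of touched sets).
#' @param size_range optional `c(min, max)` filter on gene-set size (in the
#'   universe); `NULL` (default) disables it.
#' @return data.frame `neighborhood`, `set_name`, `overlap`, `set_size`,
#'   `neighborhood_size`, `universe_size`, `p`, `threshold`, `significant`;
#'   attribute `"skipped"` lists neighborhoods with no genes in the universe.
#' @export
hypergeom_enrich <- function(neighborhoods, gene_sets, universe,
                             alpha = 0.05,
                             pathway_scope = c("global", "per_neighborhood"),
                             size_range = NULL) {
  pathway_scope <- match.arg(pathway_scope)
  tested <- Filter(function(nb) isTRUE(nb$tested), neighborhoods)
  empty <- data.frame(neighborhood = character(0), set_name = character(0),
                      overlap = integer(0), set_size = integer(0),
                      neighborhood_size = integer(0),
                      universe_size = integer(0), p = numeric(0),
                      threshold = numeric(0), significant = logical(0))
  if (!length(tested)) return(empty)

  sets_u <- lapply(gene_sets, function(s) intersect(s, universe))
  if (!is.null(size_range)) {
    keep <- lengths(sets_u) >= size_range[1] & lengths(sets_u) <= size_range[2]
    sets_u <- sets_u[keep]
  }
  N <- length(universe)
  rows <- list()
  skipped <- character(0)
  touched_global <- character(0)
  touched_by_nb <- list()
  for (nb in tested) {
    nb_id <- paste(nb$gene_a, nb$gene_b, sep = "|")
    draws <- intersect(nb$members, universe)
    if (!length(draws)) {
      skipped <- c(skipped, nb_id)
      next
    }
    touched <- names(sets_u)[vapply(sets_u, function(s) {
      length(intersect(s, draws)) > 0L
    }, TRUE)]
    touched_by_nb[[nb_id]] <- touched
    touched_global <- union(touched_global, touched)
    for (set_name in touched) {
      s <- sets_u[[set_name]]
      k <- length(intersect(s, draws))
      p <- stats::phyper(k - 1L, length(s), N - length(s), length(draws),
                         lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        neighborhood = nb_id, set_name = set_name, overlap = k,
        set_size = length(s), neighborhood_size = length(draws),
        universe_size = N, p = clamp_p(p), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    attr(empty, "skipped") <- skipped
    return(empty)
  }
  out <- do.call(rbind, rows)
  n_tested <- length(touched_by_nb)
  if (pathway_scope == "global") {
    out$threshold <- alpha / (length(touched_global) * n_tested)
  } else {
    out$threshold <- alpha /
      (vapply(out$neighborhood, function(id) length(touched_by_nb[[id]]), 0L) *
         n_tested)
  }
  out$significant <- out$p < out$threshold
  out <- out[order(out$p, out$neighborhood, out$set_name), ]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
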