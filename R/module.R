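# From a gene ranking to a PPI-anchored disease module: top-k selection,
# induced subgraph at a confidence cutoff, largest connected component,
# and edge-enrichment quantification.

#' Top-k genes of a ranking
#'
#' Genes sorted by descending exceedance count; ties are broken by the
#' larger decoded augmented value, then lexicographic gene ID, so output
#' lists are deterministic.
#'
#' @param ranking A `gene_ranking`.
#' @param k Number of genes (default 500).
#' @return Character vector of k gene IDs in rank order.
#' @export
top_k_genes <- function(ranking, k = 500L) {
  if (k <= 0L) stopf("k must be positive")
  if (k > length(ranking$gene_ids)) {
    stopf("k (%d) exceeds gene count (%d)", k, length(ranking$gene_ids))
  }
  ord <- order(-ranking$counts, -ranking$g_augmented, ranking$gene_ids)
  ranking$gene_ids[ord][seq_len(k)]
}

#' Edges of a network induced by a gene set at a score cutoff
#'
#' @param genes Character vector of gene IDs.
#' @param network An `interaction_network`.
#' @param cutoff Minimum score (inclusive, default 700).
#' @return Data frame of edges (`from`, `to`, `score`) with both
#'   endpoints in `genes`.
#' @export
induced_subgraph <- function(genes, network, cutoff = 700) {
  ed <- edges_at_cutoff(network, cutoff)
  ed[ed$from %in% genes & ed$to %in% genes, , drop = FALSE]
}

#' Largest connected component of a gene set on the PPI network
#'
#' The module is the maximum-cardinality connected component of the
#' subgraph induced by `genes` at the score cutoff. Size ties are broken
#' by the highest total rank count (when `ranking` is given), then by the
#' lexicographically smallest member set. An empty induced subgraph
#' yields a size-0 module with a warning rather than an error, so batch
#' runs over many diseases do not abort.
#'
#' @param genes Character vector (typically from [top_k_genes()]).
#' @param network An `interaction_network`.
#' @param cutoff Minimum edge score (default 700).
#' @param ranking Optional `gene_ranking` used for tie-breaking and for
#'   ordering module genes by rank.
#' @param label Provenance label.
#' @return Object of class `ppi_module` with `genes` (ordered), `edges`,
#'   and `provenance`.
#' @export
largest_connected_component <- function(genes, network, cutoff = 700,
                                        ranking = NULL, label = "") {
  ed <- induced_subgraph(genes, network, cutoff)
  prov <- list(label = label, k = length(genes), cutoff = cutoff)
  if (!nrow(ed)) {
    warnf("no edges among the %d genes at cutoff %g: size-0 module",
          length(genes), cutoff)
    return(structure(list(genes = character(0),
                          edges = ed, provenance = prov),
                     class = "ppi_module"))
  }
  gr <- igraph::graph_from_data_frame(ed[, c("from", "to")], directed = FALSE)
  comp <- igraph::components(gr)
  members <- split(names(comp$membership), comp$membership)
  sizes <- lengths(members)
  cand <- members[sizes == max(sizes)]
  if (length(cand) > 1L) {
    if (!is.null(ranking)) {
      tot <- vapply(cand, function(m) {
        sum(ranking$counts[match(m, ranking$gene_ids)])
      }, numeric(1))
      cand <- cand[tot == max(tot)]
    }
    if (length(cand) > 1L) {
      keys <- vapply(cand, function(m) paste(sort(m), collapse = "\r"), "")
      cand <- cand[order(keys)[1L]]
    }
  }
  mod_genes <- cand[[1L]]
  # order by the input gene order (rank order when `genes` came from top_k)
  mod_genes <- genes[genes %in% mod_genes]
  structure(list(genes = mod_genes,
                 edges = ed[ed$from %in% mod_genes & ed$to %in% mod_genes, ,
                            drop = FALSE],
                 provenance = prov),
            class = "ppi_module")
}

#' @export
print.ppi_module <- function(x, ...) {
  cat(sprintf("ppi_module '%s': %d genes, %d edges (cutoff %g, from top %d)\n",
              x$provenance$label %||% "", length(x$genes), nrow(x$edges),
              x$provenance$cutoff, x$provenance$k))
  invisible(x)
}

#' Edge enrichment of a gene set on the PPI network
#'
#' Compares the observed induced edge count to an expectation under a
#' null model:
#' \describe{
#'   \item{degree}{degree-preserving (Chung-Lu) expectation
#'     sum over pairs i<j in the set of k_i k_j / (2m), degrees and m
#'     taken from the cutoff-filtered network; p from a Poisson upper
#'     tail at that expectation.}
#'   \item{density}{choose(|S|, 2) times the global edge density;
#'     Poisson upper-tail p.}
#'   \item{permutation}{mean edge count over `n_perm` uniformly drawn
#'     same-size node sets, with p = (1 + #\{perm >= obs\}) / (n_perm + 1).}
#' }
#'
#' @param genes Character vector (>= 2 genes).
#' @param network An `interaction_network`.
#' @param cutoff Minimum edge score (default 700).
#' @param method One of `"degree"`, `"density"`, `"permutation"`.
#' @param n_perm Permutations for the permutation method.
#' @param seed Seed for the permutation method.
#' @return Object of class `edge_enrichment` with `observed`, `expected`,
#'   `fold`, `p_value`, `method`.
#' @export
edge_enrichment <- function(genes, network, cutoff = 700,
                            method = c("degree", "density", "permutation"),
                            n_perm = 1000L, seed = 1L) {
  method <- match.arg(method)
  genes <- unique(genes)
  if (length(genes) < 2L) stopf("need at least 2 genes")
  ed <- edges_at_cutoff(network, cutoff)
  if (!nrow(ed)) stopf("network has no edges at cutoff %g", cutoff)
  observed <- sum(ed$from %in% genes & ed$to %in% genes)
  nodes <- unique(c(ed$from, ed$to))
  m <- nrow(ed)
  if (method == "degree") {
    deg <- table(c(ed$from, ed$to))
    ks <- as.numeric(deg[genes[genes %in% names(deg)]])
    expected <- (sum(ks)^2 - sum(ks^2)) / 2 / (2 * m)
    p <- stats::ppois(observed - 1L, expected, lower.tail = FALSE)
  } else if (method == "density") {
    dens <- m / choose(length(nodes), 2L)
    expected <- choose(length(genes), 2L) * dens
    p <- stats::ppois(observed - 1L, expected, lower.tail = FALSE)
  } else {
    n_in_net <- sum(genes %in% nodes)
    perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      s <- sample(nodes, n_in_net)
      sum(ed$from %in% s & ed$to %in% s)
    }, numeric(1)))
    expected <- mean(perm)
    p <- (1 + sum(perm >= observed)) / (n_perm + 1)
  }
  structure(list(observed = observed, expected = expected,
                 fold = if (expected > 0) observed / expected else NA_real_,
                 p_value = min(p, 1), method = method),
            class = "edge_enrichment")
}

#' @export
print.edge_enrichment <- function(x, ...) {
  cat(sprintf("edge_enrichment (%s): observed %d, expected %.2f, fold %.2f, p = %.3g\n",
              x$method, x$observed, x$expected, x$fold, x$p_value))
  invisible(x)
}

#' Write a module (genes, edges, summary) to a directory
#'
#' @param module A `ppi_module`.
#' @param ranking The `gene_ranking` it came from (for per-gene counts).
#' @param dir Output directory (created if needed).
#' @param enrichment Optional `edge_enrichment` to include in the summary.
#' @export
write_module <- function(module, ranking, dir, enrichment = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- data.frame(gene_id = ranking$gene_ids,
                   rank_count = ranking$counts,
                   in_largest_component = ranking$gene_ids %in% module$genes)
  utils::write.table(df[order(-df$rank_count, df$gene_id), ],
                     file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(module$edges, file.path(dir, "module_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- c(module$provenance,
               list(module_size = length(module$genes),
                    module_edges = nrow(module$edges)))
  if (!is.null(enrichment)) {
    summary <- c(summary, unclass(enrichment))
  }
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
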