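# Weighted protein-protein interaction networks in the STRING dialect:
# undirected edges scored on an integer 0-1000 confidence scale.

#' Construct an interaction network from an edge table
#'
#' Edges are undirected: pairs are stored with endpoints in lexicographic
#' order, duplicates (including reversed duplicates) are collapsed keeping
#' the maximum score, and self-loops are dropped.
#'
#' @param edges Data frame with columns `from`, `to`, `score` (integer
#'   0-1000).
#' @return An object of class `interaction_network`.
#' @export
interaction_network <- function(edges) {
  req <- c("from", "to", "score")
  if (!all(req %in% names(edges))) {
    stopf("edge table needs columns: %s", paste(req, collapse = ", "))
  }
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$score <- as.numeric(edges$score)
  if (any(!is.finite(edges$score)) ||
      any(edges$score < 0 | edges$score > 1000)) {
    stopf("edge scores must lie in [0, 1000]")
  }
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  key <- paste(a, b, sep = "\r")
  ord <- order(key, -edges$score)
  keep <- ord[!duplicated(key[ord])]
  out <- data.frame(from = a[keep], to = b[keep], score = edges$score[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  structure(list(edges = out), class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("interaction_network: %d nodes, %d edges\n",
              length(network_nodes(x)), nrow(x$edges)))
  invisible(x)
}

#' @rdname interaction_network
#' @param network An `interaction_network`.
#' @export
network_nodes <- function(network) {
  sort(unique(c(network$edges$from, network$edges$to)))
}

#' Read a STRING-style weighted edge list
#'
#' Three whitespace/tab-separated columns: node, node, combined score on
#' the 0-1000 scale. A header line is tolerated (detected by a
#' non-numeric third field). Node IDs can be translated into the
#' expression gene namespace through `id_map`; edges touching unmapped
#' nodes are dropped with a reported count.
#'
#' @param path Path to the edge list.
#' @param id_map Optional named character vector or two-column data frame
#'   (`node`, `gene_id`) mapping network node IDs to gene IDs.
#' @return An `interaction_network`.
#' @export
read_edge_list <- function(path, id_map = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stopf("empty edge list: %s", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  if (any(lengths(fields) < 3L)) {
    stopf("edge list line %d has fewer than 3 fields",
          which(lengths(fields) < 3L)[1L])
  }
  first_score <- suppressWarnings(as.numeric(fields[[1L]][3L]))
  if (is.na(first_score)) fields <- fields[-1L]  # header row
  from <- vapply(fields, `[[`, "", 1L)
  to <- vapply(fields, `[[`, "", 2L)
  score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(score)) stopf("non-numeric score on edge list line %d",
                          which(is.na(score))[1L])
  if (!is.null(id_map)) {
    if (is.data.frame(id_map)) {
      map <- stats::setNames(as.character(id_map[[2L]]),
                             as.character(id_map[[1L]]))
    } else {
      map <- id_map
    }
    mapped_from <- unname(map[from])
    mapped_to <- unname(map[to])
    keep <- !is.na(mapped_from) & !is.na(mapped_to)
    n_drop <- length(unique(c(from[is.na(mapped_from)], to[is.na(mapped_to)])))
    if (n_drop > 0L) {
      message(sprintf("read_edge_list: dropped %d unmapped node(s)", n_drop))
    }
    from <- mapped_from[keep]; to <- mapped_to[keep]; score <- score[keep]
  }
  interaction_network(data.frame(from = from, to = to, score = score,
                                 stringsAsFactors = FALSE))
}

#' Write an interaction network as a 3-column TSV
#'
#' @inheritParams network_nodes
#' @param path Output path.
#' @export
write_edge_list <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = c("node1", "node2", "score"))
  invisible(path)
}

# Edges at or above the confidence cutoff, as a plain data frame.
edges_at_cutoff <- function(network, cutoff) {
  network$edges[network$edges$score >= cutoff, , drop = FALSE]
}

# igraph view of the network at a cutoff; isolated nodes included when
# `nodes` is given.
network_igraph <- function(network, cutoff = 0, nodes = NULL) {
  ed <- edges_at_cutoff(network, cutoff)
  vs <- unique(c(nodes, ed$from, ed$to))
  igraph::graph_from_data_frame(ed[, c("from", "to")], directed = FALSE,
                                vertices = data.frame(name = vs))
}
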