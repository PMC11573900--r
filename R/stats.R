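# Enrichment statistics: 2x2 overlap tables, right-sided Fisher tests,
# odds ratios, multiple-testing adjustments, exact binomial and paired-t
# summaries, and the module-versus-DEG comparison harness.

#' 2x2 overlap contingency table
#'
#' Cell layout: `a` = query AND annotation, `b` = query only, `c` =
#' annotation only, `d` = neither; the universe size is a+b+c+d.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return Object of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stopf("cells must be non-negative integers")
  }
  structure(as.list(cells), class = "contingency_table")
}

#' Right-sided Fisher exact test
#'
#' P(X >= a) under the hypergeometric distribution fixed at the table's
#' margins: drawing `a + b` query genes from a universe of `a+b+c+d`
#' containing `a + c` annotated genes.
#'
#' @param table A `contingency_table`.
#' @return p-value in (0, 1].
#' @export
fisher_right_tail <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  with(table, {
    if (a == 0) return(1)
    stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
  })
}

#' Sample (cross-product) odds ratio of a 2x2 table
#'
#' (a d) / (b c); when any cell is zero and `haldane = TRUE`, 0.5 is
#' added to all four cells first so the ratio stays finite.
#'
#' @param table A `contingency_table`.
#' @param haldane Apply the Haldane-Anscombe 0.5 correction when a cell
#'   is zero (default `TRUE`).
#' @return Positive scalar (possibly `Inf`/0 when `haldane = FALSE`).
#' @export
odds_ratio <- function(table, haldane = TRUE) {
  stopifnot(inherits(table, "contingency_table"))
  with(table, {
    if (haldane && any(c(a, b, c, d) == 0)) {
      (a + 0.5) * (d + 0.5) / ((b + 0.5) * (c + 0.5))
    } else {
      (a * d) / (b * c)
    }
  })
}

#' Enrichment of a query gene set in an annotation set
#'
#' Builds the 2x2 table by set arithmetic inside a declared universe and
#' computes the right-sided Fisher p and the odds ratio.
#'
#' @param query,annotation Character vectors; must be subsets of
#'   `universe`.
#' @param universe Character vector defining the background.
#' @param label Label carried into the result.
#' @param haldane Passed to [odds_ratio()].
#' @return Object of class `enrichment_result` with `table`,
#'   `odds_ratio`, `p_right`, `p_adjusted` (NA until adjusted), `label`.
#' @export
set_enrichment <- function(query, annotation, universe, label = "",
                           haldane = TRUE) {
  query <- unique(query); annotation <- unique(annotation)
  universe <- unique(universe)
  bad_q <- setdiff(query, universe)
  bad_a <- setdiff(annotation, universe)
  if (length(bad_q)) stopf("query genes outside universe: %s",
                           paste(utils::head(bad_q, 5L), collapse = ", "))
  if (length(bad_a)) stopf("annotation genes outside universe: %s",
                           paste(utils::head(bad_a, 5L), collapse = ", "))
  a <- length(intersect(query, annotation))
  b <- length(query) - a
  c <- length(annotation) - a
  d <- length(universe) - a - b - c
  tab <- contingency_table(a, b, c, d)
  structure(list(table = tab, odds_ratio = odds_ratio(tab, haldane),
                 p_right = fisher_right_tail(tab), p_adjusted = NA_real_,
                 label = label),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment '%s': a=%d b=%d c=%d d=%d, OR = %.3g, p = %.3g\n",
              x$label, x$table$a, x$table$b, x$table$c, x$table$d,
              x$odds_ratio, x$p_right))
  invisible(x)
}

#' Bonferroni adjustment with an explicit family size
#'
#' min(1, p * m) per entry; `m` may exceed the vector length when the
#' family is larger than the p-values at hand.
#'
#' @param p_values Numeric vector in [0, 1].
#' @param m Family size (defaults to `length(p_values)`).
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  if (m < length(p_values)) stopf("m must be >= length(p_values)")
  pmin(1, p_values * m)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement; invariant to input
#' order.
#'
#' @param p_values Numeric vector in [0, 1].
#' @return Adjusted p-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stopf("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Exact right-tail binomial probability
#'
#' P(X >= k) for X ~ Binomial(n, p0); used for success/trial summaries
#' such as "more sets than expected were nominally significant".
#'
#' @param k Observed successes (0..n).
#' @param n Trials.
#' @param p0 Null success probability (default 0.5).
#' @return p-value in (0, 1].
#' @export
binomial_right_tail <- function(k, n, p0 = 0.5) {
  if (k < 0 || k > n || n < 1) stopf("need 0 <= k <= n, n >= 1")
  if (k == 0) return(1)
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' One-tailed paired Student t test (alternative: mean(x - y) > 0)
#'
#' t = mean(d) / (sd(d)/sqrt(n)) with d = x - y and df = n - 1.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return List with `t`, `df`, `p`.
#' @export
paired_one_tailed_t <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    stopf("x and y must have equal length >= 2")
  }
  d <- x - y
  if (stats::sd(d) == 0) stopf("zero variance of paired differences")
  n <- length(d)
  t_stat <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = t_stat, df = n - 1L,
       p = stats::pt(t_stat, df = n - 1L, lower.tail = FALSE))
}

#' Compare a module against top DEGs for disease-gene enrichment
#'
#' Harmonisation before testing: DEGs are restricted to network genes,
#' and disease-associated genes absent from the DEG table's universe are
#' removed so both gene sets are drawn from the same pool. Three
#' enrichments are computed against the harmonised disease genes: the
#' module, the top-|module| DEGs, and the largest connected component of
#' the top-DEG set (the topology-only baseline).
#'
#' @param module A `ppi_module`.
#' @param deg_table Character vector of DEG gene IDs ordered most
#'   significant first.
#' @param disease_genes Character vector of known disease-associated
#'   genes.
#' @param universe Background gene universe.
#' @param network An `interaction_network`.
#' @param cutoff Edge score cutoff (default 700).
#' @return List of class `comparison_row` with the three
#'   `enrichment_result`s (`module`, `top_deg`, `deg_lcc`), sizes, and an
#'   `untestable` flag.
#' @export
compare_module_vs_deg <- function(module, deg_table, disease_genes, universe,
                                  network, cutoff = 700) {
  degs <- deg_table[deg_table %in% network_nodes(network)]
  degs <- degs[degs %in% universe]
  # genes annotated to the disease must exist in the DEG table's pool
  disease <- intersect(intersect(disease_genes, deg_table), universe)
  size <- length(module$genes)
  if (!length(disease) || size == 0L) {
    return(structure(list(module = NULL, top_deg = NULL, deg_lcc = NULL,
                          module_size = size, n_disease_genes = length(disease),
                          untestable = TRUE), class = "comparison_row"))
  }
  top_deg <- utils::head(degs, size)
  deg_lcc <- largest_connected_component(top_deg, network, cutoff,
                                         label = "deg_lcc")
  res <- list(
    module = set_enrichment(module$genes, disease, universe, "module"),
    top_deg = set_enrichment(top_deg, disease, universe, "top_deg"),
    deg_lcc = if (length(deg_lcc$genes) >= 1L) {
      set_enrichment(deg_lcc$genes, disease, universe, "deg_lcc")
    } else NULL)
  structure(c(res, list(module_size = size,
                        n_disease_genes = length(disease),
                        untestable = FALSE)),
            class = "comparison_row")
}

#' Odds-ratio sweep over module sizes
#'
#' Repeats the module-versus-DEG comparison at each candidate size: the
#' module side takes the top-`size` ranked genes and their largest
#' connected component; the DEG side takes the top-`size` DEGs.
#'
#' @param ranking A `gene_ranking`.
#' @param deg_table Ordered DEG gene IDs (most significant first).
#' @param disease_genes Known disease-associated genes.
#' @param universe Background universe.
#' @param sizes Integer vector of sizes (default seq(50, 500, by = 50)).
#' @param network An `interaction_network`.
#' @param cutoff Edge score cutoff.
#' @return Data frame with columns `size`, `module_size`, `module_or`,
#'   `module_p`, `deg_or`, `deg_p`.
#' @export
or_size_sweep <- function(ranking, deg_table, disease_genes, universe,
                          sizes = seq(50L, 500L, by = 50L), network,
                          cutoff = 700) {
  if (max(sizes) > length(ranking$gene_ids)) {
    stopf("max size exceeds the ranked gene count")
  }
  rows <- lapply(sizes, function(sz) {
    top <- top_k_genes(ranking, sz)
    mod <- suppressWarnings(
      largest_connected_component(top, network, cutoff, ranking))
    cmp <- compare_module_vs_deg(mod, deg_table, disease_genes, universe,
                                 network, cutoff)
    data.frame(size = sz, module_size = cmp$module_size,
               module_or = if (cmp$untestable) NA_real_ else cmp$module$odds_ratio,
               module_p = if (cmp$untestable) NA_real_ else cmp$module$p_right,
               deg_or = if (cmp$untestable) NA_real_ else cmp$top_deg$odds_ratio,
               deg_p = if (cmp$untestable) NA_real_ else cmp$top_deg$p_right)
  })
  do.call(rbind, rows)
}
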