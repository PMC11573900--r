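# Drug repurposing ranking: one right-sided Fisher test per agent
# between the module genes and the agent's target set, FDR-corrected
# across agents.

#' Filter agents by target-set size within the analysis universe
#'
#' Targets are first restricted to the universe; agents retaining
#' strictly more than `min_targets` targets are kept (the "more than 10
#' known target genes" rule: an agent with exactly 10 is dropped).
#'
#' @param table A `target_table`.
#' @param universe Background gene universe.
#' @param min_targets Threshold (default 10).
#' @return Named list agent -> character vector of targets.
#' @export
filter_drugs <- function(table, universe, min_targets = 10L) {
  sets <- lapply(targets_by_agent(table), function(tg) {
    intersect(unique(tg), universe)
  })
  sets <- sets[lengths(sets) > min_targets]
  if (!length(sets)) warnf("no agents retain > %d targets", min_targets)
  sets
}

#' Rank drugs by target-set enrichment in a module
#'
#' For each retained agent, a right-sided Fisher exact test of the
#' overlap between the module genes and the agent's targets within the
#' declared universe (the intersection of model genes and the target
#' table's gene space); p-values are BH-FDR corrected across agents.
#' Direction of dysregulation is deliberately ignored: overlap is purely
#' set-based. Rows are ordered by FDR, then p, then agent name.
#'
#' @param module_genes Character vector of module gene IDs.
#' @param drug_targets Named list agent -> targets (from
#'   [filter_drugs()]) or a `target_table`.
#' @param universe Background gene universe.
#' @param min_targets Passed to [filter_drugs()] when `drug_targets` is
#'   a table.
#' @return Data frame of class `drug_ranking` with columns `agent`,
#'   `n_targets`, `overlap`, `odds_ratio`, `p_right`, `fdr`.
#' @export
drug_enrichment <- function(module_genes, drug_targets, universe,
                            min_targets = 10L) {
  module_genes <- intersect(unique(module_genes), universe)
  if (!length(module_genes)) stopf("module is empty within the universe")
  sets <- if (inherits(drug_targets, "target_table")) {
    filter_drugs(drug_targets, universe, min_targets)
  } else {
    lapply(drug_targets, function(tg) intersect(unique(tg), universe))
  }
  if (!length(sets)) stopf("no drug target sets to test")
  rows <- lapply(names(sets), function(agent) {
    res <- set_enrichment(module_genes, sets[[agent]], universe, agent)
    data.frame(agent = agent, n_targets = length(sets[[agent]]),
               overlap = res$table$a, odds_ratio = res$odds_ratio,
               p_right = res$p_right, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df$fdr <- bh_fdr(df$p_right)
  df <- df[order(df$fdr, df$p_right, df$agent), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("drug_ranking", "data.frame")
  df
}

#' Count of nominally significant tests vs the null expectation
#'
#' For a family of m tests at level alpha, the expected number of
#' nominal rejections under the global null is m * alpha; returns the
#' observed count, the expectation, and the exact right-tail binomial
#' probability of the observed count.
#'
#' @param p_values Numeric vector of nominal p-values.
#' @param alpha Nominal level (default 0.05).
#' @return List with `observed`, `expected`, `fold`, `p_binomial`.
#' @export
nominal_significance_summary <- function(p_values, alpha = 0.05) {
  m <- length(p_values)
  observed <- sum(p_values < alpha)
  list(observed = observed, expected = m * alpha,
       fold = observed / (m * alpha),
       p_binomial = binomial_right_tail(observed, m, alpha))
}
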