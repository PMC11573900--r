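# Module extraction: top-k selection, induced subgraphs, largest
# connected components and edge enrichment.

toy_ranking <- function(counts, decoded = NULL, ids = NULL) {
  ids <- ids %||% sprintf("g%02d", seq_along(counts))
  structure(list(gene_ids = ids, counts = as.integer(counts),
                 g_augmented = decoded %||% rev(seq_along(counts)),
                 B = max(counts), provenance = list(label = "toy")),
            class = "gene_ranking")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("top_k_genes sorts by count with documented tie-breaks", {
  r <- toy_ranking(c(5, 9, 1, 7))
  expect_equal(top_k_genes(r, 4L), c("g02", "g04", "g01", "g03"))
  set.seed(3)
  counts <- sample(0:50, 30, replace = FALSE)
  r2 <- toy_ranking(counts)
  expect_equal(top_k_genes(r2, 30L),
               r2$gene_ids[order(counts, decreasing = TRUE)])
  # ties: larger decoded value first, then lexicographic ID
  r3 <- toy_ranking(c(5, 5, 5), decoded = c(1, 3, 1),
                    ids = c("b", "a", "c"))
  expect_equal(top_k_genes(r3, 3L), c("a", "b", "c"))
  expect_error(top_k_genes(r, 0L), "positive")
  expect_error(top_k_genes(r, 9L), "exceeds")
})

toy_network <- function() {
  interaction_network(data.frame(
    from = c("a", "b", "c", "d", "e", "a"),
    to = c("b", "c", "d", "e", "f", "c"),
    score = c(900, 800, 650, 900, 700, 950)))
}

test_that("induced_subgraph filters by membership and cutoff", {
  net <- toy_network()
  expect_equal(nrow(induced_subgraph(c("a", "b", "c"), net, 1001)), 0L)
  expect_equal(nrow(induced_subgraph(c("a", "b", "c"), net, 0)), 3L)
  ed <- induced_subgraph(c("a", "b", "c", "d"), net, 700)
  oracle <- net$edges[net$edges$score >= 700 &
                        net$edges$from %in% c("a", "b", "c", "d") &
                        net$edges$to %in% c("a", "b", "c", "d"), ]
  expect_equal(ed$from, oracle$from)
  expect_equal(ed$to, oracle$to)
})

test_that("largest_connected_component matches a brute-force closure", {
  net <- toy_network()
  # path a-b-c at 700 plus isolated d
  mod <- largest_connected_component(c("a", "b", "c", "d"), net, 700)
  expect_setequal(mod$genes, c("a", "b", "c"))
  # two components: {a,b,c} (size 3 at cutoff 800) beats {d,e} (900)
  mod2 <- largest_connected_component(c("a", "b", "c", "d", "e"), net, 800)
  expect_setequal(mod2$genes, c("a", "b", "c"))
  expect_warning(largest_connected_component(c("x", "y"), net, 700),
                 "size-0")
  # random graphs against an independent reachability expansion
  set.seed(17)
  for (rep in 1:10) {
    n <- 25L
    ids <- sprintf("n%02d", 1:n)
    m <- 30L
    ed <- unique(data.frame(from = sample(ids, m, TRUE),
                            to = sample(ids, m, TRUE)))
    ed <- ed[ed$from != ed$to, ]
    net_r <- interaction_network(cbind(ed, score = 900))
    sub <- sample(ids, 15L)
    mod_r <- suppressWarnings(
      largest_connected_component(sub, net_r, 700))
    # brute force: expand reachability sets from each seed gene
    ed_in <- induced_subgraph(sub, net_r, 700)
    if (!nrow(ed_in)) {
      expect_length(mod_r$genes, 0L)
      next
    }
    comp_of <- function(start) {
      comp <- start
      repeat {
        nb <- unique(c(ed_in$to[ed_in$from %in% comp],
                       ed_in$from[ed_in$to %in% comp]))
        new <- setdiff(nb, comp)
        if (!length(new)) return(sort(comp))
        comp <- c(comp, new)
      }
    }
    comps <- unique(lapply(unique(c(ed_in$from, ed_in$to)), comp_of))
    best <- max(lengths(comps))
    expect_length(mod_r$genes, best)
    expect_true(any(vapply(comps, function(cc)
      setequal(cc, mod_r$genes), logical(1))))
    # connectivity of the output verified by the same expansion
    ed_mod <- mod_r$edges
    expect_true(all(ed_mod$from %in% mod_r$genes &
                      ed_mod$to %in% mod_r$genes))
  }
})

test_that("edge enrichment expectations follow the three null models", {
  # complete graph: any subset has fold 1 under the density method
  ids <- letters[1:6]
  pairs <- t(utils::combn(ids, 2))
  full <- interaction_network(data.frame(from = pairs[, 1], to = pairs[, 2],
                                         score = 900))
  enr <- edge_enrichment(c("a", "b", "c"), full, 700, method = "density")
  expect_equal(enr$fold, 1.0)
  expect_equal(enr$observed, 3L)
  # empty induced subgraph -> fold 0
  sparse <- interaction_network(data.frame(from = "a", to = "b", score = 900))
  enr0 <- edge_enrichment(c("c", "d", "e"), sparse, 700, method = "density")
  expect_equal(enr0$fold, 0)
  # degree method equals the hand-summed k_i k_j / (2m) expectation
  set.seed(23)
  ids10 <- sprintf("v%02d", 1:10)
  ed <- unique(data.frame(from = sample(ids10, 20, TRUE),
                          to = sample(ids10, 20, TRUE)))
  ed <- ed[ed$from != ed$to, ]
  net <- interaction_network(cbind(ed, score = 800))
  genes <- ids10[c(1, 3, 5, 7)]
  enr_d <- edge_enrichment(genes, net, 700, method = "degree")
  deg <- table(c(net$edges$from, net$edges$to))
  ks <- as.numeric(deg[genes[genes %in% names(deg)]])
  m <- nrow(net$edges)
  hand <- 0
  if (length(ks) >= 2) {
    for (i in seq_along(ks)) for (j in seq_along(ks)) {
      if (i < j) hand <- hand + ks[i] * ks[j] / (2 * m)
    }
  }
  expect_equal(enr_d$expected, hand, tolerance = 1e-12)
  expect_equal(enr_d$fold, enr_d$observed / hand, tolerance = 1e-12)
  expect_error(edge_enrichment("a", full, 700), "at least 2")
})

test_that("permutation p-values are near-uniform for random gene sets", {
  set.seed(41)
  ids <- sprintf("v%02d", 1:20)
  pairs <- t(utils::combn(ids, 2))
  keep <- runif(nrow(pairs)) < 0.25
  net <- interaction_network(data.frame(from = pairs[keep, 1],
                                        to = pairs[keep, 2], score = 900))
  ps <- vapply(1:500, function(i) {
    genes <- sample(ids, 6)
    edge_enrichment(genes, net, 700, method = "permutation",
                    n_perm = 99L, seed = i)$p_value
  }, numeric(1))
  # with tied integer edge counts the permutation p is discrete and
  # conservative; the guaranteed property is validity, P(p <= a) <= a
  # (up to sampling noise), plus non-degeneracy of the distribution
  for (alpha in c(0.05, 0.1, 0.25, 0.5)) {
    frac <- mean(ps <= alpha)
    tol <- 3 * sqrt(alpha * (1 - alpha) / length(ps)) + 1 / 100
    expect_lt(frac, alpha + tol)
  }
  expect_gt(mean(ps), 0.45)
  expect_gt(length(unique(ps)), 5L)
})

test_that("modules written to disk carry genes, edges and summary", {
  net <- toy_network()
  r <- toy_ranking(c(9, 7, 5, 3), ids = c("a", "b", "c", "d"))
  mod <- largest_connected_component(top_k_genes(r, 4L), net, 700, r)
  d <- withr::local_tempdir()
  write_module(mod, r, d,
               edge_enrichment(mod$genes, net, 700, method = "density"))
  expect_true(file.exists(file.path(d, "genes.tsv")))
  expect_true(file.exists(file.path(d, "module_edges.tsv")))
  summ <- jsonlite::read_json(file.path(d, "summary.json"))
  expect_equal(summ$module_size, length(mod$genes))
})
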