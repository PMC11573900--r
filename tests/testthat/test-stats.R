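# Enrichment statistics against independent oracles: exhaustive
# hypergeometric enumeration, direct binomial summation, hand step-up
# FDR, and closed-form t arithmetic.

test_that("fisher_right_tail equals exhaustive hypergeometric enumeration", {
  expect_equal(fisher_right_tail(contingency_table(0, 10, 5, 85)), 1.0)
  # saturated overlap in a large universe is extreme
  tab <- contingency_table(5, 0, 0, 195)
  expect_equal(fisher_right_tail(tab), hyper_right_oracle(5, 0, 0, 195),
               tolerance = 1e-12)
  expect_lt(fisher_right_tail(tab), 1e-8)
  # the worked example (3,2,2,93) against direct factorial arithmetic
  expect_equal(fisher_right_tail(contingency_table(3, 2, 2, 93)),
               hyper_right_oracle(3, 2, 2, 93), tolerance = 1e-12)
  # exhaustive sweep over small universes plus random larger tables
  for (N in c(4L, 8L, 12L)) {
    parts <- expand.grid(a = 0:N, b = 0:N, c = 0:N)
    parts <- parts[rowSums(parts) <= N, ]
    for (i in seq_len(nrow(parts))) {
      a <- parts$a[i]; b <- parts$b[i]; c <- parts$c[i]
      d <- N - a - b - c
      p <- fisher_right_tail(contingency_table(a, b, c, d))
      o <- hyper_right_oracle(a, b, c, d)
      expect_equal(p, o, tolerance = 1e-12)
    }
  }
  set.seed(19)
  for (rep in 1:300) {
    N <- sample(4:200, 1)
    cuts <- sort(sample(0:N, 3, replace = TRUE))
    a <- cuts[1]; b <- cuts[2] - cuts[1]; c <- cuts[3] - cuts[2]
    d <- N - cuts[3]
    p <- fisher_right_tail(contingency_table(a, b, c, d))
    o <- hyper_right_oracle(a, b, c, d)
    if (o > 0) expect_lt(abs(p - o) / o, 1e-12) else expect_equal(p, o)
  }
})

test_that("odds ratios use the cross-product with Haldane correction", {
  expect_equal(odds_ratio(contingency_table(1, 1, 1, 1)), 1.0)
  expect_equal(odds_ratio(contingency_table(10, 490, 90, 16229)),
               162290 / 44100, tolerance = 1e-12)
  expect_equal(odds_ratio(contingency_table(5, 0, 3, 100)),
               (5.5 * 100.5) / (0.5 * 3.5), tolerance = 1e-12)
  expect_equal(odds_ratio(contingency_table(5, 0, 3, 100), haldane = FALSE),
               Inf)
})

test_that("set_enrichment builds tables by set arithmetic inside the universe", {
  uni <- sprintf("u%03d", 1:100)
  q <- uni[1:20]; ann <- uni[11:40]
  res <- set_enrichment(q, ann, uni)
  expect_equal(unlist(res$table[c("a", "b", "c", "d")], use.names = FALSE),
               c(10L, 10L, 20L, 60L))
  set.seed(8)
  for (rep in 1:20) {
    q <- sample(uni, sample(5:50, 1)); ann <- sample(uni, sample(5:50, 1))
    r <- set_enrichment(q, ann, uni)
    expect_equal(r$table$a, length(intersect(q, ann)))
    expect_equal(r$table$b, length(setdiff(q, ann)))
    expect_equal(r$table$c, length(setdiff(ann, q)))
    expect_equal(r$table$d, 100 - length(union(q, ann)))
  }
  disj <- set_enrichment(uni[1:10], uni[51:60], uni)
  expect_lt(disj$odds_ratio, 1)
  expect_equal(set_enrichment(uni, uni, uni)$p_right, 1)
  expect_error(set_enrichment(c(uni[1], "zz"), uni[1:5], uni), "zz")
})

test_that("bonferroni and BH adjustments match hand computation", {
  expect_equal(bonferroni_adjust(0.01, m = 5), 0.05)
  expect_equal(bonferroni_adjust(0.5, m = 10), 1.0)
  set.seed(14)
  p <- runif(20)
  expect_equal(bonferroni_adjust(p, 64), pmin(1, p * 64), tolerance = 1e-15)
  expect_error(bonferroni_adjust(runif(10), m = 5), "m must be")

  expect_equal(bh_fdr(rep(0.2, 7)), rep(0.2, 7))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  # hand step-up on a random vector
  p <- runif(15)
  n <- length(p)
  o <- order(p)
  hand <- numeric(n)
  prev <- 1
  for (i in n:1) {
    prev <- min(prev, p[o[i]] * n / i)
    hand[o[i]] <- prev
  }
  expect_equal(bh_fdr(p), hand, tolerance = 1e-15)
  # permutation invariance
  perm <- sample(n)
  expect_equal(bh_fdr(p[perm]), bh_fdr(p)[perm], tolerance = 1e-15)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("binomial right tails match direct summation and printed summaries", {
  expect_equal(binomial_right_tail(0, 10), 1.0)
  # direct summation oracle for n <= 64
  set.seed(26)
  for (rep in 1:50) {
    n <- sample(1:64, 1); k <- sample(0:n, 1); p0 <- runif(1, 0.05, 0.95)
    direct <- sum(choose(n, k:n) * p0^(k:n) * (1 - p0)^(n - (k:n)))
    expect_equal(binomial_right_tail(k, n, p0), direct,
                 tolerance = 1e-12)
  }
  # the three published success/trial summaries (exact one-sided tails;
  # the printed values round coarsely: 2.4e-11, 0.002, 4.6e-13)
  expect_lt(abs(binomial_right_tail(140, 190, 0.5) / 2.4e-11 - 1), 0.10)
  expect_identical(signif(binomial_right_tail(20, 25, 0.5), 1), 0.002)
  expect_lt(abs(binomial_right_tail(59, 64, 0.5) / 4.6e-13 - 1), 0.10)
  expect_error(binomial_right_tail(5, 3), "k <= n")
})

test_that("paired one-tailed t matches closed form and is antisymmetric", {
  x <- c(3, 5); y <- c(1, 2)
  res <- paired_one_tailed_t(x, y)
  d <- x - y
  expect_equal(res$t, mean(d) / (sd(d) / sqrt(2)), tolerance = 1e-12)
  expect_equal(res$df, 1L)
  expect_equal(res$p, pt(res$t, 1, lower.tail = FALSE), tolerance = 1e-12)
  set.seed(33)
  a <- rnorm(25, 1); b <- rnorm(25)
  r1 <- paired_one_tailed_t(a, b)
  ref <- t.test(a, b, paired = TRUE, alternative = "greater")
  expect_equal(r1$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(r1$p, ref$p.value, tolerance = 1e-10)
  r2 <- paired_one_tailed_t(b, a)
  expect_equal(r1$p, 1 - r2$p, tolerance = 1e-10)
  expect_error(paired_one_tailed_t(a, a - 2), "zero variance")
})

test_that("module-vs-DEG comparison harmonises gene pools before testing", {
  set.seed(44)
  uni <- sprintf("u%03d", 1:200)
  pairs <- t(utils::combn(uni[1:40], 2))
  keep <- runif(nrow(pairs)) < 0.2
  net <- interaction_network(data.frame(from = pairs[keep, 1],
                                        to = pairs[keep, 2], score = 900))
  module <- suppressWarnings(
    largest_connected_component(uni[1:20], net, 700))
  disease <- uni[c(1:10, 150:160)]
  deg <- sample(uni)
  cmp <- compare_module_vs_deg(module, deg, disease, uni, net, 700)
  expect_false(cmp$untestable)
  # identical sets give identical ORs
  same <- compare_module_vs_deg(module, c(module$genes,
                                          setdiff(deg, module$genes)),
                                disease, uni, net, 700)
  expect_equal(same$module$odds_ratio, same$top_deg$odds_ratio)
  # harmonisation: disease genes absent from the DEG pool are dropped
  deg_short <- setdiff(deg, uni[1:5])
  cmp2 <- compare_module_vs_deg(module, deg_short, disease, uni, net, 700)
  expect_equal(cmp2$n_disease_genes,
               length(intersect(intersect(disease, deg_short), uni)))
  # constructed separation: annotated module vs random DEGs
  disease_mod <- module$genes
  cmp3 <- compare_module_vs_deg(module, deg, disease_mod, uni, net, 700)
  expect_gt(cmp3$module$odds_ratio, cmp3$top_deg$odds_ratio)
})

test_that("or_size_sweep walks the documented sizes", {
  set.seed(55)
  ids <- sprintf("u%03d", 1:100)
  pairs <- t(utils::combn(ids, 2))
  keep <- runif(nrow(pairs)) < 0.1
  net <- interaction_network(data.frame(from = pairs[keep, 1],
                                        to = pairs[keep, 2], score = 900))
  ranking <- structure(list(gene_ids = ids,
                            counts = as.integer(seq(100, 1, -1)),
                            g_augmented = seq(100, 1, -1), B = 100L,
                            provenance = list(label = "toy")),
                       class = "gene_ranking")
  sweep_tab <- or_size_sweep(ranking, sample(ids), ids[1:30], ids,
                             sizes = c(20L, 40L, 60L), network = net,
                             cutoff = 700)
  expect_equal(nrow(sweep_tab), 3L)
  expect_equal(sweep_tab$size, c(20L, 40L, 60L))
  expect_true(all(sweep_tab$module_size <= sweep_tab$size))
  expect_error(or_size_sweep(ranking, ids, ids[1:5], ids,
                             sizes = c(50L, 200L), network = net),
               "max size")
})
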