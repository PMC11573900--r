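# Latent arithmetic: disease vectors, amplified decoding, backgrounds,
# the exceedance rank statistic, PCA augmentation and TF perturbation.

test_that("condition_mean_latent is the column mean of the encodings", {
  model <- tiny_model()
  expr <- log_normalize(fx()$expr)
  one <- subset_samples(expr, sample_ids(expr)[1])
  expect_equal(condition_mean_latent(model, one),
               drop(vae_encode(model, one)$mu), tolerance = 1e-12)
  five <- subset_samples(expr, sample_ids(expr)[1:5])
  expect_equal(condition_mean_latent(model, five),
               colMeans(vae_encode(model, five)$mu), tolerance = 1e-12)
})

test_that("disease vectors subtract elementwise with provenance", {
  z <- rnorm(8)
  expect_equal(disease_vector(z, z)$nu, rep(0, 8))
  e3 <- replace(rep(0, 8), 3, 1)
  expect_equal(disease_vector(z + e3, z)$nu, e3)
  z2 <- rnorm(8)
  expect_equal(disease_vector(z, z2, "x", 4L, 6L)$nu, z - z2)
  expect_error(disease_vector(rnorm(3), rnorm(4)), "lengths differ")
})

test_that("amplify_decode composes decode with scalar amplification", {
  model <- tiny_model()
  dv1 <- disease_vector(rnorm(4), rnorm(4))
  dv2 <- disease_vector(rnorm(4), rnorm(4))
  # eta = 0 lands at the latent origin for every disease vector
  expect_equal(amplify_decode(model, dv1, eta = 0),
               amplify_decode(model, dv2, eta = 0), tolerance = 1e-12)
  expect_equal(amplify_decode(model, dv1, eta = 3),
               drop(vae_decode(model, 3 * dv1$nu)), tolerance = 1e-12)
  # decoder nonlinearity: opposite amplification differs
  expect_false(isTRUE(all.equal(amplify_decode(model, dv1, 3),
                                amplify_decode(model, dv1, -3))))
})

test_that("random backgrounds are seeded, scaled and decoded consistently", {
  model <- tiny_model()
  b1 <- random_background(model, B = 50L, seed = 9L)
  b2 <- random_background(model, B = 50L, seed = 9L)
  expect_identical(b1$latent_draws, b2$latent_draws)
  expect_identical(b1$decoded, b2$decoded)
  b0 <- random_background(model, B = 5L, sigma = 0, seed = 1L)
  origin <- drop(vae_decode(model, rep(0, 4)))
  for (i in 1:5) expect_equal(unname(b0$decoded[i, ]), unname(origin))
  b <- random_background(model, B = 1000L, sigma = 1, seed = 3L)
  expect_true(all(abs(colMeans(b$latent_draws)) < 4 / sqrt(1000)))
})

test_that("rank_genes counts strict exceedances over the background", {
  g_aug <- c(G1 = 5, G2 = 0, G3 = 2.5)
  decoded <- matrix(c(1, 2, 3, 4,   # G1: all below 5 -> 4
                      0, 0, 0, 0,   # G2: ties are not exceedances -> 0
                      1, 3, 2, 9),  # G3: two below -> 2
                    nrow = 4, dimnames = list(NULL, c("G1", "G2", "G3")))
  r <- rank_genes(g_aug, decoded)
  expect_equal(r$counts, c(4L, 0L, 2L))
  expect_equal(r$B, 4L)
  # property: brute force agreement and row-permutation invariance
  set.seed(31)
  for (rep in 1:20) {
    B <- sample(2:100, 1); g <- sample(2:50, 1)
    dec <- matrix(rnorm(B * g), B, g,
                  dimnames = list(NULL, sprintf("g%02d", seq_len(g))))
    aug <- rnorm(g); names(aug) <- colnames(dec)
    r <- rank_genes(aug, dec)
    brute <- vapply(seq_len(g), function(i) sum(aug[i] > dec[, i]),
                    numeric(1))
    expect_equal(r$counts, as.integer(brute))
    expect_true(all(r$counts >= 0 & r$counts <= B))
    perm <- rank_genes(aug, dec[sample(B), , drop = FALSE])
    expect_identical(perm$counts, r$counts)
  }
  expect_error(rank_genes(rnorm(3), matrix(0, 2, 4)), "dimensions")
})

test_that("latent_distance is the Euclidean norm of the difference", {
  z <- rnorm(16)
  expect_equal(latent_distance(z, z), 0)
  expect_equal(latent_distance(z + replace(rep(0, 16), 5, 1), z), 1)
  z2 <- rnorm(16)
  expect_equal(latent_distance(z, z2), sqrt(sum((z - z2)^2)))
})

test_that("latent PCA recovers known axes with orthonormal components", {
  set.seed(6)
  # rank-1 data on a line
  dir <- c(3, 4) / 5
  line <- outer(rnorm(40), dir)
  ax <- fit_latent_pca(line)
  expect_lt(ax$score_sd[2], 1e-8)
  expect_equal(abs(sum(ax$components[1, ] * dir)), 1, tolerance = 1e-8)
  # 2-D anisotropic Gaussian: axes match analytic eigenvectors
  S <- matrix(c(4, 1.5, 1.5, 1), 2, 2)
  X <- matrix(rnorm(4000 * 2), 4000, 2) %*% chol(S)
  ax2 <- fit_latent_pca(X)
  ev <- eigen(S)$vectors
  expect_gt(abs(sum(ax2$components[1, ] * ev[, 1])), 0.99)
  G <- ax2$components %*% t(ax2$components)
  expect_equal(unname(G), diag(2), tolerance = 1e-8)
  expect_error(fit_latent_pca(matrix(0, 1, 3)), "2 samples")
})

test_that("component augmentation responds as a decoder difference", {
  model <- tiny_model()
  mu <- vae_encode(model, log_normalize(fx()$expr))$mu
  axes <- fit_latent_pca(mu)
  r0 <- augment_along_component(model, mu, axes, 1, multiple = 0)
  expect_equal(unname(r0$response), rep(0, ncol(model$weights$Wo)))
  r5 <- augment_along_component(model, mu, axes, 1, multiple = 5)
  expect_true(all(r5$response >= 0))
  one <- mu[1, , drop = FALSE]
  r1 <- augment_along_component(model, one, axes, 2, multiple = 5)
  shift <- 5 * axes$score_sd[2] * axes$components[2, ]
  direct <- abs(vae_decode(model, one + rep(shift, each = 1)) -
                  vae_decode(model, one))
  expect_equal(unname(r1$response), unname(drop(direct)), tolerance = 1e-12)
})

test_that("TF perturbation responses behave like mean output changes", {
  model <- tiny_model()
  expr <- log_normalize(fx()$expr)
  tf <- gene_ids(expr)[5]
  r0 <- tf_perturbation_response(model, expr, tf, multiple = 0)
  expect_equal(unname(r0$response), rep(0, length(gene_ids(expr))))
  resp <- tf_perturbation_response(model, expr, tf, multiple = 5)
  expect_true(all(resp$response >= 0))
  # responses over disjoint subsets average (weighted) to the full set
  ids <- sample_ids(expr)
  aa <- subset_samples(expr, ids[1:10]); bb <- subset_samples(expr, ids[-(1:10)])
  sd_full <- sd(expr$values[tf, ])
  ra <- tf_perturbation_response(model, aa, tf, sd_value = sd_full)
  rb <- tf_perturbation_response(model, bb, tf, sd_value = sd_full)
  w <- c(10, length(ids) - 10) / length(ids)
  expect_equal(w[1] * ra$response + w[2] * rb$response, resp$response,
               tolerance = 1e-10)
  const <- expr
  const$values[tf, ] <- 1
  expect_error(tf_perturbation_response(model, const, tf), "degenerate")
  expect_error(tf_perturbation_response(model, expr, "NOPE"), "not in model")
})

test_that("responsivity_ratio divides target by non-target mean response", {
  resp <- structure(list(response = stats::setNames(rep(2, 10),
                                                    sprintf("g%02d", 1:10)),
                         entity = "g01", multiple = 5),
                    class = "perturbation_response")
  expect_equal(responsivity_ratio(resp, c("g02", "g03")), 1.0)
  resp$response[c("g02", "g03")] <- 4
  expect_equal(responsivity_ratio(resp, c("g02", "g03")), 2.0)
  set.seed(12)
  resp$response <- stats::setNames(runif(10, 1, 3), sprintf("g%02d", 1:10))
  targets <- c("g04", "g07", "g09")
  oracle <- mean(resp$response[targets]) /
    mean(resp$response[setdiff(sprintf("g%02d", 2:10), targets)])
  expect_equal(responsivity_ratio(resp, targets), oracle, tolerance = 1e-12)
})

test_that("random module latents are seeded with sigma ~ U(0.01, 0.4)", {
  model <- tiny_model()
  r1 <- random_module_latent(model, seed = 4L)
  expect_identical(r1, random_module_latent(model, seed = 4L))
  sig <- vapply(1:10000, function(s) random_module_latent(model, s)$sigma,
                numeric(1))
  expect_true(all(sig >= 0.01 & sig <= 0.4))
  ks <- suppressWarnings(stats::ks.test(sig, "punif", 0.01, 0.4))
  expect_gt(ks$p.value, 0.01)
})

test_that("tissue signatures are reproducible and bounded", {
  model <- tiny_model()
  expr <- log_normalize(fx()$expr)
  t1_ids <- expr$sample_meta$sample_id[expr$sample_meta$tissue == "T01"]
  tex <- subset_samples(expr, t1_ids)
  s1 <- tissue_signature(model, tex, B = 100L, seed = 2L)
  s2 <- tissue_signature(model, tex, B = 100L, seed = 2L)
  expect_identical(s1$counts, s2$counts)
  expect_true(all(s1$counts >= 0 & s1$counts <= 100L))
  small <- subset_samples(expr, t1_ids[1:3])
  expect_error(tissue_signature(model, small, B = 10L), "3 samples")
  expect_silent(tissue_signature(model, small, B = 10L, min_samples = 2L))
})

test_that("disease-vector ranking recovers the implanted module at desk scale", {
  # the case-control path (difference vector, eta-amplified) carries a
  # recoverable signal on the default cohort; the seed-1 run recovers
  # the implanted module far above chance
  b <- bench_result(1L)
  expect_lt(b$recovery_p, 1e-6)
  expect_gte(b$recovery_overlap, 10L)
})
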