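# Latent-space arithmetic: condition mean vectors, disease vectors
# (case - control), eta-amplified decoding, random decoded backgrounds,
# the per-gene exceedance rank statistic, principal-axis augmentation,
# in-silico TF perturbation, and tissue signatures.

#' Mean latent activation of a sample subset
#'
#' Column means of the mu encodings of the given samples: the condition's
#' mean activation vector z.
#'
#' @inheritParams vae_encode
#' @return Numeric D-vector.
#' @export
condition_mean_latent <- function(model, expr) {
  if (n_samples(expr) < 1L) stopf("need at least one sample")
  colMeans(vae_encode(model, expr)$mu)
}

#' Disease vector: difference of case and control latent means
#'
#' @param z_case,z_control Latent mean vectors of equal length.
#' @param label Label recorded in the result.
#' @param n_case,n_control Optional sample counts recorded as provenance.
#' @return Object of class `disease_vector` with fields `nu`, `label`,
#'   `n_case`, `n_control`.
#' @export
disease_vector <- function(z_case, z_control, label = "disease",
                           n_case = NA_integer_, n_control = NA_integer_) {
  if (length(z_case) != length(z_control)) {
    stopf("z_case and z_control lengths differ (%d vs %d)",
          length(z_case), length(z_control))
  }
  nu <- as.numeric(z_case) - as.numeric(z_control)
  if (!all(is.finite(nu))) stopf("disease vector must be finite")
  structure(list(nu = nu, label = label, n_case = n_case,
                 n_control = n_control), class = "disease_vector")
}

#' @export
print.disease_vector <- function(x, ...) {
  cat(sprintf("disease_vector '%s': D = %d, |nu| = %.4g (n_case=%s, n_control=%s)\n",
              x$label, length(x$nu), sqrt(sum(x$nu^2)), x$n_case, x$n_control))
  invisible(x)
}

#' Amplify a disease vector and decode it
#'
#' Decodes eta * nu as a single latent point, yielding the augmented
#' gene-expression profile carrying the amplified disease signal.
#'
#' @param model A `vae_model`.
#' @param dv A `disease_vector` (or bare D-vector).
#' @param eta Amplification factor (default 3).
#' @return Named numeric vector over the model genes.
#' @export
amplify_decode <- function(model, dv, eta = 3) {
  nu <- if (inherits(dv, "disease_vector")) dv$nu else as.numeric(dv)
  assert_scalar_number(eta, "eta")
  drop(vae_decode(model, eta * nu))
}

#' Ensemble of decoded random latent profiles
#'
#' Draws B latent vectors i.i.d. N(0, sigma^2) per coordinate and decodes
#' them; the decoded rows are the null reference ("background") gene
#' expression profiles.
#'
#' @param model A `vae_model`.
#' @param B Number of draws (default 1000).
#' @param sigma Standard deviation of the latent draws (default 1).
#' @param seed Integer seed.
#' @return Object of class `background_ensemble` with `latent_draws`
#'   (B x D), `decoded` (B x genes), `sigma`, `seed`.
#' @export
random_background <- function(model, B = 1000L, sigma = 1.0, seed = 1L) {
  if (B < 1L) stopf("B must be >= 1")
  D <- model$spec$latent_dim
  draws <- with_seed(seed, matrix(stats::rnorm(B * D, sd = sigma), B, D))
  structure(list(latent_draws = draws, decoded = vae_decode(model, draws),
                 sigma = sigma, seed = seed, B = as.integer(B)),
            class = "background_ensemble")
}

#' Rank genes against a decoded random background
#'
#' For each gene i, counts the background profiles whose decoded value is
#' strictly exceeded by the augmented profile:
#' counts_i = #\{ j : g_augmented_i > background_i,j \}, in [0, B].
#'
#' @param g_augmented Named numeric vector over genes (from
#'   [amplify_decode()]).
#' @param background A `background_ensemble` (or bare B x genes matrix).
#' @param label,eta,seed Provenance recorded in the result.
#' @return Object of class `gene_ranking` with `gene_ids`, `counts`,
#'   `g_augmented`, `B`, `provenance`.
#' @export
rank_genes <- function(g_augmented, background, label = "", eta = NA_real_,
                       seed = NA_integer_) {
  decoded <- if (inherits(background, "background_ensemble")) {
    background$decoded
  } else background
  if (length(g_augmented) != ncol(decoded)) {
    stopf("gene dimensions differ: profile %d vs background %d",
          length(g_augmented), ncol(decoded))
  }
  counts <- rowSums(t(decoded) < as.numeric(g_augmented))
  ids <- names(g_augmented) %||% colnames(decoded)
  structure(list(gene_ids = ids, counts = as.integer(counts),
                 g_augmented = as.numeric(g_augmented),
                 B = nrow(decoded),
                 provenance = list(label = label, eta = eta, seed = seed)),
            class = "gene_ranking")
}

#' @export
print.gene_ranking <- function(x, ...) {
  cat(sprintf("gene_ranking '%s': %d genes vs B = %d backgrounds (max count %d)\n",
              x$provenance$label, length(x$gene_ids), x$B, max(x$counts)))
  invisible(x)
}

#' Write a gene ranking as TSV with a provenance header
#'
#' @param ranking A `gene_ranking`.
#' @param path Output path.
#' @export
write_gene_ranking <- function(ranking, path) {
  hdr <- sprintf("# %s", jsonlite::toJSON(
    c(ranking$provenance, list(B = ranking$B)), auto_unbox = TRUE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(
    data.frame(gene_id = ranking$gene_ids, count = ranking$counts,
               decoded_value = ranking$g_augmented),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Euclidean distance between two latent vectors
#'
#' @param z_case,z_control Numeric vectors of equal length.
#' @return Non-negative scalar.
#' @export
latent_distance <- function(z_case, z_control) {
  if (length(z_case) != length(z_control)) stopf("latent lengths differ")
  sqrt(sum((z_case - z_control)^2))
}

#' Principal-component axes of a latent encoding
#'
#' Centred linear PCA of the mu matrix. The latent coordinates are not
#' constrained to be orthogonal, so encoded features may be linear
#' combinations of mu-nodes; the principal axes give a basis for
#' perturbing them one at a time.
#'
#' @param mu_matrix Samples x D matrix of latent means.
#' @return Object of class `pca_axes` with `components` (K x D
#'   orthonormal rows), `score_sd` (per-component SD of scores), and
#'   `center`.
#' @export
fit_latent_pca <- function(mu_matrix) {
  if (nrow(mu_matrix) < 2L) stopf("PCA needs at least 2 samples")
  K <- min(nrow(mu_matrix) - 1L, ncol(mu_matrix))
  pc <- stats::prcomp(mu_matrix, center = TRUE, scale. = FALSE, rank. = K)
  structure(list(components = t(pc$rotation), score_sd = pc$sdev[seq_len(K)],
                 center = pc$center), class = "pca_axes")
}

#' Decoder response to augmentation along one principal axis
#'
#' Shifts every latent row by `multiple * score_sd[k]` along component k,
#' decodes shifted and unshifted points, and reports the per-gene mean
#' absolute output change over samples.
#'
#' @param model A `vae_model`.
#' @param mu_matrix Samples x D latent means.
#' @param axes A `pca_axes` from [fit_latent_pca()].
#' @param k_index Component index (1-based).
#' @param multiple Shift size in score standard deviations (default 5).
#' @return Object of class `perturbation_response` with the per-gene mean
#'   absolute change in `response`.
#' @export
augment_along_component <- function(model, mu_matrix, axes, k_index,
                                    multiple = 5) {
  if (k_index < 1L || k_index > length(axes$score_sd)) {
    stopf("k_index out of range (1..%d)", length(axes$score_sd))
  }
  shift <- multiple * axes$score_sd[k_index] * axes$components[k_index, ]
  Y0 <- vae_decode(model, mu_matrix)
  Y1 <- vae_decode(model, sweep(mu_matrix, 2L, shift, `+`))
  response <- colMeans(abs(Y1 - Y0))
  structure(list(response = response, entity = sprintf("PC%d", k_index),
                 multiple = multiple), class = "perturbation_response")
}

#' In-silico transcription-factor perturbation through the full VAE
#'
#' Adds `multiple` times the per-gene SD of the TF (computed on the given
#' test split, in normalised space) to the TF's input coordinate in every
#' sample, passes original and perturbed data through encoder and decoder
#' deterministically, and reports the per-gene mean absolute output
#' change.
#'
#' @param model A `vae_model`.
#' @param expr_test Normalised `expression_matrix` (test split).
#' @param tf_gene Gene ID of the transcription factor; must have nonzero
#'   variance in `expr_test`.
#' @param multiple Perturbation size in SDs (default 5).
#' @param sd_value Optional fixed SD for the perturbation; by default the
#'   TF's SD is computed on `expr_test` itself. Supplying it keeps the
#'   perturbation magnitude constant when responses are evaluated on
#'   sample subsets.
#' @return A `perturbation_response`.
#' @export
tf_perturbation_response <- function(model, expr_test, tf_gene, multiple = 5,
                                     sd_value = NULL) {
  if (!tf_gene %in% model$gene_ids) stopf("TF '%s' not in model genes", tf_gene)
  X <- model_input(model, expr_test)
  sd_tf <- sd_value %||% stats::sd(X[, tf_gene])
  if (sd_tf == 0) stopf("degenerate TF '%s': zero variance in test data", tf_gene)
  Xp <- X
  Xp[, tf_gene] <- Xp[, tf_gene] + multiple * sd_tf
  Y0 <- decoder_forward(model, encoder_forward(model, X)$mu)
  Y1 <- decoder_forward(model, encoder_forward(model, Xp)$mu)
  structure(list(response = colMeans(abs(Y1 - Y0)), entity = tf_gene,
                 multiple = multiple), class = "perturbation_response")
}

#' Target-vs-non-target responsivity ratio
#'
#' Mean response over known target genes divided by the mean response
#' over all other genes; the perturbed entity itself is excluded from
#' both groups. A ratio above 1 means known targets respond more.
#'
#' @param response A `perturbation_response`.
#' @param target_genes Character vector of known target gene IDs.
#' @return Positive scalar.
#' @export
responsivity_ratio <- function(response, target_genes) {
  r <- response$response
  genes <- names(r)
  genes_eval <- setdiff(genes, response$entity)
  targets <- intersect(target_genes, genes_eval)
  if (!length(targets)) stopf("no target genes present")
  non_targets <- setdiff(genes_eval, targets)
  if (!length(non_targets)) stopf("target set must be a proper subset of genes")
  denom <- mean(r[non_targets])
  if (denom == 0) stopf("zero mean response among non-targets")
  mean(r[targets]) / denom
}

#' Tissue signature ranking without case-control data
#'
#' Controls are B random N(0,1) latent draws decoded to profiles and
#' re-encoded through the model; the tissue's samples act as cases. The
#' (unamplified) difference of mean latent activations is decoded and
#' ranked against a second, independent B-draw decoded background.
#'
#' @param model A `vae_model`.
#' @param tissue_expr Normalised `expression_matrix` of one tissue's
#'   samples (>= `min_samples`).
#' @param B Background size (default 1000).
#' @param seed Integer seed.
#' @param min_samples Minimum tissue sample count (default 10).
#' @return A `gene_ranking`.
#' @export
tissue_signature <- function(model, tissue_expr, B = 1000L, seed = 1L,
                             min_samples = 10L) {
  if (n_samples(tissue_expr) < min_samples) {
    stopf("tissue has %d samples; %d required (lower `min_samples` to override)",
          n_samples(tissue_expr), min_samples)
  }
  ctrl <- random_background(model, B = B, sigma = 1.0, seed = seed)
  ctrl_mu <- encoder_forward(model, ctrl$decoded)$mu
  z_case <- condition_mean_latent(model, tissue_expr)
  z_control <- colMeans(ctrl_mu)
  g <- drop(vae_decode(model, z_case - z_control))
  bg <- random_background(model, B = B, sigma = 1.0, seed = seed + 1L)
  rank_genes(g, bg, label = "tissue_signature", eta = 1, seed = seed)
}

#' Random low-activation latent vector for modularity scans
#'
#' Draws sigma ~ U(0.01, 0.4) and a latent vector with i.i.d. N(0,
#' sigma^2) coordinates, mimicking the low activation amplitudes typical
#' of case-control difference vectors relative to whole-transcriptome
#' encodings.
#'
#' @param model A `vae_model`.
#' @param seed Integer seed.
#' @return List with `latent` (D-vector) and `sigma`.
#' @export
random_module_latent <- function(model, seed = 1L) {
  D <- model$spec$latent_dim
  with_seed(seed, {
    sigma <- stats::runif(1L, 0.01, 0.4)
    list(latent = stats::rnorm(D, sd = sigma), sigma = sigma)
  })
}
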