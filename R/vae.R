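# Variational autoencoder on ln(x+1) expression profiles.
#
# Architecture: input -> dropout -> dense(h, leaky ReLU)
#   -> [dense mu(D), dense logvar(D)] -> reparameterised sampling
#   -> dense(h, leaky ReLU) -> dense(input_dim, linear).
#
# Loss: L = L_rec + L_KL with
#   L_rec = beta * mean over samples and genes of squared error
#   L_KL  = mean over samples of -1/2 sum_j (1 + logvar - mu^2 - sigma^2)
# Training runs a staged schedule in which beta starts large (favouring
# reconstruction) and is stepped down until reconstruction and KL are in
# balance. Implemented in base R matrix algebra with an analytic backward
# pass and Adam updates; the gradients are checked against finite
# differences in the test suite.

#' Architecture specification for the expression VAE
#'
#' @param input_dim Number of genes at the input/output layer.
#' @param latent_dim Latent dimensionality D (mean/log-variance node
#'   pairs); 64 at full scale.
#' @param encoder_hidden,decoder_hidden Hidden layer widths (128 at full
#'   scale).
#' @param dropout_rate Input dropout rate during training, in [0, 1).
#' @param leaky_slope Negative slope of the leaky-ReLU activations.
#' @return A list of class `vae_architecture`.
#' @export
vae_architecture <- function(input_dim, latent_dim = 64L,
                             encoder_hidden = 128L, decoder_hidden = 128L,
                             dropout_rate = 0.20, leaky_slope = 0.01) {
  dims <- c(input_dim = input_dim, latent_dim = latent_dim,
            encoder_hidden = encoder_hidden, decoder_hidden = decoder_hidden)
  if (any(dims < 1L)) stopf("all layer dimensions must be >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1) stopf("dropout_rate must be in [0, 1)")
  structure(list(input_dim = as.integer(input_dim),
                 latent_dim = as.integer(latent_dim),
                 encoder_hidden = as.integer(encoder_hidden),
                 decoder_hidden = as.integer(decoder_hidden),
                 dropout_rate = dropout_rate, leaky_slope = leaky_slope),
            class = "vae_architecture")
}

#' Staged training schedule
#'
#' Stages run sequentially without resetting weights; each stage fixes the
#' reconstruction weight beta for a number of epochs. The full-scale
#' default mirrors 500 epochs at beta = 100 followed by 100 epochs each at
#' beta = 50, 20 and 10.
#'
#' @param stages List of `c(epochs, beta)` pairs, or a 2-column matrix.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam learning rate.
#' @return A list of class `training_schedule`.
#' @export
training_schedule <- function(stages = list(c(500, 100), c(100, 50),
                                            c(100, 20), c(100, 10)),
                              batch_size = 128L, learning_rate = 1e-3) {
  if (is.matrix(stages)) stages <- lapply(seq_len(nrow(stages)),
                                          function(i) stages[i, ])
  if (!length(stages)) stopf("schedule must contain at least one stage")
  st <- do.call(rbind, lapply(stages, function(s) {
    if (length(s) != 2L || s[1L] < 1 || s[2L] <= 0) {
      stopf("each stage must be c(epochs >= 1, beta > 0)")
    }
    data.frame(epochs = as.integer(s[1L]), beta = as.numeric(s[2L]))
  }))
  structure(list(stages = st, batch_size = as.integer(batch_size),
                 learning_rate = learning_rate),
            class = "training_schedule")
}

#' Desk-scale defaults for synthetic cohorts
#'
#' A reduced architecture (latent 16, hidden 64) and compressed schedule
#' (200/50/50/50 epochs at beta 100/50/20/10) with the same staged shape
#' as the full-scale configuration. The smaller cohort sees far fewer
#' gradient steps per epoch than the full-scale data, so the desk
#' schedule uses more epochs, a smaller batch (32) and a higher Adam
#' learning rate (3e-3); a default synthetic cohort trains in about a
#' minute on one CPU.
#'
#' @param input_dim Number of genes.
#' @return List with elements `architecture` and `schedule`.
#' @export
desk_scale_config <- function(input_dim) {
  list(architecture = vae_architecture(input_dim, latent_dim = 16L,
                                       encoder_hidden = 64L,
                                       decoder_hidden = 64L),
       schedule = training_schedule(list(c(200, 100), c(50, 50),
                                         c(50, 20), c(50, 10)),
                                    batch_size = 32L,
                                    learning_rate = 3e-3))
}

leaky_relu <- function(x, slope) ifelse(x > 0, x, slope * x)
dleaky_relu <- function(x, slope) ifelse(x > 0, 1, slope)

# Numerical guard: log-variances are clamped to +/- LOGVAR_CLAMP in the
# forward pass (gradient zero outside), preventing exp() overflow early
# in training; sigma stays within [e^-4, e^4].
LOGVAR_CLAMP <- 8

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' Build an untrained VAE
#'
#' Weight initialisation is Glorot-uniform and reproducible under `seed`.
#'
#' @param spec A `vae_architecture`.
#' @param gene_ids Character vector of gene IDs fixing the input order;
#'   length must equal `spec$input_dim`.
#' @param seed Integer seed for weight initialisation.
#' @return A `vae_model`.
#' @export
build_vae <- function(spec, gene_ids, seed = 1L) {
  stopifnot(inherits(spec, "vae_architecture"))
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != spec$input_dim) {
    stopf("gene_ids length (%d) must equal input_dim (%d)",
          length(gene_ids), spec$input_dim)
  }
  g <- spec$input_dim; h1 <- spec$encoder_hidden
  D <- spec$latent_dim; h2 <- spec$decoder_hidden
  weights <- with_seed(seed, list(
    W1 = glorot(g, h1), b1 = numeric(h1),
    Wm = glorot(h1, D), bm = numeric(D),
    Wv = glorot(h1, D), bv = numeric(D),
    W2 = glorot(D, h2), b2 = numeric(h2),
    Wo = glorot(h2, g), bo = numeric(g)))
  structure(list(spec = spec, gene_ids = gene_ids, weights = weights,
                 history = NULL, seed = as.integer(seed)),
            class = "vae_model")
}

#' @export
print.vae_model <- function(x, ...) {
  cat(sprintf(
    "vae_model: %d genes -> %d -> %d (mu/logvar) -> %d -> %d genes%s\n",
    x$spec$input_dim, x$spec$encoder_hidden, x$spec$latent_dim,
    x$spec$decoder_hidden, x$spec$input_dim,
    if (is.null(x$history)) " [untrained]" else
      sprintf(" [trained %d epochs]", nrow(x$history))))
  invisible(x)
}

#' Kullback-Leibler term of the loss
#'
#' Per sample: -1/2 sum_j (1 + logvar_j - mu_j^2 - exp(logvar_j)); the
#' returned batch value is the mean over samples. Zero exactly when the
#' encoding matches the standard-normal prior (mu = 0, logvar = 0).
#'
#' @param mu,logvar Numeric matrices (samples x D) or vectors.
#' @return Non-negative scalar.
#' @export
kl_term <- function(mu, logvar) {
  if (is.null(dim(mu))) mu <- matrix(mu, nrow = 1L)
  if (is.null(dim(logvar))) logvar <- matrix(logvar, nrow = 1L)
  if (!all(dim(mu) == dim(logvar))) stopf("mu and logvar shapes differ")
  if (!all(is.finite(mu)) || !all(is.finite(logvar))) {
    stopf("mu/logvar must be finite")
  }
  per_sample <- -0.5 * rowSums(1 + logvar - mu^2 - exp(logvar))
  mean(per_sample)
}

#' Weighted squared-error reconstruction term
#'
#' beta times the mean squared error over samples and genes (the
#' "per input variable" convention, so reported losses are comparable
#' across gene-set sizes).
#'
#' @param y_true,y_pred Matrices of identical shape (samples x genes).
#' @param beta Positive reconstruction weight.
#' @return Non-negative scalar.
#' @export
reconstruction_term <- function(y_true, y_pred, beta = 1) {
  if (is.null(dim(y_true))) y_true <- matrix(y_true, nrow = 1L)
  if (is.null(dim(y_pred))) y_pred <- matrix(y_pred, nrow = 1L)
  if (!all(dim(y_true) == dim(y_pred))) stopf("shape mismatch in reconstruction")
  beta * mean((y_true - y_pred)^2)
}

#' Total loss: reconstruction + KL
#'
#' @param rec,kl Scalars from [reconstruction_term()] and [kl_term()].
#' @export
total_loss <- function(rec, kl) rec + kl

# Expression matrix -> samples x genes input matrix in model gene order.
model_input <- function(model, expr) {
  if (!expr$normalized) stopf("expression must be ln(x+1) normalized")
  miss <- setdiff(model$gene_ids, gene_ids(expr))
  if (length(miss)) {
    stopf("expression is missing %d model gene(s), e.g. %s",
          length(miss), paste(utils::head(miss, 5L), collapse = ", "))
  }
  t(expr$values[model$gene_ids, , drop = FALSE])
}

# Deterministic encoder pass on a samples x genes matrix.
encoder_forward <- function(model, X) {
  w <- model$weights; s <- model$spec
  H1 <- leaky_relu(sweep(X %*% w$W1, 2L, w$b1, `+`), s$leaky_slope)
  list(mu = sweep(H1 %*% w$Wm, 2L, w$bm, `+`),
       logvar = pmin(pmax(sweep(H1 %*% w$Wv, 2L, w$bv, `+`),
                          -LOGVAR_CLAMP), LOGVAR_CLAMP))
}

# Deterministic decoder pass on a samples x D latent matrix.
decoder_forward <- function(model, Z) {
  w <- model$weights; s <- model$spec
  H2 <- leaky_relu(sweep(Z %*% w$W2, 2L, w$b2, `+`), s$leaky_slope)
  Y <- sweep(H2 %*% w$Wo, 2L, w$bo, `+`)
  colnames(Y) <- model$gene_ids
  Y
}

#' Encode expression profiles to the latent space
#'
#' Deterministic: dropout is off and no sampling occurs; all downstream
#' latent arithmetic operates on the mu coordinates.
#'
#' @param model A trained `vae_model`.
#' @param expr A normalised `expression_matrix` covering the model genes.
#' @return List of class `latent_encoding` with matrices `mu` and
#'   `logvar` (samples x D, rownames = sample IDs).
#' @export
vae_encode <- function(model, expr) {
  X <- model_input(model, expr)
  enc <- encoder_forward(model, X)
  rownames(enc$mu) <- rownames(X)
  rownames(enc$logvar) <- rownames(X)
  structure(enc, class = "latent_encoding")
}

#' Decode latent vectors to expression space
#'
#' Latent vectors are decoded directly (no sampling); values are on the
#' ln(x+1) scale of the training data.
#'
#' @param model A `vae_model`.
#' @param latent A D-vector or a (rows x D) matrix of latent points.
#' @return Matrix (rows x genes) of decoded profiles.
#' @export
vae_decode <- function(model, latent) {
  if (is.null(dim(latent))) latent <- matrix(latent, nrow = 1L)
  if (ncol(latent) != model$spec$latent_dim) {
    stopf("latent width (%d) must equal latent_dim (%d)",
          ncol(latent), model$spec$latent_dim)
  }
  decoder_forward(model, latent)
}

# One training step on a minibatch: forward with dropout + sampling,
# analytic backward pass, returns gradients and loss components.
vae_step <- function(model, Xb, beta) {
  w <- model$weights; s <- model$spec
  n <- nrow(Xb); g <- s$input_dim
  keep <- 1 - s$dropout_rate
  M <- if (s$dropout_rate > 0) {
    matrix(stats::rbinom(n * g, 1L, keep), n, g) / keep
  } else 1
  Xd <- Xb * M
  H1p <- sweep(Xd %*% w$W1, 2L, w$b1, `+`)
  H1 <- leaky_relu(H1p, s$leaky_slope)
  Mu <- sweep(H1 %*% w$Wm, 2L, w$bm, `+`)
  Lv_raw <- sweep(H1 %*% w$Wv, 2L, w$bv, `+`)
  Lv <- pmin(pmax(Lv_raw, -LOGVAR_CLAMP), LOGVAR_CLAMP)
  Lv_mask <- (abs(Lv_raw) < LOGVAR_CLAMP) * 1
  Eps <- matrix(stats::rnorm(n * s$latent_dim), n, s$latent_dim)
  Sig <- exp(Lv / 2)
  Z <- Mu + Sig * Eps
  H2p <- sweep(Z %*% w$W2, 2L, w$b2, `+`)
  H2 <- leaky_relu(H2p, s$leaky_slope)
  Y <- sweep(H2 %*% w$Wo, 2L, w$bo, `+`)

  # objective follows the squared-norm convention: sum over genes, mean
  # over samples, so reconstruction and KL compete on the intended scale
  rec <- beta * sum((Y - Xb)^2) / n
  kl <- kl_term(Mu, Lv)

  dY <- 2 * beta * (Y - Xb) / n
  dH2 <- (dY %*% t(w$Wo)) * dleaky_relu(H2p, s$leaky_slope)
  dZ <- dH2 %*% t(w$W2)
  dMu <- dZ + Mu / n
  dLv <- (dZ * Eps * 0.5 * Sig - 0.5 * (1 - exp(Lv)) / n) * Lv_mask
  dH1 <- (dMu %*% t(w$Wm) + dLv %*% t(w$Wv)) * dleaky_relu(H1p, s$leaky_slope)

  grads <- list(W1 = crossprod(Xd, dH1), b1 = colSums(dH1),
                Wm = crossprod(H1, dMu), bm = colSums(dMu),
                Wv = crossprod(H1, dLv), bv = colSums(dLv),
                W2 = crossprod(Z, dH2), b2 = colSums(dH2),
                Wo = crossprod(H2, dY), bo = colSums(dY))
  list(grads = grads, rec = rec, kl = kl)
}

adam_init <- function(weights) {
  list(m = lapply(weights, function(w) w * 0),
       v = lapply(weights, function(w) w * 0), t = 0L)
}

adam_update <- function(weights, grads, state, lr, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(weights)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    weights[[nm]] <- weights[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(weights = weights, state = state)
}

#' Train the VAE under a staged beta schedule
#'
#' Stages run sequentially without resetting weights. Dropout and
#' reparameterised sampling (z = mu + exp(logvar/2) * eps, fresh eps per
#' step) are active only during training. Per-epoch training losses are
#' averaged over minibatches; validation losses are computed with the
#' deterministic forward pass. Training is reproducible under `seed`.
#'
#' @param model An (untrained or trained) `vae_model`.
#' @param train_expr,val_expr Normalised `expression_matrix` objects;
#'   `val_expr` may be `NULL`.
#' @param schedule A `training_schedule`.
#' @param seed Integer seed governing shuffling, dropout and sampling.
#' @return The trained `vae_model` with a `history` data frame
#'   (stage, epoch, beta, loss, rec, kl, val_loss, val_rec, val_kl).
#' @export
train_vae <- function(model, train_expr, val_expr = NULL, schedule,
                      seed = 1L) {
  stopifnot(inherits(model, "vae_model"), inherits(schedule, "training_schedule"))
  X <- model_input(model, train_expr)
  Xval <- if (!is.null(val_expr)) model_input(model, val_expr) else NULL
  n <- nrow(X)
  bs <- min(schedule$batch_size, n)
  state <- adam_init(model$weights)
  history <- list()
  with_seed(seed, {
    for (si in seq_len(nrow(schedule$stages))) {
      beta <- schedule$stages$beta[si]
      for (ep in seq_len(schedule$stages$epochs[si])) {
        ord <- sample.int(n)
        ep_rec <- 0; ep_kl <- 0; nb <- 0L
        for (start in seq(1L, n, by = bs)) {
          idx <- ord[start:min(start + bs - 1L, n)]
          step <- vae_step(model, X[idx, , drop = FALSE], beta)
          if (!is.finite(step$rec) || !is.finite(step$kl)) {
            stopf("non-finite loss at stage %d, epoch %d (beta = %g)",
                  si, ep, beta)
          }
          upd <- adam_update(model$weights, step$grads, state,
                             schedule$learning_rate)
          model$weights <- upd$weights
          state <- upd$state
          ep_rec <- ep_rec + step$rec; ep_kl <- ep_kl + step$kl
          nb <- nb + 1L
        }
        row <- data.frame(stage = si, epoch = ep, beta = beta,
                          rec = ep_rec / nb, kl = ep_kl / nb,
                          loss = (ep_rec + ep_kl) / nb,
                          val_rec = NA_real_, val_kl = NA_real_,
                          val_loss = NA_real_)
        if (!is.null(Xval)) {
          enc <- encoder_forward(model, Xval)
          Yv <- decoder_forward(model, enc$mu)
          # history is on the objective scale: squared-norm reconstruction
          # (= input_dim x the per-variable reconstruction_term)
          row$val_rec <- reconstruction_term(Xval, Yv, beta) * ncol(Xval)
          row$val_kl <- kl_term(enc$mu, enc$logvar)
          row$val_loss <- row$val_rec + row$val_kl
        }
        history[[length(history) + 1L]] <- row
      }
    }
  })
  model$history <- do.call(rbind, history)
  model
}

#' Spearman rank correlation between two expression profiles
#'
#' Average-rank tie handling; returns `NA` (with a warning) when either
#' profile is constant.
#'
#' @param x_profile,y_profile Numeric vectors of equal length >= 3.
#' @return Spearman's rho, or `NA_real_` for a degenerate input.
#' @export
profile_correlation <- function(x_profile, y_profile) {
  if (length(x_profile) != length(y_profile) || length(x_profile) < 3L) {
    stopf("profiles must have equal length >= 3")
  }
  if (stats::sd(x_profile) == 0 || stats::sd(y_profile) == 0) {
    warnf("constant profile: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(x_profile, y_profile, method = "spearman")
}

#' Mean per-profile reconstruction correlation on held-out data
#'
#' Encodes each sample, decodes its mu vector, and reports the mean
#' Spearman correlation between input and reconstruction.
#'
#' @inheritParams vae_encode
#' @return List with `mean_rho` and the per-sample `rho` vector.
#' @export
reconstruction_spearman <- function(model, expr) {
  X <- model_input(model, expr)
  Y <- decoder_forward(model, encoder_forward(model, X)$mu)
  rho <- vapply(seq_len(nrow(X)), function(i) {
    profile_correlation(X[i, ], Y[i, ])
  }, numeric(1))
  list(mean_rho = mean(rho, na.rm = TRUE), rho = rho)
}

#' Save / load a VAE checkpoint
#'
#' The checkpoint is a single RDS archive holding the architecture, gene
#' order, weights and training history; loading verifies internal
#' consistency.
#'
#' @param model A `vae_model`.
#' @param path Checkpoint path.
#' @export
save_vae <- function(model, path) {
  stopifnot(inherits(model, "vae_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_vae
#' @export
load_vae <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "vae_model") ||
      length(model$gene_ids) != model$spec$input_dim) {
    stopf("corrupt checkpoint: gene list does not match architecture")
  }
  model
}
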