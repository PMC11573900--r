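# End-to-end orchestration: a YAML run configuration, stage commands
# that read/write files with a run manifest, and the seeded synthetic
# benchmark composing the whole workflow.

default_params <- function() {
  list(eta = 3, B = 1000L, k = 500L, cutoff = 700, min_targets = 10L,
       sizes = seq(50L, 450L, by = 50L), min_tissue_samples = 10L,
       fractions = c(0.65, 0.25, 0.10),
       latent_dim = 16L, hidden_dim = 64L, dropout_rate = 0.2,
       stages = list(c(40, 100), c(10, 50), c(10, 20), c(10, 10)),
       batch_size = 128L, learning_rate = 1e-3)
}

#' Load and validate a run configuration
#'
#' A YAML file (or list) with blocks `paths` (expression, metadata,
#' network, gene_sets, deg, drug_targets, checkpoint, output_dir),
#' `params` (eta, B, k, cutoff, min_targets, sizes, architecture and
#' schedule settings) and `seed`. Unset parameters take the documented
#' defaults. Referenced input paths are checked at validation time.
#'
#' @param config Path to a YAML file or a list.
#' @param require_paths Character vector of path keys that must exist.
#' @return Validated config list of class `run_config`.
#' @export
run_config <- function(config = list(), require_paths = character(0)) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- list(paths = config$paths %||% list(),
              params = utils::modifyList(default_params(),
                                         config$params %||% list()),
              seed = as.integer(config$seed %||% 1L))
  for (key in require_paths) {
    p <- cfg$paths[[key]]
    if (is.null(p)) stopf("config is missing required path '%s'", key)
    if (!file.exists(p)) stopf("config path '%s' does not exist: %s", key, p)
  }
  structure(cfg, class = "run_config")
}

out_dir <- function(cfg) {
  d <- cfg$paths$output_dir %||% "latentmod_run"
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}

write_manifest <- function(cfg, dir, stage) {
  manifest <- list(stage = stage, seed = cfg$seed, params = cfg$params,
                   paths = cfg$paths,
                   package_version = as.character(utils::packageVersion("latentmod")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(dir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA)
}

#' Pipeline stage: write a synthetic input bundle to disk
#'
#' Runs the synthetic generators at the configured seed and writes the
#' expression/metadata TSVs, case and control TSVs, the network edge
#' list, the disease GMT and the drug target table.
#'
#' @param config A `run_config` (or path / list accepted by
#'   [run_config()]).
#' @return The output directory, invisibly.
#' @export
run_simulate <- function(config = list()) {
  cfg <- run_config(config)
  d <- out_dir(cfg)
  sim <- simulate_healthy_cohort(simulation_config(seed = cfg$seed))
  cc <- implant_disease_signal(sim$truth)
  net <- simulate_network(sim$truth)
  ann <- simulate_annotations(sim$truth)
  write_expression_tsv(sim$expr, file.path(d, "expression.tsv"),
                       file.path(d, "metadata.tsv"))
  write_expression_tsv(cc$case, file.path(d, "case.tsv"),
                       file.path(d, "case_metadata.tsv"))
  write_expression_tsv(cc$control, file.path(d, "control.tsv"),
                       file.path(d, "control_metadata.tsv"))
  write_edge_list(net, file.path(d, "network.tsv"))
  write_gmt(ann$disease, file.path(d, "disease.gmt"))
  write_target_table(ann$drugs, file.path(d, "drug_targets.tsv"))
  jsonlite::write_json(
    list(modules = sim$truth$modules,
         tissue_markers = sim$truth$tissue_markers,
         implanted_module = sim$truth$implanted_module,
         true_drug = ann$true_drug),
    file.path(d, "truth.json"), auto_unbox = TRUE)
  write_manifest(cfg, d, "simulate")
  invisible(d)
}

# Shared preprocessing: read expression + network, filter, normalise.
load_normalized <- function(cfg) {
  expr <- read_expression_tsv(cfg$paths$expression,
                              cfg$paths$metadata %||% NULL)
  net <- read_edge_list(cfg$paths$network)
  expr <- suppressMessages(filter_to_network_genes(expr, net))
  list(expr = log_normalize(expr), network = net)
}

#' Pipeline stage: train the VAE and write a checkpoint
#'
#' Reads the configured expression matrix and network, filters to
#' network genes, ln(x+1)-normalises, splits train/validation/test, and
#' trains under the configured staged schedule. Writes the checkpoint
#' and a per-epoch history TSV.
#'
#' @inheritParams run_simulate
#' @return Path to the checkpoint, invisibly.
#' @export
run_train <- function(config) {
  cfg <- run_config(config, require_paths = c("expression", "network"))
  d <- out_dir(cfg)
  inp <- load_normalized(cfg)
  split <- split_samples(inp$expr, cfg$params$fractions, seed = cfg$seed)
  spec <- vae_architecture(length(gene_ids(inp$expr)),
                           latent_dim = cfg$params$latent_dim,
                           encoder_hidden = cfg$params$hidden_dim,
                           decoder_hidden = cfg$params$hidden_dim,
                           dropout_rate = cfg$params$dropout_rate)
  sched <- training_schedule(cfg$params$stages, cfg$params$batch_size,
                             cfg$params$learning_rate)
  model <- build_vae(spec, gene_ids(inp$expr), seed = cfg$seed)
  model <- train_vae(model, split$train, split$validation, sched,
                     seed = cfg$seed)
  ckpt <- cfg$paths$checkpoint %||% file.path(d, "vae_checkpoint.rds")
  save_vae(model, ckpt)
  utils::write.table(model$history, file.path(d, "history.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_manifest(cfg, d, "train")
  invisible(ckpt)
}

#' Pipeline stage: encode expression to the latent space
#'
#' @inheritParams run_simulate
#' @return Path to the mu TSV, invisibly.
#' @export
run_encode <- function(config) {
  cfg <- run_config(config, require_paths = c("expression", "checkpoint"))
  d <- out_dir(cfg)
  model <- load_vae(cfg$paths$checkpoint)
  expr <- log_normalize(read_expression_tsv(cfg$paths$expression,
                                            cfg$paths$metadata %||% NULL))
  enc <- vae_encode(model, expr)
  for (part in c("mu", "logvar")) {
    utils::write.table(
      data.frame(sample_id = rownames(enc[[part]]), enc[[part]]),
      file.path(d, paste0("latent_", part, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_manifest(cfg, d, "encode")
  invisible(file.path(d, "latent_mu.tsv"))
}

#' Pipeline stage: extract a disease module from case/control data
#'
#' Encodes case and control samples, forms the disease vector, amplifies
#' by eta and decodes, ranks genes against B random decoded backgrounds,
#' takes the top k, and extracts the largest connected component on the
#' network at the score cutoff. Writes the ranking, the module files and
#' an edge-enrichment summary.
#'
#' @inheritParams run_simulate
#' @return The `ppi_module`, invisibly.
#' @export
run_extract_module <- function(config) {
  cfg <- run_config(config,
                    require_paths = c("case", "control", "network",
                                      "checkpoint"))
  d <- out_dir(cfg)
  model <- load_vae(cfg$paths$checkpoint)
  net <- read_edge_list(cfg$paths$network)
  case <- log_normalize(read_expression_tsv(cfg$paths$case))
  control <- log_normalize(read_expression_tsv(cfg$paths$control))
  res <- extract_disease_module(model, case, control, net,
                                eta = cfg$params$eta, B = cfg$params$B,
                                k = cfg$params$k, cutoff = cfg$params$cutoff,
                                seed = cfg$seed)
  write_gene_ranking(res$ranking, file.path(d, "ranking.tsv"))
  write_module(res$module, res$ranking, file.path(d, "module"),
               res$edge_enrichment)
  write_manifest(cfg, d, "extract_module")
  invisible(res$module)
}

#' Disease-module extraction in memory
#'
#' The core composition: case/control latent means -> disease vector ->
#' eta-amplified decode -> rank against B standard-normal decoded
#' backgrounds -> top-k -> largest connected component at the cutoff.
#'
#' @param model A trained `vae_model`.
#' @param case_expr,control_expr Normalised `expression_matrix` objects.
#' @param network An `interaction_network`.
#' @param eta,B,k,cutoff Method parameters (defaults 3, 1000, 500, 700).
#' @param seed Integer seed for the background draws.
#' @param label Provenance label.
#' @return List with `dv`, `g_augmented`, `ranking`, `top_genes`,
#'   `module`, `edge_enrichment`.
#' @export
extract_disease_module <- function(model, case_expr, control_expr, network,
                                   eta = 3, B = 1000L, k = 500L,
                                   cutoff = 700, seed = 1L,
                                   label = "disease") {
  z_case <- condition_mean_latent(model, case_expr)
  z_control <- condition_mean_latent(model, control_expr)
  dv <- disease_vector(z_case, z_control, label,
                       n_case = n_samples(case_expr),
                       n_control = n_samples(control_expr))
  g_aug <- amplify_decode(model, dv, eta = eta)
  bg <- random_background(model, B = B, sigma = 1.0, seed = seed)
  ranking <- rank_genes(g_aug, bg, label = label, eta = eta, seed = seed)
  k <- min(k, length(ranking$gene_ids))
  top <- top_k_genes(ranking, k)
  module <- suppressWarnings(
    largest_connected_component(top, network, cutoff, ranking, label))
  enr <- if (length(module$genes) >= 2L) {
    edge_enrichment(module$genes, network, cutoff, method = "degree")
  } else NULL
  list(dv = dv, g_augmented = g_aug, ranking = ranking, top_genes = top,
       module = module, edge_enrichment = enr)
}

#' Pipeline stage: per-tissue signature rankings
#'
#' For every tissue with enough samples in the configured expression
#' data, contrasts the tissue's samples against re-encoded random
#' decoded profiles and writes the resulting rankings; when a gene-set
#' GMT is configured, also writes a Fisher enrichment table of each
#' tissue's top-k genes.
#'
#' @inheritParams run_simulate
#' @return Data frame of enrichment rows (or `NULL`), invisibly.
#' @export
run_tissue_signatures <- function(config) {
  cfg <- run_config(config, require_paths = c("expression", "checkpoint"))
  d <- out_dir(cfg)
  model <- load_vae(cfg$paths$checkpoint)
  expr <- log_normalize(read_expression_tsv(cfg$paths$expression,
                                            cfg$paths$metadata %||% NULL))
  sets <- if (!is.null(cfg$paths$gene_sets)) read_gmt(cfg$paths$gene_sets)
  tissues <- unique(expr$sample_meta$tissue)
  rows <- list()
  for (t in tissues) {
    idx <- expr$sample_meta$sample_id[expr$sample_meta$tissue %in% t]
    if (length(idx) < cfg$params$min_tissue_samples) next
    sig <- tissue_signature(model, subset_samples(expr, idx),
                            B = cfg$params$B, seed = cfg$seed,
                            min_samples = cfg$params$min_tissue_samples)
    write_gene_ranking(sig, file.path(d, sprintf("tissue_%s_ranking.tsv", t)))
    if (!is.null(sets) && t %in% names(sets$sets)) {
      top <- top_k_genes(sig, min(cfg$params$k, length(sig$gene_ids)))
      res <- set_enrichment(top, intersect(sets$sets[[t]], model$gene_ids),
                            model$gene_ids, t)
      rows[[t]] <- data.frame(tissue = t, a = res$table$a,
                              odds_ratio = res$odds_ratio,
                              p_right = res$p_right)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(tab)) {
    utils::write.table(tab, file.path(d, "tissue_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_manifest(cfg, d, "tissue_signatures")
  invisible(tab)
}

#' Pipeline stage: principal-component augmentation scan
#'
#' Fits a PCA to the latent encodings of the configured expression data,
#' augments each component by 5 score-SDs, takes the top-k responding
#' genes per component, and tests them for overlap with each configured
#' gene set (Bonferroni-corrected right-sided Fisher tests over all
#' component-set pairs).
#'
#' @inheritParams run_simulate
#' @return Data frame of component-set enrichment rows, invisibly.
#' @export
run_pca_scan <- function(config) {
  cfg <- run_config(config,
                    require_paths = c("expression", "checkpoint", "gene_sets"))
  d <- out_dir(cfg)
  model <- load_vae(cfg$paths$checkpoint)
  expr <- log_normalize(read_expression_tsv(cfg$paths$expression))
  sets <- read_gmt(cfg$paths$gene_sets)
  mu <- vae_encode(model, expr)$mu
  axes <- fit_latent_pca(mu)
  K <- length(axes$score_sd)
  rows <- list()
  for (kk in seq_len(K)) {
    resp <- augment_along_component(model, mu, axes, kk)
    top <- names(sort(resp$response, decreasing = TRUE))[
      seq_len(min(cfg$params$k, length(resp$response)))]
    for (nm in names(sets$sets)) {
      ann <- intersect(sets$sets[[nm]], model$gene_ids)
      if (!length(ann)) next
      res <- set_enrichment(top, ann, model$gene_ids,
                            sprintf("PC%d:%s", kk, nm))
      rows[[length(rows) + 1L]] <- data.frame(
        component = kk, set = nm, a = res$table$a,
        odds_ratio = res$odds_ratio, p_right = res$p_right)
    }
  }
  tab <- do.call(rbind, rows)
  tab$p_bonferroni <- bonferroni_adjust(tab$p_right, nrow(tab))
  utils::write.table(tab, file.path(d, "pca_scan.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_manifest(cfg, d, "pca_scan")
  invisible(tab)
}

#' Pipeline stage: TF responsivity scan
#'
#' Perturbs each configured TF by 5 input SDs, measures the decoder
#' response, and reports the target-vs-non-target responsivity ratio per
#' TF plus the exact binomial summary of how many ratios exceed 1.
#'
#' @inheritParams run_simulate
#' @return List with the per-TF data frame and the binomial summary,
#'   invisibly.
#' @export
run_tf_response <- function(config) {
  cfg <- run_config(config,
                    require_paths = c("expression", "checkpoint",
                                      "tf_targets"))
  d <- out_dir(cfg)
  model <- load_vae(cfg$paths$checkpoint)
  expr <- log_normalize(read_expression_tsv(cfg$paths$expression))
  tf_tab <- read_target_table(cfg$paths$tf_targets)
  sets <- filter_drugs(tf_tab, model$gene_ids,
                       min_targets = cfg$params$min_targets)
  sets <- sets[names(sets) %in% model$gene_ids]
  rows <- lapply(names(sets), function(tf) {
    resp <- tf_perturbation_response(model, expr, tf)
    data.frame(tf = tf, n_targets = length(sets[[tf]]),
               ratio = responsivity_ratio(resp, sets[[tf]]))
  })
  tab <- do.call(rbind, rows)
  summ <- list(n_above_1 = sum(tab$ratio > 1), n = nrow(tab),
               p_binomial = binomial_right_tail(sum(tab$ratio > 1),
                                                nrow(tab), 0.5))
  utils::write.table(tab, file.path(d, "tf_response.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(summ, file.path(d, "tf_response_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(cfg, d, "tf_response")
  invisible(list(table = tab, summary = summ))
}

#' Pipeline stage: module-vs-DEG enrichment comparison
#'
#' @inheritParams run_simulate
#' @return The `comparison_row`, invisibly.
#' @export
run_enrich <- function(config) {
  cfg <- run_config(config,
                    require_paths = c("case", "control", "network",
                                      "checkpoint", "deg", "gene_sets"))
  d <- out_dir(cfg)
  model <- load_vae(cfg$paths$checkpoint)
  net <- read_edge_list(cfg$paths$network)
  case <- log_normalize(read_expression_tsv(cfg$paths$case))
  control <- log_normalize(read_expression_tsv(cfg$paths$control))
  deg <- readLines(cfg$paths$deg)
  sets <- read_gmt(cfg$paths$gene_sets)
  res <- extract_disease_module(model, case, control, net,
                                eta = cfg$params$eta, B = cfg$params$B,
                                k = cfg$params$k, cutoff = cfg$params$cutoff,
                                seed = cfg$seed)
  disease_genes <- sets$sets[[1L]]
  cmp <- compare_module_vs_deg(res$module, deg, disease_genes,
                               model$gene_ids, net, cfg$params$cutoff)
  out <- list(module_size = cmp$module_size,
              n_disease_genes = cmp$n_disease_genes,
              untestable = cmp$untestable)
  if (!cmp$untestable) {
    out$module_or <- cmp$module$odds_ratio
    out$module_p <- cmp$module$p_right
    out$top_deg_or <- cmp$top_deg$odds_ratio
    out$deg_lcc_or <- if (!is.null(cmp$deg_lcc)) cmp$deg_lcc$odds_ratio
  }
  jsonlite::write_json(out, file.path(d, "comparison.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(cfg, d, "enrich")
  invisible(cmp)
}

#' Pipeline stage: drug repurposing ranking
#'
#' @inheritParams run_simulate
#' @return The `drug_ranking`, invisibly.
#' @export
run_drugs <- function(config) {
  cfg <- run_config(config,
                    require_paths = c("case", "control", "network",
                                      "checkpoint", "drug_targets"))
  d <- out_dir(cfg)
  model <- load_vae(cfg$paths$checkpoint)
  net <- read_edge_list(cfg$paths$network)
  case <- log_normalize(read_expression_tsv(cfg$paths$case))
  control <- log_normalize(read_expression_tsv(cfg$paths$control))
  drugs <- read_target_table(cfg$paths$drug_targets)
  res <- extract_disease_module(model, case, control, net,
                                eta = cfg$params$eta, B = cfg$params$B,
                                k = cfg$params$k, cutoff = cfg$params$cutoff,
                                seed = cfg$seed)
  # analysis universe: model genes restricted to the drug table's gene space
  universe <- intersect(model$gene_ids, unique(drugs$target))
  if (length(universe) < 100L) universe <- model$gene_ids
  ranking <- drug_enrichment(intersect(res$module$genes, universe), drugs,
                             universe, min_targets = cfg$params$min_targets)
  utils::write.table(ranking, file.path(d, "drug_ranking.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_manifest(cfg, d, "drugs")
  invisible(ranking)
}

#' Seeded end-to-end synthetic benchmark
#'
#' Composes the full workflow on a synthetic cohort at one seed:
#' simulate -> filter to network genes -> normalise -> split -> train the
#' desk-scale VAE -> held-out reconstruction -> implant case/control ->
#' disease vector -> amplified decode -> rank against backgrounds ->
#' module -> edge enrichment -> disease-gene enrichment (vs a random DEG
#' baseline of the same size) -> drug ranking.
#'
#' @param seed Integer seed driving every stochastic stage.
#' @param eta,B,k,cutoff Method parameters.
#' @return Named list of metrics: `mean_spearman`, `recovery_overlap`,
#'   `recovery_p`, `implanted_size`, `module_size`, `module_edge_fold`,
#'   `implanted_edge_fold`, `module_or`, `deg_or`, `true_drug_rank`,
#'   `latent_case_control_distance`.
#' @export
synthetic_benchmark <- function(seed = 1L, eta = 3, B = 1000L, k = 500L,
                                cutoff = 700) {
  cfg <- simulation_config(seed = seed)
  sim <- simulate_healthy_cohort(cfg)
  net <- simulate_network(sim$truth)
  expr <- suppressMessages(filter_to_network_genes(sim$expr, net))
  expr <- log_normalize(expr)
  split <- split_samples(expr, seed = seed)
  desk <- desk_scale_config(length(gene_ids(expr)))
  model <- build_vae(desk$architecture, gene_ids(expr), seed = seed)
  model <- train_vae(model, split$train, split$validation, desk$schedule,
                     seed = seed)
  recon <- reconstruction_spearman(model, split$test)

  cc <- implant_disease_signal(sim$truth)
  case <- log_normalize(subset_genes_to(cc$case, gene_ids(expr)))
  control <- log_normalize(subset_genes_to(cc$control, gene_ids(expr)))
  res <- extract_disease_module(model, case, control, net, eta = eta,
                                B = B, k = k, cutoff = cutoff, seed = seed)
  universe <- model$gene_ids
  implanted <- intersect(sim$truth$implanted_module, universe)
  top_imp <- top_k_genes(res$ranking, length(implanted))
  rec_tab <- set_enrichment(top_imp, implanted, universe, "recovery")

  ann <- simulate_annotations(sim$truth)
  disease_genes <- intersect(ann$disease$sets$implanted_disease, universe)
  deg_random <- with_seed(seed + 5L, sample(universe))
  cmp <- compare_module_vs_deg(res$module, deg_random, disease_genes,
                               universe, net, cutoff)
  drug_rank <- drug_enrichment(res$module$genes, ann$drugs, universe)
  imp_enr <- edge_enrichment(implanted, net, cutoff, method = "degree")

  list(mean_spearman = recon$mean_rho,
       recovery_overlap = rec_tab$table$a,
       recovery_p = rec_tab$p_right,
       implanted_size = length(implanted),
       module_size = length(res$module$genes),
       module_edge_fold = if (!is.null(res$edge_enrichment))
         res$edge_enrichment$fold else NA_real_,
       implanted_edge_fold = imp_enr$fold,
       module_or = if (!cmp$untestable) cmp$module$odds_ratio else NA_real_,
       deg_or = if (!cmp$untestable) cmp$top_deg$odds_ratio else NA_real_,
       true_drug_rank = match(ann$true_drug, drug_rank$agent),
       latent_case_control_distance = latent_distance(
         condition_mean_latent(model, case),
         condition_mean_latent(model, control)))
}

# Restrict an expression matrix to a gene ID vector (intersection, given
# order).
subset_genes_to <- function(expr, ids) {
  keep <- intersect(ids, gene_ids(expr))
  expression_matrix(expr$values[keep, , drop = FALSE], expr$sample_meta,
                    normalized = expr$normalized)
}

#' Pipeline stage: multi-seed synthetic benchmark
#'
#' Runs [synthetic_benchmark()] over `n_seeds` seeds derived from the
#' config seed and writes the per-seed metric table plus the aggregate
#' summary (recovery successes, module-vs-DEG wins with the exact
#' binomial p, true-drug rank-1 count).
#'
#' @inheritParams run_simulate
#' @param n_seeds Number of seeds (default 5).
#' @return List with `metrics` (data frame) and `summary`, invisibly.
#' @export
run_benchmark <- function(config = list(), n_seeds = 5L) {
  cfg <- run_config(config)
  d <- out_dir(cfg)
  seeds <- cfg$seed + seq_len(n_seeds) - 1L
  rows <- lapply(seeds, function(s) {
    as.data.frame(c(list(seed = s),
                    synthetic_benchmark(s, eta = cfg$params$eta,
                                        B = cfg$params$B, k = cfg$params$k,
                                        cutoff = cfg$params$cutoff)))
  })
  metrics <- do.call(rbind, rows)
  wins <- sum(metrics$module_or > metrics$deg_or, na.rm = TRUE)
  summary <- list(
    n_seeds = n_seeds,
    mean_spearman = mean(metrics$mean_spearman),
    recovery_successes = sum(metrics$recovery_p < 1e-6),
    module_vs_deg_wins = wins,
    win_binomial_p = binomial_right_tail(wins, n_seeds, 0.5),
    true_drug_rank1 = sum(metrics$true_drug_rank == 1L, na.rm = TRUE),
    distance_or_spearman = if (n_seeds >= 3L) {
      stats::cor(metrics$latent_case_control_distance, metrics$module_or,
                 method = "spearman")
    } else NA_real_)
  utils::write.table(metrics, file.path(d, "benchmark_metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(summary, file.path(d, "benchmark_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(cfg, d, "benchmark")
  invisible(list(metrics = metrics, summary = summary))
}
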