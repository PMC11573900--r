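# Synthetic multi-tissue RNA-seq cohorts with block-modular
# co-expression, tissue archetypes, TF-target dependencies, an
# implantable case-control perturbation, a PPI network consistent with
# the implanted modules, and noisy annotation tables. Every generator is
# a pure function of (config, seed), so the whole workflow is testable
# without any download.

#' Configuration of the synthetic cohort generator
#'
#' Defaults define the reference study conditions used throughout the
#' test suite: 2,000 genes across 10 tissues with 60 samples each, 20
#' disjoint co-expression modules of size 20-100, negative-binomial
#' counts (dispersion 0.3), and a case-control perturbation implanted on
#' module 1 with a +1 log-space effect on 40 cases vs 40 controls.
#'
#' @param n_genes,n_tissues,samples_per_tissue,n_modules Cohort shape.
#' @param module_size_range Inclusive range for module sizes (uniform).
#' @param markers_per_tissue Tissue-specific marker genes per tissue.
#' @param archetype_scale Log-fold elevation of markers in their tissue.
#' @param module_strength SD of the per-sample log-normal module factor.
#' @param dispersion Negative-binomial dispersion (size = 1/dispersion).
#' @param baseline_log_mean,baseline_log_sd Log-normal baseline means.
#' @param implant List: `module` (index), `effect` (log-space shift),
#'   `n_case`, `n_control`, `mixed_signs` (logical).
#' @param n_tfs,targets_per_tf,tf_coef TF-target ground-truth structure
#'   (targets depend linearly on the TF in log space).
#' @param seed Integer seed.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 2000L, n_tissues = 10L,
                              samples_per_tissue = 60L, n_modules = 20L,
                              module_size_range = c(20L, 100L),
                              markers_per_tissue = 30L,
                              archetype_scale = 1.5,
                              module_strength = 0.8, dispersion = 0.3,
                              baseline_log_mean = log(100),
                              baseline_log_sd = 1,
                              implant = list(module = 1L, effect = 1.0,
                                             n_case = 40L, n_control = 40L,
                                             mixed_signs = FALSE),
                              n_tfs = 5L, targets_per_tf = 20L,
                              tf_coef = 0.8, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_tissues = as.integer(n_tissues),
              samples_per_tissue = as.integer(samples_per_tissue),
              n_modules = as.integer(n_modules),
              module_size_range = as.integer(module_size_range),
              markers_per_tissue = as.integer(markers_per_tissue),
              archetype_scale = archetype_scale,
              module_strength = module_strength, dispersion = dispersion,
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              implant = utils::modifyList(
                list(module = 1L, effect = 1.0, n_case = 40L,
                     n_control = 40L, mixed_signs = FALSE), implant),
              n_tfs = as.integer(n_tfs),
              targets_per_tf = as.integer(targets_per_tf),
              tf_coef = tf_coef, seed = as.integer(seed))
  if (any(c(cfg$n_genes, cfg$n_tissues, cfg$samples_per_tissue) < 1L)) {
    stopf("cohort dimensions must be positive")
  }
  structure(cfg, class = "simulation_config")
}

# Draw the ground-truth gene assignments (baseline means, module and
# marker membership, TF-target structure). Pure function of the config.
draw_ground_truth <- function(config) {
  with_seed(config$seed, {
    g <- config$n_genes
    ids <- sprintf("G%04d", seq_len(g))
    baseline <- stats::setNames(
      exp(stats::rnorm(g, config$baseline_log_mean, config$baseline_log_sd)),
      ids)
    pool <- sample(ids)
    take <- function(n) {
      if (n > length(pool)) stopf("gene pool exhausted; reduce module/marker sizes")
      out <- pool[seq_len(n)]
      pool <<- pool[-seq_len(n)]
      sort(out)
    }
    sizes <- sample(seq(config$module_size_range[1L],
                        config$module_size_range[2L]),
                    config$n_modules, replace = TRUE)
    modules <- lapply(sizes, take)
    names(modules) <- sprintf("M%02d", seq_along(modules))
    tissues <- sprintf("T%02d", seq_len(config$n_tissues))
    markers <- lapply(tissues, function(t) take(config$markers_per_tissue))
    names(markers) <- tissues
    tfs <- if (config$n_tfs > 0L) take(config$n_tfs) else character(0)
    tf_targets <- lapply(tfs, function(tf) {
      list(targets = take(config$targets_per_tf), coef = config$tf_coef)
    })
    names(tf_targets) <- tfs
    imp <- config$implant
    signs <- if (isTRUE(imp$mixed_signs)) {
      sample(c(-1, 1), length(modules[[imp$module]]), replace = TRUE)
    } else {
      rep(1, length(modules[[imp$module]]))
    }
    list(gene_ids = ids, baseline = baseline, modules = modules,
         tissue_markers = markers, tf_targets = tf_targets,
         implanted_module = modules[[imp$module]],
         implant_signs = stats::setNames(signs, modules[[imp$module]]),
         config = config)
  })
}

# Sample negative-binomial counts for a vector of tissue labels; runs in
# the caller's RNG context. `case` multiplies implanted-module means by
# exp(effect * sign).
sample_counts <- function(truth, tissues, sample_ids, case = FALSE) {
  cfg <- truth$config
  g <- cfg$n_genes
  n <- length(tissues)
  mu <- matrix(truth$baseline, g, n,
               dimnames = list(truth$gene_ids, sample_ids))
  for (t in unique(tissues)) {
    mk <- truth$tissue_markers[[t]]
    mu[mk, tissues == t] <- mu[mk, tissues == t] * exp(cfg$archetype_scale)
  }
  for (mod in truth$modules) {
    fac <- exp(stats::rnorm(n, 0, cfg$module_strength))
    mu[mod, ] <- sweep(mu[mod, , drop = FALSE], 2L, fac, `*`)
  }
  for (tf in names(truth$tf_targets)) {
    act <- stats::rnorm(n)
    mu[tf, ] <- mu[tf, ] * exp(0.5 * act)
    tg <- truth$tf_targets[[tf]]
    mu[tg$targets, ] <- sweep(mu[tg$targets, , drop = FALSE], 2L,
                              exp(tg$coef * 0.5 * act), `*`)
  }
  if (case) {
    imp <- truth$implanted_module
    mu[imp, ] <- mu[imp, ] * exp(cfg$implant$effect * truth$implant_signs[imp])
  }
  counts <- matrix(stats::rnbinom(g * n, size = 1 / cfg$dispersion, mu = mu),
                   g, n, dimnames = dimnames(mu))
  counts
}

#' Simulate a healthy multi-tissue cohort
#'
#' Per-gene per-tissue means are baseline x tissue-archetype factor
#' (markers elevated in their tissue) x one shared log-normal module
#' factor per module per sample x TF-driven factors; counts are drawn
#' negative-binomial around the means.
#'
#' @param config A `simulation_config`.
#' @return List with `expr` (raw `expression_matrix`) and `truth`
#'   (gene assignments: modules, markers, TF targets, implant).
#' @export
simulate_healthy_cohort <- function(config = simulation_config()) {
  truth <- draw_ground_truth(config)
  tissues <- rep(sprintf("T%02d", seq_len(config$n_tissues)),
                 each = config$samples_per_tissue)
  ids <- sprintf("S%04d", seq_along(tissues))
  counts <- with_seed(config$seed + 1L,
                      sample_counts(truth, tissues, ids))
  meta <- data.frame(sample_id = ids, tissue = tissues,
                     condition = "unknown", stringsAsFactors = FALSE)
  list(expr = expression_matrix(counts, meta, normalized = FALSE),
       truth = truth)
}

#' Implant a case-control perturbation
#'
#' Control samples are drawn from the healthy-cohort process restricted
#' to one tissue; case samples use the identical process plus an
#' effect-size shift, in log-mean space, on the implanted-module genes
#' (signs per `config$implant$mixed_signs`).
#'
#' @param truth Ground truth from [simulate_healthy_cohort()].
#' @param tissue Tissue label to draw from (default the first tissue).
#' @param seed Integer seed (default derived from the config seed).
#' @return List with raw `expression_matrix` objects `case` and
#'   `control`.
#' @export
implant_disease_signal <- function(truth, tissue = NULL, seed = NULL) {
  cfg <- truth$config
  imp <- cfg$implant
  if (imp$n_case < 2L || imp$n_control < 2L) {
    stopf("need at least 2 case and 2 control samples")
  }
  tissue <- tissue %||% names(truth$tissue_markers)[1L]
  seed <- seed %||% (cfg$seed + 2L)
  with_seed(seed, {
    ctrl_ids <- sprintf("CTRL%03d", seq_len(imp$n_control))
    case_ids <- sprintf("CASE%03d", seq_len(imp$n_case))
    ctrl <- sample_counts(truth, rep(tissue, imp$n_control), ctrl_ids)
    case <- sample_counts(truth, rep(tissue, imp$n_case), case_ids,
                          case = TRUE)
    meta <- function(ids, cond) data.frame(sample_id = ids, tissue = tissue,
                                           condition = cond,
                                           stringsAsFactors = FALSE)
    list(case = expression_matrix(case, meta(case_ids, "case")),
         control = expression_matrix(ctrl, meta(ctrl_ids, "control")))
  })
}

#' Simulate a PPI network consistent with the modules
#'
#' Within-module node pairs are connected with high probability and
#' STRING-style scores drawn uniformly from 700-999; background pairs
#' are sparse with scores uniform on 150-999.
#'
#' @param truth Ground truth from [simulate_healthy_cohort()].
#' @param within_p Within-module edge probability (default 0.3).
#' @param background_density Background pair edge probability (default
#'   0.005).
#' @param seed Integer seed.
#' @return An `interaction_network`.
#' @export
simulate_network <- function(truth, within_p = 0.3,
                             background_density = 0.005, seed = NULL) {
  if (background_density <= 0 || background_density >= 1) {
    stopf("background_density must be in (0, 1)")
  }
  seed <- seed %||% (truth$config$seed + 3L)
  ids <- truth$gene_ids
  g <- length(ids)
  with_seed(seed, {
    # sparse background: sample pair indices without materialising all pairs
    n_pairs <- g * (g - 1) / 2
    n_bg <- stats::rbinom(1L, n_pairs, background_density)
    lin <- sort(sample(n_pairs, n_bg))
    # linear index -> (i, j), i < j, column-major over the upper triangle
    j <- ceiling((1 + sqrt(1 + 8 * lin)) / 2)
    i <- lin - (j - 1) * (j - 2) / 2
    bg <- data.frame(from = ids[i], to = ids[j],
                     score = sample(150:999, n_bg, replace = TRUE))
    within <- lapply(truth$modules, function(mod) {
      pr <- t(utils::combn(mod, 2L))
      keep <- stats::runif(nrow(pr)) < within_p
      data.frame(from = pr[keep, 1L], to = pr[keep, 2L],
                 score = sample(700:999, sum(keep), replace = TRUE))
    })
    interaction_network(rbind(bg, do.call(rbind, within)))
  })
}

#' Simulate disease-gene and drug-target annotation tables
#'
#' The disease gene set contains a `coverage` fraction of the implanted
#' module plus `noise` (as a fraction of the module size) random
#' non-module genes. The drug table contains one "true drug" whose
#' targets are a subset of the implanted module, plus random decoy
#' agents.
#'
#' @param truth Ground truth from [simulate_healthy_cohort()].
#' @param coverage Fraction of the implanted module annotated (default
#'   0.8).
#' @param noise Noise genes as a fraction of the module size (default
#'   0.5).
#' @param n_decoys Number of decoy agents (default 30).
#' @param true_drug_coverage Fraction of the module targeted by the true
#'   drug (default 0.8).
#' @param seed Integer seed.
#' @return List with `disease` (a `gene_set_collection`), `drugs` (a
#'   `target_table`) and `true_drug` (its agent name).
#' @export
simulate_annotations <- function(truth, coverage = 0.8, noise = 0.5,
                                 n_decoys = 30L, true_drug_coverage = 0.8,
                                 seed = NULL) {
  if (coverage < 0 || coverage > 1 || noise < 0) {
    stopf("coverage must be in [0, 1] and noise >= 0")
  }
  seed <- seed %||% (truth$config$seed + 4L)
  mod <- truth$implanted_module
  other <- setdiff(truth$gene_ids, mod)
  with_seed(seed, {
    n_true <- round(coverage * length(mod))
    n_noise <- round(noise * length(mod))
    disease_genes <- sort(c(sample(mod, n_true), sample(other, n_noise)))
    disease <- gene_set_collection(
      list(implanted_disease = disease_genes),
      c(implanted_disease = "synthetic disease-gene annotation"))
    n_drug <- max(11L, round(true_drug_coverage * length(mod)))
    true_targets <- sample(mod, min(n_drug, length(mod)))
    decoys <- lapply(seq_len(n_decoys), function(i) {
      sample(truth$gene_ids,
             min(sample(12:40, 1L), length(truth$gene_ids)))
    })
    names(decoys) <- sprintf("DRUG_DECOY%02d", seq_len(n_decoys))
    all_sets <- c(list(DRUG_TRUE = true_targets), decoys)
    drugs <- target_table(rep(names(all_sets), lengths(all_sets)),
                          unlist(all_sets, use.names = FALSE))
    list(disease = disease, drugs = drugs, true_drug = "DRUG_TRUE")
  })
}

#' Tiny deterministic worked fixture
#'
#' A fixed 30-gene, 3-tissue, 2-module micro-dataset (with its network,
#' implanted case-control sets and annotations) for documentation
#' examples and fast smoke tests; bit-stable across calls.
#'
#' @return List with `expr`, `truth`, `network`, `case`, `control`,
#'   `annotations`, and `config`.
#' @export
worked_fixture <- function() {
  cfg <- simulation_config(
    n_genes = 30L, n_tissues = 3L, samples_per_tissue = 12L,
    n_modules = 2L, module_size_range = c(5L, 7L),
    markers_per_tissue = 3L,
    implant = list(module = 1L, effect = 1.2, n_case = 6L, n_control = 6L),
    n_tfs = 1L, targets_per_tf = 3L, seed = 42L)
  cohort <- simulate_healthy_cohort(cfg)
  cc <- implant_disease_signal(cohort$truth)
  net <- simulate_network(cohort$truth, within_p = 0.8,
                          background_density = 0.05)
  ann <- simulate_annotations(cohort$truth, n_decoys = 5L)
  c(cohort, cc, list(network = net, annotations = ann, config = cfg))
}
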