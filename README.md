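# latentmod

Disease-module extraction by latent-space arithmetic on a transcriptome
variational autoencoder (VAE), with drug-repurposing ranking.

## The problem

Case-control RNA-seq cohorts for specific diseases are usually small,
while healthy bulk RNA-seq is abundant. `latentmod` trains a VAE
exclusively on healthy expression profiles so that its latent space
encodes the shared structure of transcriptome regulation, then uses
elementary vector arithmetic in that space to pull a disease's signal out
of small case-control sets:

- **Disease vector** (per latent node): ν = z̄_case − z̄_control, the
  difference of mean latent encodings.
- **Amplified decode**: g = f(η·ν) with the decoder f and η = 3.
- **Rank statistic**: for each gene *i*, count how often
  g_i > G_i,j over B = 1000 profiles decoded from latent draws
  X ~ N(0, 1) — a per-gene exceedance count in [0, B].
- **Module**: the largest connected component of the top 500 ranked
  genes on a protein–protein interaction network at confidence ≥ 700.
- **Scoring**: right-sided Fisher exact tests (cross-product odds
  ratios, Haldane-corrected) of the module against disease-gene
  annotations, compared with equally sized top-DEG baselines; per-drug
  Fisher tests with Benjamini–Hochberg FDR rank candidate compounds by
  target overlap with the module.

The training loss is `L = β·(1/N)Σ‖y_true−y_pred‖² + L_KL` with a staged
β (100 → 50 → 20 → 10) that learns reconstruction first and latent
geometry second. Everything is seeded and reproducible; a synthetic
multi-tissue cohort generator (negative-binomial counts, block-modular
co-expression, implanted case-control perturbations, a matching PPI
network, noisy annotations) makes the full workflow testable offline.
The VAE itself is a compact base-R implementation (analytic backward
pass, Adam, staged β), verified against finite differences in the test
suite.

## Worked example

The bundled worked fixture is a deterministic 30-gene, 3-tissue cohort
with a 6-gene implanted disease module, its PPI network, and annotation
tables:

```r
library(latentmod)
f <- worked_fixture()
expr <- log_normalize(f$expr)

arch  <- vae_architecture(30, latent_dim = 4, encoder_hidden = 16,
                          decoder_hidden = 16)
sched <- training_schedule(list(c(60, 100), c(20, 10)),
                           batch_size = 12, learning_rate = 3e-3)
model <- train_vae(build_vae(arch, gene_ids(expr), seed = 1),
                   expr, NULL, sched, seed = 1)

res <- extract_disease_module(model,
                              log_normalize(f$case),
                              log_normalize(f$control),
                              f$network, eta = 3, B = 200, k = 12,
                              seed = 1)
res$module
#> ppi_module 'disease': 3 genes, 3 edges (cutoff 700, from top 12)
res$edge_enrichment
#> edge_enrichment (degree): observed 3, expected 1.27, fold 2.36, p = 0.137

drug_enrichment(res$module$genes, f$annotations$drugs,
                model$gene_ids, min_targets = 3)[1:2, ]
#>          agent n_targets overlap odds_ratio     p_right        fdr
#> 1    DRUG_TRUE         6       3       49.0 0.004926108 0.02955665
#> 2 DRUG_DECOY05        14       2        2.5 0.448275862 1.00000000
```

All three module genes (`G0027 G0026 G0006`) belong to the implanted
6-gene module, the module's PPI edge count is 2.4-fold its
degree-preserving expectation, and the drug whose targets were drawn
from the implanted module ranks first at FDR 0.03. At the package's
reference scale (2,000 genes, 600 healthy samples, desk-scale VAE), the
same pipeline reaches a held-out per-profile reconstruction Spearman of
about 0.82 and recovers implanted modules of ~80 genes with
hypergeometric p < 1e-50 (`synthetic_benchmark(seed = 1)`).

Pipeline stages are also exposed as `run_*()` functions over a YAML
config (`run_simulate`, `run_train`, `run_extract_module`, `run_drugs`,
`run_benchmark`, ...) and as a thin CLI at `inst/scripts/latentmod`.

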