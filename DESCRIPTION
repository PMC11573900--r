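Package: latentmod
Title: Disease Module Extraction by Latent-Space Arithmetic on a
    Transcriptome Variational Autoencoder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains a variational autoencoder on healthy bulk RNA-seq
    count profiles, performs arithmetic on its latent space to isolate
    case-versus-control (disease) and tissue signal vectors, decodes and
    ranks genes against ensembles of randomly decoded background
    profiles, and anchors the top-ranked genes on a weighted
    protein-protein interaction network to form connected disease
    modules. Modules are scored against disease-gene annotations with
    Fisher exact enrichment and matched to drug target sets to rank
    candidate compounds for repurposing. Includes a synthetic multi-
    tissue cohort generator with implanted case-control perturbations so
    the full workflow is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
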