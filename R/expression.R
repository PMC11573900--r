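# Expression-matrix container and the preprocessing steps applied before
# model training: ln(x+1) normalisation, restriction to network genes, and
# seeded train/validation/test splitting.

#' Construct an expression matrix container
#'
#' Genes are rows, samples are columns. The container tracks per-sample
#' metadata (tissue, condition) and whether values have been
#' log-normalised; raw matrices must be non-negative.
#'
#' @param values Numeric matrix (genes x samples) with unique rownames
#'   (gene IDs) and colnames (sample IDs).
#' @param sample_meta Optional data frame with columns `sample_id`,
#'   `tissue`, `condition`; `condition` must be one of `"case"`,
#'   `"control"`, `"unknown"`.
#' @param normalized Logical; `TRUE` if values are already ln(x+1).
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, sample_meta = NULL, normalized = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("`values` must be a numeric matrix")
  }
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stopf("`values` must carry gene rownames and sample colnames")
  }
  if (anyDuplicated(gene_ids)) {
    stopf("duplicate gene IDs: %s",
          paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stopf("duplicate sample IDs: %s",
          paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (!all(is.finite(values))) stopf("expression values must be finite")
  if (!normalized && any(values < 0)) {
    stopf("raw expression values must be non-negative")
  }
  if (is.null(sample_meta)) {
    sample_meta <- data.frame(sample_id = sample_ids,
                              tissue = NA_character_,
                              condition = "unknown",
                              stringsAsFactors = FALSE)
  } else {
    req <- c("sample_id", "tissue", "condition")
    if (!all(req %in% names(sample_meta))) {
      stopf("sample_meta must have columns: %s", paste(req, collapse = ", "))
    }
    sample_meta <- sample_meta[match(sample_ids, sample_meta$sample_id),
                               req, drop = FALSE]
    if (anyNA(sample_meta$sample_id)) {
      stopf("sample_meta is missing entries for some samples")
    }
    bad <- !sample_meta$condition %in% c("case", "control", "unknown")
    if (any(bad)) stopf("condition must be case/control/unknown")
    rownames(sample_meta) <- NULL
  }
  structure(list(values = values, sample_meta = sample_meta,
                 normalized = isTRUE(normalized)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) "ln(x+1) normalized" else "raw counts"))
  invisible(x)
}

#' @rdname expression_matrix
#' @param expr An `expression_matrix`.
#' @export
gene_ids <- function(expr) rownames(expr$values)

#' @rdname expression_matrix
#' @export
sample_ids <- function(expr) colnames(expr$values)

#' @rdname expression_matrix
#' @export
n_samples <- function(expr) ncol(expr$values)

#' Subset an expression matrix by sample IDs
#'
#' @param expr An `expression_matrix`.
#' @param ids Sample IDs to keep, in the requested order.
#' @return An `expression_matrix` restricted to `ids`.
#' @export
subset_samples <- function(expr, ids) {
  miss <- setdiff(ids, sample_ids(expr))
  if (length(miss)) stopf("unknown sample IDs: %s", paste(miss, collapse = ", "))
  expression_matrix(expr$values[, ids, drop = FALSE],
                    expr$sample_meta[match(ids, expr$sample_meta$sample_id), ,
                                     drop = FALSE],
                    normalized = expr$normalized)
}

#' Read a gene-by-sample expression TSV
#'
#' Expects a header row of sample IDs and gene IDs in the first column.
#' Optionally joins a metadata TSV (columns `sample_id`, `tissue`,
#' `condition`) by sample ID.
#'
#' @param path Path to the expression TSV.
#' @param meta_path Optional path to the metadata TSV.
#' @return An `expression_matrix` with `normalized = FALSE`.
#' @export
read_expression_tsv <- function(path, meta_path = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stopf("expression file needs a gene column plus samples")
  ids <- df[[1L]]
  body <- as.matrix(df[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stopf("malformed numeric value at gene '%s', sample '%s'",
          ids[bad[1L]], colnames(body)[bad[2L]])
  }
  dimnames(vals) <- list(ids, colnames(body))
  meta <- if (!is.null(meta_path)) {
    utils::read.delim(meta_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  } else NULL
  expression_matrix(vals, sample_meta = meta, normalized = FALSE)
}

#' Write an expression matrix (and optionally its metadata) as TSV
#'
#' @inheritParams subset_samples
#' @param path Output path for the expression TSV.
#' @param meta_path Optional output path for the metadata TSV.
#' @export
write_expression_tsv <- function(expr, path, meta_path = NULL) {
  df <- data.frame(gene_id = gene_ids(expr), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path)) {
    utils::write.table(expr$sample_meta, meta_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' ln(x+1) normalisation of raw counts
#'
#' The only transformation applied before training: every value x becomes
#' ln(x+1). Refuses to run twice.
#'
#' @inheritParams subset_samples
#' @return A normalised `expression_matrix`.
#' @export
log_normalize <- function(expr) {
  if (expr$normalized) stopf("expression matrix is already normalized")
  expression_matrix(log1p(expr$values), expr$sample_meta, normalized = TRUE)
}

#' Restrict an expression matrix to genes present in a PPI network
#'
#' Genes absent from the interaction network are removed (their
#' interactions are unknown, so they cannot take part in modules); the
#' original gene order is preserved. The number of removed genes is
#' attached as attribute `n_removed` and reported via `message()`.
#'
#' @inheritParams subset_samples
#' @param network An `interaction_network`.
#' @export
filter_to_network_genes <- function(expr, network) {
  keep <- gene_ids(expr) %in% network_nodes(network)
  if (!any(keep)) stopf("no expression genes found in the network")
  out <- expression_matrix(expr$values[keep, , drop = FALSE],
                           expr$sample_meta, normalized = expr$normalized)
  n_removed <- sum(!keep)
  message(sprintf("filter_to_network_genes: removed %d of %d genes",
                  n_removed, length(keep)))
  attr(out, "n_removed") <- n_removed
  out
}

#' Seeded train/validation/test split of samples
#'
#' Validation and test sizes are `round(n * fraction)`; the remainder goes
#' to training. The shuffle is reproducible under `seed`. Exact sizes can
#' be forced with `counts` (train, validation, test).
#'
#' @inheritParams subset_samples
#' @param fractions Length-3 positive fractions (train, validation, test)
#'   summing to 1.
#' @param seed Integer seed for the shuffle.
#' @param counts Optional integer vector of exact sizes overriding
#'   `fractions`; must sum to the sample count.
#' @return Named list of `expression_matrix` objects: `train`,
#'   `validation`, `test`.
#' @export
split_samples <- function(expr, fractions = c(0.65, 0.25, 0.10), seed = 1L,
                          counts = NULL) {
  s <- n_samples(expr)
  if (s < 3L) stopf("need at least 3 samples to split")
  if (is.null(counts)) {
    if (length(fractions) != 3L || any(fractions <= 0)) {
      stopf("`fractions` must be 3 positive numbers")
    }
    if (abs(sum(fractions) - 1) > 1e-9) stopf("`fractions` must sum to 1")
    n_val <- round(s * fractions[2L])
    n_test <- round(s * fractions[3L])
    n_train <- s - n_val - n_test
  } else {
    if (length(counts) != 3L || sum(counts) != s) {
      stopf("`counts` must be 3 sizes summing to the sample count (%d)", s)
    }
    n_train <- counts[1L]; n_val <- counts[2L]; n_test <- counts[3L]
  }
  if (min(n_train, n_val, n_test) < 1L) {
    stopf("split produces an empty partition (%d/%d/%d)", n_train, n_val, n_test)
  }
  ids <- with_seed(seed, sample(sample_ids(expr)))
  list(train = subset_samples(expr, sort(ids[seq_len(n_train)])),
       validation = subset_samples(expr, sort(ids[n_train + seq_len(n_val)])),
       test = subset_samples(expr, sort(ids[n_train + n_val + seq_len(n_test)])))
}
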