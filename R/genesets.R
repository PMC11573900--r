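# Gene-set collections (GMT) and two-column agent -> target tables
# (drug-target, TF-target, disease-gene, tissue-gene annotations).

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (set name -> member gene
#'   IDs); members must be non-empty and names unique.
#' @param descriptions Optional named character vector of set
#'   descriptions.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stopf("all gene sets must be named")
  }
  if (anyDuplicated(names(sets))) stopf("gene set names must be unique")
  if (any(lengths(sets) == 0L)) {
    stopf("empty gene set: %s", names(sets)[lengths(sets) == 0L][1L])
  }
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  } else {
    descriptions <- descriptions[names(sets)]
    descriptions[is.na(descriptions)] <- ""
    names(descriptions) <- names(sets)
  }
  structure(list(sets = sets, descriptions = descriptions),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, median size %g\n",
              length(x$sets), stats::median(lengths(x$sets))))
  invisible(x)
}

#' Read / write gene sets in GMT format
#'
#' GMT lines are `name TAB description TAB member1 TAB member2 ...`; a
#' line with fewer than three fields is a parse error.
#'
#' @param path Path to a GMT file.
#' @return `read_gmt()` returns a `gene_set_collection`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short)) stopf("GMT line %d has fewer than 3 fields", which(short)[1L])
  nm <- vapply(fields, `[[`, "", 1L)
  desc <- stats::setNames(vapply(fields, `[[`, "", 2L), nm)
  sets <- stats::setNames(lapply(fields, function(f) {
    members <- f[-(1:2)]
    members[nzchar(members)]
  }), nm)
  gene_set_collection(sets, desc)
}

#' @rdname read_gmt
#' @param collection A `gene_set_collection`.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Construct an agent -> target table
#'
#' Rows pair an agent (a drug or a transcription factor) with one target
#' gene; duplicate pairs are collapsed.
#'
#' @param agent,target Character vectors of equal length.
#' @return A data frame of class `target_table` with columns `agent`,
#'   `target`.
#' @export
target_table <- function(agent, target) {
  df <- unique(data.frame(agent = as.character(agent),
                          target = as.character(target),
                          stringsAsFactors = FALSE))
  df <- df[order(df$agent, df$target), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("target_table", "data.frame")
  df
}

#' Read a two-column agent/target annotation TSV (header required)
#'
#' @param path Path to the TSV.
#' @return A `target_table`.
#' @export
read_target_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stopf("target table needs two columns (agent, target)")
  target_table(df[[1L]], df[[2L]])
}

#' @rdname read_target_table
#' @param table A `target_table`.
#' @export
write_target_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Split a target table into a named list agent -> target vector
#'
#' @param table A `target_table`.
#' @return Named list of character vectors.
#' @export
targets_by_agent <- function(table) {
  split(table$target, table$agent)
}
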