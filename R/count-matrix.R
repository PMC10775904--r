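#' Construct a paired enrichment/input count matrix
#'
#' The central container of the package: an integer gene-by-library count
#' matrix together with per-library metadata (stage, replicate, fraction)
#' and per-row metadata (spike-in status and class). Every (stage,
#' replicate) pair must contribute exactly one `input` and one
#' `enrichment` library.
#'
#' @param counts Integer matrix, rows = genes and spike-ins, columns =
#'   libraries. Row and column names are required.
#' @param libraries Data frame with one row per column of `counts` and
#'   columns `library_id`, `stage`, `replicate`, `fraction`
#'   (`"input"` or `"enrichment"`).
#' @param rows Data frame with one row per row of `counts` and columns
#'   `gene_id`, `is_spikein` (logical) and `spikein_class`
#'   (`NA` for genes, otherwise one of `"scaling"`, `"sensitivity"`,
#'   `"specificity"`).
#'
#' @return An object of class `count_matrix`: a list with elements
#'   `counts`, `libraries`, `rows`.
#' @export
count_matrix <- function(counts, libraries, rows) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stopf("'counts' must have row and column names")
  }
  if (anyNA(counts) || any(counts < 0L)) {
    stopf("counts must be non-negative integers without NA")
  }
  libraries <- as.data.frame(libraries, stringsAsFactors = FALSE)
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  needed_lib <- c("library_id", "stage", "replicate", "fraction")
  if (!all(needed_lib %in% names(libraries))) {
    stopf("'libraries' must have columns %s", paste(needed_lib, collapse = ", "))
  }
  if (nrow(libraries) != ncol(counts)) {
    stopf("'libraries' must have one row per count column")
  }
  if (!identical(libraries$library_id, colnames(counts))) {
    stopf("library_id must match the count column names, in order")
  }
  if (!all(libraries$fraction %in% c("input", "enrichment"))) {
    stopf("fraction must be 'input' or 'enrichment'")
  }
  needed_row <- c("gene_id", "is_spikein", "spikein_class")
  if (!all(needed_row %in% names(rows))) {
    stopf("'rows' must have columns %s", paste(needed_row, collapse = ", "))
  }
  if (nrow(rows) != nrow(counts)) {
    stopf("'rows' must have one row per count row")
  }
  if (!identical(rows$gene_id, rownames(counts))) {
    stopf("gene_id must match the count row names, in order")
  }
  if (anyDuplicated(rows$gene_id)) {
    stopf("duplicate gene_id in count matrix: %s",
          rows$gene_id[anyDuplicated(rows$gene_id)])
  }
  ok_class <- is.na(rows$spikein_class) |
    rows$spikein_class %in% c("scaling", "sensitivity", "specificity")
  if (!all(ok_class)) stopf("unknown spikein_class value")
  if (any(!rows$is_spikein & !is.na(rows$spikein_class))) {
    stopf("spike-in rows must be disjoint from gene rows")
  }
  # pairing: each (stage, replicate) has exactly one input and one enrichment
  key <- paste(libraries$stage, libraries$replicate, sep = "/")
  for (k in unique(key)) {
    fr <- libraries$fraction[key == k]
    if (sum(fr == "input") != 1L || sum(fr == "enrichment") != 1L) {
      stopf("pairing error: (stage, replicate) %s lacks a complete input/enrichment pair", k)
    }
  }
  structure(list(counts = counts, libraries = libraries, rows = rows),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  ns <- sum(x$rows$is_spikein)
  cat(sprintf("count_matrix: %d genes + %d spike-ins x %d libraries\n",
              nrow(x$counts) - ns, ns, ncol(x$counts)))
  cat(sprintf("  stages: %s\n", paste(unique(x$libraries$stage), collapse = ", ")))
  cat(sprintf("  replicates per stage/fraction: %s\n",
              paste(unique(table(x$libraries$stage, x$libraries$fraction)),
                    collapse = ", ")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Write a count matrix and its library sheet to TSV
#'
#' @param cm A [count_matrix()].
#' @param counts_path Path for the counts TSV (first columns `gene_id`,
#'   `is_spikein`, `spikein_class`, then one column per library).
#' @param libraries_path Path for the library-sheet TSV.
#' @return Invisibly, the two paths.
#' @export
write_count_matrix <- function(cm, counts_path, libraries_path) {
  tab <- cbind(cm$rows, as.data.frame(cm$counts, check.names = FALSE))
  write.table(tab, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cm$libraries, libraries_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(counts = counts_path, libraries = libraries_path))
}

#' Read a count matrix from TSV
#'
#' Counterpart of [write_count_matrix()]. The counts file must carry a
#' `gene_id` column; `is_spikein`/`spikein_class` columns are optional
#' (all-gene matrix assumed when absent). The library sheet must list
#' every count column with its stage, replicate and fraction.
#'
#' @param counts_path,libraries_path Paths to the two TSV files.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(counts_path, libraries_path) {
  tab <- read.delim(counts_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(tab)) stopf("counts TSV lacks a gene_id column")
  libs <- read.delim(libraries_path, stringsAsFactors = FALSE)
  if (anyDuplicated(tab$gene_id)) {
    stopf("duplicate gene_id in %s", counts_path)
  }
  meta_cols <- intersect(c("gene_id", "is_spikein", "spikein_class"), names(tab))
  count_cols <- setdiff(names(tab), meta_cols)
  missing <- setdiff(count_cols, libs$library_id)
  if (length(missing)) {
    stopf("count columns absent from library sheet: %s",
          paste(missing, collapse = ", "))
  }
  libs <- libs[match(count_cols, libs$library_id), , drop = FALSE]
  counts <- as.matrix(tab[, count_cols, drop = FALSE])
  if (any(counts < 0)) stopf("negative count in %s", counts_path)
  rownames(counts) <- tab$gene_id
  rows <- data.frame(
    gene_id = tab$gene_id,
    is_spikein = if ("is_spikein" %in% names(tab)) as.logical(tab$is_spikein) else FALSE,
    spikein_class = if ("spikein_class" %in% names(tab)) {
      ifelse(tab$spikein_class %in% c("", "NA"), NA_character_,
             as.character(tab$spikein_class))
    } else NA_character_,
    stringsAsFactors = FALSE
  )
  count_matrix(counts, libs, rows)
}
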