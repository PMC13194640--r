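#' Assemble a count matrix object
#'
#' Bundles an integer gene-by-sample count matrix with its gene annotation and
#' sample metadata tables. This is the raw input of the expression pipeline;
#' [simulate_counts()] produces one and [read_counts()] loads one from disk.
#'
#' @param counts Integer matrix, genes in rows, samples in columns. Row names
#'   are gene ids, column names sample ids.
#' @param genes Data frame with columns `gene_id`, `symbol`, `biotype`, one row
#'   per matrix row, same order.
#' @param samples Data frame with columns `sample_id`, `cell_line`,
#'   `condition`, `shRNA`, `replicate`, one row per matrix column, same order.
#' @return An object of class `count_matrix`: a list with elements `counts`,
#'   `genes` (tibble) and `samples` (tibble).
#' @export
count_matrix <- function(counts, genes, samples) {
  counts <- as.matrix(counts)
  genes <- as_tibble(genes)
  samples <- as_tibble(samples)
  need_g <- c("gene_id", "symbol", "biotype")
  need_s <- c("sample_id", "cell_line", "condition", "shRNA", "replicate")
  if (!all(need_g %in% names(genes))) {
    abort(paste0("gene annotation must have columns: ", paste(need_g, collapse = ", ")))
  }
  if (!all(need_s %in% names(samples))) {
    abort(paste0("sample metadata must have columns: ", paste(need_s, collapse = ", ")))
  }
  if (nrow(genes) != nrow(counts)) {
    abort("gene annotation rows must match count matrix rows")
  }
  if (nrow(samples) != ncol(counts)) {
    abort("sample metadata rows must match count matrix columns")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  rownames(counts) <- genes$gene_id
  colnames(counts) <- samples$sample_id
  structure(list(counts = counts, genes = genes, samples = samples),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  bt <- table(x$genes$biotype)
  cat("  biotypes:", paste(sprintf("%s=%d", names(bt), bt), collapse = ", "), "\n")
  cat("  cell lines:", paste(unique(x$samples$cell_line), collapse = ", "), "\n")
  cat("  conditions:", paste(unique(x$samples$condition), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Long tidy view of a count matrix
#'
#' @param x A [count_matrix()].
#' @param ... Unused.
#' @return A tibble with one row per gene-sample pair: gene annotation,
#'   sample metadata and the raw `count`.
#' @method tidy count_matrix
#' @export
tidy.count_matrix <- function(x, ...) {
  long <- as_tibble(x$counts, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "sample_id", values_to = "count")
  long |>
    dplyr::left_join(x$genes, by = "gene_id") |>
    dplyr::left_join(x$samples, by = "sample_id")
}

new_expr_matrix <- function(values, genes, samples, unit = "log2_cpm") {
  structure(list(values = values, genes = as_tibble(genes),
                 samples = as_tibble(samples), unit = unit),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Long tidy view of an expression matrix
#'
#' @param x An `expr_matrix` as returned by [log2_cpm()].
#' @param ... Unused.
#' @return A tibble with one row per gene-sample pair; the expression value is
#'   in the column named after the matrix unit (e.g. `log2_cpm`).
#' @method tidy expr_matrix
#' @export
tidy.expr_matrix <- function(x, ...) {
  long <- as_tibble(x$values, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "sample_id", values_to = x$unit)
  long |>
    dplyr::left_join(x$genes, by = "gene_id") |>
    dplyr::left_join(x$samples, by = "sample_id")
}

# subset an expr_matrix by gene ids (order of `ids` preserved)
expr_subset <- function(x, ids) {
  idx <- match(ids, rownames(x$values))
  if (anyNA(idx)) {
    abort(paste0("genes absent from expression matrix: ",
                 paste(head(ids[is.na(idx)], 5), collapse = ", ")))
  }
  new_expr_matrix(x$values[idx, , drop = FALSE], x$genes[idx, ], x$samples, x$unit)
}
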