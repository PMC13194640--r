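# All tables are UTF-8, tab-separated, with a header row. Counts are keyed by
# Ensembl-style gene ids; gene-set work downstream is keyed by symbol.

#' Read a count matrix from its three tables
#'
#' Loads the counts TSV (`gene_id` column plus one column per sample), the
#' gene annotation TSV (`gene_id`, `symbol`, `biotype`) and the sample
#' metadata TSV (`sample_id`, `cell_line`, `condition`, `shRNA`, `replicate`)
#' and checks they describe the same genes and samples.
#'
#' @param counts_path,annotation_path,metadata_path Paths to the three TSVs.
#' @return A [count_matrix()].
#' @export
read_counts <- function(counts_path, annotation_path, metadata_path) {
  for (p in c(counts_path, annotation_path, metadata_path)) {
    if (!file.exists(p)) abort(paste0("file not found: ", p),
                               class = "kdconcord_format_error")
  }
  counts <- readr::read_tsv(counts_path, show_col_types = FALSE, progress = FALSE)
  genes <- readr::read_tsv(annotation_path, show_col_types = FALSE, progress = FALSE)
  samples <- readr::read_tsv(metadata_path, show_col_types = FALSE, progress = FALSE)
  if (!"gene_id" %in% names(counts)) {
    abort("counts table needs a gene_id column", class = "kdconcord_format_error")
  }
  mat_cols <- setdiff(names(counts), "gene_id")
  extra <- setdiff(mat_cols, samples$sample_id)
  missing <- setdiff(samples$sample_id, mat_cols)
  if (length(extra) || length(missing)) {
    abort(paste0(
      "counts/metadata sample mismatch",
      if (length(extra)) paste0("; counts-only: ", paste(extra, collapse = ", ")),
      if (length(missing)) paste0("; metadata-only: ", paste(missing, collapse = ", "))
    ), class = "kdconcord_format_error")
  }
  mat <- as.matrix(counts[, samples$sample_id, drop = FALSE])
  if (!is.numeric(mat) || anyNA(mat) || any(mat != round(mat)) || any(mat < 0)) {
    abort("counts must be non-negative integers with no missing values",
          class = "kdconcord_format_error")
  }
  idx <- match(counts$gene_id, genes$gene_id)
  if (anyNA(idx)) {
    abort(paste0("genes missing from annotation: ",
                 paste(head(counts$gene_id[is.na(idx)], 5), collapse = ", ")),
          class = "kdconcord_format_error")
  }
  count_matrix(mat, genes[idx, ], samples)
}

#' Write a count matrix to its three tables
#'
#' Inverse of [read_counts()]; the write/read pair round-trips losslessly.
#'
#' @param x A [count_matrix()].
#' @inheritParams read_counts
#' @return `x`, invisibly.
#' @export
write_counts <- function(x, counts_path, annotation_path, metadata_path) {
  stopifnot(inherits(x, "count_matrix"))
  readr::write_tsv(as_tibble(x$counts, rownames = "gene_id"), counts_path,
                   progress = FALSE)
  readr::write_tsv(x$genes, annotation_path, progress = FALSE)
  readr::write_tsv(x$samples, metadata_path, progress = FALSE)
  invisible(x)
}

new_gene_set_collection <- function(tbl) {
  structure(tbl, class = c("gene_set_collection", class(tibble())))
}

#' Read gene sets in GMT format
#'
#' One set per line: set name, description, then member gene symbols, all
#' tab-separated (the Broad dialect). Duplicate members within a set are
#' stored once; sets with no members are rejected.
#'
#' @param path Path to a `.gmt` file.
#' @return A `gene_set_collection`: a tibble with columns `set`,
#'   `description` and list-column `genes`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path),
                                class = "kdconcord_format_error")
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort("empty GMT file", class = "kdconcord_format_error")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3
  if (any(bad)) {
    abort(paste0("GMT lines with no members: ", paste(which(bad), collapse = ", ")),
          class = "kdconcord_format_error")
  }
  tbl <- tibble(
    set = vapply(fields, `[[`, "", 1L),
    description = vapply(fields, `[[`, "", 2L),
    genes = lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  )
  if (any(lengths(tbl$genes) == 0)) {
    abort("GMT set with only empty member fields", class = "kdconcord_format_error")
  }
  if (anyDuplicated(tbl$set)) {
    abort(paste0("duplicate set names in GMT: ",
                 paste(unique(tbl$set[duplicated(tbl$set)]), collapse = ", ")),
          class = "kdconcord_format_error")
  }
  new_gene_set_collection(tbl)
}

#' Write a gene-set collection to GMT
#'
#' @param x A `gene_set_collection`.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_gmt <- function(x, path) {
  lines <- purrr::pmap_chr(list(x$set, x$description, x$genes),
                           function(s, d, g) paste(c(s, d, g), collapse = "\t"))
  readr::write_lines(lines, path)
  invisible(x)
}

#' Merge gene-set collections
#'
#' Union of the collections; a set name present in more than one collection is
#' an error rather than a silent overwrite.
#'
#' @param ... `gene_set_collection` objects (e.g. one per GMT file).
#' @return A single merged `gene_set_collection`.
#' @export
merge_gene_sets <- function(...) {
  parts <- list(...)
  tbl <- dplyr::bind_rows(lapply(parts, as_tibble))
  if (anyDuplicated(tbl$set)) {
    abort(paste0("set name collision on merge: ",
                 paste(unique(tbl$set[duplicated(tbl$set)]), collapse = ", ")),
          class = "kdconcord_format_error")
  }
  new_gene_set_collection(tbl)
}

# named list: set -> member character vector
gene_set_list <- function(x) setNames(x$genes, x$set)

#' Read a ranked gene list (RNK)
#'
#' Two tab-separated columns, gene symbol and rank score, with a header row.
#' Rows with a missing/empty symbol are removed (and counted in a message);
#' remaining entries are ordered by descending score, ties kept in input file
#' order so enrichment scores are deterministic. Duplicate symbols are an
#' error: no aggregation rule is assumed.
#'
#' @param path Path to a `.rnk` file.
#' @return A `ranked_list`: a tibble with columns `symbol` and `score`,
#'   descending by score.
#' @export
read_rnk <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path),
                                class = "kdconcord_format_error")
  tbl <- readr::read_tsv(path, col_names = c("symbol", "score"), skip = 1,
                         col_types = "cd", progress = FALSE)
  ranked_list(tbl)
}

#' Build a ranked list from a symbol/score table
#'
#' @param tbl Data frame with columns `symbol` and `score`.
#' @return A `ranked_list` tibble sorted by descending score (stable ties).
#' @export
ranked_list <- function(tbl) {
  tbl <- as_tibble(tbl)[, c("symbol", "score")]
  drop <- is.na(tbl$symbol) | !nzchar(trimws(tbl$symbol))
  if (any(drop)) {
    inform(sprintf("ranked list: removed %d entries with missing symbols", sum(drop)))
    tbl <- tbl[!drop, ]
  }
  if (anyNA(tbl$score)) abort("ranked list has missing scores",
                              class = "kdconcord_format_error")
  if (anyDuplicated(tbl$symbol)) {
    abort(paste0("duplicate symbols in ranked list: ",
                 paste(unique(tbl$symbol[duplicated(tbl$symbol)]), collapse = ", ")),
          class = "kdconcord_format_error")
  }
  tbl <- tbl[order(-tbl$score), ]  # order() is stable: ties keep input order
  structure(tbl, class = c("ranked_list", class(tibble())))
}

#' Write a ranked list to RNK
#'
#' @param x A `ranked_list`.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_rnk <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  invisible(x)
}
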