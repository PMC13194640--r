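#' Cross-model concordant core signature
#'
#' Merges two per-line differential tables on gene id and keeps genes with
#' `|log2FC| >= lfc_threshold` in *both* lines and the same direction of
#' change, irrespective of any multiple-testing adjustment. The comparison is
#' inclusive, so a gene at exactly the threshold in both lines is a member.
#'
#' @param de1,de2 [de_table()] results for the two cell lines.
#' @param lfc_threshold Absolute log2 fold-change cut, > 0 (default 1).
#' @return A `core_signature` tibble: `gene_id`, `symbol`, `direction`
#'   (`"up"`/`"down"`), `log2fc_line1`, `log2fc_line2`, with the line labels
#'   stored in the `"lines"` attribute.
#' @export
core_signature <- function(de1, de2, lfc_threshold = 1) {
  if (lfc_threshold <= 0) abort("lfc_threshold must be > 0")
  lines <- c(de1$cell_line[1], de2$cell_line[1])
  merged <- dplyr::inner_join(
    dplyr::select(as_tibble(de1), "gene_id", "symbol", log2fc_line1 = "log2fc"),
    dplyr::select(as_tibble(de2), "gene_id", log2fc_line2 = "log2fc"),
    by = "gene_id")
  if (nrow(merged) == 0) abort("no genes shared between the two tables")
  keep <- abs(merged$log2fc_line1) >= lfc_threshold &
    abs(merged$log2fc_line2) >= lfc_threshold &
    sign(merged$log2fc_line1) == sign(merged$log2fc_line2)
  out <- merged[keep, ]
  out$direction <- ifelse(out$log2fc_line1 > 0, "up", "down")
  out <- out[, c("gene_id", "symbol", "direction", "log2fc_line1", "log2fc_line2")]
  inform(sprintf("core signature: %d genes (%d up, %d down) at |log2FC| >= %g in both lines",
                 nrow(out), sum(out$direction == "up"),
                 sum(out$direction == "down"), lfc_threshold))
  structure(out, lines = lines,
            class = c("core_signature", class(tibble())))
}

#' @describeIn core_signature Membership counts by direction.
#' @param x A `core_signature`.
#' @param ... Unused.
#' @method glance core_signature
#' @export
glance.core_signature <- function(x, ...) {
  tibble(n_genes = nrow(x),
         n_up = sum(x$direction == "up"),
         n_down = sum(x$direction == "down"))
}

new_heatmap_matrix <- function(values, row_order = seq_len(nrow(values))) {
  structure(list(values = values, row_order = row_order),
            class = "heatmap_matrix")
}

#' @export
print.heatmap_matrix <- function(x, ...) {
  cat(sprintf("<heatmap_matrix> %d genes x %d columns (z-scores)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Gene-wise z-scores
#'
#' Centers and scales each row to mean 0, SD 1 across columns (sample SD,
#' n - 1 denominator). Constant rows cannot be scaled and are set to zero
#' with a warning.
#'
#' @param x An `expr_matrix` or a plain numeric matrix with >= 2 columns.
#' @return A `heatmap_matrix` whose `values` are the z-scores and whose
#'   `row_order` is the identity (see [cluster_gene_order()]).
#' @export
zscore_rows <- function(x) {
  vals <- if (inherits(x, "expr_matrix")) x$values else as.matrix(x)
  if (ncol(vals) < 2) abort("z-scoring needs >= 2 columns")
  m <- rowMeans(vals)
  s <- apply(vals, 1, sd)
  const <- s == 0
  if (any(const)) {
    warn(sprintf("%d constant row(s) z-scored to zeros", sum(const)))
    s[const] <- 1
  }
  z <- (vals - m) / s
  z[const, ] <- 0
  new_heatmap_matrix(z)
}

#' Hierarchical gene ordering for heatmaps
#'
#' Average-linkage (UPGMA) agglomeration over Euclidean distances between
#' rows; returns the dendrogram leaf order. `stats::hclust` is deterministic
#' for a fixed input matrix, so the ordering is reproducible.
#'
#' @param x A `heatmap_matrix` (or numeric matrix) with >= 2 rows.
#' @return Integer vector: row indices in leaf order.
#' @export
cluster_gene_order <- function(x) {
  vals <- if (inherits(x, "heatmap_matrix")) x$values else as.matrix(x)
  if (nrow(vals) < 2) abort("clustering needs >= 2 rows")
  hclust(dist(vals, method = "euclidean"), method = "average")$order
}

#' Condition-mean module matrix
#'
#' For a curated gene module, averages log2-CPM across biological replicates
#' within each (cell line, condition) cell to obtain the condition means
#' (line 1 control and knockdowns, then line 2, in the order the conditions
#' appear in the metadata), z-scores each gene across those means, and
#' orders genes by average-linkage clustering.
#'
#' @param expr A `log2_cpm` `expr_matrix`.
#' @param module_genes Character vector of gene symbols; symbols absent from
#'   the matrix are dropped with a warning.
#' @return A `heatmap_matrix`, genes x condition means, with clustered
#'   `row_order` (identity for a single-gene module).
#' @export
module_condition_means <- function(expr, module_genes) {
  stopifnot(inherits(expr, "expr_matrix"))
  idx <- match(module_genes, expr$genes$symbol)
  if (anyNA(idx)) {
    warn(paste0("module genes absent from matrix: ",
                paste(module_genes[is.na(idx)], collapse = ", ")))
    idx <- idx[!is.na(idx)]
  }
  if (!length(idx)) abort("no module genes present in the expression matrix")
  smp <- expr$samples
  lines <- unique(smp$cell_line)
  conds <- unique(smp$condition)
  cols <- tidyr::expand_grid(cell_line = lines, condition = conds)
  means <- sapply(seq_len(nrow(cols)), function(j) {
    sel <- smp$cell_line == cols$cell_line[j] & smp$condition == cols$condition[j]
    if (!any(sel)) abort(paste0("no samples for ", cols$cell_line[j], " / ",
                                cols$condition[j]))
    rowMeans(expr$values[idx, sel, drop = FALSE])
  })
  means <- matrix(means, nrow = length(idx),
                  dimnames = list(expr$genes$symbol[idx],
                                  paste(cols$cell_line, cols$condition)))
  hm <- zscore_rows(means)
  if (nrow(hm$values) >= 2) hm$row_order <- cluster_gene_order(hm)
  hm
}

#' Intersect a core signature with gene sets
#'
#' For each set, the core-signature members it contains, with their
#' directions -- the first step of building focused pathway modules.
#'
#' @param signature A [core_signature()].
#' @param sets A `gene_set_collection`.
#' @return A tibble: `set`, `n_overlap`, and list-column `members`
#'   (tibbles with `symbol` and `direction`).
#' @export
intersect_with_sets <- function(signature, sets) {
  tibble(
    set = sets$set,
    members = purrr::map(sets$genes, function(g) {
      hit <- signature$symbol %in% g
      tibble(symbol = signature$symbol[hit], direction = signature$direction[hit])
    })
  ) |>
    dplyr::mutate(n_overlap = vapply(.data$members, nrow, 0L), .after = "set")
}

#' Default focused pathway modules
#'
#' Four curated seven-gene modules spanning the biological axes the
#' knockdown program touches: G2M checkpoint/DNA repair, TNF-alpha/NF-kB,
#' IL-6/inflammatory, and EMT/adhesion. These are configuration defaults --
#' module membership is expert curation, not an algorithmic output -- and can
#' be replaced wholesale in [pipeline_config()].
#'
#' @return Named list of character vectors of gene symbols.
#' @export
default_modules <- function() {
  list(
    g2m_dna_repair = c("AURKB", "SLC7A5", "TP53", "MLH1", "NEK6", "CKS1B", "RPS3A"),
    tnfa_nfkb = c("NFKB1", "SDC4", "CXCL2", "PLK2", "BIRC3", "CD83", "TNFAIP3"),
    il6_inflammatory = c("HMOX1", "IL6", "EREG", "SERPINE1", "IL6R", "CCL17", "PANX1"),
    emt_adhesion = c("SERPINE1", "FERMT2", "ARPC3", "SDC4", "TGFBR3", "AKT3", "EGFR")
  )
}

#' Heatmap matrix for the core signature
#'
#' Extracts the signature genes from the expression matrix, z-scores each
#' gene across all samples, and clusters genes for the row order. Samples
#' stay in metadata order (line by line, condition by condition).
#'
#' @param expr A `log2_cpm` `expr_matrix` containing the signature genes.
#' @param signature A [core_signature()].
#' @return A `heatmap_matrix` with clustered `row_order`.
#' @export
signature_heatmap <- function(expr, signature) {
  sub <- expr_subset(expr, signature$gene_id)
  hm <- zscore_rows(sub)
  rownames(hm$values) <- signature$symbol
  if (nrow(hm$values) >= 2) hm$row_order <- cluster_gene_order(hm)
  hm
}

#' Write a heatmap matrix as TSV
#'
#' Rows are emitted in the clustered `row_order`.
#'
#' @param x A `heatmap_matrix`.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_heatmap <- function(x, path) {
  ord <- x$values[x$row_order, , drop = FALSE]
  readr::write_tsv(as_tibble(ord, rownames = "gene"), path, progress = FALSE)
  invisible(x)
}
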