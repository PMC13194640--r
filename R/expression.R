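#' Counts per million
#'
#' Divides each sample's counts by its total library size and multiplies by
#' one million. Library size is the column sum over *all* features of the
#' supplied matrix, so CPM should be computed before any biotype restriction.
#'
#' @param x A [count_matrix()].
#' @return An `expr_matrix` in `cpm` units; every column sums to 1e6.
#' @export
cpm <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  lib <- colSums(x$counts)
  if (any(lib == 0)) {
    abort(paste0("zero library size in sample(s): ",
                 paste(colnames(x$counts)[lib == 0], collapse = ", ")))
  }
  vals <- sweep(x$counts, 2, lib, "/") * 1e6
  new_expr_matrix(vals, x$genes, x$samples, unit = "cpm")
}

#' log2(CPM + 1) expression values
#'
#' Applies the pseudocount-one log2 transform, computing CPM first if handed
#' raw counts. A value is 0 exactly when the raw count is 0.
#'
#' @param x A [count_matrix()] or a `cpm`-unit `expr_matrix`.
#' @return An `expr_matrix` in `log2_cpm` units.
#' @export
log2_cpm <- function(x) {
  if (inherits(x, "count_matrix")) x <- cpm(x)
  stopifnot(inherits(x, "expr_matrix"))
  if (x$unit != "cpm") abort("log2_cpm expects counts or a CPM matrix")
  new_expr_matrix(log2(x$values + 1), x$genes, x$samples, unit = "log2_cpm")
}

#' Restrict to protein-coding genes
#'
#' Keeps rows annotated `protein_coding`, preserving order, and reports the
#' retained count. Applied after CPM (library sizes use all features) and
#' before PCA and differential expression.
#'
#' @param x A [count_matrix()] or `expr_matrix`.
#' @return Object of the same class, protein-coding rows only.
#' @export
filter_protein_coding <- function(x) {
  keep <- x$genes$biotype == "protein_coding"
  inform(sprintf("retained %d of %d genes annotated protein_coding",
                 sum(keep), length(keep)))
  if (!any(keep)) warn("no protein_coding genes retained")
  if (inherits(x, "count_matrix")) {
    count_matrix(x$counts[keep, , drop = FALSE], x$genes[keep, ], x$samples)
  } else {
    new_expr_matrix(x$values[keep, , drop = FALSE], x$genes[keep, ], x$samples, x$unit)
  }
}

new_expr_pca <- function(scores, loadings, var_explained, samples, adjusted) {
  structure(list(scores = scores, loadings = loadings,
                 var_explained = var_explained, samples = samples,
                 adjusted = adjusted),
            class = "expr_pca")
}

# SVD of the gene-centered matrix; component signs fixed so the
# largest-magnitude gene loading of each component is positive.
pca_core <- function(vals, samples, adjusted) {
  if (ncol(vals) < 2) abort("PCA needs >= 2 samples")
  if (anyNA(vals)) abort("PCA input has missing values")
  centered <- vals - rowMeans(vals)
  sv <- svd(t(centered))  # samples x genes
  keep <- sv$d > max(sv$d) * 1e-12
  d <- sv$d[keep]
  scores <- sv$u[, keep, drop = FALSE] %*% diag(d, length(d))
  loadings <- sv$v[, keep, drop = FALSE]
  for (j in seq_along(d)) {
    g <- which.max(abs(loadings[, j]))
    if (loadings[g, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  pcs <- paste0("PC", seq_along(d))
  dimnames(scores) <- list(colnames(vals), pcs)
  dimnames(loadings) <- list(rownames(vals), pcs)
  score_tbl <- dplyr::bind_cols(samples, as_tibble(scores))
  new_expr_pca(score_tbl, loadings, setNames(d^2 / sum(sv$d^2), pcs),
               samples, adjusted)
}

#' Principal component analysis of an expression matrix
#'
#' Genes are mean-centered across all samples (no variance scaling) and the
#' samples are projected by singular-value decomposition. Components are
#' ordered by decreasing explained variance and signs are fixed
#' deterministically.
#'
#' @param x An `expr_matrix` (typically log2-CPM, protein-coding subset).
#' @return An `expr_pca` with `scores` (tibble: sample metadata + `PC*`
#'   columns), `loadings` (gene x component matrix) and `var_explained`.
#' @export
pca_global <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  pca_core(x$values, x$samples, adjusted = FALSE)
}

#' Cell-line-adjusted principal component analysis
#'
#' Subtracts, for each gene, its mean expression within each cell line
#' separately, then repeats the PCA on the adjusted matrix. This removes
#' baseline between-line differences so that condition structure (e.g.
#' knockdown versus control) dominates the leading components. After
#' adjustment every gene's mean within each line is exactly zero, and the
#' result is invariant to any per-line per-gene additive shift.
#'
#' @param x An `expr_matrix` whose sample table has a `cell_line` column.
#' @return An `expr_pca` (with `adjusted = TRUE`).
#' @export
pca_line_adjusted <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  lines <- x$samples$cell_line
  vals <- x$values
  for (l in unique(lines)) {
    idx <- which(lines == l)
    if (length(idx) < 2) {
      abort(paste0("cell line ", l, " has a single sample; ",
                   "its adjusted values would be identically zero"))
    }
    vals[, idx] <- vals[, idx] - rowMeans(vals[, idx, drop = FALSE])
  }
  pca_core(vals, x$samples, adjusted = TRUE)
}

#' @export
print.expr_pca <- function(x, ...) {
  cat(sprintf("<expr_pca>%s %d samples, %d components\n",
              if (x$adjusted) " (cell-line adjusted)" else "",
              nrow(x$scores), length(x$var_explained)))
  cat("  variance explained:",
      paste(sprintf("%s %.1f%%", names(x$var_explained)[1:min(3, length(x$var_explained))],
                    100 * x$var_explained[1:min(3, length(x$var_explained))]),
            collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn pca_global Sample scores with metadata, one row per sample.
#' @param ... Unused.
#' @method tidy expr_pca
#' @export
tidy.expr_pca <- function(x, ...) as_tibble(x$scores)

#' @describeIn pca_global One row per component: variance explained and its
#'   cumulative sum.
#' @method glance expr_pca
#' @export
glance.expr_pca <- function(x, ...) {
  tibble(component = names(x$var_explained),
         var_explained = unname(x$var_explained),
         cumulative = cumsum(unname(x$var_explained)))
}

#' @describeIn pca_global Score scatter plot of two components, colored by
#'   condition and shaped by cell line.
#' @param object An `expr_pca`.
#' @param components Two component names to plot.
#' @method autoplot expr_pca
#' @export
autoplot.expr_pca <- function(object, components = c("PC1", "PC2"), ...) {
  sc <- tidy(object)
  ve <- object$var_explained[components]
  ggplot2::ggplot(sc, ggplot2::aes(.data[[components[1]]], .data[[components[2]]],
                                   colour = .data$condition,
                                   shape = .data$cell_line)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", components[1], 100 * ve[1]),
      y = sprintf("%s (%.1f%%)", components[2], 100 * ve[2]),
      title = if (object$adjusted) "Cell-line-adjusted PCA" else "Global PCA"
    ) +
    ggplot2::theme_minimal()
}
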