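#' Offset log2 fold change
#'
#' `log2((mean_kd + offset) / (mean_nt + offset))` on CPM-scale group means.
#' The 0.5 offset stabilises ratios for low-abundance genes and keeps the
#' fold change finite for any finite means.
#'
#' @param mean_nt,mean_kd Non-negative CPM group means (vectorised).
#' @param offset Pseudo-CPM added to both means (default 0.5).
#' @return log2 fold change, KD versus NT.
#' @export
log2_fold_change <- function(mean_nt, mean_kd, offset = 0.5) {
  if (any(mean_nt < 0) || any(mean_kd < 0)) abort("group means must be >= 0")
  log2((mean_kd + offset) / (mean_nt + offset))
}

# vectorised Welch over aligned matrix rows; handles the degenerate
# zero-variance cases documented in welch_t_test
welch_rows <- function(A, B) {
  na <- ncol(A); nb <- ncol(B)
  ma <- unname(rowMeans(A)); mb <- unname(rowMeans(B))
  va <- unname(rowSums((A - ma)^2) / (na - 1))
  vb <- unname(rowSums((B - mb)^2) / (nb - 1))
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  degenerate <- se2 == 0
  equal <- degenerate & (ma == mb)
  differ <- degenerate & (ma != mb)
  t[equal] <- 0; df[equal] <- na + nb - 2
  t[differ] <- sign(ma - mb)[differ] * Inf; df[differ] <- na + nb - 2
  p <- 2 * pt(-abs(t), df)
  p[equal] <- 1
  p[differ] <- .Machine$double.xmin  # zero spread, distinct means: below any finite t
  p <- pmax(p, .Machine$double.xmin)
  tibble(t_stat = t, df = df, p_value = p, degenerate = degenerate)
}

#' Welch's two-sample t test
#'
#' The unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom and a two-sided p value. When both groups have zero variance the
#' test is degenerate: equal means give `t = 0, p = 1`; distinct means give an
#' infinite statistic with `p` set to the smallest representable positive
#' value, flagged in the `degenerate` column, so downstream rankings are
#' preserved without dividing by zero.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return A one-row tibble: `t_stat`, `df`, `p_value`, `degenerate`.
#' @export
welch_t_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) abort("each group needs >= 2 values")
  welch_rows(matrix(a, 1), matrix(b, 1))
}

# signed -log10 p; exactly 0 at p = 1 regardless of fold-change sign
signed_log10p <- function(log2fc, p) {
  s <- sign(log2fc)
  s[p == 1] <- 0
  s * -log10(pmax(p, .Machine$double.xmin))
}

#' Per-cell-line differential expression table
#'
#' For one cell line, compares all knockdown samples (every non-control
#' condition combined) against the control. Fold changes are computed from
#' CPM-scale group means (arithmetic means of per-sample CPM, recovered
#' exactly from the log2(CPM+1) matrix) with a 0.5 offset; the test statistic
#' is Welch's t on the log2-CPM values; the rank score is the signed
#' `-log10 p` used for preranked enrichment.
#'
#' @param expr A `log2_cpm`-unit `expr_matrix` (typically protein-coding
#'   subset).
#' @param cell_line Which cell line to analyse.
#' @param control Control condition label (default `"NT"`).
#' @param offset Fold-change offset, see [log2_fold_change()].
#' @return A `de_table` tibble, one row per gene: `gene_id`, `symbol`,
#'   `mean_cpm_nt`, `mean_cpm_kd`, `log2fc`, `t_stat`, `df`, `p_value`,
#'   `rank_score`, `cell_line`.
#' @export
de_table <- function(expr, cell_line, control = "NT", offset = 0.5) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (expr$unit != "log2_cpm") abort("de_table expects a log2_cpm matrix")
  smp <- expr$samples
  if (!cell_line %in% smp$cell_line) {
    abort(paste0("unknown cell line: ", cell_line), class = "kdconcord_config_error")
  }
  in_line <- smp$cell_line == cell_line
  if (!control %in% smp$condition[in_line]) {
    abort(paste0("control condition '", control, "' absent in line ", cell_line),
          class = "kdconcord_config_error")
  }
  nt <- in_line & smp$condition == control
  kd <- in_line & smp$condition != control
  if (sum(nt) < 2 || sum(kd) < 2) {
    abort("need >= 2 control and >= 2 knockdown samples in the line",
          class = "kdconcord_config_error")
  }
  logv <- expr$values
  cpmv <- 2^logv - 1
  mean_nt <- unname(rowMeans(cpmv[, nt, drop = FALSE]))
  mean_kd <- unname(rowMeans(cpmv[, kd, drop = FALSE]))
  lfc <- log2_fold_change(mean_nt, mean_kd, offset)
  wt <- welch_rows(logv[, kd, drop = FALSE], logv[, nt, drop = FALSE])
  out <- dplyr::bind_cols(
    expr$genes[, c("gene_id", "symbol")],
    tibble(mean_cpm_nt = mean_nt, mean_cpm_kd = mean_kd, log2fc = lfc),
    wt[, c("t_stat", "df", "p_value")]
  )
  out$rank_score <- signed_log10p(out$log2fc, out$p_value)
  out$cell_line <- cell_line
  structure(out, class = c("de_table", class(tibble())))
}

#' Annotate a differential table for volcano display
#'
#' Adds `neg_log10_p` and a strict `significant` flag (`p < p_threshold`; a
#' gene at exactly the threshold is not flagged). Raw, unadjusted p values
#' drive the flag.
#'
#' @param de A [de_table()].
#' @param p_threshold Significance line (default 0.01).
#' @return The table with `neg_log10_p` and `significant` columns.
#' @export
volcano_table <- function(de, p_threshold = 0.01) {
  if (p_threshold <= 0) abort("p_threshold must be positive")
  dplyr::mutate(de,
                neg_log10_p = -log10(pmax(.data$p_value, .Machine$double.xmin)),
                significant = .data$p_value < p_threshold)
}

#' @describeIn de_table Number of genes tested and significant counts at
#'   p < 0.01 by fold-change direction.
#' @param x A `de_table`.
#' @param ... Unused.
#' @method glance de_table
#' @export
glance.de_table <- function(x, ...) {
  tibble(cell_line = x$cell_line[1],
         n_genes = nrow(x),
         n_sig_p01 = sum(x$p_value < 0.01),
         n_up_sig = sum(x$p_value < 0.01 & x$log2fc > 0),
         n_down_sig = sum(x$p_value < 0.01 & x$log2fc < 0))
}

#' @describeIn de_table Volcano plot: log2 fold change against -log10 p, the
#'   p-threshold line drawn horizontally, significant genes coloured.
#' @param object A `de_table`.
#' @param p_threshold Threshold for the significance flag and the line.
#' @method autoplot de_table
#' @export
autoplot.de_table <- function(object, p_threshold = 0.01, ...) {
  v <- volcano_table(object, p_threshold)
  ggplot2::ggplot(v, ggplot2::aes(.data$log2fc, .data$neg_log10_p,
                                  colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(p_threshold), linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "purple"),
                                 guide = "none") +
    ggplot2::labs(x = "log2 fold change (KD vs NT)", y = "-log10 p",
                  title = paste0("Differential expression: ", object$cell_line[1])) +
    ggplot2::theme_minimal()
}
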