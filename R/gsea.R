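#' Parameters for preranked gene set enrichment
#'
#' @param min_size,max_size Sets are tested only if, after intersection with
#'   the ranked list, their size lies in `[min_size, max_size]` (defaults 15
#'   and 500).
#' @param n_perm Number of gene-permutation null draws per set size
#'   (default 10000, minimum 100).
#' @param weight_exponent Exponent on `|score|` when weighting hits in the
#'   running sum; 1 is the classic weighted statistic, 0 the unweighted
#'   Kolmogorov-Smirnov form.
#' @param seed Integer seed for the permutation null.
#' @return A validated `gsea_params` list.
#' @export
gsea_params <- function(min_size = 15, max_size = 500, n_perm = 10000,
                        weight_exponent = 1, seed = 1) {
  p <- list(min_size = as.integer(min_size), max_size = as.integer(max_size),
            n_perm = as.integer(n_perm), weight_exponent = weight_exponent,
            seed = as.integer(seed))
  if (p$min_size < 1 || p$min_size > p$max_size) {
    abort("need 0 < min_size <= max_size", class = "kdconcord_config_error")
  }
  if (p$n_perm < 100) abort("n_perm must be >= 100", class = "kdconcord_config_error")
  if (p$weight_exponent < 0) abort("weight_exponent must be >= 0",
                                   class = "kdconcord_config_error")
  structure(p, class = "gsea_params")
}

# ES from sorted hit positions without materialising the running sum.
# Positions 1..pos_i-1 hold (i-1) hits, so the running sum just before hit i
# is C[i-1] - (pos_i - i) * d and just after it C[i] - (pos_i - i) * d, where
# C is the cumulative hit weight and d the per-miss decrement. The global
# extremum of the walk is attained at one of those 2n points (the walk starts
# and ends at 0).
es_from_positions <- function(pos, w, N) {
  n <- length(pos)
  if (n >= N) abort("gene set covers the whole ranked list")
  tw <- sum(w)
  hw <- if (tw > 0) w / tw else rep(1 / n, n)  # all-zero scores: equal weights
  d <- 1 / (N - n)
  cw <- cumsum(hw)
  gap <- (pos - seq_len(n)) * d
  tops <- cw - gap
  bottoms <- c(0, cw[-n]) - gap
  hi <- max(tops)
  lo <- min(bottoms)
  if (hi >= -lo) {
    i <- which.max(tops)
    list(es = hi, extremum_at = pos[i], leading = seq_len(i))
  } else {
    i <- which.min(bottoms)
    list(es = lo, extremum_at = pos[i], leading = if (i <= n) i:n else integer())
  }
}

#' Running-sum enrichment score of one gene set
#'
#' Walks the ranked list from top to bottom: at each member ("hit") the sum
#' increases by that gene's share of the total member weight
#' `|score|^weight_exponent`; at each non-member it decreases by
#' `1/(N - n_members)`. The enrichment score is the extremum of the walk by
#' absolute value; the leading edge is the members at or before the extremum
#' (positive ES) or at and after it (negative ES).
#'
#' @param ranked A `ranked_list` (see [ranked_list()] / [read_rnk()]).
#' @param members Character vector of member gene symbols.
#' @param weight_exponent See [gsea_params()].
#' @return A list: `es`, `size_used`, `leading_edge` (symbols, rank order),
#'   and `running_sum`, a tibble with `position`, `symbol`, `hit`,
#'   `running_sum` for plotting.
#' @export
enrichment_score <- function(ranked, members, weight_exponent = 1) {
  stopifnot(inherits(ranked, "ranked_list"))
  N <- nrow(ranked)
  if (N < 2) abort("ranked list needs >= 2 genes")
  hit <- ranked$symbol %in% members
  n <- sum(hit)
  if (n == 0) abort("no set members present in the ranked list",
                    class = "kdconcord_empty_set")
  pos <- which(hit)
  w <- abs(ranked$score[pos])^weight_exponent
  res <- es_from_positions(pos, w, N)
  tw <- sum(w)
  inc <- numeric(N)
  inc[pos] <- if (tw > 0) w / tw else 1 / n
  inc[!hit] <- -1 / (N - n)
  rs <- cumsum(inc)
  list(es = res$es, size_used = n,
       leading_edge = ranked$symbol[pos[res$leading]],
       running_sum = tibble(position = seq_len(N), symbol = ranked$symbol,
                            hit = hit, running_sum = rs))
}

#' Preranked gene set enrichment analysis
#'
#' From-scratch preranked GSEA: the classic weighted running-sum enrichment
#' score per set, a gene-permutation null (uniform random same-size subsets
#' of the ranked universe, the only permutation scheme available for
#' preranked input), one-sided same-sign permutation p values with the
#' `1/(1 + n)` floor, normalised enrichment scores (ES divided by the mean
#' |null ES| of matching sign), and Benjamini-Hochberg FDR across the tested
#' sets. Null distributions are shared across sets of equal size, and the
#' whole table is deterministic given the seed.
#'
#' @param ranked A `ranked_list`.
#' @param sets A `gene_set_collection` from [read_gmt()] / [merge_gene_sets()].
#' @param params A [gsea_params()].
#' @return A `gsea_result` tibble: `set`, `size_used`, `es`, `nes`,
#'   `p_value`, `fdr` and list-column `leading_edge`. Sets skipped for size
#'   or absence are recorded in the `"skipped"` attribute.
#' @export
gsea_preranked <- function(ranked, sets, params = gsea_params()) {
  stopifnot(inherits(ranked, "ranked_list"))
  N <- nrow(ranked)
  absw <- abs(ranked$score)^params$weight_exponent
  universe <- ranked$symbol

  prep <- purrr::map(gene_set_list(sets), function(g) which(universe %in% g))
  size <- lengths(prep)
  ok <- size >= params$min_size & size <= params$max_size
  skipped <- tibble(set = sets$set[!ok],
                    size_used = size[!ok],
                    reason = dplyr::case_when(
                      size[!ok] == 0 ~ "no members in ranked list",
                      size[!ok] < params$min_size ~ "below min_size",
                      TRUE ~ "above max_size"))
  if (!any(ok)) abort("no gene sets within the size window",
                      class = "kdconcord_empty_set")
  prep <- prep[ok]

  obs <- purrr::map(prep, function(pos) es_from_positions(pos, absw[pos], N))
  es <- vapply(obs, `[[`, 0, "es")

  local_seed(params$seed)
  null_by_size <- list()
  for (n in sort(unique(lengths(prep)))) {
    null <- numeric(params$n_perm)
    for (i in seq_len(params$n_perm)) {
      pos <- sort.int(sample.int(N, n))
      null[i] <- es_from_positions(pos, absw[pos], N)$es
    }
    null_by_size[[as.character(n)]] <- null
  }

  p <- nes <- numeric(length(prep))
  for (k in seq_along(prep)) {
    null <- null_by_size[[as.character(length(prep[[k]]))]]
    if (es[k] >= 0) {
      same <- null[null >= 0]
      p[k] <- (1 + sum(same >= es[k])) / (1 + length(same))
    } else {
      same <- null[null < 0]
      p[k] <- (1 + sum(same <= es[k])) / (1 + length(same))
    }
    nes[k] <- if (length(same)) es[k] / mean(abs(same)) else NA_real_
  }

  out <- tibble(
    set = names(prep),
    size_used = lengths(prep),
    es = es,
    nes = nes,
    p_value = p,
    fdr = p.adjust(p, method = "BH"),
    leading_edge = purrr::map2(prep, obs, function(pos, o) universe[pos[o$leading]])
  )
  structure(out, skipped = skipped,
            class = c("gsea_result", class(tibble())))
}

#' Ranked list from a differential expression table
#'
#' Extracts `(symbol, rank_score)` from a [de_table()], drops entries with
#' missing symbols (counted in a message) and orders by descending score --
#' the preranked GSEA input.
#'
#' @param de A [de_table()].
#' @return A `ranked_list`.
#' @export
build_rank_file <- function(de) {
  ranked_list(tibble(symbol = de$symbol, score = de$rank_score))
}

#' @describeIn gsea_preranked Summary counts: sets tested, significant at
#'   FDR < 0.05, positive/negative NES.
#' @param x A `gsea_result`.
#' @param ... Unused.
#' @method glance gsea_result
#' @export
glance.gsea_result <- function(x, ...) {
  tibble(n_sets = nrow(x),
         n_skipped = nrow(attr(x, "skipped") %||% tibble()),
         n_fdr05 = sum(x$fdr < 0.05),
         n_positive = sum(x$es > 0),
         n_negative = sum(x$es < 0))
}

#' @describeIn gsea_preranked NES bar chart, sets ordered by NES, filled by
#'   FDR < 0.05.
#' @param object A `gsea_result`.
#' @method autoplot gsea_result
#' @export
autoplot.gsea_result <- function(object, ...) {
  d <- dplyr::arrange(as_tibble(object), .data$nes)
  d$set <- factor(d$set, levels = d$set)
  ggplot2::ggplot(d, ggplot2::aes(.data$nes, .data$set,
                                  fill = .data$fdr < 0.05)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Normalized enrichment score", y = NULL,
                  fill = "FDR < 0.05") +
    ggplot2::theme_minimal()
}

#' Write a GSEA result table to CSV
#'
#' Leading-edge gene lists are semicolon-joined.
#'
#' @param x A `gsea_result`.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_gsea <- function(x, path) {
  flat <- dplyr::mutate(as_tibble(x),
                        leading_edge = vapply(.data$leading_edge,
                                              paste, "", collapse = ";"))
  readr::write_csv(flat, path, progress = FALSE)
  invisible(x)
}
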