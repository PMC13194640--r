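#' Kaplan-Meier product-limit estimator
#'
#' @param time Positive follow-up times.
#' @param event Event indicator (1 = event, 0 = censored).
#' @return A `km_fit` tibble with one row per distinct observed time:
#'   `time`, `n_risk`, `n_event`, `n_censor`, `survival`. Survival starts at
#'   1 and is non-increasing; with no censoring it equals the empirical
#'   survival function.
#' @export
km_estimate <- function(time, event) {
  if (!length(time)) abort("empty cohort")
  if (any(time <= 0)) abort("times must be > 0")
  event <- as.integer(event)
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  ut <- unique(time)
  n <- length(time)
  tbl <- tibble(
    time = ut,
    n_risk = vapply(ut, function(t) sum(time >= t), 0L),
    n_event = vapply(ut, function(t) sum(time == t & event == 1L), 0L),
    n_censor = vapply(ut, function(t) sum(time == t & event == 0L), 0L)
  )
  tbl$survival <- cumprod(1 - tbl$n_event / tbl$n_risk)
  structure(tbl, class = c("km_fit", class(tibble())))
}

#' @describeIn km_estimate Step plot of the survival curve.
#' @param object A `km_fit` (optionally with a `group` column from
#'   [tidy.screen_fit] style tables).
#' @param ... Unused.
#' @method autoplot km_fit
#' @export
autoplot.km_fit <- function(object, ...) {
  d <- dplyr::bind_rows(tibble(time = 0, survival = 1), as_tibble(object))
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability") +
    ggplot2::theme_minimal()
}

#' Two-group log-rank test
#'
#' The one-degree-of-freedom observed-minus-expected statistic over the
#' pooled event times. Invariant to which group is called high or low.
#'
#' @param time,event Follow-up times and event indicators.
#' @param group Two-level grouping (logical or factor-like).
#' @return A one-row tibble: `chi2`, `df`, `p_value`, `observed_1`,
#'   `expected_1` (for the first group level).
#' @export
logrank_test <- function(time, event, group) {
  g <- as.factor(group)
  if (nlevels(g) != 2) abort("log-rank test needs exactly two groups")
  event <- as.integer(event)
  if (sum(event) == 0) abort("no events observed")
  is1 <- g == levels(g)[1]
  et <- sort(unique(time[event == 1L]))
  O <- E <- V <- 0
  for (t in et) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & is1)
    d <- sum(time == t & event == 1L)
    d1 <- sum(time == t & event == 1L & is1)
    e1 <- d * n1 / n
    O <- O + d1; E <- E + e1
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- if (V > 0) (O - E)^2 / V else 0
  tibble(chi2 = chi2, df = 1L,
         p_value = pchisq(chi2, 1L, lower.tail = FALSE),
         observed_1 = O, expected_1 = E)
}

# Efron partial-likelihood score/information for one binary covariate
# (x in {0, 1}; note x^2 = x so the second moment equals the first).
cox_binary_derivs <- function(beta, time, event, x) {
  eb <- exp(beta * x)
  et <- sort(unique(time[event == 1L]))
  U <- I <- 0
  for (t in et) {
    risk <- time >= t
    dead <- time == t & event == 1L
    d <- sum(dead)
    s0r <- sum(eb[risk]); s1r <- sum((eb * x)[risk])
    s0d <- sum(eb[dead]); s1d <- sum((eb * x)[dead])
    U <- U + sum(x[dead])
    for (l in seq_len(d) - 1) {
      s0 <- s0r - (l / d) * s0d
      s1 <- s1r - (l / d) * s1d
      U <- U - s1 / s0
      I <- I + s1 / s0 - (s1 / s0)^2
    }
  }
  list(U = U, I = I)
}

#' Hazard ratio from a single-binary-covariate proportional-hazards fit
#'
#' Newton-Raphson maximisation of the Cox partial likelihood with Efron
#' handling of tied event times, for the indicator high-versus-low group.
#' The 95% CI comes from the normal approximation on the log hazard ratio
#' using the observed information. With zero events in one group the
#' partial likelihood is monotone; the HR is reported as `Inf` (no events in
#' the low group) or 0 (none in the high group) with `finite = FALSE`.
#'
#' @param time,event Follow-up times and event indicators.
#' @param high Logical: TRUE for the high-expression group.
#' @return A one-row tibble: `hr`, `log_hr`, `se_log_hr`, `ci_low`,
#'   `ci_high`, `n_high`, `n_low`, `events_high`, `events_low`, `finite`.
#' @export
hazard_ratio <- function(time, event, high) {
  high <- as.logical(high)
  event <- as.integer(event)
  eh <- sum(event[high]); el <- sum(event[!high])
  base <- tibble(hr = NA_real_, log_hr = NA_real_, se_log_hr = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_,
                 n_high = sum(high), n_low = sum(!high),
                 events_high = eh, events_low = el, finite = FALSE)
  if (eh + el == 0) abort("no events observed")
  if (eh == 0 || el == 0) {
    base$hr <- if (eh == 0) 0 else Inf
    base$log_hr <- log(base$hr)
    return(base)
  }
  x <- as.numeric(high)
  beta <- 0
  for (it in 1:30) {
    d <- cox_binary_derivs(beta, time, event, x)
    if (d$I <= 0) break
    step <- d$U / d$I
    beta <- beta + step
    if (abs(step) < 1e-10) break
  }
  info <- cox_binary_derivs(beta, time, event, x)$I
  se <- 1 / sqrt(info)
  z <- qnorm(0.975)
  base$hr <- exp(beta); base$log_hr <- beta; base$se_log_hr <- se
  base$ci_low <- exp(beta - z * se); base$ci_high <- exp(beta + z * se)
  base$finite <- TRUE
  base
}

#' Dichotomise expression into high/low groups
#'
#' `median`: split at the median, ties going to the low group. `best_cutoff`:
#' scan candidate cutoffs at the 0.2-0.8 quantiles (0.05 steps) and pick the
#' one minimising the log-rank p value -- an exploratory choice whose scan is
#' attached so the multiplicity is visible.
#'
#' @param expression Numeric expression values (>= 4 subjects).
#' @param method `"median"` (default) or `"best_cutoff"`.
#' @param time,event Required for `best_cutoff`.
#' @return Logical vector (`TRUE` = high) with attributes `cutoff`, `method`
#'   and, for `best_cutoff`, `scan` (tibble of cutoffs and p values).
#' @export
dichotomize <- function(expression, method = c("median", "best_cutoff"),
                        time = NULL, event = NULL) {
  method <- match.arg(method)
  if (length(expression) < 4) abort("need >= 4 subjects to split")
  if (length(unique(expression)) == 1) {
    abort("all expression values equal; no split possible")
  }
  if (method == "median") {
    cut <- median(expression)
    high <- expression > cut
    if (!any(high) || all(high)) {
      # heavily tied at the median: fall back to the nearest splitting value
      cut <- max(expression[expression < max(expression)])
      high <- expression > cut
    }
    return(structure(high, cutoff = cut, method = "median"))
  }
  if (is.null(time) || is.null(event)) {
    abort("best_cutoff needs time and event")
  }
  qs <- quantile(expression, probs = seq(0.2, 0.8, by = 0.05), names = FALSE)
  qs <- unique(qs)
  scan <- purrr::map_dfr(qs, function(cut) {
    high <- expression > cut
    if (!any(high) || all(high)) return(tibble(cutoff = cut, p_value = NA_real_))
    tibble(cutoff = cut, p_value = logrank_test(time, event, high)$p_value)
  })
  scan <- scan[!is.na(scan$p_value), ]
  if (!nrow(scan)) abort("no admissible cutoff in the 0.2-0.8 quantile band")
  best <- scan$cutoff[which.min(scan$p_value)]
  structure(expression > best, cutoff = best, method = "best_cutoff", scan = scan)
}

#' Multi-gene survival screen
#'
#' For every gene column, dichotomises expression, estimates the
#' high-versus-low hazard ratio and log-rank p value, and ranks the table by
#' HR descending -- the screen logic behind "how many family members
#' associate with worse outcome". Raw p values drive the significance
#' summary; a BH-adjusted column is also emitted.
#'
#' @param cohort Tibble with columns `time`, `event` and one numeric column
#'   per gene (see [simulate_screen_cohort()]).
#' @param genes Gene columns to screen; default all columns other than
#'   `subject_id`, `time`, `event`.
#' @param method Dichotomisation method, see [dichotomize()].
#' @return A `screen_table` tibble ranked by `hr` descending: `gene`, `hr`,
#'   `ci_low`, `ci_high`, `logrank_p`, `p_adj`, `n_high`, `n_low`, `cutoff`.
#' @export
screen_genes <- function(cohort, genes = NULL,
                         method = c("median", "best_cutoff")) {
  method <- match.arg(method)
  genes <- genes %||% setdiff(names(cohort), c("subject_id", "time", "event"))
  rows <- purrr::map_dfr(genes, function(g) {
    high <- dichotomize(cohort[[g]], method, time = cohort$time,
                        event = cohort$event)
    fit <- hazard_ratio(cohort$time, cohort$event, high)
    tibble(gene = g, hr = fit$hr, ci_low = fit$ci_low, ci_high = fit$ci_high,
           logrank_p = logrank_test(cohort$time, cohort$event, high)$p_value,
           n_high = fit$n_high, n_low = fit$n_low,
           cutoff = attr(high, "cutoff"))
  })
  if (!nrow(rows)) {
    rows <- tibble(gene = character(), hr = double(), ci_low = double(),
                   ci_high = double(), logrank_p = double(), p_adj = double(),
                   n_high = integer(), n_low = integer(), cutoff = double())
    return(structure(rows, method = method,
                     class = c("screen_table", class(tibble()))))
  }
  rows$p_adj <- p.adjust(rows$logrank_p, method = "BH")
  rows <- dplyr::arrange(rows, dplyr::desc(.data$hr))
  rows <- rows[, c("gene", "hr", "ci_low", "ci_high", "logrank_p", "p_adj",
                   "n_high", "n_low", "cutoff")]
  structure(rows, method = method, class = c("screen_table", class(tibble())))
}

#' @describeIn screen_genes Screen summary: genes tested, HR > 1 count, and
#'   HR > 1 with raw log-rank p < 0.05.
#' @param x A `screen_table`.
#' @param ... Unused.
#' @method glance screen_table
#' @export
glance.screen_table <- function(x, ...) {
  tibble(n_genes = nrow(x),
         n_hr_gt1 = sum(x$hr > 1, na.rm = TRUE),
         n_hr_gt1_sig = sum(x$hr > 1 & x$logrank_p < 0.05, na.rm = TRUE))
}

#' @describeIn screen_genes Forest-style plot of HR estimates with 95% CIs,
#'   ranked by HR.
#' @param object A `screen_table`.
#' @method autoplot screen_table
#' @export
autoplot.screen_table <- function(object, ...) {
  d <- as_tibble(object)
  d$gene <- factor(d$gene, levels = rev(d$gene))
  ggplot2::ggplot(d, ggplot2::aes(.data$hr, .data$gene)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high), height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Hazard ratio (high vs low)", y = NULL) +
    ggplot2::theme_minimal()
}
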