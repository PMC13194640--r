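# scoped RNG: seeds a fresh stream for the call, restores caller state on exit
local_seed <- function(seed, env = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  do.call(on.exit, list(quote({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }), add = TRUE), envir = env)
  assign("old", old, envir = env)
  set.seed(as.integer(seed))
  invisible(seed)
}

#' Configuration for the negative-binomial count simulator
#'
#' Describes a two-factor (cell line x knockdown condition) bulk RNA-seq
#' experiment. The defaults mirror the design the pipeline targets: two cell
#' lines with distinct baselines, three conditions per line (a non-targeting
#' control `NT` and two knockdown hairpins `KD1`, `KD2`), and two biological
#' replicates per condition, i.e. twelve samples in total.
#'
#' Counts for gene g in sample s are drawn from a negative binomial with mean
#' `2^(base_g + line_shift_gl + effect_gl[KD]) * lib_s / mean(lib range)` and
#' size (dispersion) `k`, so `Var = m + m^2/k`. Library sizes are drawn
#' uniformly from `library_size_range`, which makes CPM normalisation
#' non-trivial downstream.
#'
#' @param n_genes Number of genes.
#' @param line_labels Character vector of cell-line labels (default two lines).
#' @param conditions Ordered condition labels; the first is the control, all
#'   later ones receive the planted knockdown effects.
#' @param n_reps Biological replicates per condition per line.
#' @param baseline_log_mean_range Length-2 range of per-gene baseline log2 mean
#'   counts at the reference depth. The default `[4, 11]` (16 to 2048 expected
#'   counts) spans the detectably expressed stratum, where group fold changes
#'   are estimable from a handful of replicates.
#' @param line_effect_sd SD of the per-gene per-line baseline shift (log2
#'   units); this is what the cell-line-adjusted PCA removes.
#' @param dispersion Negative-binomial size parameter, scalar or per-gene.
#' @param library_size_range Length-2 positive range; per-sample depth factors
#'   are drawn uniformly from it.
#' @param program Planted effect table from [plant_program()], or `NULL` for
#'   the default program (concordant up/down genes, line-private genes,
#'   discordant genes, non-coding genes, nulls).
#' @param seed Integer seed; the one RNG stream of the simulation.
#' @return A `sim_count_config` list, validated.
#' @export
sim_count_config <- function(n_genes = 2000,
                             line_labels = c("LINE_A", "LINE_B"),
                             conditions = c("NT", "KD1", "KD2"),
                             n_reps = 2,
                             baseline_log_mean_range = c(4, 11),
                             line_effect_sd = 1,
                             dispersion = 10,
                             library_size_range = c(5e5, 1.5e6),
                             program = NULL,
                             seed = 1) {
  cfg <- list(n_genes = as.integer(n_genes), line_labels = line_labels,
              conditions = conditions, n_reps = as.integer(n_reps),
              baseline_log_mean_range = baseline_log_mean_range,
              line_effect_sd = line_effect_sd, dispersion = dispersion,
              library_size_range = library_size_range,
              program = program, seed = as.integer(seed))
  class(cfg) <- "sim_count_config"
  validate_sim_count_config(cfg)
}

validate_sim_count_config <- function(cfg) {
  if (cfg$n_genes < 1) abort("n_genes must be positive", class = "kdconcord_config_error")
  if (length(cfg$line_labels) < 1 || anyDuplicated(cfg$line_labels)) {
    abort("line_labels must be non-empty and unique", class = "kdconcord_config_error")
  }
  if (length(cfg$conditions) < 2 || anyDuplicated(cfg$conditions)) {
    abort("need >= 2 unique conditions (control first)", class = "kdconcord_config_error")
  }
  if (cfg$n_reps < 1) abort("n_reps must be positive", class = "kdconcord_config_error")
  if (any(cfg$dispersion <= 0)) abort("dispersion must be > 0", class = "kdconcord_config_error")
  if (!length(cfg$dispersion) %in% c(1L, cfg$n_genes)) {
    abort("dispersion must be scalar or one value per gene", class = "kdconcord_config_error")
  }
  if (length(cfg$library_size_range) != 2 || any(cfg$library_size_range <= 0) ||
      diff(cfg$library_size_range) < 0) {
    abort("library_size_range must be a positive, non-decreasing interval",
          class = "kdconcord_config_error")
  }
  if (length(cfg$baseline_log_mean_range) != 2 ||
      diff(cfg$baseline_log_mean_range) < 0) {
    abort("baseline_log_mean_range must be a non-decreasing interval",
          class = "kdconcord_config_error")
  }
  if (!is.null(cfg$program)) {
    miss <- setdiff(cfg$line_labels, names(cfg$program))
    if (length(miss)) {
      abort(paste0("program lacks effect columns for lines: ",
                   paste(miss, collapse = ", ")), class = "kdconcord_config_error")
    }
    if (any(duplicated(cfg$program$gene_id))) {
      abort("program gene ids must be unique", class = "kdconcord_config_error")
    }
  }
  cfg
}

sim_gene_ids <- function(n) sprintf("SIMG%05d", seq_len(n))
sim_symbols <- function(n) sprintf("G%05d", seq_len(n))

#' Build a planted knockdown program
#'
#' Lays out which simulated genes carry which log2 fold-change effect in which
#' cell line. Genes are assigned, in id order: concordant up, concordant down,
#' line-private (effect in one line only, alternating), discordant (opposite
#' signs in the two lines), then nulls. A slice of the null genes is labelled
#' with a non-coding biotype so the protein-coding filter has work to do.
#'
#' A gene is "planted concordant" when its effect magnitude is at least 1 in
#' every line with a common sign -- exactly the structure the core-signature
#' filter is designed to detect.
#'
#' @param n_genes Total genes in the simulation.
#' @param line_labels Cell-line labels, matching the count config.
#' @param n_up,n_down Numbers of concordant up-/down-regulated genes.
#' @param effect Absolute log2 fold change of planted concordant genes.
#' @param n_private Line-private genes (effect `effect` in one line, 0 in the
#'   others).
#' @param n_discordant Genes with effect `+effect` in the first line and
#'   `-effect` in the second (requires >= 2 lines when nonzero).
#' @param n_noncoding Null genes labelled `lncRNA` instead of `protein_coding`.
#' @return A tibble with columns `gene_id`, `biotype`, `role`, and one effect
#'   column per cell line.
#' @export
plant_program <- function(n_genes, line_labels = c("LINE_A", "LINE_B"),
                          n_up = 50, n_down = 50, effect = 2,
                          n_private = 50, n_discordant = 10,
                          n_noncoding = 200) {
  n_planted <- n_up + n_down + n_private + n_discordant
  if (n_planted + n_noncoding > n_genes) {
    abort("planted + non-coding genes exceed n_genes", class = "kdconcord_config_error")
  }
  if (n_discordant > 0 && length(line_labels) < 2) {
    abort("discordant genes need >= 2 lines", class = "kdconcord_config_error")
  }
  ids <- sim_gene_ids(n_genes)
  nl <- length(line_labels)
  eff <- matrix(0, n_genes, nl, dimnames = list(NULL, line_labels))
  role <- rep("null", n_genes)
  at <- 0L
  take <- function(n) seq_len(n) + at
  if (n_up > 0) {
    eff[take(n_up), ] <- effect; role[take(n_up)] <- "concordant_up"; at <- at + n_up
  }
  if (n_down > 0) {
    eff[take(n_down), ] <- -effect; role[take(n_down)] <- "concordant_down"; at <- at + n_down
  }
  if (n_private > 0) {
    idx <- take(n_private)
    for (i in seq_along(idx)) eff[idx[i], 1 + (i - 1) %% nl] <- effect
    role[idx] <- "line_private"; at <- at + n_private
  }
  if (n_discordant > 0) {
    idx <- take(n_discordant)
    eff[idx, 1] <- effect
    eff[idx, 2] <- -effect
    role[idx] <- "discordant"; at <- at + n_discordant
  }
  biotype <- rep("protein_coding", n_genes)
  if (n_noncoding > 0) {
    nc <- which(role == "null")[seq_len(n_noncoding)]
    biotype[nc] <- "lncRNA"
  }
  dplyr::bind_cols(tibble(gene_id = ids, biotype = biotype, role = role),
                   as_tibble(eff))
}

#' Simulate a knockdown RNA-seq count matrix
#'
#' Draws negative-binomial counts for the factorial design described by a
#' [sim_count_config()]. Baseline log2 means are uniform over the configured
#' range; each gene additionally receives an independent Gaussian per-line
#' baseline shift (the "cell-line effect"); planted knockdown effects act
#' multiplicatively on the mean (`2^effect`) in every non-control condition;
#' per-sample depth scales all means. The same seed always reproduces the
#' same matrix.
#'
#' @param config A [sim_count_config()].
#' @return A [count_matrix()] whose gene table carries the program's `role`
#'   and per-line `effect_*` columns alongside `gene_id`, `symbol`, `biotype`.
#' @export
simulate_counts <- function(config) {
  config <- validate_sim_count_config(config)
  local_seed(config$seed)
  ng <- config$n_genes
  lines <- config$line_labels
  conds <- config$conditions
  program <- config$program %||%
    plant_program(ng, lines,
                  n_up = min(50L, ng %/% 8L), n_down = min(50L, ng %/% 8L),
                  n_private = min(50L, ng %/% 8L),
                  n_discordant = min(10L, ng %/% 20L),
                  n_noncoding = min(200L, ng %/% 4L))
  if (nrow(program) != ng || !identical(program$gene_id, sim_gene_ids(ng))) {
    abort("program must cover exactly the simulated gene ids, in order",
          class = "kdconcord_config_error")
  }

  samples <- tidyr::expand_grid(cell_line = lines, condition = conds,
                                replicate = seq_len(config$n_reps)) |>
    dplyr::mutate(
      shRNA = ifelse(.data$condition == conds[1], "shNT",
                     paste0("sh", match(.data$condition, conds) - 1L)),
      sample_id = paste(.data$cell_line, .data$condition, .data$replicate, sep = "_")
    ) |>
    dplyr::select("sample_id", "cell_line", "condition", "shRNA", "replicate")

  base_log2 <- runif(ng, config$baseline_log_mean_range[1],
                     config$baseline_log_mean_range[2])
  line_shift <- matrix(rnorm(ng * length(lines), 0, config$line_effect_sd),
                       ng, length(lines), dimnames = list(NULL, lines))
  eff <- as.matrix(program[, lines, drop = FALSE])
  lib <- runif(nrow(samples), config$library_size_range[1],
               config$library_size_range[2])
  depth <- lib / mean(config$library_size_range)
  size <- rep_len(config$dispersion, ng)

  counts <- matrix(0L, ng, nrow(samples))
  for (s in seq_len(nrow(samples))) {
    li <- match(samples$cell_line[s], lines)
    kd <- samples$condition[s] != conds[1]
    lmu <- base_log2 + line_shift[, li] + if (kd) eff[, li] else 0
    mu <- 2^lmu * depth[s]
    counts[, s] <- rnbinom(ng, mu = mu, size = size)
  }

  genes <- tibble(gene_id = program$gene_id, symbol = sim_symbols(ng),
                  biotype = program$biotype, role = program$role)
  for (l in lines) genes[[paste0("effect_", l)]] <- program[[l]]
  count_matrix(counts, genes, samples)
}

#' Configuration for the exponential survival-cohort simulator
#'
#' One continuous expression covariate with a log-linear proportional effect
#' on an exponential baseline hazard, `h(t|x) = h0 * exp(beta * x)`, with
#' independent exponential censoring.
#'
#' @param n_subjects Cohort size.
#' @param baseline_hazard Exponential event rate `h0` (per month), > 0.
#' @param log_hr_per_unit `beta`: log hazard ratio per unit of expression.
#' @param censor_rate Rate of the independent exponential censoring process,
#'   > 0 (use a tiny rate for near-complete follow-up).
#' @param expression_mean,expression_sd Normal distribution of the simulated
#'   expression covariate.
#' @param seed Integer seed.
#' @return A validated `sim_survival_config` list.
#' @export
sim_survival_config <- function(n_subjects = 500,
                                baseline_hazard = 0.02,
                                log_hr_per_unit = 0,
                                censor_rate = 0.01,
                                expression_mean = 0,
                                expression_sd = 1,
                                seed = 1) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              baseline_hazard = baseline_hazard,
              log_hr_per_unit = log_hr_per_unit,
              censor_rate = censor_rate,
              expression_mean = expression_mean,
              expression_sd = expression_sd,
              seed = as.integer(seed))
  class(cfg) <- "sim_survival_config"
  validate_sim_survival_config(cfg)
}

validate_sim_survival_config <- function(cfg) {
  if (cfg$n_subjects < 1) abort("n_subjects must be positive", class = "kdconcord_config_error")
  if (cfg$baseline_hazard <= 0) abort("baseline_hazard must be > 0", class = "kdconcord_config_error")
  if (cfg$censor_rate <= 0) abort("censor_rate must be > 0", class = "kdconcord_config_error")
  if (cfg$expression_sd < 0) abort("expression_sd must be >= 0", class = "kdconcord_config_error")
  cfg
}

#' Simulate a survival cohort with one expression covariate
#'
#' @param config A [sim_survival_config()].
#' @return A tibble with columns `subject_id`, `time` (months, > 0), `event`
#'   (1 = event observed, 0 = censored) and `expression`. Observed time is the
#'   minimum of the latent event and censoring times.
#' @export
simulate_survival <- function(config) {
  config <- validate_sim_survival_config(config)
  local_seed(config$seed)
  n <- config$n_subjects
  x <- rnorm(n, config$expression_mean, config$expression_sd)
  t_event <- rexp(n, rate = config$baseline_hazard * exp(config$log_hr_per_unit * x))
  t_cens <- rexp(n, rate = config$censor_rate)
  tibble(subject_id = sprintf("S%05d", seq_len(n)),
         time = pmin(t_event, t_cens),
         event = as.integer(t_event <= t_cens),
         expression = x)
}

#' Simulate a multi-gene screening cohort
#'
#' Builds a cohort for [screen_genes()]: survival times depend (through the
#' proportional-hazards model of [sim_survival_config()]) on one planted
#' gene's expression; every other gene is independent standard-normal noise.
#'
#' @param config A [sim_survival_config()] driving the planted gene and the
#'   outcome.
#' @param n_null_genes Number of additional no-effect genes.
#' @param planted_gene Column name for the planted gene (`NULL` for a pure
#'   null cohort with `n_null_genes` genes only).
#' @return A tibble with `subject_id`, `time`, `event` and one expression
#'   column per gene (`NULLG0001`, ... plus the planted gene).
#' @export
simulate_screen_cohort <- function(config, n_null_genes = 50,
                                   planted_gene = "PLANTED") {
  cohort <- simulate_survival(config)
  local_seed(config$seed + 1L)
  out <- dplyr::select(cohort, "subject_id", "time", "event")
  if (!is.null(planted_gene)) out[[planted_gene]] <- cohort$expression
  if (n_null_genes > 0) {
    nulls <- matrix(rnorm(nrow(out) * n_null_genes), nrow(out), n_null_genes,
                    dimnames = list(NULL, sprintf("NULLG%04d", seq_len(n_null_genes))))
    out <- dplyr::bind_cols(out, as_tibble(nulls))
  }
  out
}
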