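# Fixture builders and independent brute-force oracles used across tests.

# count_matrix from a bare matrix; metadata derived from the label vectors
toy_count_matrix <- function(mat, cell_line, condition,
                             biotype = rep("protein_coding", nrow(mat))) {
  ng <- nrow(mat)
  genes <- tibble::tibble(gene_id = sprintf("TG%03d", seq_len(ng)),
                          symbol = sprintf("SYM%03d", seq_len(ng)),
                          biotype = biotype)
  reps <- stats::ave(seq_along(cell_line),
                     paste(cell_line, condition), FUN = seq_along)
  samples <- tibble::tibble(
    sample_id = paste(cell_line, condition, reps, sep = "_"),
    cell_line = cell_line, condition = condition,
    shRNA = ifelse(condition == "NT", "shNT", paste0("sh", condition)),
    replicate = as.integer(reps))
  count_matrix(mat, genes, samples)
}

# expr_matrix straight from log2-CPM-like values (bypasses normalisation)
toy_expr <- function(vals, cell_line, condition) {
  cnt <- matrix(1L, nrow(vals), ncol(vals))
  cm <- toy_count_matrix(cnt, cell_line, condition)
  e <- log2_cpm(cm)
  e$values[] <- vals
  rownames(e$values) <- cm$genes$gene_id
  colnames(e$values) <- cm$samples$sample_id
  e
}

# literal O(N) walk of the GSEA running sum, independent of the package's
# position-based shortcut
brute_es <- function(scores_desc, hit, w = 1) {
  N <- length(scores_desc)
  n <- sum(hit)
  wt <- abs(scores_desc)^w
  tot <- sum(wt[hit])
  rs <- 0
  walk <- numeric(N)
  for (i in seq_len(N)) {
    rs <- rs + if (hit[i]) wt[i] / tot else -1 / (N - n)
    walk[i] <- rs
  }
  walk[which.max(abs(walk))]
}

# naive UPGMA on a Euclidean distance matrix; returns sorted merge heights
brute_upgma_heights <- function(mat) {
  d <- as.matrix(dist(mat))
  active <- as.list(seq_len(nrow(mat)))
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(NA, NA); bd <- Inf
    for (i in seq_along(active)) {
      for (j in seq_len(i - 1)) {
        dd <- mean(d[active[[i]], active[[j]], drop = FALSE])
        if (dd < bd) { bd <- dd; best <- c(j, i) }
      }
    }
    heights <- c(heights, bd)
    merged <- c(active[[best[1]]], active[[best[2]]])
    active <- c(active[-best], list(merged))
  }
  sort(heights)
}

# small simulated experiment shared by several tests
sim_small <- function(seed = 42, n_genes = 600, n_reps = 2, effect = 2) {
  k <- n_genes / 600
  simulate_counts(sim_count_config(
    n_genes = n_genes, n_reps = n_reps, seed = seed,
    program = plant_program(n_genes,
                            n_up = max(1, round(30 * k)),
                            n_down = max(1, round(30 * k)),
                            effect = effect,
                            n_private = max(2, round(20 * k)),
                            n_discordant = max(1, round(10 * k)),
                            n_noncoding = max(1, round(60 * k)))))
}
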