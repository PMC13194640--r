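test_that("CPM rescales each sample to a million and flags empty samples", {
  cm <- toy_count_matrix(matrix(c(90L, 10L), 2, 1), "L1", "NT")
  expect_equal(unname(cpm(cm)$values[, 1]), c(9e5, 1e5))
  # all-zero gene stays all zero
  cm2 <- toy_count_matrix(rbind(c(5L, 5L), c(0L, 0L)),
                          c("L1", "L1"), c("NT", "NT"))
  expect_equal(unname(cpm(cm2)$values[2, ]), c(0, 0))
  # property: random matrix, every column sums to 1e6
  set.seed(1)
  mat <- matrix(rpois(500 * 12, 40), 500, 12)
  cm3 <- toy_count_matrix(mat, rep(c("L1", "L2"), each = 6),
                          rep(c("NT", "KD1", "KD2"), 4))
  expect_equal(unname(colSums(cpm(cm3)$values)), rep(1e6, 12), tolerance = 1e-9)
  # zero library size errors with the sample named
  cm4 <- toy_count_matrix(matrix(c(1L, 0L), 1), c("L1", "L1"), c("NT", "KD1"))
  expect_error(cpm(cm4), cm4$samples$sample_id[2])
})

test_that("log2(CPM+1) maps 0, 1, 3 CPM to 0, 1, 2 and is monotone", {
  cm <- toy_count_matrix(matrix(c(0L, 1L, 3L, 999996L), 4, 1), "L1", "NT")
  e <- log2_cpm(cm)
  expect_equal(unname(e$values[1:3, 1]), c(0, 1, 2))
  expect_true(all(diff(e$values[, 1]) >= 0))  # monotone in counts
  expect_true(all((e$values == 0) == (cm$counts == 0)))
})

test_that("protein-coding restriction keeps order and warns when empty", {
  mat <- matrix(1L, 5, 2)
  cm <- toy_count_matrix(mat, c("L1", "L1"), c("NT", "NT"),
                         biotype = c("protein_coding", "lncRNA",
                                     "protein_coding", "pseudogene",
                                     "protein_coding"))
  expect_message(f <- filter_protein_coding(cm), "3 of 5")
  expect_equal(f$genes$gene_id, cm$genes$gene_id[c(1, 3, 5)])
  cm_none <- toy_count_matrix(mat, c("L1", "L1"), c("NT", "NT"),
                              biotype = rep("lncRNA", 5))
  expect_warning(suppressMessages(filter_protein_coding(cm_none)),
                 "no protein_coding")
})

test_that("PCA matches an eigen-decomposition oracle and reconstructs", {
  set.seed(2)
  e <- toy_expr(matrix(rnorm(200 * 12, 6, 2), 200, 12),
                rep(c("L1", "L2"), each = 6), rep(c("NT", "KD1", "KD2"), 4))
  p <- pca_global(e)
  centered <- e$values - rowMeans(e$values)
  # oracle: eigen-decomposition of the sample covariance across genes
  ev <- eigen(crossprod(centered), symmetric = TRUE)
  k <- length(p$var_explained)
  scores <- as.matrix(p$scores[, paste0("PC", 1:k)])
  oracle_scores <- ev$vectors[, 1:k] %*% diag(sqrt(ev$values[1:k]))
  for (j in 1:k) {
    expect_equal(abs(scores[, j]), abs(oracle_scores[, j]), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  expect_equal(unname(ev$values[1:k] / sum(ev$values)),
               unname(p$var_explained), tolerance = 1e-10)
  # reconstruction from all components
  expect_equal(p$loadings %*% t(scores), centered, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("duplicated samples share scores and 1-D variation loads on PC1", {
  vals <- matrix(rnorm(50 * 3, 5), 50, 3)
  e <- toy_expr(vals[, c(1, 1, 2, 2, 3, 3)],
                rep("L1", 6), rep(c("NT", "KD1", "KD2"), each = 2))
  p <- pca_global(e)
  sc <- as.matrix(p$scores[, grep("^PC", names(p$scores))])
  expect_equal(sc[1, ], sc[2, ], tolerance = 1e-10)
  expect_equal(sc[3, ], sc[4, ], tolerance = 1e-10)
  # toy with variance along a single direction
  e2 <- toy_expr(matrix(c(0, 2, 0, 0), 2, 2), c("L1", "L1"), c("NT", "KD1"))
  p2 <- pca_global(e2)
  expect_equal(unname(p2$var_explained[1]), 1)
})

test_that("line adjustment zeroes per-line gene means and ignores line offsets", {
  cm <- sim_small(seed = 3, n_genes = 300)
  e <- suppressMessages(filter_protein_coding(log2_cpm(cm)))
  pa <- pca_line_adjusted(e)
  # shifting one whole line leaves the adjusted analysis unchanged
  e2 <- e
  e2$values[, e$samples$cell_line == "LINE_A"] <-
    e2$values[, e$samples$cell_line == "LINE_A"] + 5
  pa2 <- pca_line_adjusted(e2)
  expect_equal(pa$var_explained, pa2$var_explained, tolerance = 1e-10)
  expect_equal(as.data.frame(pa$scores), as.data.frame(pa2$scores),
               tolerance = 1e-8)
  # per-line means exactly zero after adjustment
  adj <- e$values
  for (l in unique(e$samples$cell_line)) {
    idx <- e$samples$cell_line == l
    adj[, idx] <- adj[, idx] - rowMeans(adj[, idx, drop = FALSE])
    expect_lt(max(abs(rowMeans(adj[, idx, drop = FALSE]))), 1e-12)
  }
  # a line with a single sample cannot be adjusted
  e1 <- e
  keep <- c(which(e$samples$cell_line == "LINE_A"),
            which(e$samples$cell_line == "LINE_B")[1])
  e1$values <- e1$values[, keep]
  e1$samples <- e1$samples[keep, ]
  expect_error(pca_line_adjusted(e1), "single sample")
})

test_that("adjustment flips the dominant structure from line to condition", {
  prog <- plant_program(500, n_up = 50, n_down = 50, effect = 3,
                        n_private = 0, n_discordant = 0, n_noncoding = 0)
  cm <- simulate_counts(sim_count_config(n_genes = 500, line_effect_sd = 3,
                                         program = prog, seed = 8))
  e <- suppressMessages(filter_protein_coding(log2_cpm(cm)))
  sil <- function(p, label) {
    sc <- as.matrix(p$scores[, c("PC1", "PC2")])
    mean(cluster::silhouette(as.integer(factor(label)), dist(sc))[, 3])
  }
  kd <- ifelse(e$samples$condition == "NT", "NT", "KD")
  pg <- pca_global(e); pa <- pca_line_adjusted(e)
  expect_gt(sil(pg, e$samples$cell_line), sil(pg, kd))      # unadjusted: line wins
  expect_gt(sil(pa, kd), sil(pa, e$samples$cell_line))      # adjusted: condition wins
})
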