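make_de <- function(lfc, line = "L1") {
  n <- length(lfc)
  structure(tibble::tibble(
    gene_id = sprintf("g%03d", seq_len(n)), symbol = sprintf("s%03d", seq_len(n)),
    mean_cpm_nt = 1, mean_cpm_kd = 2, log2fc = lfc, t_stat = 0, df = 2,
    p_value = 0.5, rank_score = 0, cell_line = line),
    class = c("de_table", class(tibble::tibble())))
}

test_that("concordance filter applies inclusive thresholds in both lines", {
  de1 <- make_de(c(1.2, 1.2, 0.9, 1.0, -1.4, 2.0), "L1")
  de2 <- make_de(c(1.5, -1.5, 1.5, 1.0, -1.1, 0.2), "L2")
  sig <- suppressMessages(core_signature(de1, de2))
  expect_setequal(sig$gene_id, c("g001", "g004", "g005"))
  expect_equal(sig$direction[sig$gene_id == "g001"], "up")       # (1.2, 1.5)
  expect_equal(sig$direction[sig$gene_id == "g005"], "down")
  expect_false("g002" %in% sig$gene_id)   # discordant
  expect_false("g003" %in% sig$gene_id)   # below threshold in one line
  expect_true("g004" %in% sig$gene_id)    # boundary (1.0, 1.0) included
})

test_that("signature is symmetric in its inputs and shrinks monotonically", {
  set.seed(11)
  de1 <- make_de(rnorm(200, 0, 1.2), "L1")
  de2 <- make_de(rnorm(200, 0, 1.2), "L2")
  s12 <- suppressMessages(core_signature(de1, de2))
  s21 <- suppressMessages(core_signature(de2, de1))
  expect_setequal(s12$gene_id, s21$gene_id)
  for (thr in c(0.5, 1, 1.5, 2)) {
    lo <- suppressMessages(core_signature(de1, de2, thr))
    hi <- suppressMessages(core_signature(de1, de2, thr + 0.5))
    expect_true(all(hi$gene_id %in% lo$gene_id))
  }
})

test_that("planted concordant genes are kept, discordant genes never", {
  cm <- sim_small(seed = 12, n_genes = 800, effect = 3)
  e <- suppressMessages(filter_protein_coding(log2_cpm(cm)))
  sig <- suppressMessages(core_signature(de_table(e, "LINE_A"),
                                         de_table(e, "LINE_B")))
  disc <- cm$genes$gene_id[cm$genes$role == "discordant"]
  expect_length(intersect(disc, sig$gene_id), 0)
  conc <- cm$genes$gene_id[cm$genes$role %in% c("concordant_up", "concordant_down")]
  expect_gt(mean(conc %in% sig$gene_id), 0.9)
})

test_that("row z-scores have mean 0 and sample SD 1; constant rows zero", {
  z <- zscore_rows(matrix(c(1, 2, 3), 1))
  expect_equal(unname(z$values[1, ]), c(-1, 0, 1))
  expect_warning(zc <- zscore_rows(rbind(c(2, 2, 2), c(1, 5, 6))), "constant")
  expect_equal(unname(zc$values[1, ]), c(0, 0, 0))
  set.seed(13)
  m <- matrix(rnorm(50 * 8), 50, 8)
  zz <- zscore_rows(m)$values
  expect_equal(unname(rowMeans(zz)), rep(0, 50), tolerance = 1e-12)
  expect_equal(unname(apply(zz, 1, sd)), rep(1, 50), tolerance = 1e-12)
})

test_that("average-linkage ordering merges near rows first and matches a brute-force oracle", {
  m <- rbind(a = c(0, 0), b = c(10, 0), c = c(0.001, 0), d = c(30, 30))
  ord <- cluster_gene_order(m)
  expect_equal(abs(diff(match(c(1, 3), ord))), 1)  # identical-ish pair adjacent
  # 3 rows with pairwise distances 1, 5, ~5: distance-1 pair adjacent
  m3 <- rbind(c(0, 0), c(1, 0), c(5, 0.4))
  expect_equal(abs(diff(match(c(1, 2), cluster_gene_order(m3)))), 1)
  # merge heights equal a naive UPGMA implementation
  set.seed(14)
  m20 <- matrix(rnorm(20 * 6), 20, 6)
  h <- hclust(dist(m20), method = "average")
  expect_equal(sort(h$height), brute_upgma_heights(m20), tolerance = 1e-10)
})

test_that("module matrices average replicates within condition then z-score", {
  vals <- rbind(c(4, 6, 1, 3, 2, 2, 10, 10, 10, 10, 10, 10),
                rep(5, 12))
  e <- toy_expr(vals, rep(c("LA", "LB"), each = 6),
                rep(rep(c("NT", "KD1", "KD2"), each = 2), 2))
  expect_warning(hm <- module_condition_means(e, c("SYM001", "SYM002")),
                 "constant")
  expect_equal(colnames(hm$values),
               c("LA NT", "LA KD1", "LA KD2", "LB NT", "LB KD1", "LB KD2"))
  # condition means before z-scoring: 5, 2, 2, 10, 10, 10 for gene 1
  means <- c(5, 2, 2, 10, 10, 10)
  expect_equal(unname(hm$values[1, ]), (means - mean(means)) / sd(means))
  expect_equal(unname(hm$values[2, ]), rep(0, 6))  # flat gene -> zero row
})

test_that("planted up-modules show positive KD and negative NT condition scores", {
  cm <- sim_small(seed = 15, n_genes = 500, effect = 3)
  e <- suppressMessages(filter_protein_coding(log2_cpm(cm)))
  up <- head(cm$genes$symbol[cm$genes$role == "concordant_up"], 7)
  hm <- module_condition_means(e, up)
  nt_cols <- grepl(" NT$", colnames(hm$values))
  expect_true(all(rowMeans(hm$values[, !nt_cols]) > 0))
  expect_true(all(rowMeans(hm$values[, nt_cols]) < 0))
})

test_that("set intersection counts match brute force", {
  de1 <- make_de(c(2, 2, -2, 2, 0), "L1")
  de2 <- make_de(c(2, 2, -2, 2, 0), "L2")
  sig <- suppressMessages(core_signature(de1, de2))
  sets <- merge_gene_sets(
    kdconcord:::new_gene_set_collection(tibble::tibble(
      set = c("disjoint", "all", "partial"),
      description = "",
      genes = list(c("zzz"), sig$symbol, c("s001", "s003", "nope")))))
  ov <- intersect_with_sets(sig, sets)
  expect_equal(ov$n_overlap, c(0L, nrow(sig), 2L))
  expect_equal(ov$members[[3]]$direction,
               sig$direction[match(c("s001", "s003"), sig$symbol)])
})

test_that("signature heatmaps carry z-scored rows in clustered order", {
  cm <- sim_small(seed = 16, n_genes = 400, effect = 3)
  e <- suppressMessages(filter_protein_coding(log2_cpm(cm)))
  sig <- suppressMessages(core_signature(de_table(e, "LINE_A"),
                                         de_table(e, "LINE_B")))
  hm <- signature_heatmap(e, sig)
  expect_equal(nrow(hm$values), nrow(sig))
  expect_setequal(hm$row_order, seq_len(nrow(sig)))
  expect_equal(unname(rowMeans(hm$values)), rep(0, nrow(sig)), tolerance = 1e-12)
})
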