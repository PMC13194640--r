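rl <- function(scores, symbols = sprintf("g%03d", seq_along(scores))) {
  ranked_list(tibble::tibble(symbol = symbols, score = scores))
}

test_that("extreme single-member sets reach the ES bounds", {
  r <- rl(seq(10, 1))                       # strictly positive, descending
  top <- enrichment_score(r, r$symbol[1])
  expect_equal(top$es, 1)                   # lone member ranked first
  bottom <- enrichment_score(r, r$symbol[10])
  # hand-run: nine misses of -1/9 reach -1 just before the final hit
  expect_equal(bottom$es, -1)
  expect_equal(bottom$leading_edge, r$symbol[10])
})

test_that("the running sum matches a brute-force walk and fgsea", {
  set.seed(21)
  for (i in 1:10) {
    scores <- sort(rnorm(100), decreasing = TRUE)
    r <- rl(scores)
    members <- sample(r$symbol, 10)
    es <- enrichment_score(r, members)
    expect_equal(es$es, brute_es(scores, r$symbol %in% members),
                 tolerance = 1e-12)
    fg <- fgsea::calcGseaStat(stats = setNames(scores, r$symbol),
                              selectedStats = which(r$symbol %in% members),
                              gseaParam = 1)
    expect_equal(es$es, fg, tolerance = 1e-12)
  }
})

test_that("ES is antisymmetric under score negation and scale invariant", {
  set.seed(22)
  scores <- sort(rnorm(80), decreasing = TRUE)
  syms <- sprintf("g%03d", 1:80)
  members <- sample(syms, 12)
  es_pos <- enrichment_score(rl(scores, syms), members)$es
  neg <- ranked_list(tibble::tibble(symbol = syms, score = -scores))
  es_neg <- enrichment_score(neg, members)$es
  expect_equal(es_pos, -es_neg, tolerance = 1e-12)
  es_scaled <- enrichment_score(rl(scores * 7.3, syms), members)$es
  expect_equal(es_pos, es_scaled, tolerance = 1e-12)
})

test_that("leading edge sits on the correct side of the extremum", {
  set.seed(23)
  scores <- sort(rnorm(60), decreasing = TRUE)
  r <- rl(scores)
  up <- enrichment_score(r, r$symbol[c(1, 3, 5, 40)])
  expect_true(all(match(up$leading_edge, r$symbol) <=
                  which.max(abs(up$running_sum$running_sum))))
  dn <- enrichment_score(r, r$symbol[c(20, 55, 57, 59)])
  expect_lt(dn$es, 0)
})

test_that("a top-loaded set gets a positive NES at the permutation floor", {
  set.seed(24)
  scores <- sort(abs(rnorm(300)) + 0.1, decreasing = TRUE)
  syms <- sprintf("g%03d", 1:300)
  sets <- kdconcord:::new_gene_set_collection(tibble::tibble(
    set = c("top", "random"), description = "",
    genes = list(syms[1:15], sample(syms, 15))))
  res <- gsea_preranked(rl(scores, syms), sets,
                        gsea_params(n_perm = 1000, seed = 9))
  top <- res[res$set == "top", ]
  expect_gt(top$nes, 0)
  expect_lte(top$p_value, 0.01)
  expect_gte(top$p_value, 1 / (1 + 1000))
})

test_that("preranked results are seed-deterministic with sign(nes) = sign(es)", {
  set.seed(25)
  syms <- sprintf("g%04d", 1:400)
  scores <- sort(rnorm(400), decreasing = TRUE)
  sets <- kdconcord:::new_gene_set_collection(tibble::tibble(
    set = sprintf("S%02d", 1:8), description = "",
    genes = lapply(1:8, function(i) sample(syms, 20))))
  p <- gsea_params(n_perm = 500, seed = 31)
  a <- gsea_preranked(rl(scores, syms), sets, p)
  b <- gsea_preranked(rl(scores, syms), sets, p)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_true(all(sign(a$nes) == sign(a$es)))
  expect_true(all(a$p_value >= 1 / (1 + p$n_perm)))
  expect_true(all(vapply(seq_len(nrow(a)), function(i) {
    all(a$leading_edge[[i]] %in% sets$genes[[match(a$set[i], sets$set)]])
  }, TRUE)))
})

test_that("size filtering skips sets with reasons and errors when none survive", {
  syms <- sprintf("g%03d", 1:100)
  scores <- sort(rnorm(100), decreasing = TRUE)
  sets <- kdconcord:::new_gene_set_collection(tibble::tibble(
    set = c("tiny", "ok", "absent"), description = "",
    genes = list(syms[1:3], syms[10:30], c("none1", "none2"))))
  res <- gsea_preranked(rl(scores, syms), sets,
                        gsea_params(min_size = 10, n_perm = 200, seed = 1))
  expect_equal(res$set, "ok")
  skipped <- attr(res, "skipped")
  expect_setequal(skipped$set, c("tiny", "absent"))
  expect_equal(skipped$reason[skipped$set == "absent"], "no members in ranked list")
  only_bad <- kdconcord:::new_gene_set_collection(sets[c(1, 3), ])
  expect_error(gsea_preranked(rl(scores, syms), only_bad,
                              gsea_params(min_size = 10, n_perm = 200)),
               class = "kdconcord_empty_set")
})

test_that("rank files order by score with p = 1 genes scored zero", {
  de <- structure(tibble::tibble(
    gene_id = c("a", "b", "c"), symbol = c("A", "B", "C"),
    mean_cpm_nt = 1, mean_cpm_kd = 2, log2fc = c(2, -3, 1.5),
    t_stat = 0, df = 2, p_value = c(0.001, 0.001, 1),
    rank_score = kdconcord:::signed_log10p(c(2, -3, 1.5), c(0.001, 0.001, 1)),
    cell_line = "L"), class = c("de_table", class(tibble::tibble())))
  r <- build_rank_file(de)
  expect_equal(r$symbol, c("A", "C", "B"))
  expect_equal(r$score[r$symbol == "C"], 0)
  # property: output is a sorted permutation of the rank scores
  set.seed(26)
  n <- 500
  de2 <- de[rep(1, n), ]
  de2$symbol <- sprintf("R%04d", sample(n))
  de2$rank_score <- rnorm(n)
  r2 <- build_rank_file(de2)
  expect_equal(sort(r2$score), sort(de2$rank_score))
  expect_true(!is.unsorted(rev(r2$score)))
})
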