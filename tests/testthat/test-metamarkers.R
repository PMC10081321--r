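# AUROC statistic, per-dataset DE, meta-ranking, aggregate prediction, LOO.

test_that("mann-whitney auroc endpoints and worked case", {
  expect_equal(mann_whitney_auroc(c(4, 3, 2, 1), c(1, 1, 0, 0)), 1)
  expect_equal(mann_whitney_auroc(c(4, 3, 2, 1), c(0, 0, 1, 1)), 0)
  # scores [3,1,2,4], positives at scores {3,2}: 2 of 4 pairs won
  expect_equal(mann_whitney_auroc(c(3, 1, 2, 4),
                                  c(TRUE, FALSE, TRUE, FALSE)), 0.5)
  expect_equal(mann_whitney_auroc(rep(1, 6), c(1, 0, 1, 0, 0, 1)), 0.5)
  expect_error(mann_whitney_auroc(1:3, c(TRUE, TRUE, TRUE)), "undefined")
  expect_error(mann_whitney_auroc(1:3, c(FALSE, FALSE, FALSE)),
               "undefined")
})

test_that("auroc equals pair counting on random tied instances", {
  set.seed(7)
  for (i in 1:200) {
    n <- sample(3:40, 1)
    scores <- sample(1:8, n, replace = TRUE)  # heavy ties
    labels <- rep(FALSE, n)
    labels[sample(n, sample(seq_len(n - 1), 1))] <- TRUE
    expect_identical(mann_whitney_auroc(scores, labels),
                     oracle_auroc(scores, labels))
  }
})

test_that("auroc complementarity under label flip", {
  set.seed(8)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    scores <- rnorm(n)
    labels <- rep(FALSE, n); labels[sample(n, 2)] <- TRUE
    expect_equal(mann_whitney_auroc(scores, labels) +
                   mann_whitney_auroc(scores, !labels), 1)
  }
})

de_toy <- function() {
  # 4 genes x 8 cells (4 target, 4 rest), values already CPM-scale
  vals <- rbind(
    hi  = c(31, 31, 31, 31, 1, 1, 1, 1),   # mean 31 vs 1
    flat = rep(7, 8),                        # identical everywhere
    excl = c(5, 6, 7, 8, 0, 0, 0, 0),       # exclusive to target
    rev  = c(1, 1, 1, 1, 9, 9, 9, 9))       # anti-marker
  make_em(vals, gene_ids = rownames(vals),
          cell_type = rep(c("target", "rest"), each = 4))
}

test_that("per-dataset DE statistics follow the declared definitions", {
  de <- compute_markers(de_toy())
  tgt <- de[de$cell_type == "target", ]
  rownames(tgt) <- tgt$gene
  # log2((31+1)/(1+1)) = 4 exactly with the 1-CPM pseudocount
  expect_equal(tgt["hi", "log2_fc"], 4)
  expect_equal(tgt["flat", "log2_fc"], 0)
  expect_equal(tgt["flat", "auroc"], 0.5)
  expect_equal(tgt["excl", "auroc"], 1)
  expect_equal(tgt["rev", "auroc"], 0)
  # aurocs agree with the pair-counting oracle
  vals <- as.matrix(de_toy()$values)
  pos <- rep(c(TRUE, FALSE), each = 4)
  for (g in rownames(vals))
    expect_equal(tgt[g, "auroc"], oracle_auroc(vals[g, ], pos))
  expect_true(all(de$fdr >= 0 & de$fdr <= 1))
})

test_that("cell-types below the minimum size are excluded with warning", {
  em <- make_em(rbind(c(1, 2, 3, 4, 5)),
                cell_type = c("a", "a", "b", "b", "tiny"))
  expect_warning(de <- compute_markers(em), "tiny")
  expect_setequal(unique(de$cell_type), c("a", "b"))
  em2 <- make_em(rbind(c(1, 2, 3)), cell_type = c("a", "a", "tiny"))
  expect_error(suppressWarnings(compute_markers(em2)), "2 cell-types")
})

fake_de <- function(genes, de_flags, aurocs, cell_type = "ct",
                    log2_fc = NULL) {
  if (is.null(log2_fc)) log2_fc <- ifelse(de_flags, 5, 0)
  s <- data.frame(gene = genes, cell_type = cell_type,
                  log2_fc = log2_fc, auroc = aurocs,
                  p_value = ifelse(de_flags, 1e-6, 0.5),
                  fdr = ifelse(de_flags, 1e-5, 0.8),
                  frac_in = 1, frac_out = 0, stringsAsFactors = FALSE)
  class(s) <- c("de_stats", "data.frame")
  s
}

test_that("meta ranking orders by recurrence, then mean auroc, then id", {
  mk <- function(fx, fy) fake_de(c("X", "Y"), c(fx, fy), c(0.9, 0.8))
  mm <- make_meta_markers(list(mk(TRUE, TRUE), mk(TRUE, TRUE),
                               mk(TRUE, FALSE)))
  expect_equal(mm$gene[mm$rank == 1], "X")  # 3/3 beats 2/3
  expect_equal(mm$recurrence[mm$gene == "X"], 3L)
  expect_equal(mm$recurrence[mm$gene == "Y"], 2L)

  # equal recurrence: mean auroc breaks the tie
  tie <- list(fake_de(c("X", "Y"), c(TRUE, TRUE), c(0.9, 0.8)),
              fake_de(c("X", "Y"), c(TRUE, TRUE), c(0.9, 0.8)))
  mm2 <- make_meta_markers(tie)
  expect_equal(mm2$gene, c("X", "Y"))

  # equal everything: ascending gene id
  same <- list(fake_de(c("B", "A"), c(TRUE, TRUE), c(0.9, 0.9)))
  expect_equal(make_meta_markers(same)$gene, c("A", "B"))

  expect_error(make_meta_markers(list(fake_de("X", TRUE, 0.9, "ct1"),
                                      fake_de("X", TRUE, 0.9, "ct2"))),
               "shared")
})

test_that("single-dataset meta ranking reduces to (DE flag, auroc) order", {
  s <- fake_de(c("A", "B", "C"), c(FALSE, TRUE, TRUE), c(0.99, 0.7, 0.9))
  mm <- make_meta_markers(list(s))
  expect_equal(mm$gene, c("C", "B", "A"))
})

test_that("single-dataset top markers rank by auroc with id tie-break", {
  s <- fake_de(c("A", "B", "C", "D"), rep(TRUE, 4),
               c(0.7, 0.95, 0.7, 0.9))
  top <- top_markers_single_dataset(s, k = 1)
  expect_equal(top$ct, "B")
  top3 <- top_markers_single_dataset(s, k = 3)
  expect_equal(top3$ct, c("B", "D", "A"))  # A before C at tied 0.7
  expect_warning(all4 <- top_markers_single_dataset(s, k = 10), "exceeds")
  expect_equal(length(all4$ct), 4L)
})

test_that("aggregate expression prediction matches the oracle", {
  em <- de_toy()
  expect_equal(aggregate_expression_predict(em, "excl", "target"), 1)
  # markers with all-zero expression give a total tie
  em0 <- make_em(rbind(z1 = rep(0, 6), g = c(1, 2, 3, 4, 5, 6)),
                 gene_ids = c("z1", "g"),
                 cell_type = rep(c("a", "b"), 3))
  expect_equal(aggregate_expression_predict(em0, "z1", "a"), 0.5)
  # 6-cell toy against brute-force pair counting
  vals <- rbind(m1 = c(3, 0, 5, 1, 2, 2), m2 = c(1, 1, 4, 0, 0, 3))
  em6 <- make_em(vals, gene_ids = rownames(vals),
                 cell_type = c("t", "o", "t", "o", "t", "o"))
  expect_equal(aggregate_expression_predict(em6, c("m1", "m2"), "t"),
               oracle_auroc(colSums(vals), c(1, 0, 1, 0, 1, 0)))
  expect_error(aggregate_expression_predict(em6, "absent", "t"),
               "no marker genes")
  expect_error(aggregate_expression_predict(em6, "m1", "nope"),
               "not present")
})

test_that("loo recovers planted markers and handles absent cell-types", {
  cfg <- function(seed) simulation_config(n_cell_types = 3,
                                          cells_per_type = 60,
                                          n_genes = 300,
                                          markers_per_type = 15,
                                          seed = seed)
  ds <- lapply(1:2, function(i)
    cpm_normalize(simulate_dataset(cfg(40 + i), paste0("d", i))))
  res <- loo_cross_validate(ds, k_list = c(10))
  expect_true(all(res$auroc > 0.9))
  expect_setequal(unique(res$cell_type), paste0("type", 1:3))

  # drop one cell-type from the left-out dataset: its rows disappear
  keep <- ds[[1]]$cell_meta$cell_type != "type3"
  ds1 <- ds[[1]]
  ds1$values <- ds1$values[, keep]
  ds1$cell_meta <- ds1$cell_meta[keep, ]
  res2 <- loo_cross_validate(list(ds1, ds[[2]]), k_list = 10)
  expect_false(any(res2$cell_type == "type3" & res2$left_out == 1))
  # and with only two datasets the type3 ranking cannot be learned from
  # the remaining dataset either, so no type3 row appears at all
  expect_false(any(res2$cell_type == "type3"))
  expect_setequal(res2$cell_type, c("type1", "type2"))

  # shuffled labels in the left-out dataset: chance-level prediction
  shuf <- ds[[1]]
  set.seed(99)
  shuf$cell_meta$cell_type <- sample(shuf$cell_meta$cell_type)
  res3 <- loo_cross_validate(list(shuf, ds[[2]]), k_list = 10)
  near_null <- res3$auroc[res3$left_out == 1]
  expect_true(all(abs(near_null - 0.5) < 0.1))
})
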