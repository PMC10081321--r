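# Preserved co-expression: top-k partners, per-gene AUROC, summaries.

hand_net <- function(vals) {
  make_net(vals, gene_ids = paste0("g", seq_len(nrow(vals))))
}

test_that("top-k partners exclude self and break ties lexicographically", {
  v <- matrix(0, 5, 5)
  v[1, 2:5] <- c(0.9, 0.7, 0.5, 0.3)
  net <- hand_net(v)
  expect_equal(top_k_partners(net, "g1", k = 2), c("g2", "g3"))
  expect_false("g1" %in% top_k_partners(net, "g1", k = 4))

  # three-way tie at the k-th value: smallest ids win
  v2 <- matrix(0, 6, 6)
  v2[1, 2:6] <- c(0.9, 0.5, 0.5, 0.5, 0.1)
  net2 <- hand_net(v2)
  expect_equal(top_k_partners(net2, "g1", k = 2), c("g2", "g3"))
  expect_setequal(top_k_partners(net2, "g1", k = 2, include_ties = TRUE),
                  c("g2", "g3", "g4", "g5"))

  expect_error(top_k_partners(net, "nope", k = 2), "absent")
  expect_error(top_k_partners(net, "g1", k = 5), "more than k")
})

test_that("preserved auroc matches hand pair-counting on a 5-gene pair", {
  ref_v <- matrix(0, 5, 5)
  ref_v[1, 2:5] <- c(0.9, 0.8, 0.2, 0.1)   # top-2 of g1: g2, g3
  ref <- hand_net(ref_v)
  test_v <- matrix(0, 5, 5)
  test_v[1, 2:5] <- c(0.6, 0.1, 0.5, 0.4)  # g2 ranks 1st, g3 last
  test <- hand_net(test_v)
  got <- preserved_auroc(ref, test, "g1", k = 2)
  want <- oracle_auroc(c(0.6, 0.1, 0.5, 0.4),
                       c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(got, want)          # g2 wins 2 pairs, g3 none: 2/4
  expect_equal(want, 0.5)

  # identical networks: AUROC 1 for untied genes
  expect_equal(preserved_auroc(ref, ref, "g1", k = 2), 1)

  # fully tied test row: 0.5, flagged uninformative
  flat <- hand_net(matrix(0.4, 5, 5))
  r <- preserved_auroc(ref, flat, "g1", k = 2)
  expect_equal(as.numeric(r), 0.5)
  expect_true(attr(r, "uninformative"))
})

test_that("namespace mismatches are rejected", {
  a <- hand_net(matrix(0.1, 4, 4))
  b <- make_net(matrix(0.1, 4, 4), gene_ids = c("x1", "x2", "x3", "x4"))
  expect_error(preserved_auroc(a, b, "g1"), "identical gene")
  expect_error(score_preservation(a, b), "identical gene")
})

test_that("self-preservation is exact and set scores are exact means", {
  np <- simulate_network_pair(120, modules = rep(11, 3), p = 0.5,
                              seed = 11)
  self <- score_preservation(np$ref, np$ref, gene_sets = np$modules,
                             k = 10)
  expect_equal(unname(self$gene_auroc), rep(1, 120))
  expect_equal(self$global_score, 1)

  res <- score_preservation(np$ref, np$test, gene_sets = np$modules,
                            k = 10)
  for (m in names(np$modules))
    expect_equal(res$set_scores[[m]],
                 mean(res$gene_auroc[np$modules[[m]]]))
  expect_equal(res$global_score, mean(res$gene_auroc))

  # member order never matters
  shuffled <- lapply(np$modules, rev)
  res2 <- score_preservation(np$ref, np$test, gene_sets = shuffled,
                             k = 10)
  expect_equal(res2$set_scores, res$set_scores)
})

test_that("missing set members are excluded; empty sets score NA", {
  np <- simulate_network_pair(60, modules = c(11), p = 1, seed = 12)
  sets <- list(ok = c(np$modules$module1, "ghost1", "ghost2"),
               gone = c("ghost3", "ghost4"))
  expect_message(
    res <- score_preservation(np$ref, np$test, gene_sets = sets),
    "missing")
  expect_equal(res$set_scores[["ok"]],
               mean(res$gene_auroc[np$modules$module1]))
  expect_true(is.na(res$set_scores[["gone"]]))
})

test_that("an unrelated random test network scores near chance", {
  set.seed(13)
  mk <- function() {
    m <- matrix(runif(300^2), 300)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- 1
    rank_standardize(m)
  }
  a <- mk(); b <- mk()
  res <- score_preservation(a, b, k = 10)
  expect_lt(abs(res$global_score - 0.5), 0.02)
})

test_that("preservation degrades monotonically as test noise grows", {
  set.seed(14)
  base <- matrix(runif(100^2), 100)
  base[lower.tri(base)] <- t(base)[lower.tri(base)]
  diag(base) <- 1
  ref <- rank_standardize(base)
  scores <- vapply(c(0, 0.25, 0.75, 2), function(s) {
    mean(vapply(1:5, function(i) {
      set.seed(100 * s + i)
      noise <- matrix(rnorm(100^2, sd = s), 100)
      noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
      test <- rank_standardize(base + noise)
      score_preservation(ref, test, k = 10)$global_score
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(scores) < 0))
})

test_that("identical networks score 1 for every k below the namespace", {
  np <- simulate_network_pair(80, modules = c(11), p = 1, seed = 15)
  for (k in c(5, 10, 25))
    expect_equal(score_preservation(np$ref, np$ref, k = k)$global_score, 1)
})

test_that("fine marker extraction ranks by adjusted p with overlap filter", {
  de <- data.frame(cell_type = "ctA",
                   gene = sprintf("g%02d", 1:12),
                   adj_p = c(0.01, 0.02, 0.03, 0.04, 0.05, 0.06, 0.07,
                             0.08, 0.09, 0.10, 0.11, 0.12))
  top <- fine_markers_from_de(de, k = 10)
  expect_equal(top$ctA, sprintf("g%02d", 1:10))

  # excluding a shared gene pulls in rank 11
  top2 <- fine_markers_from_de(de, k = 10, exclude = list(other = "g03"))
  expect_equal(top2$ctA, sprintf("g%02d", c(1, 2, 4:11)))

  # p ties break by gene id
  tie <- data.frame(cell_type = "ct", gene = c("zz", "aa", "mm"),
                    adj_p = c(0.5, 0.5, 0.5))
  expect_equal(suppressWarnings(fine_markers_from_de(tie, k = 2))$ct,
               c("aa", "mm"))

  expect_warning(fine_markers_from_de(de[1:4, ], k = 10), "only")
  expect_error(fine_markers_from_de(de[0, ], k = 10), "non-empty")
})

test_that("reference percentiles use the strictly-below mid-rank rule", {
  expect_equal(reference_percentile(9, c(1, 2, 3)), 100)
  expect_equal(reference_percentile(2, c(1, 2, 3)), 50)
  expect_equal(reference_percentile(0.7, c(0.5, 0.6, 0.8, 0.9)), 50)
  expect_equal(reference_percentile(0, c(1, 2, 3)), 0)
  expect_error(reference_percentile(1, numeric(0)), "empty")
})
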