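# Reading, QC filtering, CPM normalization and universe harmonization.

write_triplet <- function(dir, entries, n_genes, n_cells, gene_ids,
                          barcodes = paste0("bc", seq_len(n_cells)),
                          gz = FALSE) {
  ext <- if (gz) ".gz" else ""
  mtx <- file.path(dir, paste0("matrix.mtx", ext))
  feats <- file.path(dir, paste0("features.tsv", ext))
  bars <- file.path(dir, paste0("barcodes.tsv", ext))
  open <- function(p) if (gz) gzfile(p, "w") else file(p, "w")
  con <- open(mtx)
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               paste(n_genes, n_cells, nrow(entries)),
               apply(entries, 1, paste, collapse = " ")), con)
  close(con)
  con <- open(feats)
  writeLines(paste(paste0("ENS", seq_along(gene_ids)), gene_ids,
                   "Gene Expression", sep = "\t"), con)
  close(con)
  con <- open(bars)
  writeLines(barcodes, con)
  close(con)
  list(matrix = mtx, features = feats, barcodes = bars)
}

test_that("sparse triplet reading recovers the dense matrix, plain and gz", {
  for (gz in c(FALSE, TRUE)) {
    d <- withr::local_tempdir()
    f <- write_triplet(d, rbind(c(1, 1, 5), c(2, 2, 3)), 3, 2,
                       c("A", "B", "C"), gz = gz)
    em <- read_sparse_triplet(f$matrix, f$features, f$barcodes)
    expect_equal(unname(as.matrix(em$values)),
                 rbind(c(5, 0), c(0, 3), c(0, 0)))
    expect_equal(em$gene_ids, c("A", "B", "C"))
    expect_equal(em$cell_meta$barcode, c("bc1", "bc2"))
    expect_equal(em$normalized, "counts")
  }
})

test_that("sidecar dimension mismatches name the offending file", {
  d <- withr::local_tempdir()
  f <- write_triplet(d, rbind(c(1, 1, 5)), 3, 2, c("A", "B", "C"))
  short <- file.path(d, "short_features.tsv")
  writeLines(c("E1\tA", "E2\tB"), short)
  expect_error(read_sparse_triplet(f$matrix, short, f$barcodes),
               "short_features")
  short_bc <- file.path(d, "short_barcodes.tsv")
  writeLines("bc1", short_bc)
  expect_error(read_sparse_triplet(f$matrix, f$features, short_bc),
               "short_barcodes")
})

test_that("duplicate gene ids keep the row with the larger total count", {
  d <- withr::local_tempdir()
  # gene DUP appears on rows 1 (total 7) and 3 (total 2)
  f <- write_triplet(d, rbind(c(1, 1, 3), c(1, 2, 4),
                              c(2, 1, 1), c(3, 2, 2)),
                     3, 2, c("DUP", "B", "DUP"))
  expect_message(em <- read_sparse_triplet(f$matrix, f$features, f$barcodes),
                 "duplicated")
  expect_equal(em$gene_ids, c("DUP", "B"))
  expect_equal(unname(as.matrix(em$values)["DUP" == em$gene_ids, ]),
               c(3, 4))
})

test_that("dense reading handles tables, single rows, and bad input", {
  d <- withr::local_tempdir()
  p <- file.path(d, "expr.tsv")
  writeLines(c("gene\tc1\tc2", "A\t1\t2", "B\t3\t4"), p)
  em <- read_dense(p)
  expect_equal(unname(as.matrix(em$values)), rbind(c(1, 2), c(3, 4)))
  expect_equal(em$gene_ids, c("A", "B"))

  one <- file.path(d, "one.tsv")
  writeLines(c("gene\tc1\tc2\tc3", "A\t1\t0\t2"), one)
  expect_equal(dim(read_dense(one)$values), c(1L, 3L))

  empty <- file.path(d, "empty.tsv")
  file.create(empty)
  expect_error(read_dense(empty))

  bad <- file.path(d, "bad.tsv")
  writeLines(c("gene\tc1\tc2", "A\t1\tx"), bad)
  expect_error(read_dense(bad), "row 1.*c2|c2.*row 1")
})

qc_toy <- function() {
  # 10 genes, first is mitochondrial; three cells engineered to hit the
  # worked QC example when thresholds are scaled to the toy size
  counts <- matrix(0, 10, 3)
  counts[, 1] <- c(60, rep(5, 8), 0)   # 60% mito, 9 detected genes
  counts[, 2] <- c(10, 90, 0, 0, 0, 0, 0, 0, 0, 0)  # 10% mito, 2 detected
  counts[, 3] <- c(10, rep(10, 8), 10) # 10% mito, 10 detected
  make_em(counts, gene_ids = c("MT-ND1", paste0("g", 1:9)),
          normalized = "counts")
}

test_that("qc keeps only cells passing mito and detected-gene thresholds", {
  em <- qc_toy()
  out <- qc_filter(em, mito_max = 0.5, min_genes = 3, max_genes = 100)
  expect_equal(ncol(out$values), 1L)
  expect_equal(out$cell_meta$barcode, "c3")
  expect_equal(nrow(out$values), 10L)  # gene dimension unchanged
})

test_that("mito bound is strict and gene-count bounds are inclusive", {
  counts <- matrix(c(5, 5, 0,   # exactly 50% mito
                     1, 4, 4),  # 10% mito, exactly 3 detected
                   nrow = 3)
  em <- make_em(counts, gene_ids = c("MT-1", "g1", "g2"),
                normalized = "counts")
  out <- qc_filter(em, mito_max = 0.5, min_genes = 3, max_genes = 3)
  expect_equal(out$cell_meta$barcode, "c2")
})

test_that("doublet-flagged cells are removed and qc is idempotent", {
  em <- qc_toy()
  em$cell_meta$doublet <- c(FALSE, FALSE, TRUE)
  expect_error(qc_filter(em, min_genes = 3, max_genes = 100),
               "no cells survive")
  em$cell_meta$doublet <- c(TRUE, FALSE, FALSE)
  out <- qc_filter(em, min_genes = 3, max_genes = 100)
  expect_equal(out$cell_meta$barcode, "c3")
  twice <- qc_filter(out, min_genes = 3, max_genes = 100)
  expect_identical(as.matrix(twice$values), as.matrix(out$values))
  expect_identical(twice$cell_meta, out$cell_meta)
})

test_that("cpm scales cells to 1e6, leaves zero cells alone, keeps ranks", {
  counts <- cbind(c(1, 1, 2), c(0, 0, 0), c(10, 30, 60))
  em <- make_em(counts, normalized = "counts")
  out <- cpm_normalize(em)
  expect_equal(unname(as.matrix(out$values)[, 1]),
               c(250000, 250000, 500000))
  expect_equal(unname(as.matrix(out$values)[, 2]), c(0, 0, 0))
  sums <- colSums(as.matrix(out$values))
  expect_true(all(abs(sums[sums > 0] - 1e6) < 1e-6 * 1e6))
  expect_equal(out$normalized, "cpm")
  # within-cell ranks preserved exactly
  for (j in c(1, 3))
    expect_identical(unname(rank(as.matrix(out$values)[, j])),
                     rank(counts[, j]))
  expect_warning(cpm_normalize(out), "already")
})

test_that("cpm rank preservation holds on random count matrices", {
  set.seed(42)
  for (i in 1:5) {
    counts <- matrix(rpois(120, 3), nrow = 12)
    out <- cpm_normalize(make_em(counts, normalized = "counts"))
    for (j in seq_len(ncol(counts)))
      expect_identical(unname(rank(as.matrix(out$values)[, j])),
                       rank(counts[, j]))
  }
})

test_that("harmonization reindexes to the universe with zero padding", {
  em <- make_em(rbind(A = c(1, 2), B = c(3, 4), X = c(5, 6)),
                gene_ids = c("A", "B", "X"))
  uni <- gene_universe(c("A", "B", "C"))
  expect_message(out <- harmonize_universe(em, uni), "dropping 1")
  expect_equal(out$gene_ids, c("A", "B", "C"))
  expect_equal(unname(as.matrix(out$values)),
               rbind(c(1, 2), c(3, 4), c(0, 0)))

  same <- harmonize_universe(make_em(rbind(c(1, 2), c(3, 4)),
                                     gene_ids = c("A", "B")),
                             gene_universe(c("A", "B")))
  expect_equal(unname(as.matrix(same$values)), rbind(c(1, 2), c(3, 4)))

  expect_error(harmonize_universe(em, gene_universe(c("Q", "R"))),
               "namespace mismatch")
})

test_that("harmonized gene order is identical across datasets", {
  uni <- gene_universe(c("C", "A", "B"))
  em1 <- make_em(rbind(c(1, 1), c(2, 2)), gene_ids = c("A", "C"))
  em2 <- make_em(rbind(c(3, 3), c(4, 4)), gene_ids = c("B", "A"))
  expect_equal(suppressMessages(harmonize_universe(em1, uni))$gene_ids,
               suppressMessages(harmonize_universe(em2, uni))$gene_ids)
})

test_that("gmt and universe files round-trip", {
  d <- withr::local_tempdir()
  sets <- list(s1 = c("A", "B", "C"), s2 = c("B", "D"))
  p <- file.path(d, "sets.gmt")
  write_gmt(sets, p)
  expect_equal(read_gmt(p), sets)
  uni <- read_universe(p)
  expect_equal(uni$genes, c("A", "B", "C", "D"))
  expect_equal(uni$term_map$s2, c("B", "D"))

  tsv <- file.path(d, "uni.tsv")
  writeLines(c("t1\tA", "t1\tB", "t2\tB"), tsv)
  uni2 <- read_universe(tsv)
  expect_equal(uni2$genes, c("A", "B"))
  expect_equal(uni2$term_map$t1, c("A", "B"))
})

test_that("cell metadata attaches by barcode", {
  em <- make_em(rbind(c(1, 2, 3)), normalized = "counts")
  meta <- data.frame(barcode = c("c3", "c1"),
                     cell_type = c("tN", "tA"))
  out <- attach_cell_meta(em, meta)
  expect_equal(out$cell_meta$cell_type, c("tA", NA, "tN"))
})
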