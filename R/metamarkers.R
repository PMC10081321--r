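#' Mann-Whitney AUROC of a labeled score vector
#'
#' The workhorse statistic of the package. With positives labelled 1 and
#' negatives 0, the AUROC is \code{U / (n0 * n1)} where
#' \code{U = R0 - n0*(n0+1)/2} and \code{R0} is the sum of the positive
#' ranks (average ranks for ties). This equals the fraction of
#' (positive, negative) pairs in which the positive outranks the negative,
#' counting ties as one half.
#'
#' @param scores numeric vector.
#' @param labels logical (or 0/1) vector of the same length; TRUE marks a
#'   positive.
#' @return AUROC in \[0, 1\].
#' @export
mann_whitney_auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels))
    stop("scores and labels differ in length")
  if (anyNA(scores) || anyNA(labels)) stop("scores/labels contain NA")
  n0 <- sum(labels)
  n1 <- sum(!labels)
  if (n0 == 0 || n1 == 0)
    stop("AUROC undefined: need at least one positive and one negative ",
         "(n0 = ", n0, ", n1 = ", n1, ")")
  r <- rank(scores, ties.method = "average")
  u <- sum(r[labels]) - n0 * (n0 + 1) / 2
  u / (n0 * n1)
}

# vectorized AUROC over rows of a rank matrix: ranks is genes x cells where
# each row already holds rank(expression across cells); pos is logical over
# cells. Returns per-gene AUROC.
row_auroc_from_ranks <- function(ranks, pos) {
  n0 <- sum(pos)
  n1 <- sum(!pos)
  r0 <- rowSums(ranks[, pos, drop = FALSE])
  (r0 - n0 * (n0 + 1) / 2) / (n0 * n1)
}

#' One-vs-rest differential expression statistics for one dataset
#'
#' For every (gene, cell-type) pair computes the log2 fold change of mean
#' CPM with a pseudocount, the expression-ranking AUROC for cells of that
#' type versus the rest, a one-sided (greater) rank-sum p-value with tie
#' correction and continuity correction, and BH-adjusted p-values within
#' each cell-type. Cell-types with fewer than \code{min_cells} cells are
#' excluded with a warning.
#'
#' @param em an [expression_matrix] of CPM values whose \code{cell_meta}
#'   has a \code{cell_type} column.
#' @param pseudocount pseudocount epsilon added to both means before the
#'   log2 ratio (default 1 CPM).
#' @param min_cells minimum cells per cell-type (default 2).
#' @return data.frame of class \code{de_stats} with columns \code{gene},
#'   \code{cell_type}, \code{log2_fc}, \code{auroc}, \code{p_value},
#'   \code{fdr}, \code{frac_in}, \code{frac_out}; the dataset identifier
#'   (from \code{cell_meta$dataset}, if unique) is stored in
#'   \code{attr(,"dataset")}.
#' @export
compute_markers <- function(em, pseudocount = 1, min_cells = 2) {
  stopifnot(inherits(em, "expression_matrix"))
  if (is.null(em$cell_meta$cell_type))
    stop("cell_meta must contain a `cell_type` column")
  if (em$normalized != "cpm")
    warning("compute_markers expects CPM input; got ", em$normalized)
  ct <- as.character(em$cell_meta$cell_type)
  counts <- table(ct)
  small <- names(counts)[counts < min_cells]
  if (length(small)) {
    warning("excluding cell-type(s) with < ", min_cells, " cells: ",
            paste(small, collapse = ", "))
    keep <- !(ct %in% small)
    em$values <- em$values[, keep, drop = FALSE]
    ct <- ct[keep]
  }
  types <- sort(unique(ct))
  if (length(types) < 2)
    stop("need at least 2 cell-types with >= ", min_cells, " cells")
  x <- as.matrix(em$values)
  n <- ncol(x)
  ranks <- t(apply(x, 1, rank))        # genes x cells
  # tie-correction term per gene for the rank-sum normal approximation
  tie_term <- apply(x, 1, function(v) {
    t <- rle(sort(v))$lengths
    sum(t^3 - t)
  })
  out <- vector("list", length(types))
  for (i in seq_along(types)) {
    pos <- ct == types[i]
    n0 <- sum(pos); n1 <- n - n0
    mean_in <- rowMeans(x[, pos, drop = FALSE])
    mean_out <- rowMeans(x[, !pos, drop = FALSE])
    auroc <- row_auroc_from_ranks(ranks, pos)
    u <- auroc * n0 * n1
    sigma2 <- n0 * n1 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    sigma <- sqrt(pmax(sigma2, 0))
    z <- ifelse(sigma > 0, (u - n0 * n1 / 2 - 0.5) / sigma, 0)
    p <- stats::pnorm(z, lower.tail = FALSE)
    out[[i]] <- data.frame(
      gene = em$gene_ids,
      cell_type = types[i],
      log2_fc = log2((mean_in + pseudocount) / (mean_out + pseudocount)),
      auroc = auroc,
      p_value = p,
      fdr = stats::p.adjust(p, method = "BH"),
      frac_in = rowMeans(x[, pos, drop = FALSE] > 0),
      frac_out = rowMeans(x[, !pos, drop = FALSE] > 0),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  ds <- unique(as.character(em$cell_meta$dataset))
  attr(res, "dataset") <- if (length(ds) == 1) ds else NA_character_
  class(res) <- c("de_stats", "data.frame")
  res
}

#' Meta-analytic marker ranking across datasets
#'
#' Genes are ranked per cell-type first by recurrence — the number of
#' datasets in which they were called differentially expressed at
#' \code{log2_fc >= fc_threshold} and \code{fdr <= fdr_threshold} — and
#' then by the averaged differential-expression statistics (mean AUROC)
#' across datasets, with remaining ties broken by ascending gene id for
#' reproducibility.
#'
#' @param stats_list list of \code{de_stats} tables from [compute_markers]
#'   (a single table is also accepted).
#' @param fc_threshold log2 fold-change threshold for the DE call
#'   (default 4).
#' @param fdr_threshold FDR threshold for the DE call (default 0.05).
#' @return data.frame of class \code{meta_markers} with columns
#'   \code{cell_type}, \code{gene}, \code{rank}, \code{recurrence},
#'   \code{n_datasets}, \code{mean_auroc}, \code{mean_log2_fc}.
#' @export
make_meta_markers <- function(stats_list, fc_threshold = 4,
                              fdr_threshold = 0.05) {
  if (inherits(stats_list, "de_stats")) stats_list <- list(stats_list)
  if (!length(stats_list)) stop("need at least one de_stats table")
  type_sets <- lapply(stats_list, function(s) unique(s$cell_type))
  shared <- Reduce(intersect, type_sets)
  if (!length(shared))
    stop("no cell-types shared across all input datasets")
  all_stats <- do.call(rbind, lapply(seq_along(stats_list), function(i) {
    s <- as.data.frame(stats_list[[i]])
    s$dataset_idx <- i
    s[s$cell_type %in% shared, , drop = FALSE]
  }))
  all_stats$de <- all_stats$log2_fc >= fc_threshold &
    all_stats$fdr <= fdr_threshold
  out <- lapply(shared, function(tp) {
    s <- all_stats[all_stats$cell_type == tp, , drop = FALSE]
    key <- s$gene
    agg <- data.frame(
      gene = sort(unique(key)),
      stringsAsFactors = FALSE)
    agg$recurrence <- as.integer(
      tapply(s$de, key, sum)[agg$gene])
    agg$n_datasets <- as.integer(tapply(s$de, key, length)[agg$gene])
    agg$mean_auroc <- as.numeric(tapply(s$auroc, key, mean)[agg$gene])
    agg$mean_log2_fc <- as.numeric(tapply(s$log2_fc, key, mean)[agg$gene])
    ord <- order(-agg$recurrence, -agg$mean_auroc, agg$gene)
    agg <- agg[ord, , drop = FALSE]
    agg$rank <- seq_len(nrow(agg))
    agg$cell_type <- tp
    agg
  })
  res <- do.call(rbind, out)
  res <- res[, c("cell_type", "gene", "rank", "recurrence", "n_datasets",
                 "mean_auroc", "mean_log2_fc")]
  rownames(res) <- NULL
  class(res) <- c("meta_markers", "data.frame")
  res
}

#' Top-k marker sets from a ranking
#'
#' @param mm a \code{meta_markers} table (or any data.frame with
#'   \code{cell_type}, \code{gene}, \code{rank}).
#' @param k number of markers per cell-type (default 100).
#' @return named list of character vectors (one per cell-type).
#' @export
top_meta_markers <- function(mm, k = 100) {
  stopifnot(all(c("cell_type", "gene", "rank") %in% colnames(mm)))
  sets <- lapply(split(as.data.frame(mm), mm$cell_type), function(s) {
    s <- s[order(s$rank), , drop = FALSE]
    utils::head(s$gene, k)
  })
  sets[order(names(sets))]
}

#' Top-k markers per cell-type within a single dataset, ranked by AUROC
#'
#' @param stats a \code{de_stats} table from [compute_markers].
#' @param k markers per cell-type (default 100, the conventional size for
#'   single-dataset marker sets). AUROC ties are broken by ascending gene
#'   id. If \code{k} exceeds the number of genes all genes are returned
#'   with a warning.
#' @return named list of character vectors.
#' @export
top_markers_single_dataset <- function(stats, k = 100) {
  stopifnot(all(c("cell_type", "gene", "auroc") %in% colnames(stats)))
  lapply(split(as.data.frame(stats), stats$cell_type), function(s) {
    if (k > nrow(s))
      warning("k = ", k, " exceeds the ", nrow(s),
              " available genes; returning all")
    s <- s[order(-s$auroc, s$gene), , drop = FALSE]
    utils::head(s$gene, k)
  })
}

#' Aggregate-expression cell-type prediction AUROC
#'
#' Sums the expression of a marker set within each cell and ranks all
#' cells by this aggregate; the AUROC of that ranking against the
#' target-vs-rest labels quantifies the predictive strength of the marker
#' list. A perfect marker set — genes expressed only in the target
#' cell-type — yields an AUROC of 1.
#'
#' @param em a labeled [expression_matrix] (CPM by default; see
#'   \code{use}).
#' @param marker_set character vector of gene ids; genes absent from the
#'   matrix are ignored (error if none remain).
#' @param target_label cell-type treated as positive.
#' @param use \code{"values"} (default) sums the matrix as given, which is
#'   CPM after normalization; provided for symmetry with raw-count input.
#' @return AUROC in \[0, 1\].
#' @export
aggregate_expression_predict <- function(em, marker_set, target_label,
                                         use = "values") {
  stopifnot(inherits(em, "expression_matrix"))
  if (is.null(em$cell_meta$cell_type))
    stop("cell_meta must contain a `cell_type` column")
  genes <- intersect(marker_set, em$gene_ids)
  if (!length(genes))
    stop("no marker genes present in the expression matrix")
  if (!target_label %in% em$cell_meta$cell_type)
    stop("target label ", dQuote(target_label), " not present")
  sub <- em$values[match(genes, em$gene_ids), , drop = FALSE]
  score <- col_sums(sub)
  mann_whitney_auroc(score, em$cell_meta$cell_type == target_label)
}

#' Leave-one-out cross-validation of meta-analytic markers
#'
#' For each dataset in turn, meta-markers are learned from the remaining
#' datasets and used to predict the left-out dataset's cell-type
#' annotations with the aggregate-expression predictor, for each marker
#' list size in \code{k_list}. Cell-types absent from the left-out dataset
#' (or absent from the learned ranking) are omitted.
#'
#' @param datasets list of labeled CPM [expression_matrix] objects.
#' @param k_list marker list sizes (default \code{c(10, 20, 50, 100, 250,
#'   500)}).
#' @param stats_list optional precomputed list of \code{de_stats}, one per
#'   dataset, to avoid recomputing differential expression.
#' @param ... passed to [compute_markers].
#' @return data.frame with columns \code{left_out}, \code{cell_type},
#'   \code{k}, \code{auroc}.
#' @export
loo_cross_validate <- function(datasets, k_list = c(10, 20, 50, 100, 250, 500),
                               stats_list = NULL, ...) {
  if (length(datasets) < 2) stop("need at least 2 datasets for LOO")
  if (is.null(stats_list))
    stats_list <- lapply(datasets, compute_markers, ...)
  rows <- list()
  for (i in seq_along(datasets)) {
    mm <- make_meta_markers(stats_list[-i])
    test <- datasets[[i]]
    present <- intersect(unique(mm$cell_type),
                         unique(test$cell_meta$cell_type))
    for (tp in present) {
      for (k in k_list) {
        markers <- top_meta_markers(mm, k)[[tp]]
        markers <- intersect(markers, test$gene_ids)
        if (!length(markers)) next
        rows[[length(rows) + 1]] <- data.frame(
          left_out = i, cell_type = tp, k = k,
          auroc = aggregate_expression_predict(test, markers, tp),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) stop("no (dataset, cell-type) combination was scorable")
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
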