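#' Ordered marker co-expression submatrix
#'
#' Restricts a network to the union of marker sets, groups genes by set
#' (in the order the sets are supplied), and orders genes within each set
#' by descending mean co-expression to the other members of the same set
#' (ties by ascending gene id) — the conventional ordering for marker
#' co-expression heatmaps.
#'
#' @param net a [coexpression_network].
#' @param marker_sets named list of gene sets; genes absent from the
#'   network are dropped.
#' @return the ordered submatrix, with \code{attr(,"set_labels")} giving
#'   the marker-set label of each row. Genes in multiple sets are assigned
#'   to the first set containing them.
#' @export
marker_submatrix <- function(net, marker_sets) {
  stopifnot(inherits(net, "coexpression_network"))
  if (!length(marker_sets) || is.null(names(marker_sets)))
    stop("`marker_sets` must be a non-empty named list")
  seen <- character(0)
  blocks <- list()
  labels <- character(0)
  for (nm in names(marker_sets)) {
    genes <- setdiff(intersect(unique(marker_sets[[nm]]), net$gene_ids),
                     seen)
    if (!length(genes)) next
    seen <- c(seen, genes)
    idx <- match(genes, net$gene_ids)
    if (length(genes) > 1) {
      sub <- net$values[idx, idx, drop = FALSE]
      intra <- (rowSums(sub) - diag(sub)) / (length(genes) - 1)
    } else {
      intra <- 0
    }
    ord <- order(-intra, genes)
    blocks[[nm]] <- genes[ord]
    labels <- c(labels, rep(nm, length(genes)))
  }
  all_genes <- unlist(blocks, use.names = FALSE)
  if (!length(all_genes))
    stop("no marker gene present in the network namespace")
  idx <- match(all_genes, net$gene_ids)
  sub <- net$values[idx, idx, drop = FALSE]
  dimnames(sub) <- list(all_genes, all_genes)
  attr(sub, "set_labels") <- stats::setNames(labels, all_genes)
  sub
}

#' Consensus k-means Adjusted Rand Index of marker modularity
#'
#' Partitions the rows of a marker co-expression submatrix with k-means
#' repeated \code{repeats} times under seeded initializations, derives a
#' consensus partition, and reports the Adjusted Rand Index against the
#' perfect grouping of genes by their marker set. The consensus partition
#' is the partition of the single run whose co-clustering pattern agrees
#' best (on average over gene pairs) with the co-clustering frequency
#' matrix of all runs; agreement ties are broken by lower within-cluster
#' sum of squares, then run order.
#'
#' @param submatrix ordered submatrix from [marker_submatrix] (must carry
#'   the \code{set_labels} attribute, or supply \code{true_labels}).
#' @param k number of clusters (default 6, one per broad cell-type).
#' @param repeats number of k-means restarts (default 100).
#' @param seed integer seed.
#' @param true_labels optional vector of reference labels, overriding the
#'   attribute.
#' @return the ARI (numeric in \[-1, 1\]) with attributes
#'   \code{partition} (the consensus partition) and \code{agreement}.
#' @export
consensus_kmeans_ari <- function(submatrix, k = 6, repeats = 100, seed = 1,
                                 true_labels = NULL) {
  if (is.null(true_labels))
    true_labels <- attr(submatrix, "set_labels")
  if (is.null(true_labels))
    stop("no reference labels: supply `true_labels` or a submatrix from ",
         "marker_submatrix()")
  g <- nrow(submatrix)
  if (k > g) stop("k exceeds the number of genes")
  m <- unname(as.matrix(submatrix))
  n_distinct <- nrow(unique(m))
  if (n_distinct == 1) {
    warning("all rows identical; reporting ARI of the single-cluster ",
            "partition")
    part <- rep(1L, g)
    ari <- mclust::adjustedRandIndex(part, true_labels)
    attr(ari, "partition") <- part
    return(ari)
  }
  if (n_distinct < k) {
    warning("only ", n_distinct, " distinct rows; reducing k from ", k)
    k <- n_distinct
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  parts <- matrix(0L, nrow = repeats, ncol = g)
  wss <- numeric(repeats)
  for (r in seq_len(repeats)) {
    set.seed(seed + r)
    km <- suppressWarnings(stats::kmeans(m, centers = k, nstart = 1,
                                         iter.max = 50))
    parts[r, ] <- km$cluster
    wss[r] <- km$tot.withinss
  }
  # co-clustering frequency over all runs, pair by pair
  same <- matrix(0, g, g)
  for (r in seq_len(repeats)) {
    ind <- outer(parts[r, ], parts[r, ], `==`)
    same <- same + ind
  }
  freq <- same / repeats
  off <- upper.tri(freq)
  agree <- vapply(seq_len(repeats), function(r) {
    ind <- outer(parts[r, ], parts[r, ], `==`)[off]
    mean(ind * freq[off] + (1 - ind) * (1 - freq[off]))
  }, numeric(1))
  best <- order(-agree, wss, seq_len(repeats))[1]
  part <- parts[best, ]
  ari <- mclust::adjustedRandIndex(part, true_labels)
  attr(ari, "partition") <- part
  attr(ari, "agreement") <- agree[best]
  ari
}

#' Deterministic Ward dendrogram leaf order
#'
#' Agglomerative clustering of the co-expression rows with Ward's
#' criterion (ward.D2) on Euclidean distances, returning a deterministic
#' leaf order: at every merge the subtree containing the smaller original
#' row index is placed first.
#'
#' @param submatrix numeric matrix with at least 2 rows.
#' @return integer vector of row indices in leaf order, with the row names
#'   (if any) as names.
#' @export
ward_dendrogram_order <- function(submatrix) {
  if (nrow(submatrix) < 2) stop("need at least 2 rows")
  hc <- stats::hclust(stats::dist(submatrix), method = "ward.D2")
  leaves <- function(node) {
    if (node < 0) return(-node)
    m <- hc$merge[node, ]
    left <- leaves(m[1]); right <- leaves(m[2])
    if (min(left) <= min(right)) c(left, right) else c(right, left)
  }
  ord <- leaves(nrow(hc$merge))
  names(ord) <- rownames(submatrix)[ord]
  ord
}
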