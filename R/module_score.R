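#' Neighbor-voting (guilt-by-association) AUROC of a gene set
#'
#' Quantifies how strongly a gene set co-expresses relative to the rest of
#' the genome. Set members are split into \code{n_folds} folds by a seeded
#' shuffle; in each fold the held-out members are unlabeled and every gene
#' is scored by the sum of its network weights to the remaining labeled
#' members, normalized by its total network weight (degree), which
#' controls hub bias. The fold AUROC compares held-out members against
#' non-members; fold AUROCs are averaged.
#'
#' With \code{n_folds} equal to the number of members this reduces to
#' leave-one-out voting. Set members absent from the network are dropped
#' (reported via \code{message()}).
#'
#' @param net a [coexpression_network].
#' @param gene_set character vector of member genes.
#' @param n_folds number of cross-validation folds (default 3).
#' @param seed integer seed for the fold shuffle.
#' @return cross-validated AUROC in \[0, 1\].
#' @export
neighbor_voting_auroc <- function(net, gene_set, n_folds = 3, seed = 1) {
  stopifnot(inherits(net, "coexpression_network"))
  members <- intersect(unique(gene_set), net$gene_ids)
  dropped <- length(unique(gene_set)) - length(members)
  if (dropped > 0)
    message("dropping ", dropped, " set gene(s) absent from the network")
  if (length(members) < n_folds)
    stop("gene set has ", length(members), " usable member(s); ",
         "neighbor voting needs at least n_folds = ", n_folds,
         " (default 3)")
  v <- net$values
  deg <- rowSums(v)
  midx <- match(members, net$gene_ids)
  nonmember <- setdiff(seq_along(net$gene_ids), midx)
  folds <- local({
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
    sample(rep_len(seq_len(n_folds), length(midx)))
  })
  fold_auc <- vapply(seq_len(n_folds), function(f) {
    held <- midx[folds == f]
    train <- midx[folds != f]
    votes <- rowSums(v[, train, drop = FALSE]) / deg
    cand <- c(held, nonmember)
    mann_whitney_auroc(votes[cand],
                       c(rep(TRUE, length(held)),
                         rep(FALSE, length(nonmember))))
  }, numeric(1))
  mean(fold_auc)
}

# save/restore .Random.seed so seeded helpers do not disturb the caller's
# RNG stream
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Score a collection of gene sets by neighbor voting
#'
#' Applies [neighbor_voting_auroc] to every set in a collection, after
#' intersecting each set with the network namespace and filtering on set
#' size (the conventional window for GO terms is 10 to 1000 genes). The
#' collection mean AUROC summarises overall modularity. The per-set fold
#' shuffle is seeded from \code{seed} plus a hash of the member genes, so
#' identical sets receive identical fold assignments wherever they appear.
#'
#' @param net a [coexpression_network].
#' @param collection named list of character vectors.
#' @param size_min,size_max inclusive bounds on post-intersection set size
#'   (defaults 10 and 1000).
#' @param n_folds folds per set (default 3).
#' @param seed base seed.
#' @return data.frame with columns \code{set_id}, \code{n_genes_used},
#'   \code{auroc}; the collection mean is in \code{attr(,"mean_auroc")}.
#' @export
score_gene_set_collection <- function(net, collection, size_min = 10,
                                      size_max = 1000, n_folds = 3,
                                      seed = 1) {
  stopifnot(inherits(net, "coexpression_network"))
  if (!length(collection) || is.null(names(collection)))
    stop("`collection` must be a non-empty named list")
  sizes <- vapply(collection, function(g)
    length(intersect(unique(g), net$gene_ids)), integer(1))
  # a set covering the whole namespace leaves no non-members to rank
  keep <- sizes >= size_min & sizes <= size_max &
    sizes < length(net$gene_ids)
  if (sum(!keep))
    message("skipping ", sum(!keep), " set(s) outside [", size_min, ", ",
            size_max, "] genes after intersection with the network")
  if (!any(keep))
    stop("no gene set survives the size filter")
  ids <- names(collection)[keep]
  auc <- vapply(ids, function(id) {
    genes <- collection[[id]]
    suppressMessages(
      neighbor_voting_auroc(net, genes, n_folds = n_folds,
                            seed = seed + gene_set_hash(genes)))
  }, numeric(1))
  res <- data.frame(set_id = ids, n_genes_used = sizes[keep], auroc = auc,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "mean_auroc") <- mean(auc)
  res
}

# deterministic small integer derived from the member genes, independent of
# their order
gene_set_hash <- function(genes) {
  s <- sort(unique(as.character(genes)))
  sum(utf8ToInt(paste(s, collapse = "|"))) %% 100000L
}
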