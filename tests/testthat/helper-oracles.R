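# Independent oracles and small fixture builders shared across tests.

# Brute-force AUROC: fraction of (positive, negative) pairs where the
# positive outranks the negative, ties counted as one half.
oracle_auroc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  wins <- 0
  for (p in pos) for (q in neg)
    wins <- wins + (p > q) + 0.5 * (p == q)
  wins / (length(pos) * length(neg))
}

# Spearman rho from first principles: mid-ranks computed by pair counting,
# then the Pearson product-moment formula evaluated directly.
oracle_spearman <- function(x, y) {
  midrank <- function(v) vapply(v, function(vi)
    sum(v < vi) + (sum(v == vi) + 1) / 2, numeric(1))
  rx <- midrank(x); ry <- midrank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Direct leave-one-out neighbor voting, written independently of the
# package's fold machinery: each member in turn is hidden and scored by
# its degree-normalized connectivity to the remaining members.
oracle_loo_neighbor_voting <- function(values, gene_ids, members) {
  deg <- rowSums(values)
  nonmembers <- setdiff(gene_ids, members)
  aucs <- vapply(members, function(g) {
    train <- setdiff(members, g)
    votes <- rowSums(values[, match(train, gene_ids), drop = FALSE]) / deg
    cand <- c(g, nonmembers)
    oracle_auroc(votes[match(cand, gene_ids)],
                 c(TRUE, rep(FALSE, length(nonmembers))))
  }, numeric(1))
  mean(aucs)
}

# Toy CPM expression matrix with explicit values.
make_em <- function(values, gene_ids = NULL, cell_type = NULL,
                    normalized = "cpm", dataset = "toy") {
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(values)))
  meta <- data.frame(barcode = paste0("c", seq_len(ncol(values))),
                     dataset = dataset, stringsAsFactors = FALSE)
  if (!is.null(cell_type)) meta$cell_type <- cell_type
  expression_matrix(values, gene_ids, cell_meta = meta,
                    normalized = normalized)
}

# Hand-assembled symmetric network from an off-diagonal value list.
make_net <- function(values, gene_ids = NULL, ...) {
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(values)))
  vals <- (values + t(values)) / 2
  diag(vals) <- 1
  coexpression_network(vals, gene_ids, ...)
}

# Planted-clique network: members share weight `inside`, the background is
# uniform noise around `outside`.
clique_net <- function(n_genes = 200, n_members = 20, inside = 1,
                       outside = 0.1, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::runif(n_genes^2, 0, outside), n_genes)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  members <- seq_len(n_members)
  m[members, members] <- inside
  diag(m) <- 1
  ids <- sprintf("g%03d", seq_len(n_genes))
  list(net = coexpression_network(m, ids),
       members = ids[members])
}
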