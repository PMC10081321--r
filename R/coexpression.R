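#' Spearman co-expression matrix of a dataset
#'
#' Computes the gene-by-gene Spearman correlation across all cells of a
#' dataset. Correlations involving zero-variance genes (including
#' zero-padded universe genes) are set to 0, a neutral value that leaves
#' such genes in the tied middle mass after rank standardization rather
#' than propagating NA.
#'
#' @param em a harmonized [expression_matrix] with at least 2 cells.
#' @return symmetric numeric matrix of Spearman rho in \[-1, 1\] with gene
#'   ids as dimnames; diagonal is 1.
#' @export
spearman_network <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  if (ncol(em$values) < 2)
    stop("need at least 2 cells to compute correlations")
  x <- as.matrix(em$values)            # cells become rows below
  # rank each gene across cells, then Pearson on ranks == Spearman
  r <- apply(x, 1, rank)               # cells x genes
  rho <- suppressWarnings(stats::cor(r))
  rho[!is.finite(rho)] <- 0            # zero-variance genes
  diag(rho) <- 1
  rho <- (rho + t(rho)) / 2            # enforce exact symmetry
  dimnames(rho) <- list(em$gene_ids, em$gene_ids)
  rho
}

#' Rank-standardize a co-expression matrix
#'
#' Jointly ranks every entry of the symmetric matrix (ties averaged) and
#' divides by the maximum rank, mapping values into (0, 1] and making
#' networks comparable across datasets. The global maximum entries map to
#' exactly 1. Ranking the full symmetric matrix (diagonal included)
#' preserves symmetry automatically; the diagonal is then forced to 1.
#'
#' @param corr symmetric finite numeric matrix (e.g. from
#'   [spearman_network]).
#' @param n_cells,n_datasets provenance counters stored on the result.
#' @return a [coexpression_network].
#' @export
rank_standardize <- function(corr, n_cells = NA_integer_, n_datasets = 1L) {
  if (nrow(corr) != ncol(corr)) stop("input must be square")
  if (any(!is.finite(corr))) stop("input must be finite")
  check_symmetric(corr)
  r <- rank(corr, ties.method = "average")
  std <- matrix(r / length(r), nrow = nrow(corr))
  std <- (std + t(std)) / 2           # ranks of a symmetric matrix are
  diag(std) <- 1                      # symmetric; this guards rounding
  coexpression_network(std, rownames(corr) %||% as.character(seq_len(nrow(corr))),
                       n_cells = n_cells, n_datasets = n_datasets)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a rank-standardized co-expression network from a dataset
#'
#' Convenience composition of [spearman_network] and [rank_standardize].
#'
#' @param em a harmonized [expression_matrix].
#' @return a [coexpression_network].
#' @export
build_network <- function(em) {
  rank_standardize(spearman_network(em), n_cells = ncol(em$values),
                   n_datasets = 1L)
}

#' Aggregate rank-standardized co-expression networks
#'
#' Element-wise mean of rank-standardized networks over an identical gene
#' namespace. Averaging many sparse individual networks denoises them and
#' enhances shared co-expression signal.
#'
#' @param nets list of [coexpression_network] objects with identical
#'   \code{gene_ids} in identical order.
#' @return a [coexpression_network] with \code{n_datasets} equal to the sum
#'   of the inputs' dataset counts and \code{n_cells} the sum of cells.
#' @export
aggregate_networks <- function(nets) {
  if (!length(nets)) stop("need at least one network")
  lapply(nets, function(n) stopifnot(inherits(n, "coexpression_network")))
  ids <- nets[[1]]$gene_ids
  for (i in seq_along(nets)) {
    other <- nets[[i]]$gene_ids
    if (length(other) != length(ids) || any(other != ids)) {
      pos <- if (length(other) != length(ids)) 0L
             else which(other != ids)[1]
      stop("gene namespace mismatch between networks 1 and ", i,
           if (pos > 0) paste0(" (first differing position ", pos, ": ",
                               ids[pos], " vs ", other[pos], ")")
           else " (different lengths)")
    }
  }
  acc <- nets[[1]]$values
  if (length(nets) > 1)
    for (i in 2:length(nets)) acc <- acc + nets[[i]]$values
  coexpression_network(acc / length(nets), ids,
                       n_cells = sum(vapply(nets, function(n)
                         ifelse(is.na(n$n_cells), 0L, n$n_cells),
                         integer(1))),
                       n_datasets = sum(vapply(nets, function(n)
                         n$n_datasets, integer(1))))
}

#' Serialize a co-expression network to TSV
#'
#' Writes the symmetric matrix with gene ids as row/column names, preceded
#' by \code{#}-prefixed provenance lines (n_cells, n_datasets), so the
#' file round-trips through [read_network].
#'
#' @param net a [coexpression_network].
#' @param path output file.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "coexpression_network"))
  writeLines(c(paste0("# n_cells\t", net$n_cells),
               paste0("# n_datasets\t", net$n_datasets)), path)
  df <- data.table::as.data.table(net$values)
  data.table::setnames(df, net$gene_ids)
  df <- cbind(data.table::data.table(gene = net$gene_ids), df)
  data.table::fwrite(df, path, sep = "\t", append = TRUE,
                     col.names = TRUE)
  invisible(path)
}

#' Read a serialized co-expression network
#'
#' @param path TSV written by [write_network].
#' @return a [coexpression_network].
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 10)
  meta <- header[startsWith(header, "#")]
  get_meta <- function(key) {
    line <- meta[grepl(paste0("^#\\s*", key), meta)]
    if (!length(line)) return(NA_integer_)
    val <- strsplit(line[1], "\t", fixed = TRUE)[[1]][2]
    if (is.na(val) || val == "NA") NA_integer_ else as.integer(val)
  }
  df <- data.table::fread(path, sep = "\t", header = TRUE, skip = "gene\t",
                          data.table = FALSE)
  genes <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  dimnames(vals) <- list(genes, genes)
  # symmetrize away decimal round-trip noise
  vals <- (vals + t(vals)) / 2
  coexpression_network(vals, genes, n_cells = get_meta("n_cells"),
                       n_datasets = get_meta("n_datasets"))
}
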