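#' Top co-expressed partners of a gene in a reference network
#'
#' Returns the \code{k} genes with the largest co-expression to the query
#' gene, excluding the query itself. Ties at the k-th value are broken by
#' ascending gene id, giving a deterministic cut at exactly \code{k}
#' positives; set \code{include_ties = TRUE} to instead return every gene
#' tied with the k-th value.
#'
#' @param ref a [coexpression_network].
#' @param gene query gene id.
#' @param k neighborhood size (default 10).
#' @param include_ties include all genes tied at the k-th value.
#' @return character vector of partner gene ids.
#' @export
top_k_partners <- function(ref, gene, k = 10, include_ties = FALSE) {
  stopifnot(inherits(ref, "coexpression_network"))
  i <- match(gene, ref$gene_ids)
  if (is.na(i)) stop("gene ", dQuote(gene), " absent from the network")
  if (length(ref$gene_ids) <= k)
    stop("network needs more than k = ", k, " genes")
  row <- ref$values[i, ]
  ids <- ref$gene_ids
  row <- row[-i]; ids <- ids[-i]
  ord <- order(-row, ids)
  if (include_ties) {
    kth <- row[ord[k]]
    ids[row >= kth]
  } else {
    ids[ord[seq_len(k)]]
  }
}

#' Preserved co-expression AUROC for one gene
#'
#' Takes the top \code{k} co-expressed partners of the gene in the
#' reference network as positives, ranks all other genes by their
#' co-expression with the gene in the test network, and computes the
#' Mann-Whitney AUROC of that ranking. Identical top-k neighborhoods give
#' an AUROC of 1. The query gene is excluded from both the positive set
#' and the candidate ranking, since the self-edge would otherwise inflate
#' every score. A fully tied test row yields 0.5 with an
#' \code{"uninformative"} attribute flag.
#'
#' @param ref,test [coexpression_network] objects over the same namespace.
#' @param gene query gene id.
#' @param k reference neighborhood size (default 10).
#' @return AUROC in \[0, 1\].
#' @export
preserved_auroc <- function(ref, test, gene, k = 10) {
  check_same_namespace(ref, test)
  pos <- top_k_partners(ref, gene, k = k)
  i <- match(gene, test$gene_ids)
  row <- test$values[i, -i]
  ids <- test$gene_ids[-i]
  if (max(row) == min(row)) {
    res <- 0.5
    attr(res, "uninformative") <- TRUE
    return(res)
  }
  mann_whitney_auroc(row, ids %in% pos)
}

check_same_namespace <- function(a, b) {
  if (length(a$gene_ids) != length(b$gene_ids) ||
      any(a$gene_ids != b$gene_ids))
    stop("reference and test networks must share an identical gene ",
         "namespace (harmonize both to the same universe first)")
  invisible(TRUE)
}

#' Preservation of reference co-expression in a test network
#'
#' Computes the per-gene preserved co-expression AUROC (see
#' [preserved_auroc]) for every requested gene, then summarizes: a gene
#' set's preservation score is the arithmetic mean of its member genes'
#' AUROCs, and the global score is the mean over all scored genes.
#'
#' @param ref,test [coexpression_network] objects over the same namespace.
#' @param gene_sets optional named list of gene sets to score; members
#'   missing from the namespace are excluded from the mean (and reported).
#' @param k reference neighborhood size (default 10).
#' @param genes which genes get per-gene scores: \code{"all"} (default)
#'   scores the full namespace, \code{"sets"} only the union of
#'   \code{gene_sets}.
#' @return object of class \code{preservation_result}: list with
#'   \code{gene_auroc} (named vector), \code{set_scores} (named vector,
#'   \code{NA} for sets empty after intersection), \code{global_score},
#'   \code{k}, \code{n_genes_scored}, and provenance counters.
#' @export
score_preservation <- function(ref, test, gene_sets = NULL, k = 10,
                               genes = c("all", "sets")) {
  genes <- match.arg(genes)
  check_same_namespace(ref, test)
  ids <- ref$gene_ids
  if (genes == "sets") {
    if (is.null(gene_sets))
      stop("genes = \"sets\" requires `gene_sets`")
    score_genes <- intersect(unique(unlist(gene_sets)), ids)
  } else {
    score_genes <- ids
  }
  if (!length(score_genes)) stop("no genes to score")
  n <- length(ids)
  rv <- ref$values
  tv <- test$values
  auc <- vapply(score_genes, function(g) {
    i <- match(g, ids)
    rrow <- rv[i, -i]
    rids <- ids[-i]
    pos_idx <- order(-rrow, rids)[seq_len(k)]
    trow <- tv[i, -i]
    if (max(trow) == min(trow)) return(0.5)
    lab <- logical(n - 1L)
    lab[pos_idx] <- TRUE
    mann_whitney_auroc(trow, lab)
  }, numeric(1))
  names(auc) <- score_genes
  set_scores <- NULL
  if (!is.null(gene_sets)) {
    if (is.null(names(gene_sets))) stop("`gene_sets` must be named")
    set_scores <- vapply(gene_sets, function(g) {
      g2 <- intersect(unique(g), names(auc))
      miss <- length(unique(g)) - length(g2)
      if (miss > 0)
        message("gene set member(s) missing from scored genes: ", miss,
                " excluded from the mean")
      if (!length(g2)) return(NA_real_)
      mean(auc[g2])
    }, numeric(1))
  }
  structure(list(gene_auroc = auc,
                 set_scores = set_scores,
                 global_score = mean(auc),
                 k = k,
                 n_genes_scored = length(auc),
                 reference = list(n_cells = ref$n_cells,
                                  n_datasets = ref$n_datasets),
                 test = list(n_cells = test$n_cells,
                             n_datasets = test$n_datasets)),
            class = "preservation_result")
}

#' @export
print.preservation_result <- function(x, ...) {
  cat("<preservation_result> k =", x$k, "| genes scored:",
      x$n_genes_scored, "| global score:",
      format(x$global_score, digits = 4), "\n")
  if (!is.null(x$set_scores)) {
    cat("  set scores:\n")
    for (nm in names(x$set_scores))
      cat("   ", nm, ":", format(x$set_scores[[nm]], digits = 4), "\n")
  }
  invisible(x)
}

#' Fine-resolution marker sets from a differential-expression table
#'
#' Per cell-type, takes the top \code{k} genes by ascending adjusted
#' p-value (ties broken by gene id). When \code{exclude} is supplied, any
#' gene present in that collection is removed first and the next-ranked
#' genes are pulled in, guaranteeing disjointness from e.g. a broader
#' marker collection.
#'
#' @param de_table data.frame with columns \code{cell_type}, \code{gene},
#'   \code{adj_p}.
#' @param k genes per cell-type (default 10).
#' @param exclude optional character vector or list of vectors of genes to
#'   exclude before taking the top k.
#' @return named list of character vectors.
#' @export
fine_markers_from_de <- function(de_table, k = 10, exclude = NULL) {
  need <- c("cell_type", "gene", "adj_p")
  if (!is.data.frame(de_table) || nrow(de_table) == 0)
    stop("`de_table` must be a non-empty data.frame")
  if (!all(need %in% colnames(de_table)))
    stop("`de_table` needs columns: ", paste(need, collapse = ", "))
  banned <- unique(unlist(exclude, use.names = FALSE))
  lapply(split(de_table, de_table$cell_type), function(s) {
    s <- s[!(s$gene %in% banned), , drop = FALSE]
    s <- s[order(s$adj_p, s$gene), , drop = FALSE]
    if (nrow(s) < k)
      warning("cell-type ", unique(s$cell_type)[1] %||% "?", " has only ",
              nrow(s), " genes after filtering; returning all")
    utils::head(s$gene, k)
  })
}

#' Percentile of a score within a reference distribution
#'
#' Returns \code{100 * (fraction of reference values strictly below the
#' score)}, counting ties at half weight (mid-rank), so a score equal to
#' the reference median sits at the 50th percentile.
#'
#' @param score numeric scalar.
#' @param reference_scores non-empty numeric vector.
#' @return percentile in \[0, 100\].
#' @export
reference_percentile <- function(score, reference_scores) {
  if (!length(reference_scores)) stop("reference distribution is empty")
  if (anyNA(reference_scores) || is.na(score))
    stop("NA in score or reference")
  100 * (sum(reference_scores < score) +
           0.5 * sum(reference_scores == score)) / length(reference_scores)
}
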