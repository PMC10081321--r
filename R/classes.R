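#' Construct an expression matrix container
#'
#' The basic data container of the package: a gene-by-cell non-negative
#' numeric matrix (raw counts or CPM) with unique gene identifiers and a
#' per-cell metadata table. Most pipeline functions accept and return this
#' class.
#'
#' @param values gene x cell numeric matrix (base matrix or a
#'   \code{Matrix} sparse matrix); rows are genes, columns are cells.
#' @param gene_ids character vector of unique gene identifiers, one per row.
#' @param cell_meta data.frame of per-cell metadata with one row per column
#'   of \code{values}. Recognised columns: \code{barcode}, \code{dataset},
#'   \code{cell_type}, \code{doublet} (logical), \code{age}, \code{region}.
#' @param normalized either \code{"counts"} or \code{"cpm"}.
#'
#' @return An object of class \code{expression_matrix}: a list with elements
#'   \code{values}, \code{gene_ids}, \code{cell_meta}, \code{normalized}.
#' @export
expression_matrix <- function(values, gene_ids, cell_meta = NULL,
                              normalized = c("counts", "cpm")) {
  normalized <- match.arg(normalized)
  if (is.null(dim(values)) || length(dim(values)) != 2L)
    stop("`values` must be a two-dimensional matrix")
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != nrow(values))
    stop("length of `gene_ids` (", length(gene_ids),
         ") does not match number of rows (", nrow(values), ")")
  if (anyDuplicated(gene_ids))
    stop("`gene_ids` must be unique; found duplicated ids: ",
         paste(utils::head(unique(gene_ids[duplicated(gene_ids)]), 5),
               collapse = ", "))
  if (min_value(values) < 0)
    stop("expression values must be non-negative")
  if (is.null(cell_meta)) {
    cn <- colnames(values)
    if (is.null(cn)) cn <- paste0("cell_", seq_len(ncol(values)))
    cell_meta <- data.frame(barcode = cn, stringsAsFactors = FALSE)
  }
  if (nrow(cell_meta) != ncol(values))
    stop("`cell_meta` must have one row per cell (",
         ncol(values), " cells, ", nrow(cell_meta), " metadata rows)")
  rownames(values) <- gene_ids
  structure(list(values = values, gene_ids = gene_ids,
                 cell_meta = cell_meta, normalized = normalized),
            class = "expression_matrix")
}

# min that works for both base and Matrix classes without densifying
min_value <- function(m) {
  if (inherits(m, "sparseMatrix")) {
    x <- m@x
    explicit <- if (length(x)) min(x) else 0
    if (length(x) < prod(dim(m))) min(explicit, 0) else explicit
  } else {
    min(m)
  }
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix> ", nrow(x$values), " genes x ", ncol(x$values),
      " cells (", x$normalized, ")\n", sep = "")
  if (!is.null(x$cell_meta$cell_type))
    cat("  cell types:",
        paste(names(sort(table(x$cell_meta$cell_type), decreasing = TRUE)),
              collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Construct a gene universe
#'
#' The fixed, shared gene namespace (typically the GO-annotated genes) to
#' which every dataset is harmonized before network construction, optionally
#' carrying named gene sets (e.g. GO terms) over that namespace.
#'
#' @param genes character vector of unique gene identifiers, in the order
#'   networks will use.
#' @param term_map named list mapping term ids to character vectors of
#'   member genes; every member must belong to \code{genes}.
#'
#' @return An object of class \code{gene_universe} with elements
#'   \code{genes} and \code{term_map}.
#' @export
gene_universe <- function(genes, term_map = list()) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("universe genes must be unique")
  if (length(genes) == 0) stop("universe is empty")
  if (length(term_map)) {
    if (is.null(names(term_map)) || any(names(term_map) == ""))
      stop("`term_map` must be a named list")
    bad <- vapply(term_map, function(g) !all(g %in% genes), logical(1))
    if (any(bad))
      stop("term(s) with members outside the universe: ",
           paste(utils::head(names(term_map)[bad], 5), collapse = ", "))
  }
  structure(list(genes = genes, term_map = term_map),
            class = "gene_universe")
}

#' @export
print.gene_universe <- function(x, ...) {
  cat("<gene_universe> ", length(x$genes), " genes, ",
      length(x$term_map), " terms\n", sep = "")
  invisible(x)
}

#' Construct a co-expression network
#'
#' A symmetric gene-by-gene matrix of rank-standardized co-expression values
#' in (0, 1], together with the gene namespace and provenance counters.
#'
#' @param values symmetric numeric gene x gene matrix.
#' @param gene_ids character vector of gene identifiers (universe order).
#' @param n_cells number of cells the network was computed from.
#' @param n_datasets number of datasets averaged into the network (1 for an
#'   individual network, more for an aggregate).
#'
#' @return An object of class \code{coexpression_network}.
#' @export
coexpression_network <- function(values, gene_ids, n_cells = NA_integer_,
                                 n_datasets = 1L) {
  if (nrow(values) != ncol(values)) stop("network matrix must be square")
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != nrow(values))
    stop("gene_ids length does not match matrix dimension")
  if (anyDuplicated(gene_ids)) stop("network gene_ids must be unique")
  if (any(!is.finite(values))) stop("network values must all be finite")
  check_symmetric(values)
  dimnames(values) <- list(gene_ids, gene_ids)
  structure(list(values = values, gene_ids = gene_ids,
                 n_cells = as.integer(n_cells),
                 n_datasets = as.integer(n_datasets)),
            class = "coexpression_network")
}

check_symmetric <- function(m, tol = 1e-8) {
  if (max(abs(m - t(m))) > tol)
    stop("matrix is not symmetric within tolerance ", tol)
  invisible(TRUE)
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat("<coexpression_network> ", length(x$gene_ids), " genes; ",
      x$n_datasets, " dataset(s), ", x$n_cells, " cells\n", sep = "")
  invisible(x)
}

#' @export
dim.coexpression_network <- function(x) dim(x$values)
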