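#' Read a 10x-convention sparse expression triplet
#'
#' Reads a MatrixMarket sparse count matrix plus its feature and barcode
#' sidecar tables (the \code{matrix.mtx}, \code{features.tsv},
#' \code{barcodes.tsv} convention). Gzipped or plain files are both
#' accepted. Duplicate gene identifiers are collapsed by keeping the row
#' with the larger total count; the number of dropped rows is reported via
#' \code{message()}.
#'
#' @param matrix_path path to the MatrixMarket file (.mtx or .mtx.gz).
#' @param features_path path to the features table; the gene identifier is
#'   taken from the second column when present (10x style), else the first.
#' @param barcodes_path path to the one-column barcode table.
#'
#' @return An [expression_matrix] holding raw counts.
#' @export
read_sparse_triplet <- function(matrix_path, features_path, barcodes_path) {
  for (p in c(matrix_path, features_path, barcodes_path))
    if (!file.exists(p)) stop("file not found: ", p)
  m <- as(Matrix::readMM(open_maybe_gz(matrix_path)), "CsparseMatrix")
  feats <- utils::read.table(features_path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE, quote = "",
                             comment.char = "")
  bars <- utils::read.table(barcodes_path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE, quote = "",
                            comment.char = "")
  if (nrow(feats) != nrow(m))
    stop("dimension mismatch: ", features_path, " has ", nrow(feats),
         " rows but matrix declares ", nrow(m), " genes")
  if (nrow(bars) != ncol(m))
    stop("dimension mismatch: ", barcodes_path, " has ", nrow(bars),
         " rows but matrix declares ", ncol(m), " cells")
  gene_ids <- if (ncol(feats) >= 2) feats[[2]] else feats[[1]]
  gene_ids <- as.character(gene_ids)
  dedup <- dedup_genes(m, gene_ids)
  expression_matrix(dedup$values, dedup$gene_ids,
                    cell_meta = data.frame(barcode = as.character(bars[[1]]),
                                           stringsAsFactors = FALSE),
                    normalized = "counts")
}

open_maybe_gz <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path) else path
}

# keep, per duplicated id, the row with the largest total count
dedup_genes <- function(m, gene_ids) {
  if (!anyDuplicated(gene_ids))
    return(list(values = m, gene_ids = gene_ids))
  totals <- Matrix::rowSums(m)
  keep <- rep(TRUE, length(gene_ids))
  for (id in unique(gene_ids[duplicated(gene_ids)])) {
    rows <- which(gene_ids == id)
    best <- rows[order(-totals[rows], rows)][1]
    keep[setdiff(rows, best)] <- FALSE
  }
  message("collapsed ", sum(!keep), " duplicated gene row(s), keeping the ",
          "row with the larger total count")
  list(values = m[keep, , drop = FALSE], gene_ids = gene_ids[keep])
}

#' Read a dense expression table
#'
#' Reads a TSV or CSV expression table: first column gene identifiers,
#' header row of cell identifiers.
#'
#' @param path path to the table; the delimiter is inferred from the
#'   extension (.csv uses comma, anything else tab).
#' @param normalized \code{"counts"} (default) or \code{"cpm"}, describing
#'   what the file holds.
#'
#' @return An [expression_matrix].
#' @export
read_dense <- function(path, normalized = "counts") {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  df <- tryCatch(
    utils::read.table(path, sep = sep, header = TRUE, row.names = NULL,
                      stringsAsFactors = FALSE, check.names = FALSE,
                      quote = "", comment.char = ""),
    error = function(e) stop("could not parse ", path, ": ",
                             conditionMessage(e)))
  if (nrow(df) == 0 || ncol(df) < 2)
    stop("empty or malformed expression table: ", path)
  gene_ids <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      suppress <- suppressWarnings(as.numeric(col))
      if (anyNA(suppress)) {
        i <- which(is.na(suppress))[1]
        stop("non-numeric value ", dQuote(col[i]), " at row ", i,
             ", column ", colnames(vals)[j], " of ", path)
      }
      vals[[j]] <- suppress
    }
  }
  m <- as.matrix(vals)
  colnames(m) <- colnames(vals)
  dedup <- dedup_genes(m, gene_ids)
  expression_matrix(dedup$values, dedup$gene_ids,
                    cell_meta = data.frame(barcode = colnames(m),
                                           stringsAsFactors = FALSE),
                    normalized = normalized)
}

#' Attach per-cell metadata from a table
#'
#' Joins a metadata table (keyed by barcode) onto an expression matrix.
#'
#' @param em an [expression_matrix].
#' @param meta data.frame with a \code{barcode} column plus any of
#'   \code{cell_type}, \code{dataset}, \code{doublet}, \code{age},
#'   \code{region}; or a path to a TSV with those columns.
#' @return the [expression_matrix] with merged \code{cell_meta}.
#' @export
attach_cell_meta <- function(em, meta) {
  stopifnot(inherits(em, "expression_matrix"))
  if (is.character(meta) && length(meta) == 1)
    meta <- utils::read.table(meta, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE, quote = "",
                              comment.char = "")
  if (is.null(meta$barcode)) stop("metadata must contain a `barcode` column")
  idx <- match(em$cell_meta$barcode, meta$barcode)
  if (all(is.na(idx)))
    stop("no metadata barcodes match the expression matrix barcodes")
  for (col in setdiff(colnames(meta), "barcode"))
    em$cell_meta[[col]] <- meta[[col]][idx]
  em
}

#' Quality-control filter cells
#'
#' Removes cells flagged as doublets (when a \code{doublet} column is
#' present in the cell metadata), then keeps cells with a mitochondrial
#' read fraction strictly below \code{mito_max} and a number of detected
#' genes within \code{[min_genes, max_genes]} (inclusive bounds).
#' Mitochondrial genes are identified by identifier prefix and the fraction
#' is computed from the raw counts, so this filter should run before CPM
#' normalization.
#'
#' @param em an [expression_matrix] of raw counts.
#' @param mito_prefix identifier prefix marking mitochondrial genes
#'   (default \code{"MT-"}).
#' @param mito_max maximum tolerated mitochondrial fraction (exclusive;
#'   default 0.5).
#' @param min_genes,max_genes inclusive bounds on the number of genes with
#'   nonzero counts per cell (defaults 200 and 6000).
#'
#' @return the filtered [expression_matrix]; the gene dimension is
#'   unchanged.
#' @export
qc_filter <- function(em, mito_prefix = "MT-", mito_max = 0.5,
                      min_genes = 200, max_genes = 6000) {
  stopifnot(inherits(em, "expression_matrix"))
  if (em$normalized != "counts")
    warning("qc_filter expects raw counts; detected-gene and mitochondrial ",
            "fractions are computed from the values as given")
  keep <- rep(TRUE, ncol(em$values))
  if (!is.null(em$cell_meta$doublet)) {
    dbl <- em$cell_meta$doublet
    keep <- keep & !(!is.na(dbl) & as.logical(dbl))
  }
  totals <- col_sums(em$values)
  mito_rows <- startsWith(em$gene_ids, mito_prefix)
  mito_frac <- if (any(mito_rows)) {
    mt <- col_sums(em$values[mito_rows, , drop = FALSE])
    ifelse(totals > 0, mt / totals, 0)
  } else rep(0, ncol(em$values))
  detected <- col_nnz(em$values)
  keep <- keep & (mito_frac < mito_max) &
    (detected >= min_genes) & (detected <= max_genes)
  if (!any(keep))
    stop("no cells survive QC; review mito_max/min_genes/max_genes ",
         "thresholds for this dataset")
  em$values <- em$values[, keep, drop = FALSE]
  em$cell_meta <- em$cell_meta[keep, , drop = FALSE]
  rownames(em$cell_meta) <- NULL
  em
}

col_sums <- function(m) {
  if (inherits(m, "Matrix")) Matrix::colSums(m) else colSums(m)
}
col_nnz <- function(m) {
  if (inherits(m, "Matrix")) Matrix::colSums(m != 0) else colSums(m != 0)
}

#' Counts-per-million normalization
#'
#' Scales every cell so its total expression equals 1e6. All-zero cells
#' are left all-zero. Input that is already CPM is returned unchanged with
#' a warning. Within-cell expression ranks are preserved exactly.
#'
#' @param em an [expression_matrix] of raw counts.
#' @param scale_factor target per-cell total (default 1e6).
#' @return the normalized [expression_matrix] with \code{normalized="cpm"}.
#' @export
cpm_normalize <- function(em, scale_factor = 1e6) {
  stopifnot(inherits(em, "expression_matrix"))
  if (em$normalized == "cpm") {
    warning("input is already CPM normalized; returning unchanged")
    return(em)
  }
  totals <- col_sums(em$values)
  scale <- ifelse(totals > 0, scale_factor / totals, 0)
  if (inherits(em$values, "Matrix")) {
    em$values <- em$values %*% Matrix::Diagonal(x = scale)
    dimnames(em$values) <- list(em$gene_ids, em$cell_meta$barcode)
  } else {
    em$values <- sweep(em$values, 2, scale, `*`)
  }
  em$normalized <- "cpm"
  em
}

#' Harmonize an expression matrix to a gene universe
#'
#' Reindexes the gene axis of a dataset to exactly the universe namespace,
#' in universe order: genes absent from the dataset become all-zero rows
#' (zero-padding) and dataset genes absent from the universe are dropped
#' (their count is reported via \code{message()}). All datasets harmonized
#' to the same universe therefore share an identical gene axis, the
#' prerequisite for network aggregation.
#'
#' @param em an [expression_matrix].
#' @param uni a [gene_universe].
#' @return the harmonized [expression_matrix].
#' @export
harmonize_universe <- function(em, uni) {
  stopifnot(inherits(em, "expression_matrix"),
            inherits(uni, "gene_universe"))
  common <- intersect(em$gene_ids, uni$genes)
  if (length(common) == 0)
    stop("no overlap between dataset genes and universe genes; ",
         "likely a gene namespace mismatch")
  dropped <- length(setdiff(em$gene_ids, uni$genes))
  if (dropped > 0)
    message("dropping ", dropped, " gene(s) absent from the universe; ",
            "zero-padding ", length(setdiff(uni$genes, em$gene_ids)),
            " universe gene(s) absent from the dataset")
  idx <- match(uni$genes, em$gene_ids)
  if (inherits(em$values, "Matrix")) {
    out <- Matrix::Matrix(0, nrow = length(uni$genes),
                          ncol = ncol(em$values), sparse = TRUE)
    out[!is.na(idx), ] <- em$values[idx[!is.na(idx)], , drop = FALSE]
  } else {
    out <- matrix(0, nrow = length(uni$genes), ncol = ncol(em$values))
    out[!is.na(idx), ] <- em$values[idx[!is.na(idx)], , drop = FALSE]
    colnames(out) <- colnames(em$values)
  }
  expression_matrix(out, uni$genes, cell_meta = em$cell_meta,
                    normalized = em$normalized)
}

#' Read a GMT gene-set file
#'
#' @param path GMT file: tab-separated, one set per line,
#'   \code{name<TAB>description<TAB>gene1<TAB>gene2...}.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty GMT file: ", path)
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop("malformed GMT line (need name, description, >=1 gene): ",
           substr(l, 1, 60))
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

#' Write gene sets as GMT
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @param description recycled description column (default the set name).
#' @export
write_gmt <- function(sets, path, description = NULL) {
  if (is.null(names(sets))) stop("`sets` must be named")
  desc <- if (is.null(description)) names(sets)
          else rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene universe (with optional term map) from GMT or two-column TSV
#'
#' A GMT file yields terms whose union of members defines the universe. A
#' two-column TSV (term, gene; no header required) is stacked into the same
#' structure.
#'
#' @param path GMT or TSV file.
#' @return a [gene_universe].
#' @export
read_universe <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1)
  nfield <- length(strsplit(first, "\t", fixed = TRUE)[[1]])
  if (nfield >= 3) {
    term_map <- read_gmt(path)
  } else {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE, quote = "",
                            comment.char = "")
    if (ncol(df) < 2) stop("universe TSV needs two columns (term, gene)")
    term_map <- split(as.character(df[[2]]), as.character(df[[1]]))
    term_map <- lapply(term_map, unique)
  }
  genes <- sort(unique(unlist(term_map, use.names = FALSE)))
  gene_universe(genes, term_map)
}
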