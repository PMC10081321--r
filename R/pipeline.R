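#' Run the full co-expression fidelity pipeline from a config file
#'
#' Drives the standard workflow — load or simulate datasets, QC and CPM
#' normalization, harmonization to a shared gene universe, per-dataset
#' rank-standardized networks, aggregation, meta-analytic markers, module
#' scores and (when a reference network is configured) preservation
#' scoring — writing a deterministic directory of TSV/JSON artifacts plus
#' a run log of versions, seeds and thresholds. Re-running with the same
#' config and seed reproduces the outputs bit-exactly.
#'
#' The YAML config recognises these keys (all thresholds default to the
#' package's standard values): \code{seed}; either \code{simulate} (fields
#' of [simulation_config] plus \code{n_datasets}) or \code{datasets} (a
#' list of entries with \code{matrix}/\code{features}/\code{barcodes} or
#' \code{dense}, optional \code{meta}); optional \code{universe} (GMT or
#' two-column TSV), \code{gene_sets} (GMT), \code{reference_network}
#' (TSV from [write_network]); sub-maps \code{qc}, \code{markers},
#' \code{module_score}, \code{preservation}.
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @param out_dir output directory (created; must be empty or absent
#'   unless \code{overwrite = TRUE}).
#' @param overwrite allow writing into an existing directory.
#' @return (invisibly) a list with the summary (also written to
#'   \code{summary.json}) and the output paths.
#' @export
run_pipeline <- function(config, out_dir, overwrite = FALSE) {
  cfg <- if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    yaml::read_yaml(config)
  } else config
  if (!is.list(cfg)) stop("config must be a YAML file path or a list")
  # validate every referenced input before any computation starts
  for (key in c("universe", "gene_sets", "reference_network"))
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      stop("configured ", key, " not found: ", cfg[[key]])
  if (!is.null(cfg$datasets))
    for (d in cfg$datasets)
      for (p in unlist(d[intersect(names(d),
                          c("matrix", "features", "barcodes",
                            "dense", "meta"))]))
        if (!file.exists(p)) stop("configured dataset input not found: ", p)
  if (is.null(cfg$simulate) && is.null(cfg$datasets))
    stop("config must provide either `simulate` or `datasets`")
  if (dir.exists(out_dir) && length(dir(out_dir)) && !overwrite)
    stop("output directory exists and is not empty: ", out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed %||% 1L)
  qc_cfg <- utils::modifyList(list(mito_prefix = "MT-", mito_max = 0.5,
                                   min_genes = 200, max_genes = 6000),
                              cfg$qc %||% list())
  mk_cfg <- utils::modifyList(list(fc_threshold = 4, fdr_threshold = 0.05,
                                   top_k = 100),
                              cfg$markers %||% list())
  ms_cfg <- utils::modifyList(list(size_min = 10, size_max = 1000,
                                   n_folds = 3),
                              cfg$module_score %||% list())
  pv_cfg <- utils::modifyList(list(k = 10), cfg$preservation %||% list())

  log_lines <- c(paste0("coexfid version\t",
                        as.character(utils::packageVersion("coexfid"))),
                 paste0("seed\t", seed),
                 paste0("qc\t", deparse1(qc_cfg)),
                 paste0("markers\t", deparse1(mk_cfg)),
                 paste0("module_score\t", deparse1(ms_cfg)),
                 paste0("preservation\t", deparse1(pv_cfg)))

  # --- load or simulate ------------------------------------------------
  marker_map <- NULL
  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    n_ds <- as.integer(sim$n_datasets %||% 3L)
    sim$n_datasets <- NULL
    datasets <- lapply(seq_len(n_ds), function(i) {
      args <- utils::modifyList(sim, list(seed = seed + i))
      simulate_dataset(do.call(simulation_config, args),
                       dataset_id = paste0("sim", i))
    })
    marker_map <- attr(datasets[[1]], "marker_map")
    log_lines <- c(log_lines, paste0("simulated datasets\t", n_ds))
  } else {
    datasets <- lapply(seq_along(cfg$datasets), function(i) {
      d <- cfg$datasets[[i]]
      em <- if (!is.null(d$dense)) read_dense(d$dense)
            else read_sparse_triplet(d$matrix, d$features, d$barcodes)
      if (!is.null(d$meta)) em <- attach_cell_meta(em, d$meta)
      if (is.null(em$cell_meta$dataset))
        em$cell_meta$dataset <- d$id %||% paste0("dataset", i)
      em
    })
  }

  # --- QC + CPM --------------------------------------------------------
  datasets <- lapply(datasets, function(em) {
    if (em$normalized == "counts") {
      em <- qc_filter(em, mito_prefix = qc_cfg$mito_prefix,
                      mito_max = qc_cfg$mito_max,
                      min_genes = qc_cfg$min_genes,
                      max_genes = qc_cfg$max_genes)
      em <- cpm_normalize(em)
    }
    em
  })

  # --- universe + harmonization ---------------------------------------
  if (!is.null(cfg$universe)) {
    uni <- read_universe(cfg$universe)
  } else {
    uni <- gene_universe(sort(unique(unlist(lapply(datasets,
                                                   `[[`, "gene_ids")))))
  }
  datasets <- lapply(datasets, function(em)
    suppressMessages(harmonize_universe(em, uni)))

  # --- networks --------------------------------------------------------
  nets <- lapply(datasets, build_network)
  net_dir <- file.path(out_dir, "networks")
  dir.create(net_dir, showWarnings = FALSE)
  for (i in seq_along(nets))
    write_network(nets[[i]], file.path(net_dir,
                                       sprintf("network_%02d.tsv", i)))
  agg <- aggregate_networks(nets)
  write_network(agg, file.path(out_dir, "aggregate_network.tsv"))

  # --- markers ---------------------------------------------------------
  marker_sets <- NULL
  loo <- NULL
  labeled <- all(vapply(datasets, function(em)
    !is.null(em$cell_meta$cell_type), logical(1)))
  if (labeled && length(datasets) >= 1) {
    stats_list <- lapply(datasets, compute_markers)
    mm <- make_meta_markers(stats_list, fc_threshold = mk_cfg$fc_threshold,
                            fdr_threshold = mk_cfg$fdr_threshold)
    utils::write.table(mm, file.path(out_dir, "meta_markers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    marker_sets <- top_meta_markers(mm, max(mk_cfg$top_k))
    write_gmt(marker_sets, file.path(out_dir, "marker_sets.gmt"))
    if (length(datasets) >= 2) {
      loo <- loo_cross_validate(datasets, k_list = mk_cfg$top_k,
                                stats_list = stats_list)
      utils::write.table(loo, file.path(out_dir, "loo_auroc.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  # --- module scores ---------------------------------------------------
  collection <- marker_sets %||% list()
  if (!is.null(cfg$gene_sets))
    collection <- c(collection, read_gmt(cfg$gene_sets))
  module_scores <- NULL
  if (length(collection)) {
    module_scores <- suppressMessages(
      score_gene_set_collection(agg, collection,
                                size_min = ms_cfg$size_min,
                                size_max = ms_cfg$size_max,
                                n_folds = ms_cfg$n_folds, seed = seed))
    utils::write.table(module_scores,
                       file.path(out_dir, "module_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- preservation ----------------------------------------------------
  preservation <- NULL
  if (!is.null(cfg$reference_network)) {
    ref <- read_network(cfg$reference_network)
    preservation <- suppressMessages(
      score_preservation(ref, agg, gene_sets = marker_sets,
                         k = pv_cfg$k))
    utils::write.table(
      data.frame(gene = names(preservation$gene_auroc),
                 auroc = unname(preservation$gene_auroc)),
      file.path(out_dir, "preservation_per_gene.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    message("no reference network configured; preservation stage skipped")
    log_lines <- c(log_lines, "preservation\tskipped (no reference)")
  }

  # --- summary ---------------------------------------------------------
  summary <- list(
    n_datasets = length(datasets),
    n_genes = length(uni$genes),
    n_cells = vapply(datasets, function(em) ncol(em$values), integer(1)),
    seed = seed)
  if (!is.null(loo))
    summary$loo_mean_auroc <- mean(loo$auroc)
  if (!is.null(module_scores)) {
    summary$module_score_mean <- attr(module_scores, "mean_auroc")
    summary$module_scores <- stats::setNames(as.list(module_scores$auroc),
                                             module_scores$set_id)
  }
  if (!is.null(preservation)) {
    summary$global_preservation_score <- preservation$global_score
    if (!is.null(preservation$set_scores))
      summary$set_preservation_scores <-
        as.list(preservation$set_scores)
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(summary = summary, out_dir = out_dir,
                 marker_map = marker_map))
}

#' Place cell-type scores within reference distributions
#'
#' For each scored cell-type present in the reference table, reports the
#' score, its percentile within the reference distribution (strictly-below
#' fraction, mid-rank for ties) and a summary of that distribution.
#' Cell-types missing from the reference are omitted with a notice. A
#' packaged table of synthetic reference distributions ships at
#' \code{system.file("extdata", "synthetic_reference_scores.tsv",
#' package = "coexfid")}.
#'
#' @param scores named numeric vector of cell-type scores.
#' @param reference_table data.frame with columns \code{cell_type} and
#'   \code{score}, or a path to such a TSV.
#' @param out_file optional path; when given the report is written as
#'   JSON.
#' @param plot when TRUE and ggplot2 is installed, also returns a
#'   reference-distribution plot with the query scores marked.
#' @return list of class \code{reference_report} (one entry per scored
#'   cell-type: \code{score}, \code{percentile}, \code{reference} summary);
#'   when \code{plot = TRUE} the ggplot object is attached as
#'   \code{attr(,"plot")}.
#' @export
render_reference_report <- function(scores, reference_table,
                                    out_file = NULL, plot = FALSE) {
  if (is.character(reference_table) && length(reference_table) == 1)
    reference_table <- utils::read.table(reference_table, sep = "\t",
                                         header = TRUE,
                                         stringsAsFactors = FALSE)
  if (!all(c("cell_type", "score") %in% colnames(reference_table)))
    stop("reference table needs `cell_type` and `score` columns")
  if (nrow(reference_table) == 0) stop("reference table is empty")
  if (is.null(names(scores))) stop("`scores` must be named by cell-type")
  report <- list()
  for (ct in names(scores)) {
    ref <- reference_table$score[reference_table$cell_type == ct]
    if (!length(ref)) {
      message("cell-type ", dQuote(ct),
              " absent from the reference table; omitted")
      next
    }
    report[[ct]] <- list(
      score = unname(scores[[ct]]),
      percentile = reference_percentile(scores[[ct]], ref),
      reference = list(n = length(ref), median = stats::median(ref),
                       min = min(ref), max = max(ref)))
  }
  if (!length(report))
    stop("no scored cell-type present in the reference table")
  class(report) <- "reference_report"
  if (!is.null(out_file))
    jsonlite::write_json(unclass(report), out_file, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  if (plot && requireNamespace("ggplot2", quietly = TRUE)) {
    df <- reference_table[reference_table$cell_type %in% names(report), ]
    qdf <- data.frame(cell_type = names(report),
                      score = vapply(report, `[[`, numeric(1), "score"))
    gg <- ggplot2::ggplot(df, ggplot2::aes(x = cell_type, y = score)) +
      ggplot2::geom_violin(fill = "grey85") +
      ggplot2::geom_jitter(width = 0.1, alpha = 0.4, size = 0.8) +
      ggplot2::geom_point(data = qdf, colour = "red", size = 3,
                          shape = 95) +
      ggplot2::labs(x = NULL, y = "preserved co-expression score") +
      ggplot2::theme_minimal()
    attr(report, "plot") <- gg
  }
  report
}

#' @export
print.reference_report <- function(x, ...) {
  cat("<reference_report>\n")
  for (ct in names(x))
    cat(sprintf("  %-22s score %.3f  percentile %5.1f (ref n=%d)\n",
                ct, x[[ct]]$score, x[[ct]]$percentile,
                x[[ct]]$reference$n))
  invisible(x)
}

#' Load a reference report from JSON
#'
#' @param path JSON written by [render_reference_report].
#' @return a \code{reference_report} list.
#' @export
read_reference_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  class(rep) <- "reference_report"
  rep
}
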