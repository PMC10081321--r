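#' Simulation configuration for synthetic scRNA-seq datasets
#'
#' Defines a dataset of \code{n_cell_types} cell populations, each with a
#' disjoint block of \code{markers_per_type} marker genes elevated
#' \code{effect_size}-fold in its own population. Marker genes of a cell's
#' own type additionally share a per-cell latent program activity
#' (gamma-distributed, mean 1), which induces correlated within-program
#' expression — the structure that co-expression networks are meant to
#' detect. Counts follow a negative-binomial observation model at a mean
#' sequencing depth of \code{depth} counts per cell.
#'
#' @param n_cell_types number of cell populations (default 5).
#' @param cells_per_type cells per population (default 300).
#' @param n_genes total genes (default 2000).
#' @param markers_per_type planted markers per population (default 50).
#' @param effect_size mean fold elevation of a population's markers
#'   (default 32; 1 disables differential expression).
#' @param activity_sd standard deviation of the per-cell program activity
#'   multiplier (default 0.5; 0 disables the co-expression signal beyond
#'   the shared on/off pattern).
#' @param depth mean total counts per cell (default 10000).
#' @param depth_sd lognormal sd of per-cell depth variation (default 0.2).
#' @param dispersion negative-binomial dispersion, i.e. 1/size
#'   (default 0.5).
#' @param seed integer seed.
#' @return a \code{simulation_config} list.
#' @export
simulation_config <- function(n_cell_types = 5, cells_per_type = 300,
                              n_genes = 2000, markers_per_type = 50,
                              effect_size = 32, activity_sd = 0.5,
                              depth = 10000, depth_sd = 0.2,
                              dispersion = 0.5, seed = 1) {
  if (markers_per_type * n_cell_types > n_genes)
    stop("markers_per_type x n_cell_types (",
         markers_per_type * n_cell_types,
         ") exceeds n_genes (", n_genes, ")")
  if (effect_size < 1) stop("effect_size must be >= 1")
  if (dispersion <= 0) stop("dispersion must be positive")
  structure(list(n_cell_types = n_cell_types,
                 cells_per_type = cells_per_type,
                 n_genes = n_genes, markers_per_type = markers_per_type,
                 effect_size = effect_size, activity_sd = activity_sd,
                 depth = depth, depth_sd = depth_sd,
                 dispersion = dispersion, seed = seed),
            class = "simulation_config")
}

#' Simulate a labeled scRNA-seq dataset with planted marker programs
#'
#' Draws counts from the negative-binomial model described in
#' [simulation_config]. Baseline gene abundances are lognormal; for a
#' cell of type t, the type's marker genes are elevated
#' \code{effect_size}-fold and multiplied by the cell's latent program
#' activity; per-gene means are renormalized into relative abundances and
#' scaled by the cell's sequencing depth. Marker blocks are disjoint
#' across cell-types by construction. The ground-truth marker map is
#' returned with the data so downstream tests never re-derive it.
#'
#' @param cfg a [simulation_config].
#' @param dataset_id identifier stored in the cell metadata (default
#'   derived from the seed).
#' @return an [expression_matrix] of raw counts with \code{cell_type} and
#'   \code{dataset} metadata and attribute \code{marker_map}: a named
#'   list mapping each cell-type to its planted marker genes.
#' @export
simulate_dataset <- function(cfg, dataset_id = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (is.null(dataset_id)) dataset_id <- paste0("sim_seed", cfg$seed)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(cfg$seed)
  g <- cfg$n_genes
  types <- paste0("type", seq_len(cfg$n_cell_types))
  gene_ids <- sprintf("g%04d", seq_len(g))
  marker_map <- stats::setNames(lapply(seq_len(cfg$n_cell_types), function(t)
    gene_ids[((t - 1) * cfg$markers_per_type + 1):(t * cfg$markers_per_type)]),
    types)
  base <- stats::rlnorm(g, meanlog = 0, sdlog = 1)
  n_cells <- cfg$n_cell_types * cfg$cells_per_type
  cell_type <- rep(types, each = cfg$cells_per_type)
  depth_c <- stats::rlnorm(n_cells, log(cfg$depth) - cfg$depth_sd^2 / 2,
                           cfg$depth_sd)
  activity <- if (cfg$activity_sd > 0) {
    shape <- 1 / cfg$activity_sd^2
    stats::rgamma(n_cells, shape = shape, rate = shape)
  } else rep(1, n_cells)
  counts <- matrix(0L, nrow = g, ncol = n_cells)
  size <- 1 / cfg$dispersion
  for (c_i in seq_len(n_cells)) {
    mu <- base
    mk <- match(marker_map[[cell_type[c_i]]], gene_ids)
    mu[mk] <- mu[mk] * cfg$effect_size * activity[c_i]
    mu <- mu / sum(mu) * depth_c[c_i]
    counts[, c_i] <- stats::rnbinom(g, mu = mu, size = size)
  }
  meta <- data.frame(barcode = sprintf("cell_%05d", seq_len(n_cells)),
                     dataset = dataset_id, cell_type = cell_type,
                     stringsAsFactors = FALSE)
  colnames(counts) <- meta$barcode
  em <- expression_matrix(counts, gene_ids, cell_meta = meta,
                          normalized = "counts")
  attr(em, "marker_map") <- marker_map
  em
}

#' Simulate a reference/test network pair with tunable preservation
#'
#' Builds a reference network with planted co-expression modules and a
#' test network in which each module gene's reference neighborhood is
#' retained with probability \code{p} and otherwise rewired to random
#' partners. Both networks share the same background noise matrix and are
#' rank-standardized, so at \code{p = 1} the raw matrices coincide exactly
#' (preservation 1 by construction) while at \code{p = 0} module
#' neighborhoods carry no information about the reference.
#'
#' @param n_genes number of genes.
#' @param modules either an integer vector of module sizes or a list of
#'   gene-index vectors; remaining genes are unstructured background.
#' @param p preservation probability in \[0, 1\].
#' @param seed integer seed.
#' @param rewire_k partners drawn for a rewired gene (default: its module
#'   size minus 1).
#' @return list with elements \code{ref} and \code{test}
#'   ([coexpression_network] objects), \code{modules} (named list of gene
#'   ids per module) and \code{kept} (logical per module gene).
#' @export
simulate_network_pair <- function(n_genes, modules = c(11, 11, 11), p,
                                  seed = 1, rewire_k = NULL) {
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  if (is.numeric(modules) && !is.list(modules)) {
    sizes <- as.integer(modules)
    if (sum(sizes) > n_genes)
      stop("modules larger than n_genes (", sum(sizes), " > ", n_genes, ")")
    start <- cumsum(c(1L, utils::head(sizes, -1)))
    modules <- lapply(seq_along(sizes), function(i)
      seq(start[i], length.out = sizes[i]))
  }
  if (any(vapply(modules, max, numeric(1)) > n_genes))
    stop("module gene index exceeds n_genes")
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  noise <- matrix(stats::runif(n_genes^2), n_genes)
  noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
  diag(noise) <- 1
  # per-gene partner boosts: gene i lifts its partners' entries into (1, 2)
  boost_entries <- function(m, partners_of, values_of) {
    for (i in names(partners_of)) {
      gi <- as.integer(i)
      pj <- partners_of[[i]]
      m[gi, pj] <- pmax(m[gi, pj], values_of[[i]])
      m[pj, gi] <- m[gi, pj]
    }
    m
  }
  module_genes <- unlist(modules, use.names = FALSE)
  ref_partners <- list()
  ref_values <- list()
  for (mod in modules) {
    for (gidx in mod) {
      key <- as.character(gidx)
      ref_partners[[key]] <- setdiff(mod, gidx)
      ref_values[[key]] <- 1 + stats::runif(length(mod) - 1)
    }
  }
  ref_raw <- boost_entries(noise, ref_partners, ref_values)
  kept <- stats::runif(length(module_genes)) < p
  names(kept) <- as.character(module_genes)
  test_partners <- list()
  test_values <- list()
  for (key in names(ref_partners)) {
    if (kept[[key]]) {
      test_partners[[key]] <- ref_partners[[key]]
      test_values[[key]] <- ref_values[[key]]
    } else {
      kk <- if (is.null(rewire_k)) length(ref_partners[[key]]) else rewire_k
      test_partners[[key]] <- sample(setdiff(seq_len(n_genes),
                                             as.integer(key)), kk)
      test_values[[key]] <- 1 + stats::runif(kk)
    }
  }
  test_raw <- boost_entries(noise, test_partners, test_values)
  dimnames(ref_raw) <- dimnames(test_raw) <- list(gene_ids, gene_ids)
  module_ids <- lapply(modules, function(m) gene_ids[m])
  names(module_ids) <- paste0("module", seq_along(modules))
  list(ref = rank_standardize(ref_raw),
       test = rank_standardize(test_raw),
       modules = module_ids,
       kept = kept)
}
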