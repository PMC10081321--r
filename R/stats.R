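#' Closed-form z statistics for a gene-set preservation score
#'
#' Mean-sample-error machinery shared by [go_preservation_ztest]: given a
#' term's mean AUROC, its size, and the population mean and population
#' standard deviation (computed with the population formula, i.e. divided
#' by n), returns the standard error \code{SE = sd_pop / sqrt(n_go)}, the
#' z-score \code{(mu_go - mu_pop) / SE}, and the left/right one-sided
#' normal p-values (which sum to 1 exactly).
#'
#' @param mu_go term mean score.
#' @param n_go term size.
#' @param mu_pop,sd_pop population mean and population SD.
#' @return list with \code{se}, \code{z}, \code{p_left}, \code{p_right}.
#' @export
ztest_stats <- function(mu_go, n_go, mu_pop, sd_pop) {
  if (sd_pop <= 0) stop("degenerate population: SD must be positive")
  se <- sd_pop / sqrt(n_go)
  z <- (mu_go - mu_pop) / se
  p_left <- stats::pnorm(z)
  list(se = se, z = z, p_left = p_left, p_right = 1 - p_left)
}

# population (divide-by-n) standard deviation
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Gene-set preservation z-test
#'
#' Tests, for every gene set (typically GO terms), whether its mean
#' preserved co-expression AUROC differs from the population of all scored
#' genes by more than sampling error. The population mean and population
#' standard deviation are taken over the full per-gene AUROC vector; each
#' term's score is compared via \code{Z = (mu_GO - mu_pop) / SE} with
#' \code{SE = SD_pop / sqrt(n_GO)}. Left-tail significance marks terms
#' with significantly weaker preservation, right-tail significantly
#' stronger. BH adjustment is applied over the surviving terms, separately
#' per tail; terms outside the size window after intersection with the
#' scored namespace are excluded.
#'
#' @param per_gene_auroc named numeric vector of per-gene preservation
#'   AUROCs (e.g. \code{$gene_auroc} of a [score_preservation] result).
#' @param terms named list of gene sets.
#' @param size_min,size_max inclusive size window (defaults 20 and 250).
#' @param alpha FDR threshold used for the significance flags
#'   (default 1e-4).
#' @return data.frame with one row per surviving term: \code{term},
#'   \code{n_genes}, \code{mu_go}, \code{mu_pop}, \code{sd_pop},
#'   \code{se}, \code{z}, \code{p_left}, \code{p_right},
#'   \code{fdr_left}, \code{fdr_right}, \code{significant_preserved},
#'   \code{significant_not_preserved}.
#' @export
go_preservation_ztest <- function(per_gene_auroc, terms, size_min = 20,
                                  size_max = 250, alpha = 1e-4) {
  if (is.null(names(per_gene_auroc)))
    stop("`per_gene_auroc` must be a named vector")
  if (!length(terms) || is.null(names(terms)))
    stop("`terms` must be a non-empty named list")
  mu <- mean(per_gene_auroc)
  sdp <- sd_pop(per_gene_auroc)
  if (sdp == 0) stop("degenerate population: all per-gene AUROCs identical")
  members <- lapply(terms, function(g)
    intersect(unique(g), names(per_gene_auroc)))
  sizes <- lengths(members)
  keep <- sizes >= size_min & sizes <= size_max
  if (!any(keep))
    stop("no term falls inside the size window [", size_min, ", ",
         size_max, "]")
  members <- members[keep]
  res <- do.call(rbind, lapply(names(members), function(tm) {
    mg <- mean(per_gene_auroc[members[[tm]]])
    zs <- ztest_stats(mg, length(members[[tm]]), mu, sdp)
    data.frame(term = tm, n_genes = length(members[[tm]]), mu_go = mg,
               mu_pop = mu, sd_pop = sdp, se = zs$se, z = zs$z,
               p_left = zs$p_left, p_right = zs$p_right,
               stringsAsFactors = FALSE)
  }))
  res$fdr_left <- stats::p.adjust(res$p_left, method = "BH")
  res$fdr_right <- stats::p.adjust(res$p_right, method = "BH")
  res$significant_preserved <- res$fdr_right <= alpha
  res$significant_not_preserved <- res$fdr_left <= alpha
  rownames(res) <- NULL
  res
}

#' Permutation test for a correlation coefficient
#'
#' Computes the observed correlation and a two-sided permutation p-value:
#' the pairing of the two vectors is permuted \code{n_perm} times and the
#' p-value is the fraction of permuted coefficients whose absolute value
#' is at least the observed absolute value. By default the uncorrected
#' count/n_perm estimate is reported (which can be exactly 0); set
#' \code{corrected = TRUE} for the (b+1)/(B+1) variant.
#'
#' The same sampled permutations are used whichever vector is designated
#' by \code{permute}: permuting \code{x} applies the inverse of each
#' sampled permutation, which yields exactly the same coefficient as
#' permuting \code{y}, so the p-value is bit-identical either way.
#'
#' @param x,y numeric vectors of equal length (n >= 3), both non-constant.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @param method \code{"spearman"} (default) or \code{"pearson"}.
#' @param corrected use the (b+1)/(B+1) p-value estimate.
#' @param permute which vector is nominally permuted (result-invariant).
#' @return list with \code{rho}, \code{p_value}, \code{n_perm},
#'   \code{method}.
#' @export
permutation_corr_test <- function(x, y, n_perm = 10000, seed = 1,
                                  method = c("spearman", "pearson"),
                                  corrected = FALSE,
                                  permute = c("y", "x")) {
  method <- match.arg(method)
  permute <- match.arg(permute)
  if (length(x) != length(y)) stop("x and y differ in length")
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop("NA values not supported")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: correlation undefined")
  if (method == "spearman") {
    x <- rank(x); y <- rank(y)
  }
  rho <- stats::cor(x, y)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  perms <- replicate(n_perm, sample.int(n))
  xc <- x - mean(x)
  yc <- y - mean(y)
  denom <- sqrt(sum(xc^2) * sum(yc^2))
  # rho_b = cor(x, y[s_b]); permuting x by the inverse permutation gives
  # cor(x[inv(s_b)], y) == cor(x, y[s_b]), so both choices reduce to the
  # same computation and the p-value is bit-identical either way
  ymat <- matrix(yc[perms], nrow = n)
  rho_perm <- as.vector(crossprod(xc, ymat)) / denom
  hits <- sum(abs(rho_perm) >= abs(rho))
  p <- if (corrected) (hits + 1) / (n_perm + 1) else hits / n_perm
  list(rho = rho, p_value = p, n_perm = n_perm, method = method)
}

#' Rank-sum comparison of score groups with BH adjustment
#'
#' Runs a two-sided Mann-Whitney (Wilcoxon rank-sum) test for each named
#' comparison and BH-adjusts the p-values across the submitted family.
#' The exact p-value is used when the smaller group has at most 8
#' observations and there are no ties; otherwise the normal approximation
#' with continuity correction.
#'
#' @param comparisons named list; each element a list (or unnamed list of
#'   two) with numeric vectors \code{a} and \code{b}.
#' @param alpha FDR threshold for the significance flag (default 0.05).
#' @return data.frame with columns \code{comparison}, \code{n_a},
#'   \code{n_b}, \code{statistic}, \code{p_value}, \code{fdr},
#'   \code{significant}.
#' @export
compare_groups <- function(comparisons, alpha = 0.05) {
  if (!length(comparisons) || is.null(names(comparisons)))
    stop("`comparisons` must be a non-empty named list")
  rows <- lapply(names(comparisons), function(nm) {
    cmp <- comparisons[[nm]]
    a <- if (!is.null(cmp$a)) cmp$a else cmp[[1]]
    b <- if (!is.null(cmp$b)) cmp$b else cmp[[2]]
    if (!length(a) || !length(b))
      stop("comparison ", dQuote(nm), " has an empty group")
    ties <- anyDuplicated(c(a, b)) > 0
    exact <- min(length(a), length(b)) <= 8 && !ties
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, exact = exact, correct = TRUE))
    data.frame(comparison = nm, n_a = length(a), n_b = length(b),
               statistic = unname(wt$statistic), p_value = wt$p.value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$fdr <- stats::p.adjust(res$p_value, method = "BH")
  res$significant <- res$fdr <= alpha
  rownames(res) <- NULL
  res
}

#' Hypergeometric gene-set enrichment
#'
#' Fisher's-exact-style enrichment of a hit list against a gene universe:
#' for each term, the upper-tail hypergeometric probability
#' \code{P(X >= overlap)} with the universe as population, the term's
#' in-universe members as successes and the hit list as draws. Raw
#' p-values are computed for terms inside \code{test_size}; BH adjustment
#' runs over those tested terms; ranking/reporting (the \code{in_report}
#' flag) is additionally restricted to \code{report_size}.
#'
#' @param hit_set character vector; must be a subset of \code{universe}.
#' @param universe character vector of all considered genes.
#' @param terms named list of gene sets.
#' @param test_size inclusive size window for testing
#'   (default \code{c(10, 1000)}).
#' @param report_size inclusive size window for reporting
#'   (default \code{c(20, 500)}).
#' @return data.frame sorted by FDR then p, with columns \code{term},
#'   \code{n_term}, \code{n_overlap}, \code{expected}, \code{p_value},
#'   \code{fdr}, \code{in_report}.
#' @export
go_enrichment <- function(hit_set, universe, terms,
                          test_size = c(10, 1000),
                          report_size = c(20, 500)) {
  hit_set <- unique(hit_set)
  universe <- unique(universe)
  bad <- setdiff(hit_set, universe)
  if (length(bad))
    stop("hit gene(s) outside the universe: ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "")
  if (!length(terms) || is.null(names(terms)))
    stop("`terms` must be a non-empty named list")
  members <- lapply(terms, function(g) intersect(unique(g), universe))
  sizes <- lengths(members)
  tested <- sizes >= test_size[1] & sizes <= test_size[2]
  if (!any(tested)) stop("no term inside the testing size window")
  members <- members[tested]
  sizes <- sizes[tested]
  n_u <- length(universe)
  n_h <- length(hit_set)
  ov <- vapply(members, function(g) length(intersect(g, hit_set)),
               integer(1))
  p <- stats::phyper(ov - 1, sizes, n_u - sizes, n_h, lower.tail = FALSE)
  res <- data.frame(term = names(members), n_term = sizes,
                    n_overlap = ov,
                    expected = n_h * sizes / n_u,
                    p_value = p,
                    stringsAsFactors = FALSE)
  res$fdr <- stats::p.adjust(res$p_value, method = "BH")
  res$in_report <- res$n_term >= report_size[1] &
    res$n_term <= report_size[2]
  res <- res[order(res$fdr, res$p_value, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}
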