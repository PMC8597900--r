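#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic with a chi-square reference on g - 1 degrees of
#' freedom (wrapper around `stats::kruskal.test` with input checks). When all
#' values are identical the statistic is 0 and p is reported as 1.
#'
#' @param values numeric vector.
#' @param group_labels grouping vector of the same length, >= 2 non-empty
#'   groups.
#' @return tibble with `statistic`, `df`, `p`.
#' @export
kruskal_wallis <- function(values, group_labels) {
  group_labels <- as.factor(group_labels)
  if (nlevels(droplevels(group_labels)) < 2L) {
    stop("need at least 2 non-empty groups", call. = FALSE)
  }
  if (stats::var(values) == 0) {
    return(tibble::tibble(statistic = 0,
                          df = nlevels(droplevels(group_labels)) - 1L, p = 1))
  }
  kt <- stats::kruskal.test(values, group_labels)
  tibble::tibble(statistic = unname(kt$statistic),
                 df = unname(kt$parameter),
                 p = kt$p.value)
}

#' One-way ANOVA
#'
#' Parametric alternative to [kruskal_wallis()] with the same interface.
#'
#' @inheritParams kruskal_wallis
#' @return tibble with `statistic` (F), `df` (between-groups), `p`.
#' @export
one_way_anova <- function(values, group_labels) {
  group_labels <- as.factor(group_labels)
  if (nlevels(droplevels(group_labels)) < 2L) {
    stop("need at least 2 non-empty groups", call. = FALSE)
  }
  fit <- stats::oneway.test(values ~ group_labels, var.equal = TRUE)
  tibble::tibble(statistic = unname(fit$statistic),
                 df = unname(fit$parameter[1L]),
                 p = fit$p.value)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return scalar rho.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("need equal-length vectors with n >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Spearman correlation undefined for a constant vector", call. = FALSE)
  }
  stats::cor(x, y, method = "spearman")
}

#' Sample distance correlation
#'
#' Szekely-Rizzo distance correlation from doubly-centered pairwise distance
#' matrices (O(n^2) memory). Zero if and only if (asymptotically) the two
#' variables are independent; by convention 0 for a constant vector.
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @return scalar in \[0, 1\].
#' @export
distance_correlation <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 4L) {
    stop("need equal-length vectors with n >= 4", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    message("constant vector: distance correlation set to 0 by convention")
    return(0)
  }
  dc_center <- function(v) {
    d <- as.matrix(stats::dist(v))
    d - outer(rowMeans(d), colMeans(d), "+") + mean(d)
  }
  A <- dc_center(x)
  B <- dc_center(y)
  dcov2 <- mean(A * B)
  dvarx <- mean(A * A)
  dvary <- mean(B * B)
  if (dvarx <= 0 || dvary <= 0) return(0)
  sqrt(dcov2 / sqrt(dvarx * dvary))
}

#' Hypergeometric over-representation analysis
#'
#' One-sided upper-tail hypergeometric test of each gene set against a hit
#' list within a universe, BH-adjusted across sets. Sets are intersected with
#' the universe before testing.
#'
#' @param genes hit genes (subset of `universe`).
#' @param universe background gene ids.
#' @param sets named list of gene-id vectors (e.g. from [read_gmt()]).
#' @return tibble with one row per set: `set_name`, `overlap`, `set_size`,
#'   `universe_size`, `hits_in_universe`, `p`, `fdr`.
#' @export
hypergeom_enrichment <- function(genes, universe, sets) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  genes <- unique(intersect(genes, universe))
  rows <- purrr::map_dfr(names(sets), function(nm) {
    set_u <- intersect(unique(sets[[nm]]), universe)
    ov <- length(intersect(set_u, genes))
    # P(X >= ov) for X ~ Hypergeom(hits, universe - hits, draws = |set|)
    p <- stats::phyper(ov - 1L, length(genes),
                       length(universe) - length(genes),
                       length(set_u), lower.tail = FALSE)
    tibble::tibble(set_name = nm, overlap = ov, set_size = length(set_u),
                   universe_size = length(universe),
                   hits_in_universe = length(genes), p = p)
  })
  rows$fdr <- bh_adjust(rows$p)
  rows
}
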