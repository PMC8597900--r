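#' Empirical-Bayes moderated two-sample t-test
#'
#' Per gene: `log_fc = mean_a - mean_b`; the pooled residual variance
#' `s2_g` (df `d_g = n_a + n_b - 2`) is shrunk toward a prior `(d0, s0^2)`
#' estimated by moment-matching a scaled-F distribution to the observed
#' variances (the limma empirical-Bayes prior); the posterior variance is
#' `(d0*s0^2 + d_g*s2_g) / (d0 + d_g)` and the moderated t uses `d0 + d_g`
#' degrees of freedom. Setting `prior_df = 0` turns shrinkage off and gives
#' the ordinary pooled-variance t-test.
#'
#' @param x expression matrix (log2 scale recommended).
#' @param group_a,group_b disjoint character vectors of sample ids, each with
#'   at least 2 samples.
#' @param prior_df optional override of the prior degrees of freedom `d0`
#'   (`NULL` = estimate from the data; `0` = ordinary t; `Inf` = fully
#'   pooled variance `s0^2`).
#' @return a tibble with one row per gene: `gene_id`, `log_fc`, `mean_expr`,
#'   `t_mod`, `p`, `q` (BH-adjusted), `df_prior`, `s2_prior`.
#' @export
moderated_t_test <- function(x, group_a, group_b, prior_df = NULL) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("both groups need at least 2 samples", call. = FALSE)
  }
  if (length(intersect(group_a, group_b)) > 0L) {
    stop("groups must be disjoint", call. = FALSE)
  }
  missing <- setdiff(c(group_a, group_b), colnames(x))
  if (length(missing)) {
    stop("samples absent from matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  xa <- x[, group_a, drop = FALSE]
  xb <- x[, group_b, drop = FALSE]
  na <- ncol(xa); nb <- ncol(xb)
  dg <- na + nb - 2L
  if (dg < 1L) stop("zero residual degrees of freedom", call. = FALSE)

  ma <- rowMeans(xa); mb <- rowMeans(xb)
  log_fc <- ma - mb
  ssa <- rowSums((xa - ma)^2)
  ssb <- rowSums((xb - mb)^2)
  s2 <- (ssa + ssb) / dg

  if (is.null(prior_df)) {
    sq <- limma::squeezeVar(s2, df = dg)
    d0 <- sq$df.prior
    s02 <- sq$var.prior
    s2_post <- sq$var.post
  } else if (prior_df == 0) {
    d0 <- 0; s02 <- NA_real_; s2_post <- s2
  } else if (is.infinite(prior_df)) {
    fit <- limma::fitFDist(s2, df1 = dg)
    d0 <- Inf; s02 <- fit$scale
    s2_post <- rep(s02, length(s2))
  } else {
    fit <- limma::fitFDist(s2, df1 = dg)
    d0 <- prior_df; s02 <- fit$scale
    s2_post <- (d0 * s02 + dg * s2) / (d0 + dg)
  }

  se <- sqrt(s2_post * (1 / na + 1 / nb))
  t_mod <- ifelse(se > 0, log_fc / se, 0)
  df_total <- if (is.infinite(d0)) Inf else d0 + dg
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  p[se == 0 & log_fc == 0] <- 1

  tibble::tibble(
    gene_id = rownames(x),
    log_fc = unname(log_fc),
    mean_expr = unname((ma * na + mb * nb) / (na + nb)),
    t_mod = unname(t_mod),
    p = unname(p),
    q = bh_adjust(unname(p)),
    df_prior = if (length(d0) == 1L) rep(unname(d0), nrow(x)) else unname(d0),
    s2_prior = rep(unname(s02)[1L], nrow(x))
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement, order-preserving in
#' the original indexing (a validated wrapper around `p.adjust`).
#'
#' @param p vector of p-values in \[0, 1\].
#' @return vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Phenotype-associated differential genes across clusters
#'
#' One-vs-rest moderated t-tests per cluster; a gene is phenotype-associated
#' if it is significant in at least one comparison. The "any comparison"
#' evidence per gene is its Bonferroni-corrected minimum p across the
#' one-vs-rest tests, BH-adjusted across genes, so the reported discovery set
#' controls a gene-level false-discovery rate at `adj_p_threshold`.
#' Per-comparison provenance is returned alongside.
#'
#' @param x expression matrix (log2 scale).
#' @param cluster_labels named vector (sample id -> cluster) covering at least
#'   two clusters with >= 2 samples each.
#' @param adj_p_threshold BH-adjusted p cutoff.
#' @param combine `"union"` (default) across one-vs-rest comparisons, or
#'   `"intersection"`.
#' @return a list with `genes` (character vector) and `detail` (tibble of all
#'   per-comparison DE rows with a `comparison` column).
#' @export
phenotype_degs <- function(x, cluster_labels, adj_p_threshold = 0.05,
                           combine = c("union", "intersection")) {
  combine <- match.arg(combine)
  cluster_labels <- cluster_labels[names(cluster_labels) %in% colnames(x)]
  tab <- table(cluster_labels)
  if (length(tab) < 2L) stop("need at least 2 clusters", call. = FALSE)
  if (any(tab < 2L)) stop("every cluster needs >= 2 samples", call. = FALSE)

  per_cluster <- purrr::map(names(tab), function(k) {
    in_k <- names(cluster_labels)[cluster_labels == k]
    rest <- names(cluster_labels)[cluster_labels != k]
    de <- moderated_t_test(x, in_k, rest)
    de$comparison <- paste0(k, "_vs_rest")
    de
  })
  detail <- dplyr::bind_rows(per_cluster)
  # per-gene "any comparison" evidence: Bonferroni over the one-vs-rest
  # minimum p, then BH across genes -> gene-level FDR at the threshold
  n_comp <- length(per_cluster)
  gene_tab <- dplyr::summarise(
    dplyr::group_by(detail, .data$gene_id),
    p_any = min(1, n_comp * min(.data$p)),
    p_all = max(.data$p),
    .groups = "drop")
  gene_tab$q_any <- bh_adjust(gene_tab$p_any)
  gene_tab$q_all <- bh_adjust(gene_tab$p_all)
  genes <- if (combine == "union") {
    gene_tab$gene_id[gene_tab$q_any < adj_p_threshold]
  } else {
    # significant in every comparison: max p, BH across genes
    gene_tab$gene_id[gene_tab$q_all < adj_p_threshold]
  }
  list(genes = sort(genes), detail = detail, gene_tests = gene_tab)
}

#' Differential genes between score groups
#'
#' Up/down gene lists between a high and a low group using strict thresholds
#' on the moderated-t fold change and the unadjusted p-value.
#'
#' @param x expression matrix (log2 scale).
#' @param group_high,group_low sample id vectors.
#' @param lfc_threshold absolute log2 fold-change cutoff (strict inequality).
#' @param p_threshold unadjusted p cutoff (strict inequality).
#' @return list with `up`, `down` (character vectors) and `detail` (tibble).
#' @export
score_group_degs <- function(x, group_high, group_low,
                             lfc_threshold = log2(1.2), p_threshold = 0.05) {
  de <- moderated_t_test(x, group_high, group_low)
  list(
    up = de$gene_id[de$log_fc > lfc_threshold & de$p < p_threshold],
    down = de$gene_id[de$log_fc < -lfc_threshold & de$p < p_threshold],
    detail = de
  )
}
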