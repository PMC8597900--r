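#' Screen candidate genes by univariate Cox regression
#'
#' Fits [cox_univariate()] to each candidate gene's expression against
#' survival and retains genes with Wald p below `p_threshold` (the prognostic
#' screen behind the 49-gene signature construction). Genes with constant
#' expression are skipped with a message.
#'
#' @param candidate_genes character vector of gene ids present in `expr`.
#' @param clinical clinical tibble with `sample_id`, `os_time`, `os_event`.
#' @param expr expression matrix (log2 scale recommended).
#' @param p_threshold Wald p cutoff (strict inequality).
#' @return list with `genes` (retained gene ids) and `detail` (tibble of
#'   per-gene Cox results, including the excluded genes).
#' @export
select_signature_genes <- function(candidate_genes, clinical, expr,
                                   p_threshold = 0.01) {
  missing <- setdiff(candidate_genes, rownames(expr))
  if (length(missing)) {
    stop("candidate genes absent from matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  surv <- dplyr::filter(clinical, !is.na(.data$os_time), !is.na(.data$os_event),
                        .data$sample_id %in% colnames(expr))
  if (nrow(surv) < 10L || sum(surv$os_event) < 2L) {
    stop("insufficient survival data for the Cox screen", call. = FALSE)
  }
  xs <- expr[candidate_genes, surv$sample_id, drop = FALSE]
  n_const <- 0L
  detail <- purrr::map_dfr(candidate_genes, function(g) {
    v <- xs[g, ]
    if (stats::sd(v) == 0) {
      n_const <<- n_const + 1L
      return(tibble::tibble(gene_id = g, beta = NA_real_, hr = NA_real_,
                            se = NA_real_, z = NA_real_, p = NA_real_,
                            n_events = sum(surv$os_event), converged = FALSE))
    }
    res <- cox_univariate(surv$os_time, surv$os_event, v)
    dplyr::bind_cols(tibble::tibble(gene_id = g), res)
  })
  if (n_const > 0L) message(n_const, " constant-expression gene(s) skipped")
  genes <- detail$gene_id[!is.na(detail$p) & detail$p < p_threshold]
  if (length(genes) == 0L) {
    stop("no gene passed the Cox screen at p < ", p_threshold,
         "; consider relaxing the threshold", call. = FALSE)
  }
  list(genes = genes, detail = detail)
}

#' Fit the PCA score model
#'
#' Restricts the matrix to the signature genes, z-scores gene rows with
#' training statistics, and takes the first two principal components in gene
#' space via singular value decomposition. Loading signs are fixed so the
#' largest-magnitude loading of each component is positive, making scores
#' reproducible across linear-algebra backends.
#'
#' @param expr expression matrix (log2 scale recommended) containing the
#'   signature genes; >= 3 samples.
#' @param signature_genes >= 3 gene ids.
#' @return an object of class `score_model`: list with `signature_genes`,
#'   `center`, `scale` (per-gene training statistics), `loadings_pc1`,
#'   `loadings_pc2` (unit-norm, orthogonal), `explained_variance` (fractions
#'   for PC1, PC2), `sign_convention`.
#' @export
fit_score_model <- function(expr, signature_genes) {
  signature_genes <- unique(signature_genes)
  if (length(signature_genes) < 3L) stop("need >= 3 signature genes", call. = FALSE)
  if (ncol(expr) < 3L) stop("need >= 3 samples", call. = FALSE)
  missing <- setdiff(signature_genes, rownames(expr))
  if (length(missing)) {
    stop("signature genes absent from matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  x <- expr[signature_genes, , drop = FALSE]
  center <- rowMeans(x)
  scale <- apply(x, 1L, stats::sd)
  if (any(scale == 0)) {
    stop("zero-variance signature gene(s): ",
         paste(utils::head(signature_genes[scale == 0], 5L), collapse = ", "),
         call. = FALSE)
  }
  z <- (x - center) / scale                      # genes x samples, row-standardized
  sv <- svd(t(z))                                # samples x genes; v = gene loadings
  if (length(sv$d) < 2L || sv$d[2L] <= sqrt(.Machine$double.eps) * sv$d[1L]) {
    stop("fewer than 2 non-degenerate principal components", call. = FALSE)
  }
  l1 <- sv$v[, 1L]
  l2 <- sv$v[, 2L]
  s1 <- sign(l1[which.max(abs(l1))]); if (s1 == 0) s1 <- 1
  s2 <- sign(l2[which.max(abs(l2))]); if (s2 == 0) s2 <- 1
  l1 <- l1 * s1
  l2 <- l2 * s2
  names(l1) <- names(l2) <- signature_genes
  ev <- sv$d^2 / sum(sv$d^2)
  structure(list(
    signature_genes = signature_genes,
    center = center, scale = scale,
    loadings_pc1 = l1, loadings_pc2 = l2,
    explained_variance = c(pc1 = ev[1L], pc2 = ev[2L]),
    sign_convention = "largest-|loading| positive per component"
  ), class = "score_model")
}

#' @export
print.score_model <- function(x, ...) {
  cat(sprintf("PCA score model: %d signature genes; PC1 %.1f%%, PC2 %.1f%% variance\n",
              length(x$signature_genes), 100 * x$explained_variance[["pc1"]],
              100 * x$explained_variance[["pc2"]]))
  invisible(x)
}

#' @rdname fit_score_model
#' @param x,object a `score_model`.
#' @param ... unused.
#' @export
tidy.score_model <- function(x, ...) {
  tibble::tibble(gene_id = x$signature_genes,
                 center = unname(x$center),
                 scale = unname(x$scale),
                 loading_pc1 = unname(x$loadings_pc1),
                 loading_pc2 = unname(x$loadings_pc2))
}

#' @rdname fit_score_model
#' @export
glance.score_model <- function(x, ...) {
  tibble::tibble(n_genes = length(x$signature_genes),
                 explained_variance_pc1 = x$explained_variance[["pc1"]],
                 explained_variance_pc2 = x$explained_variance[["pc2"]],
                 sign_convention = x$sign_convention)
}

#' Compute the per-sample m5C score
#'
#' Standardizes each signature gene with the model's training center/scale and
#' returns, per sample, the sum of its PC1 and PC2 coordinates:
#' `score_s = sum_i (PC1_i + PC2_i) * z_is`. A sample sitting at the training
#' mean of every gene scores exactly 0; training-set scores are mean zero.
#'
#' @param model a [fit_score_model()] result.
#' @param expr expression matrix containing all model genes (same scale as
#'   training).
#' @return tibble with `sample_id`, `m5c_score`.
#' @export
compute_m5c_score <- function(model, expr) {
  stopifnot(inherits(model, "score_model"))
  missing <- setdiff(model$signature_genes, rownames(expr))
  if (length(missing)) {
    stop("model genes absent from matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  z <- (expr[model$signature_genes, , drop = FALSE] - model$center) / model$scale
  score <- drop(crossprod(z, model$loadings_pc1 + model$loadings_pc2))
  tibble::tibble(sample_id = colnames(expr), m5c_score = unname(score))
}

#' Dichotomize scores against survival
#'
#' Applies [max_rank_cutpoint()] to the score over samples with survival data
#' and labels every scored sample `"high"` if its score exceeds the cutoff,
#' `"low"` otherwise.
#'
#' @param scores tibble with `sample_id`, `m5c_score`.
#' @param clinical clinical tibble with `sample_id`, `os_time`, `os_event`.
#' @param minprop minimum group fraction for the cutpoint search.
#' @return list with `scores` (input tibble plus a `group` column) and
#'   `cutpoint` (the `cutpoint_result`).
#' @export
dichotomize_scores <- function(scores, clinical, minprop = 0.1) {
  merged <- dplyr::inner_join(scores, clinical, by = "sample_id")
  merged <- dplyr::filter(merged, !is.na(.data$os_time), !is.na(.data$os_event))
  if (nrow(merged) == 0L) stop("no samples with survival data", call. = FALSE)
  cp <- max_rank_cutpoint(merged$os_time, merged$os_event, merged$m5c_score,
                          minprop = minprop)
  scores$group <- ifelse(scores$m5c_score > cp$cutoff, "high", "low")
  list(scores = scores, cutpoint = cp)
}

#' Score distribution plot by group
#'
#' @param scores tibble with `m5c_score` and optionally `group`.
#' @return a ggplot object.
#' @export
plot_score_distribution <- function(scores) {
  p <- ggplot2::ggplot(scores, ggplot2::aes(x = .data$m5c_score))
  if ("group" %in% names(scores)) {
    p <- p + ggplot2::geom_histogram(ggplot2::aes(fill = .data$group),
                                     bins = 30L, position = "identity",
                                     alpha = 0.6)
  } else {
    p <- p + ggplot2::geom_histogram(bins = 30L)
  }
  p + ggplot2::labs(x = "m5C score", y = "samples") + ggplot2::theme_minimal()
}
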