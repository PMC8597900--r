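#' Single-sample gene-set enrichment score (ssGSEA-style)
#'
#' Rank-based per-sample enrichment: genes are ranked by expression within the
#' sample (average ranks for ties, highest expression = highest rank) and the
#' score is the unnormalized running-sum integral — the sum over the
#' descending-ranked gene list of the difference between the weighted in-set
#' step ECDF (weights `rank^alpha`) and the uniform out-of-set step ECDF.
#' Being rank-based, the score is invariant to any strictly monotone
#' transform of a sample's expression values.
#'
#' @param x expression matrix.
#' @param gene_set character vector of gene ids; genes absent from the matrix
#'   are dropped with a message.
#' @param alpha rank-weighting exponent.
#' @return named numeric vector of per-sample scores.
#' @export
ssgsea_score <- function(x, gene_set, alpha = 0.25) {
  gene_set <- unique(gene_set)
  present <- intersect(gene_set, rownames(x))
  if (length(present) == 0L) {
    stop("gene set entirely absent from the matrix", call. = FALSE)
  }
  if (length(present) < length(gene_set)) {
    message(length(gene_set) - length(present),
            " gene(s) of the set absent from the matrix; dropped")
  }
  in_set <- rownames(x) %in% present
  n_genes <- nrow(x)
  n_out <- n_genes - sum(in_set)
  scores <- vapply(seq_len(ncol(x)), function(j) {
    r <- rank(x[, j])                       # highest expression -> rank n
    ord <- order(-r)                        # descending
    w <- ifelse(in_set[ord], r[ord]^alpha, 0)
    p_in <- cumsum(w) / sum(w)
    p_out <- if (n_out > 0) cumsum(!in_set[ord]) / n_out else rep(0, n_genes)
    sum(p_in - p_out)
  }, numeric(1L))
  stats::setNames(scores, colnames(x))
}

#' Stromal, immune and composite infiltration scores
#'
#' ssGSEA-style scores of a stromal and an immune gene set per sample; the
#' composite score is their sum (the ESTIMATE-style summary of overall
#' non-tumor infiltration).
#'
#' @param x expression matrix.
#' @param stromal_set,immune_set gene-id vectors.
#' @param alpha rank-weighting exponent passed to [ssgsea_score()].
#' @return tibble with `sample_id`, `stromal_score`, `immune_score`,
#'   `estimate_score`.
#' @export
estimate_scores <- function(x, stromal_set, immune_set, alpha = 0.25) {
  s <- ssgsea_score(x, stromal_set, alpha = alpha)
  i <- ssgsea_score(x, immune_set, alpha = alpha)
  tibble::tibble(sample_id = colnames(x),
                 stromal_score = unname(s),
                 immune_score = unname(i),
                 estimate_score = unname(s + i))
}

#' Score a collection of gene sets per sample
#'
#' @param x expression matrix.
#' @param sets named list of gene-id vectors (e.g. immune-cell marker sets
#'   from [read_gmt()]).
#' @param alpha rank-weighting exponent.
#' @return tibble with `sample_id` and one column per set.
#' @export
ssgsea_score_sets <- function(x, sets, alpha = 0.25) {
  out <- tibble::tibble(sample_id = colnames(x))
  for (nm in names(sets)) {
    out[[nm]] <- unname(ssgsea_score(x, sets[[nm]], alpha = alpha))
  }
  out
}

#' Cell-fraction deconvolution by nu-support-vector regression
#'
#' CIBERSORT-style deconvolution: for each mixture sample, both the signature
#' matrix and the mixture column are z-scored over the shared genes, a linear
#' nu-SVR of the mixture on the signature columns is fit for each nu in
#' `nu_grid`, the nu minimizing the RMSE between fitted and observed mixture
#' is kept, negative coefficients are clipped to zero and the rest normalized
#' to sum to one. An all-zero coefficient vector falls back to uniform
#' fractions with a warning. Optionally a permutation p-value per sample: the
#' fraction of gene-permuted refits whose fitted-vs-observed correlation
#' exceeds the observed one.
#'
#' @param mixture expression matrix (linear scale), genes x samples.
#' @param signature marker genes x cell types matrix (>= 10 genes shared with
#'   the mixture).
#' @param nu_grid candidate nu values.
#' @param n_permutations permutations for the empirical p (0 = skip).
#' @param seed integer seed (permutations only; the fit is deterministic).
#' @return list with `fractions` (samples x cell types matrix, rows sum to 1),
#'   `stats` (tibble: `sample_id`, `nu`, `rmse`, `r`, and `p` if permuted).
#' @export
deconvolve_nusvr <- function(mixture, signature, nu_grid = c(0.25, 0.5, 0.75),
                             n_permutations = 0L, seed = 1L) {
  shared <- intersect(rownames(mixture), rownames(signature))
  if (length(shared) < 10L) {
    stop("need >= 10 signature genes shared with the mixture", call. = FALSE)
  }
  sig <- signature[shared, , drop = FALSE]
  mix <- mixture[shared, , drop = FALSE]
  sig_z <- (sig - mean(sig)) / stats::sd(sig)

  fit_one <- function(yz) {
    best <- NULL
    for (nu in nu_grid) {
      svr <- e1071::svm(x = sig_z, y = yz, type = "nu-regression",
                        kernel = "linear", nu = nu, scale = FALSE,
                        tolerance = 1e-4)
      w <- drop(crossprod(svr$coefs, svr$SV))
      fitted_y <- as.numeric(stats::predict(svr, sig_z))
      rmse <- sqrt(mean((fitted_y - yz)^2))
      if (is.null(best) || rmse < best$rmse) {
        best <- list(w = w, rmse = rmse, nu = nu,
                     r = suppressWarnings(stats::cor(fitted_y, yz)))
      }
    }
    best
  }

  n_types <- ncol(sig)
  fractions <- matrix(NA_real_, ncol(mix), n_types,
                      dimnames = list(colnames(mix), colnames(sig)))
  stats_rows <- vector("list", ncol(mix))
  for (j in seq_len(ncol(mix))) {
    y <- mix[, j]
    yz <- (y - mean(y)) / stats::sd(y)
    best <- fit_one(yz)
    w <- pmax(best$w, 0)
    if (sum(w) == 0) {
      warning("all-zero coefficient vector for sample ", colnames(mix)[j],
              "; uniform fractions returned", call. = FALSE)
      w <- rep(1, n_types)
    }
    fractions[j, ] <- w / sum(w)
    row <- tibble::tibble(sample_id = colnames(mix)[j], nu = best$nu,
                          rmse = best$rmse, r = best$r)
    if (n_permutations > 0L) {
      set.seed((as.integer(seed) %% 100000L) * 131L + j)
      perm_r <- vapply(seq_len(n_permutations), function(b) {
        fit_one(sample(yz))$r
      }, numeric(1L))
      row$p <- (1 + sum(perm_r >= best$r)) / (1 + n_permutations)
    }
    stats_rows[[j]] <- row
  }
  list(fractions = fractions, stats = dplyr::bind_rows(stats_rows))
}
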