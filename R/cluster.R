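#' Resampling-based consensus clustering
#'
#' Monti-style consensus clustering of samples on an expression matrix
#' (typically the z-scored regulator panel). For each of `reps` iterations a
#' subsample of `ceiling(subsample_fraction * n)` samples is drawn without
#' replacement and partitioned into k groups by k-means (k-means++ seeding,
#' one restart, Euclidean distance on the sample vectors). The consensus
#' matrix entry (i, j) is the fraction of co-clustering among the iterations
#' in which both samples were drawn; pairs never co-sampled are set to 0 with
#' a warning. Final labels at each k come from average-linkage hierarchical
#' clustering of the dissimilarity `1 - consensus`, cut at k.
#'
#' @param x expression matrix, genes x samples (z-score scale recommended).
#' @param k_values integer vector of candidate cluster numbers.
#' @param reps number of resampling iterations.
#' @param subsample_fraction fraction of samples drawn per iteration.
#' @param seed integer seed; iteration r uses a deterministic child seed.
#' @return an object of class `consensus_result`: list with `k_values`,
#'   `consensus` (named list of sample x sample matrices), `labels` (named
#'   list of named integer vectors), `pac`, `cdf_area` (named numeric),
#'   `reps`, `subsample_fraction`, `seed`.
#' @export
consensus_cluster <- function(x, k_values = 2:6, reps = 1000L,
                              subsample_fraction = 0.8, seed = 1L) {
  n <- ncol(x)
  k_values <- sort(unique(as.integer(k_values)))
  if (reps < 1L) stop("reps must be >= 1", call. = FALSE)
  if (n < max(k_values) * 2L) {
    stop("need at least 2 * max(k) samples", call. = FALSE)
  }
  sub_n <- ceiling(subsample_fraction * n)
  if (max(k_values) > sub_n) stop("k exceeds the subsample size", call. = FALSE)

  dat <- t(x)  # samples x genes
  samples <- colnames(x)
  consensus <- list()
  labels <- list()
  pac <- stats::setNames(numeric(length(k_values)), as.character(k_values))
  cdf_area <- pac

  for (k in k_values) {
    co_clust <- matrix(0, n, n)
    co_samp <- matrix(0, n, n)
    for (r in seq_len(reps)) {
      set.seed((as.integer(seed) %% 100000L) * 13807L + 1000L * k + r)
      idx <- sample.int(n, sub_n)
      cl <- kmeanspp(dat[idx, , drop = FALSE], k)
      ind <- outer(cl, cl, "==") * 1
      co_clust[idx, idx] <- co_clust[idx, idx] + ind
      co_samp[idx, idx] <- co_samp[idx, idx] + 1
    }
    never <- co_samp == 0
    if (any(never[upper.tri(never)])) {
      warning(sum(never[upper.tri(never)]),
              " sample pair(s) never co-sampled; consensus set to 0",
              call. = FALSE)
    }
    cons <- ifelse(co_samp > 0, co_clust / pmax(co_samp, 1), 0)
    diag(cons) <- 1
    dimnames(cons) <- list(samples, samples)

    hc <- stats::hclust(stats::as.dist(1 - cons), method = "average")
    lab <- stats::cutree(hc, k = k)
    off <- cons[upper.tri(cons)]
    pac[as.character(k)] <- mean(off > 0.1 & off < 0.9)
    cdf_area[as.character(k)] <- consensus_cdf_area(off)

    consensus[[as.character(k)]] <- cons
    labels[[as.character(k)]] <- lab
  }

  structure(list(
    k_values = k_values, consensus = consensus, labels = labels,
    pac = pac, cdf_area = cdf_area, reps = as.integer(reps),
    subsample_fraction = subsample_fraction, seed = as.integer(seed)
  ), class = "consensus_result")
}

# area under the empirical CDF of off-diagonal consensus entries on [0, 1]
consensus_cdf_area <- function(off) {
  xs <- sort(unique(c(0, off, 1)))
  cdf <- stats::ecdf(off)
  sum(diff(xs) * cdf(xs[-length(xs)]))
}

# k-means with k-means++ seeding, one restart; returns integer labels
kmeanspp <- function(dat, k) {
  n <- nrow(dat)
  if (k <= 1L) return(rep(1L, n))
  if (k >= n) return(seq_len(n))
  centers_idx <- integer(k)
  centers_idx[1L] <- sample.int(n, 1L)
  d2 <- rowSums((dat - matrix(dat[centers_idx[1L], ], n, ncol(dat),
                              byrow = TRUE))^2)
  for (j in 2:k) {
    if (sum(d2) <= 0) {
      centers_idx[j] <- sample.int(n, 1L)
    } else {
      centers_idx[j] <- sample.int(n, 1L, prob = d2)
    }
    nd2 <- rowSums((dat - matrix(dat[centers_idx[j], ], n, ncol(dat),
                                 byrow = TRUE))^2)
    d2 <- pmin(d2, nd2)
  }
  centers <- dat[centers_idx, , drop = FALSE]
  fit <- tryCatch(
    suppressWarnings(stats::kmeans(dat, centers = centers, iter.max = 50L,
                                   nstart = 1L)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    # degenerate data (duplicate centers): nearest-center assignment
    d <- vapply(seq_len(nrow(centers)), function(j) {
      rowSums((dat - matrix(centers[j, ], n, ncol(dat), byrow = TRUE))^2)
    }, numeric(n))
    return(max.col(-d, ties.method = "first"))
  }
  fit$cluster
}

#' Select the number of clusters by PAC
#'
#' Returns the candidate k minimizing the proportion of ambiguous clustering
#' (PAC): the fraction of off-diagonal consensus entries strictly inside
#' `(lower, upper)`. Ties break toward smaller k. The CDF delta-area values
#' are attached for diagnostics.
#'
#' @param result a [consensus_cluster()] result.
#' @param lower,upper PAC ambiguity bounds.
#' @return the selected k (integer) with attributes `pac` and `cdf_area`.
#' @export
select_k <- function(result, lower = 0.1, upper = 0.9) {
  stopifnot(inherits(result, "consensus_result"))
  if (length(result$k_values) < 2L) stop("need >= 2 candidate k", call. = FALSE)
  pac <- vapply(as.character(result$k_values), function(k) {
    off <- result$consensus[[k]][upper.tri(result$consensus[[k]])]
    mean(off > lower & off < upper)
  }, numeric(1L))
  best <- result$k_values[which.min(pac)]  # which.min takes the first = smallest k
  structure(as.integer(best), pac = pac, cdf_area = result$cdf_area)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement of two labelings of the same samples; 1 for
#' identical partitions up to label renaming, about 0 for independent ones.
#' If both vectors are named they are aligned by name.
#'
#' @param a,b label vectors over the same samples.
#' @return a scalar in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length", call. = FALSE)
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b))) {
      stop("label vectors cover different samples", call. = FALSE)
    }
    b <- b[names(a)]
  }
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus clustering: %d samples, %d reps, k in {%s}\n",
              nrow(x$consensus[[1L]]), x$reps,
              paste(x$k_values, collapse = ", ")))
  cat("PAC by k:\n")
  print(round(x$pac, 4))
  invisible(x)
}

#' @rdname consensus_cluster
#' @param object,x a `consensus_result`.
#' @param ... unused.
#' @export
tidy.consensus_result <- function(x, ...) {
  purrr::map_dfr(as.character(x$k_values), function(kk) {
    lab <- x$labels[[kk]]
    tibble::tibble(k = as.integer(kk),
                   sample_id = names(lab),
                   cluster = unname(lab))
  })
}

#' @rdname consensus_cluster
#' @export
glance.consensus_result <- function(x, ...) {
  tibble::tibble(k = x$k_values,
                 pac = unname(x$pac),
                 cdf_area = unname(x$cdf_area),
                 reps = x$reps,
                 subsample_fraction = x$subsample_fraction)
}

#' Consensus CDF diagnostic plot
#'
#' Empirical CDFs of off-diagonal consensus entries, one curve per k; flat
#' mid-sections (low PAC) indicate stable clusterings.
#'
#' @param object a `consensus_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.consensus_result <- function(object, ...) {
  df <- purrr::map_dfr(as.character(object$k_values), function(k) {
    off <- object$consensus[[k]][upper.tri(object$consensus[[k]])]
    tibble::tibble(k = factor(k), consensus = sort(off),
                   cdf = seq_along(off) / length(off))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$consensus, y = .data$cdf,
                                   colour = .data$k)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "consensus index", y = "CDF",
                  title = "Consensus CDF by candidate k") +
    ggplot2::theme_minimal()
}
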