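#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the statistical structure the downstream pipeline
#' assumes: a latent k-cluster structure among tumor samples expressed through
#' a small panel of regulator genes, blocks of phenotype genes correlated with
#' cluster identity, tumor-vs-normal mean shifts on the informative genes, and
#' survival times whose hazard depends on a latent per-sample score.
#'
#' All mean shifts are in units of the per-gene noise standard deviation on the
#' log2 expression scale.
#'
#' @param n_genes total number of genes.
#' @param n_samples_tumor,n_samples_normal cohort sizes.
#' @param n_regulators number of regulator genes (clustered panel).
#' @param n_clusters number of latent tumor clusters (>= 2).
#' @param cluster_effect per-cluster mean shift of that cluster's regulator and
#'   phenotype genes, in noise-SD units.
#' @param n_phenotype_genes number of genes correlated with cluster identity.
#' @param tumor_effect tumor-vs-normal shift on informative genes, SD units.
#' @param beta_hazard log-hazard per unit of the standardized latent score.
#' @param censor_rate fraction of tumor samples independently censored.
#' @param noise_sd residual SD of log2 expression.
#' @param seed integer seed; identical config + seed gives identical cohorts.
#' @return an object of class `sim_config` (a list of the above).
#' @export
sim_config <- function(n_genes = 2000L,
                       n_samples_tumor = 200L,
                       n_samples_normal = 40L,
                       n_regulators = 9L,
                       n_clusters = 3L,
                       cluster_effect = 2,
                       n_phenotype_genes = 60L,
                       tumor_effect = 2,
                       beta_hazard = 0.7,
                       censor_rate = 0.3,
                       noise_sd = 1,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_samples_tumor = as.integer(n_samples_tumor),
    n_samples_normal = as.integer(n_samples_normal),
    n_regulators = as.integer(n_regulators),
    n_clusters = as.integer(n_clusters),
    cluster_effect = cluster_effect,
    n_phenotype_genes = as.integer(n_phenotype_genes),
    tumor_effect = tumor_effect,
    beta_hazard = beta_hazard,
    censor_rate = censor_rate,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  )
  nums <- unlist(cfg)
  if (any(!is.finite(nums))) stop("sim_config values must be finite", call. = FALSE)
  counts <- c("n_genes", "n_samples_tumor", "n_samples_normal", "n_regulators",
              "n_phenotype_genes")
  if (any(unlist(cfg[counts]) < 1L)) stop("counts must be >= 1", call. = FALSE)
  if (cfg$n_clusters < 2L) stop("n_clusters must be >= 2", call. = FALSE)
  if (cfg$censor_rate < 0 || cfg$censor_rate > 1) {
    stop("censor_rate must be in [0, 1]", call. = FALSE)
  }
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (cfg$n_regulators + cfg$n_phenotype_genes > cfg$n_genes) {
    stop("n_genes must cover regulators + phenotype genes", call. = FALSE)
  }
  if (cfg$n_phenotype_genes < cfg$n_clusters) {
    stop("need at least one phenotype gene per cluster", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# independent exponential censoring: C_i ~ Exp(rc) with rc solved so the
# expected censored fraction over the cohort's hazards equals censor_rate;
# observed time = min(T, C). Keeps censoring non-informative for Cox fits.
rcensor_exp <- function(event_time, rate_i, censor_rate) {
  n <- length(event_time)
  if (censor_rate <= 0) {
    return(list(time = event_time, censored = rep(FALSE, n)))
  }
  if (censor_rate >= 1) {
    return(list(time = rep(0, n), censored = rep(TRUE, n)))
  }
  rc <- stats::uniroot(function(r) mean(r / (r + rate_i)) - censor_rate,
                       interval = c(min(rate_i) * 1e-8, max(rate_i) * 1e8),
                       tol = 1e-12)$root
  cens_time <- stats::rexp(n, rate = rc)
  censored <- cens_time < event_time
  list(time = pmin(event_time, cens_time), censored = censored)
}

# deterministic child seed for a named sub-stream; kept within 32-bit range
child_seed <- function(seed, stream) {
  offsets <- c(baseline = 11L, noise = 23L, survival = 37L, censor = 53L,
               covariates = 71L, mixture = 89L, signature = 97L,
               fractions = 113L)
  (as.integer(seed) %% 1000000L) * 1009L + offsets[[stream]]
}

#' Simulate a synthetic tumor/normal cohort with known ground truth
#'
#' Baseline log2 expression per gene is drawn from a normal distribution with
#' mean 3 and SD 1 (log-normal expression, heavy-tailed like TPM), then
#' perturbed on the log2 scale: each latent cluster elevates its own block of
#' regulator and phenotype genes by `cluster_effect` noise-SD units, tumor
#' samples are shifted by `tumor_effect` on all informative genes, and i.i.d.
#' Gaussian noise with SD `noise_sd` is added. The latent per-sample score is
#' a stated linear function of the cluster-informative genes — the mean log2
#' value of the first cluster's phenotype block minus that of the last
#' cluster's block — standardized to mean 0 / SD 1
#' across tumor samples, and overall-survival times are exponential with
#' hazard `h0 * exp(beta_hazard * score)` where `h0 = log(2) / 1200` (median
#' survival near 1200 days at score 0). Censoring times are independent
#' exponentials whose rate is solved so the expected censored fraction equals
#' `censor_rate`; the observed time is the minimum of event and censoring
#' time, keeping censoring non-informative.
#'
#' @param config a [sim_config()].
#' @return a list of class `synthetic_cohort` with elements `expression`
#'   (tpm-scale expression matrix), `clinical` (tibble), `truth` (list with
#'   `clusters`, `score`, `informative_genes`, `regulator_genes`,
#'   `phenotype_genes`) and `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  n_t <- cfg$n_samples_tumor
  n_n <- cfg$n_samples_normal
  n <- n_t + n_n
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  reg_genes <- genes[seq_len(cfg$n_regulators)]
  phen_genes <- genes[cfg$n_regulators + seq_len(cfg$n_phenotype_genes)]
  informative <- c(reg_genes, phen_genes)
  samples <- c(sprintf("T%04d", seq_len(n_t)), sprintf("N%04d", seq_len(n_n)))
  tissue <- rep(c("tumor", "normal"), c(n_t, n_n))

  # cluster assignment: round-robin over tumor samples (balanced)
  clusters <- rep_len(seq_len(cfg$n_clusters), n_t)

  set.seed(child_seed(cfg$seed, "baseline"))
  base <- stats::rnorm(cfg$n_genes, mean = 3, sd = 1)

  mu <- matrix(base, nrow = cfg$n_genes, ncol = n,
               dimnames = list(genes, samples))

  # each cluster owns a contiguous block of regulator and phenotype genes
  reg_block <- split(seq_along(reg_genes),
                     rep_len(seq_len(cfg$n_clusters), length(reg_genes)))
  phen_block <- split(seq_along(phen_genes),
                      rep_len(seq_len(cfg$n_clusters), length(phen_genes)))
  shift <- cfg$cluster_effect * cfg$noise_sd
  for (k in seq_len(cfg$n_clusters)) {
    cols <- which(tissue == "tumor")[clusters == k]
    rows <- c(match(reg_genes, genes)[reg_block[[k]]],
              match(phen_genes, genes)[phen_block[[k]]])
    mu[rows, cols] <- mu[rows, cols] + shift
  }
  mu[match(informative, genes), tissue == "tumor"] <-
    mu[match(informative, genes), tissue == "tumor"] + cfg$tumor_effect * cfg$noise_sd

  set.seed(child_seed(cfg$seed, "noise"))
  logexpr <- mu + matrix(stats::rnorm(length(mu), sd = cfg$noise_sd),
                         nrow = nrow(mu))
  dimnames(logexpr) <- dimnames(mu)
  expr <- expr_matrix(2^logexpr - 1, "tpm")
  expr[expr < 0] <- 0

  # latent score: contrast of the first vs last cluster's phenotype blocks
  # (standardized over tumor samples) so clusters separate prognostically
  b_first <- phen_genes[phen_block[[1L]]]
  b_last <- phen_genes[phen_block[[cfg$n_clusters]]]
  raw_score <- colMeans(logexpr[match(b_first, genes), , drop = FALSE]) -
    colMeans(logexpr[match(b_last, genes), , drop = FALSE])
  tum_score <- raw_score[tissue == "tumor"]
  score <- (tum_score - mean(tum_score)) / stats::sd(tum_score)

  h0 <- log(2) / 1200
  set.seed(child_seed(cfg$seed, "survival"))
  rate_i <- h0 * exp(cfg$beta_hazard * score)
  event_time <- stats::rexp(n_t, rate = rate_i)
  set.seed(child_seed(cfg$seed, "censor"))
  cens <- rcensor_exp(event_time, rate_i, cfg$censor_rate)
  censored <- cens$censored
  obs_time <- cens$time

  set.seed(child_seed(cfg$seed, "covariates"))
  clinical <- tibble::tibble(
    sample_id = samples,
    tissue = tissue,
    os_time = c(round(obs_time, 3), rep(NA_real_, n_n)),
    os_event = c(as.integer(!censored), rep(NA_integer_, n_n)),
    age = round(stats::runif(n, 20, 80)),
    gender = sample(c("female", "male"), n, replace = TRUE),
    stage = sample(c("I", "II", "III", "IV"), n, replace = TRUE)
  )

  structure(list(
    expression = expr,
    clinical = clinical,
    truth = list(
      clusters = stats::setNames(clusters, samples[tissue == "tumor"]),
      score = stats::setNames(as.numeric(score), samples[tissue == "tumor"]),
      informative_genes = informative,
      regulator_genes = reg_genes,
      phenotype_genes = phen_genes
    ),
    config = cfg
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic cohort: %d genes x %d samples (%d tumor / %d normal), %d latent clusters\n",
    nrow(x$expression), ncol(x$expression),
    x$config$n_samples_tumor, x$config$n_samples_normal, x$config$n_clusters))
  invisible(x)
}

#' Simulate a marker-gene signature matrix
#'
#' Builds a synthetic cell-type signature: each cell type owns a block of
#' marker genes expressed high in that type (log-normal, meanlog 6) and low
#' elsewhere (meanlog 2), giving well-conditioned deconvolution problems.
#'
#' @param n_cell_types number of cell types.
#' @param markers_per_type marker genes per cell type.
#' @param seed integer seed.
#' @return numeric matrix, marker genes x cell types.
#' @export
simulate_signature <- function(n_cell_types = 5L, markers_per_type = 20L,
                               seed = 1L) {
  set.seed(child_seed(seed, "signature"))
  n_g <- n_cell_types * markers_per_type
  genes <- sprintf("MK%03d", seq_len(n_g))
  types <- sprintf("celltype_%d", seq_len(n_cell_types))
  sig <- matrix(stats::rlnorm(n_g * n_cell_types, meanlog = 2, sdlog = 0.3),
                nrow = n_g, dimnames = list(genes, types))
  for (c in seq_len(n_cell_types)) {
    rows <- (c - 1L) * markers_per_type + seq_len(markers_per_type)
    sig[rows, c] <- stats::rlnorm(markers_per_type, meanlog = 6, sdlog = 0.3)
  }
  sig
}

#' Simulate bulk mixtures of known cell-type fractions
#'
#' Each sample column is `signature %*% fractions[sample, ] + noise`, with
#' i.i.d. Gaussian noise of SD `noise_sd` truncated at zero.
#'
#' @param signature marker genes x cell types matrix.
#' @param fractions samples x cell types matrix; rows non-negative, sum to 1.
#' @param noise_sd additive noise SD (linear scale).
#' @param seed integer seed.
#' @return expression matrix (tpm scale), marker genes x samples.
#' @export
simulate_mixtures <- function(signature, fractions, noise_sd = 0, seed = 1L) {
  if (ncol(signature) != ncol(fractions)) {
    stop("signature cell types and fraction columns do not match", call. = FALSE)
  }
  if (any(fractions < 0) || any(abs(rowSums(fractions) - 1) > 1e-8)) {
    stop("fraction rows must be non-negative and sum to 1", call. = FALSE)
  }
  if (nrow(signature) == 0L) stop("signature has no genes", call. = FALSE)
  m <- signature %*% t(fractions)
  if (noise_sd > 0) {
    set.seed(child_seed(seed, "mixture"))
    m <- m + matrix(stats::rnorm(length(m), sd = noise_sd), nrow = nrow(m))
    m[m < 0] <- 0
  }
  if (is.null(rownames(fractions))) {
    colnames(m) <- sprintf("MIX%03d", seq_len(ncol(m)))
  } else {
    colnames(m) <- rownames(fractions)
  }
  expr_matrix(m, "tpm")
}

#' Simulate random cell-type fraction rows
#'
#' Dirichlet(1, ..., 1) rows: uniform on the simplex.
#'
#' @param n_samples number of samples (rows).
#' @param n_cell_types number of cell types (columns).
#' @param seed integer seed.
#' @return samples x cell types matrix, rows summing to 1.
#' @export
simulate_fractions <- function(n_samples, n_cell_types, seed = 1L) {
  set.seed(child_seed(seed, "fractions"))
  g <- matrix(stats::rexp(n_samples * n_cell_types), nrow = n_samples)
  f <- g / rowSums(g)
  dimnames(f) <- list(sprintf("MIX%03d", seq_len(n_samples)),
                      sprintf("celltype_%d", seq_len(n_cell_types)))
  f
}
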