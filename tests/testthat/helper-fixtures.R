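# shared fixture builders; everything is generated in code at test time

# small labeled matrix with known structure
toy_matrix <- function(n_genes = 10, n_samples = 6, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rlnorm(n_genes * n_samples, 3, 1), n_genes,
              dimnames = list(sprintf("G%02d", seq_len(n_genes)),
                              sprintf("S%02d", seq_len(n_samples))))
  expr_matrix(m, "tpm")
}

small_cohort <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_genes = 120, n_samples_tumor = 90, n_samples_normal = 12,
         n_regulators = 9, n_clusters = 3, cluster_effect = 2,
         n_phenotype_genes = 30, seed = seed),
    list(...))
  simulate_cohort(do.call(sim_config, args))
}

tumor_ids <- function(cohort) {
  cohort$clinical$sample_id[cohort$clinical$tissue == "tumor"]
}

tumor_log_expr <- function(cohort) {
  logx <- log2_transform(cohort$expression)
  expr_matrix(logx[, tumor_ids(cohort), drop = FALSE], "log2tpm")
}

# random survival dataset for cutpoint/cox checks
random_surv <- function(n = 60, seed = 1) {
  set.seed(seed)
  list(time = stats::rexp(n, 0.001) + 1,
       event = stats::rbinom(n, 1, 0.7),
       score = stats::rnorm(n))
}
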