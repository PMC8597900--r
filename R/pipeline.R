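#' Run the full m5C-pattern analysis pipeline
#'
#' Orchestrates the whole analysis from an expression matrix + clinical table
#' (or a [sim_config()] that generates them): z-scored regulator panel ->
#' consensus clustering into modification patterns -> phenotype-associated
#' DEGs -> consensus clustering of the DEG matrix into gene-clusters ->
#' univariate Cox screen -> PCA score model and per-sample m5C score ->
#' survival cutpoint dichotomization -> score-group DEGs -> TME scores (and
#' optional deconvolution) compared across groups -> tumor/normal and
#' score-group SVM classifiers. Every stage's key outputs are written to
#' `out_dir` and summarized in a machine-readable `report.json`; a fixed seed
#' reproduces the whole run.
#'
#' @param expression expression matrix (tpm scale) or `NULL` when `sim` is
#'   given.
#' @param clinical clinical tibble or `NULL` when `sim` is given.
#' @param regulator_genes gene ids of the regulator panel; defaults to the
#'   simulated cohort's truth panel when `sim` is given.
#' @param sim optional [sim_config()]; generates the cohort when expression
#'   input is not supplied.
#' @param k_values candidate cluster numbers.
#' @param reps consensus-clustering resampling iterations.
#' @param adj_p_threshold BH-adjusted p cutoff for phenotype DEGs.
#' @param cox_p Wald p cutoff for the prognostic gene screen.
#' @param lfc_threshold log2 fold-change cutoff for score-group DEGs.
#' @param corr_threshold |rho| cutoff for diagnostic feature selection.
#' @param minprop minimum group fraction for the survival cutpoint.
#' @param signature optional cell-type signature matrix for deconvolution.
#' @param gene_sets optional named list of gene sets for per-sample scoring;
#'   defaults to small sets built from the phenotype DEGs.
#' @param out_dir output directory (created if needed); `NULL` = no files.
#' @param seed master seed for every stochastic stage.
#' @return a list of class `m5c_pipeline` with per-stage results and the
#'   report; see the elements written to `report.json`.
#' @export
run_pipeline <- function(expression = NULL, clinical = NULL,
                         regulator_genes = NULL, sim = NULL,
                         k_values = 2:5, reps = 250L,
                         adj_p_threshold = 0.05, cox_p = 0.01,
                         lfc_threshold = log2(1.2), corr_threshold = 0.4,
                         minprop = 0.1, signature = NULL, gene_sets = NULL,
                         out_dir = NULL, seed = 1L) {
  if (is.null(expression) && is.null(sim)) {
    stop("supply either an expression matrix + clinical table or a sim_config",
         call. = FALSE)
  }
  if (!is.null(expression) && !is.null(sim)) {
    stop("supply exactly one of {expression input, sim_config}", call. = FALSE)
  }
  stopifnot(adj_p_threshold > 0, adj_p_threshold <= 1, cox_p > 0, cox_p <= 1,
            lfc_threshold >= 0, corr_threshold >= 0, corr_threshold < 1,
            minprop > 0, minprop < 0.5)
  t0 <- Sys.time()
  log_stage <- function(stage, ...) {
    message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                    sprintf(...)))
  }
  truth <- NULL
  if (!is.null(sim)) {
    log_stage("simulate", "generating synthetic cohort (seed %d)", sim$seed)
    cohort <- simulate_cohort(sim)
    expression <- cohort$expression
    clinical <- cohort$clinical
    truth <- cohort$truth
    if (is.null(regulator_genes)) regulator_genes <- truth$regulator_genes
  }
  validate_clinical(clinical)
  if (is.null(regulator_genes)) stop("regulator_genes required", call. = FALSE)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  tumor_ids <- clinical$sample_id[clinical$tissue == "tumor"]
  tumor_ids <- intersect(tumor_ids, colnames(expression))
  normal_ids <- setdiff(intersect(clinical$sample_id, colnames(expression)),
                        tumor_ids)
  logx <- log2_transform(expression)
  tumor_log <- expr_matrix(logx[, tumor_ids, drop = FALSE], "log2tpm")

  # 1. consensus clustering of the regulator panel (tumor samples)
  log_stage("cluster", "consensus clustering %d regulators, %d tumor samples",
            length(regulator_genes), length(tumor_ids))
  reg_z <- zscore_rows(expr_matrix(tumor_log[regulator_genes, , drop = FALSE],
                                   "log2tpm"))
  cc_reg <- consensus_cluster(reg_z, k_values = k_values, reps = reps,
                              seed = seed)
  k_sel <- select_k(cc_reg)
  pattern_labels <- cc_reg$labels[[as.character(k_sel)]]

  # 2. phenotype-associated DEGs (one-vs-rest moderated t)
  log_stage("degs", "phenotype DEGs at adjusted p < %g", adj_p_threshold)
  degs <- phenotype_degs(tumor_log, pattern_labels,
                         adj_p_threshold = adj_p_threshold)

  # 3. gene-clusters: same consensus engine on the DEG matrix
  gene_cluster_labels <- NULL
  if (length(degs$genes) >= 2L) {
    log_stage("gene-cluster", "consensus clustering %d DEGs",
              length(degs$genes))
    deg_z <- zscore_rows(expr_matrix(tumor_log[degs$genes, , drop = FALSE],
                                     "log2tpm"))
    cc_gene <- consensus_cluster(deg_z, k_values = k_values, reps = reps,
                                 seed = seed + 1L)
    k_gene <- select_k(cc_gene)
    gene_cluster_labels <- cc_gene$labels[[as.character(k_gene)]]
  } else {
    cc_gene <- NULL; k_gene <- NA_integer_
  }

  # 4. univariate Cox screen of the DEG pool
  log_stage("cox-screen", "screening %d candidates at p < %g",
            length(degs$genes), cox_p)
  screen <- select_signature_genes(degs$genes, clinical, tumor_log,
                                   p_threshold = cox_p)

  # 5. PCA score model + per-sample score (fit on tumor samples)
  log_stage("score", "fitting PCA score on %d genes", length(screen$genes))
  model <- fit_score_model(tumor_log, screen$genes)
  scores <- compute_m5c_score(model, tumor_log)

  # 6. survival cutpoint dichotomization
  dich <- dichotomize_scores(scores, clinical, minprop = minprop)
  scores <- dich$scores
  surv_sub <- dplyr::inner_join(scores, clinical, by = "sample_id")
  surv_sub <- dplyr::filter(surv_sub, !is.na(.data$os_time))
  lr <- logrank_test(surv_sub$os_time, surv_sub$os_event, surv_sub$group)
  log_stage("cutpoint", "cutoff %.3f, log-rank p = %.3g", dich$cutpoint$cutoff,
            lr$p)

  # 7. DEGs between score groups (unadjusted p, strict lfc)
  hi <- scores$sample_id[scores$group == "high"]
  lo <- scores$sample_id[scores$group == "low"]
  sg_degs <- score_group_degs(tumor_log, hi, lo,
                              lfc_threshold = lfc_threshold)

  # 8. TME scoring across patterns and score groups
  if (is.null(gene_sets)) {
    half <- ceiling(length(degs$genes) / 2)
    gene_sets <- list(stromal_like = degs$genes[seq_len(half)],
                      immune_like = degs$genes[-seq_len(half)])
    gene_sets <- Filter(function(s) length(s) > 0, gene_sets)
  }
  tme <- NULL
  if (length(gene_sets) >= 2L) {
    log_stage("tme", "scoring %d gene sets per sample", length(gene_sets))
    tme <- estimate_scores(tumor_log, gene_sets[[1L]], gene_sets[[2L]])
    tme$group <- scores$group[match(tme$sample_id, scores$sample_id)]
    tme$pattern <- pattern_labels[tme$sample_id]
  }
  kw <- if (!is.null(tme)) {
    kruskal_wallis(tme$estimate_score, tme$pattern)
  } else NULL
  fractions <- if (!is.null(signature)) {
    log_stage("deconvolve", "nu-SVR deconvolution of %d samples", ncol(expression))
    deconvolve_nusvr(expression[, tumor_ids, drop = FALSE], signature,
                     seed = seed)
  } else NULL

  # 9. diagnostic classifiers from score-correlated features
  feats <- select_features_by_correlation(tumor_log, scores,
                                          threshold = corr_threshold)
  score_labels <- stats::setNames(scores$group, scores$sample_id)
  clf_score <- train_classifier(tumor_log, score_labels,
                                feature_genes = feats$genes,
                                positive_class = "high", seed = seed)
  eval_score <- evaluate_classifier(clf_score, tumor_log, score_labels)
  clf_tissue <- NULL; eval_tissue <- NULL; cv_tissue <- NULL
  if (length(normal_ids) >= 3L) {
    tissue_labels <- stats::setNames(
      ifelse(clinical$sample_id %in% tumor_ids, "tumor", "normal"),
      clinical$sample_id)
    tissue_labels <- tissue_labels[c(tumor_ids, normal_ids)]
    clf_tissue <- train_classifier(logx, tissue_labels,
                                   feature_genes = feats$genes,
                                   positive_class = "tumor", seed = seed)
    eval_tissue <- evaluate_classifier(clf_tissue, logx, tissue_labels)
    cv_tissue <- cross_validate_classifier(logx, tissue_labels,
                                           feature_genes = feats$genes,
                                           positive_class = "tumor",
                                           seed = seed)
  }
  log_stage("classify", "%d features; score-group accuracy %.3f",
            length(feats$genes), eval_score$accuracy)

  report <- list(
    params = list(k_values = k_values, reps = reps,
                  adj_p_threshold = adj_p_threshold, cox_p = cox_p,
                  lfc_threshold = lfc_threshold,
                  corr_threshold = corr_threshold, minprop = minprop,
                  seed = seed),
    inputs = list(n_genes = nrow(expression), n_samples = ncol(expression),
                  n_tumor = length(tumor_ids), n_normal = length(normal_ids),
                  inputs_hash = input_hash(expression)),
    stages = list(
      cluster = list(k_selected = as.integer(k_sel),
                     pac = as.list(cc_reg$pac)),
      phenotype_degs = list(n = length(degs$genes)),
      gene_cluster = list(k_selected = as.integer(k_gene)),
      cox_screen = list(n = length(screen$genes)),
      score = list(n_signature_genes = length(model$signature_genes),
                   explained_variance = as.list(model$explained_variance),
                   cutoff = dich$cutpoint$cutoff,
                   logrank_p = lr$p,
                   n_high = sum(scores$group == "high"),
                   n_low = sum(scores$group == "low")),
      score_group_degs = list(n_up = length(sg_degs$up),
                              n_down = length(sg_degs$down)),
      tme = if (!is.null(kw)) list(kruskal_wallis_p = kw$p) else NULL,
      classify = list(n_features = length(feats$genes),
                      score_group_accuracy = eval_score$accuracy,
                      score_group_auc = eval_score$auc,
                      tissue_accuracy = if (!is.null(eval_tissue)) eval_tissue$accuracy else NULL,
                      tissue_cv_accuracy = if (!is.null(cv_tissue)) cv_tissue$accuracy else NULL)
    )
  )

  result <- structure(list(
    expression = expression, clinical = clinical, truth = truth,
    regulator_genes = regulator_genes,
    consensus_regulators = cc_reg, k_selected = as.integer(k_sel),
    pattern_labels = pattern_labels,
    phenotype_degs = degs, consensus_genes = cc_gene,
    gene_cluster_labels = gene_cluster_labels,
    cox_screen = screen, score_model = model, scores = scores,
    cutpoint = dich$cutpoint, logrank = lr, score_group_degs = sg_degs,
    tme = tme, fractions = fractions,
    features = feats, classifier_score = clf_score,
    eval_score = eval_score, classifier_tissue = clf_tissue,
    eval_tissue = eval_tissue, cv_tissue = cv_tissue,
    report = report
  ), class = "m5c_pipeline")

  if (!is.null(out_dir)) {
    write_pipeline_artifacts(result, out_dir)
    log_stage("done", "artifacts written to %s (%.1f s)", out_dir,
              as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }
  result
}

# order-sensitive content hash without extra dependencies: a stable digest of
# the numeric stream
input_hash <- function(x) {
  v <- c(dim(x), as.numeric(x[seq_len(min(length(x), 10000L))]))
  sprintf("%.0f", sum(v * seq_along(v)) %% 1e15)
}

write_pipeline_artifacts <- function(result, out_dir) {
  write_expression(result$expression, file.path(out_dir, "expression.tsv"))
  write_clinical(result$clinical, file.path(out_dir, "clinical.tsv"))
  readr::write_tsv(tidy(result$consensus_regulators),
                   file.path(out_dir, "consensus_labels.tsv"), progress = FALSE)
  readr::write_tsv(result$scores, file.path(out_dir, "scores.tsv"),
                   progress = FALSE)
  readr::write_tsv(result$cox_screen$detail,
                   file.path(out_dir, "cox_screen.tsv"), progress = FALSE)
  writeLines(result$phenotype_degs$genes, file.path(out_dir, "phenotype_degs.txt"))
  jsonlite::write_json(result$report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.m5c_pipeline <- function(x, ...) {
  r <- x$report$stages
  cat("m5C-pattern pipeline run\n")
  cat(sprintf("  patterns: k = %d (PAC-selected)\n", r$cluster$k_selected))
  cat(sprintf("  phenotype DEGs: %d; Cox-screened signature genes: %d\n",
              r$phenotype_degs$n, r$cox_screen$n))
  cat(sprintf("  score cutoff %.3f; high/low log-rank p = %.3g\n",
              r$score$cutoff, r$score$logrank_p))
  cat(sprintf("  diagnostic features: %d; score-group accuracy %.3f\n",
              r$classify$n_features, r$classify$score_group_accuracy))
  invisible(x)
}
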