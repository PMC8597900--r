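test_that("Cox screen keeps prognostic genes and honors the threshold", {
  co <- small_cohort(seed = 12, n_genes = 150, n_samples_tumor = 150,
                     n_phenotype_genes = 40, beta_hazard = 0.8)
  lx <- tumor_log_expr(co)
  cand <- c(co$truth$phenotype_genes, rownames(lx)[100:140])
  res <- select_signature_genes(cand, co$clinical, lx, p_threshold = 0.01)
  expect_true(length(res$genes) >= 3)
  expect_true(all(res$genes %in% cand))

  # p_threshold = 1 retains every candidate
  all_res <- select_signature_genes(cand, co$clinical, lx, p_threshold = 1)
  expect_setequal(all_res$genes, cand)

  # constant gene is skipped with a message, not an error
  lx2 <- lx
  lx2[cand[1], ] <- 5
  expect_message(
    res2 <- select_signature_genes(cand, co$clinical, lx2, p_threshold = 1),
    "constant")
  expect_false(cand[1] %in% res2$genes)
})

test_that("PCA loadings agree with an eigen-decomposition oracle after sign fixing", {
  set.seed(13)
  for (i in 1:5) {
    m <- matrix(stats::rnorm(30 * 50, 5, 2), 30,
                dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:50)))
    x <- expr_matrix(m, "log2tpm")
    model <- fit_score_model(x, rownames(m))
    z <- t(scale(t(m)))  # row z-scores
    ev <- eigen(stats::cov(t(z)))
    fix <- function(v) if (v[which.max(abs(v))] < 0) -v else v
    expect_equal(unname(model$loadings_pc1), fix(ev$vectors[, 1]),
                 tolerance = 1e-8)
    expect_equal(unname(model$loadings_pc2), fix(ev$vectors[, 2]),
                 tolerance = 1e-8)
    # unit norm and orthogonality
    expect_equal(sum(model$loadings_pc1^2), 1, tolerance = 1e-10)
    expect_lt(abs(sum(model$loadings_pc1 * model$loadings_pc2)), 1e-10)
  }
})

test_that("rank-1 structure loads almost everything on PC1", {
  set.seed(14)
  latent <- stats::rnorm(40)
  load <- stats::runif(10, 0.5, 2)
  m <- outer(load, latent) + matrix(stats::rnorm(400, 0, 1e-3), 10)
  dimnames(m) <- list(sprintf("g%02d", 1:10), sprintf("s%02d", 1:40))
  model <- fit_score_model(expr_matrix(m, "log2tpm"), rownames(m))
  expect_gte(model$explained_variance[["pc1"]], 0.99)
})

test_that("duplicating every sample leaves the loadings unchanged", {
  m <- toy_matrix(15, 20, seed = 15)
  model <- fit_score_model(m, rownames(m))
  dup <- cbind(m, m)
  colnames(dup) <- c(colnames(m), paste0("dup_", colnames(m)))
  model2 <- fit_score_model(expr_matrix(dup, "tpm"), rownames(m))
  expect_equal(model2$loadings_pc1, model$loadings_pc1, tolerance = 1e-8)
  expect_equal(model2$loadings_pc2, model$loadings_pc2, tolerance = 1e-8)
})

test_that("the m5C score is the PC1 + PC2 sample coordinate sum", {
  m <- toy_matrix(25, 30, seed = 16)
  model <- fit_score_model(m, rownames(m))
  scores <- compute_m5c_score(model, m)

  # oracle: SVD sample-coordinate matrix of the training z-scores
  z <- t(scale(t(unclass(m))))
  sv <- svd(t(z))
  coords <- sv$u %*% diag(sv$d)
  s1 <- sign(sv$v[which.max(abs(sv$v[, 1])), 1])
  s2 <- sign(sv$v[which.max(abs(sv$v[, 2])), 2])
  oracle <- coords[, 1] * s1 + coords[, 2] * s2
  expect_equal(scores$m5c_score, unname(oracle), tolerance = 1e-10)

  # training scores are mean zero
  expect_lt(abs(mean(scores$m5c_score)), 1e-8)

  # a sample at the training mean of every gene scores zero
  at_mean <- matrix(model$center, ncol = 1,
                    dimnames = list(model$signature_genes, "mean_sample"))
  expect_equal(compute_m5c_score(model, at_mean)$m5c_score, 0,
               tolerance = 1e-10)

  # invariance to gene and sample ordering of the input
  perm <- expr_matrix(unclass(m)[sample(25), sample(30)], "tpm")
  scores_perm <- compute_m5c_score(model, perm)
  expect_equal(scores_perm$m5c_score[match(scores$sample_id,
                                           scores_perm$sample_id)],
               scores$m5c_score, tolerance = 1e-10)

  expect_error(compute_m5c_score(model, m[1:10, ]), "absent")
})

test_that("identical samples get identical scores", {
  m <- toy_matrix(12, 8, seed = 17)
  model <- fit_score_model(m, rownames(m))
  two <- unclass(m)[, c(1, 1)]
  colnames(two) <- c("a", "b")
  sc <- compute_m5c_score(model, expr_matrix(two, "tpm"))
  expect_equal(sc$m5c_score[1], sc$m5c_score[2])
})

test_that("score dichotomization splits at the maximal log-rank cutoff", {
  co <- small_cohort(seed = 18, n_samples_tumor = 120, beta_hazard = 0.7)
  lx <- tumor_log_expr(co)
  screen <- select_signature_genes(co$truth$phenotype_genes, co$clinical, lx,
                                   p_threshold = 0.05)
  model <- fit_score_model(lx, screen$genes)
  scores <- compute_m5c_score(model, lx)
  dich <- dichotomize_scores(scores, co$clinical)
  expect_true(all(dich$scores$group %in% c("high", "low")))
  expect_identical(dich$scores$group == "high",
                   dich$scores$m5c_score > dich$cutpoint$cutoff)

  # the groups separate survival in a hazard-linked cohort
  merged <- dplyr::inner_join(dich$scores, co$clinical, by = "sample_id")
  lr <- logrank_test(merged$os_time, merged$os_event, merged$group)
  expect_lt(lr$p, 0.01)

  # negating scores flips the partition labels
  neg <- scores
  neg$m5c_score <- -neg$m5c_score
  dich_neg <- dichotomize_scores(neg, co$clinical)
  tab <- table(dich$scores$group, dich_neg$scores$group)
  expect_equal(tab["high", "high"] + tab["low", "low"], 0)

  # median split forced at minprop = 0.5 with even n
  even <- dichotomize_scores(scores, co$clinical, minprop = 0.5)
  expect_identical(even$cutpoint$n_high, 60L)
})

test_that("fitted score recovers the latent simulated score", {
  co <- small_cohort(seed = 19, n_samples_tumor = 150, cluster_effect = 2,
                     n_phenotype_genes = 45, beta_hazard = 0.7)
  lx <- tumor_log_expr(co)
  screen <- select_signature_genes(co$truth$phenotype_genes, co$clinical, lx,
                                   p_threshold = 0.05)
  model <- fit_score_model(lx, screen$genes)
  scores <- compute_m5c_score(model, lx)
  r <- stats::cor(scores$m5c_score, co$truth$score[scores$sample_id])
  expect_gte(abs(r), 0.8)   # sign is indeterminate under the loading convention
})

test_that("tidy and glance expose the score model", {
  m <- toy_matrix(10, 12, seed = 20)
  model <- fit_score_model(m, rownames(m))
  td <- tidy(model)
  expect_identical(nrow(td), 10L)
  expect_named(td, c("gene_id", "center", "scale", "loading_pc1", "loading_pc2"))
  gl <- glance(model)
  expect_identical(gl$n_genes, 10L)
})
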