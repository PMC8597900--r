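test_that("with the prior forced off the moderated t equals the ordinary pooled t", {
  x <- toy_matrix(50, 12, seed = 2)
  lx <- log2_transform(x)
  a <- colnames(lx)[1:6]; b <- colnames(lx)[7:12]
  de <- moderated_t_test(lx, a, b, prior_df = 0)
  ord <- apply(lx, 1, function(v) {
    tt <- stats::t.test(v[1:6], v[7:12], var.equal = TRUE)
    c(t = unname(tt$statistic), p = tt$p.value)
  })
  expect_equal(de$t_mod, unname(ord["t", ]), tolerance = 1e-10)
  expect_equal(de$p, unname(ord["p", ]), tolerance = 1e-10)
  expect_true(all(de$q >= de$p))
})

test_that("identical group values give zero fold change and p = 1", {
  x <- toy_matrix(20, 4, seed = 3)
  lx <- log2_transform(x)
  dup <- cbind(lx, lx)
  colnames(dup) <- c(paste0("a", 1:4), paste0("b", 1:4))
  dup <- expr_matrix(dup, "log2tpm")
  de <- moderated_t_test(dup, paste0("a", 1:4), paste0("b", 1:4))
  expect_equal(de$log_fc, rep(0, 20))
  expect_equal(de$p, rep(1, 20))
})

test_that("moderated t agrees with the limma reference implementation", {
  x <- toy_matrix(200, 16, seed = 4)
  lx <- log2_transform(x)
  a <- colnames(lx)[1:8]; b <- colnames(lx)[9:16]
  de <- moderated_t_test(lx, a, b)
  design <- cbind(1, rep(c(1, 0), each = 8))
  fit <- limma::eBayes(limma::lmFit(lx[, c(a, b)], design))
  expect_equal(de$t_mod, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(de$p, unname(fit$p.value[, 2]), tolerance = 1e-8)
  expect_equal(de$df_prior[1], unname(fit$df.prior), tolerance = 1e-8)
})

test_that("as the prior df grows the moderated t approaches the pooled-prior limit", {
  x <- toy_matrix(100, 10, seed = 5)
  lx <- log2_transform(x)
  a <- colnames(lx)[1:5]; b <- colnames(lx)[6:10]
  de_inf <- moderated_t_test(lx, a, b, prior_df = Inf)
  s02 <- de_inf$s2_prior[1]
  expected <- de_inf$log_fc / sqrt(s02 * (1 / 5 + 1 / 5))
  expect_equal(de_inf$t_mod, expected, tolerance = 1e-10)
})

test_that("BH adjustment matches the step-up definition and preserves order", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(1, 1, 1)), c(1, 1, 1))
  expect_equal(bh_adjust(0.2), 0.2)
  p <- c(0.04, 0.001, 0.9, 0.02)
  q <- bh_adjust(p)
  perm <- c(3, 1, 4, 2)
  expect_equal(bh_adjust(p[perm]), q[perm])   # permutation invariance
  expect_true(all(diff(q[order(p)]) >= 0))    # monotone in p
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("phenotype DEG screen recovers informative genes with few false positives", {
  co <- small_cohort(seed = 6, n_genes = 400, n_samples_tumor = 120,
                     n_phenotype_genes = 60, cluster_effect = 2)
  lx <- tumor_log_expr(co)
  res <- phenotype_degs(lx, co$truth$clusters)
  informative <- co$truth$informative_genes
  recall <- mean(co$truth$phenotype_genes %in% res$genes)
  false_frac <- mean(!(res$genes %in% informative))
  expect_gte(recall, 0.95)
  expect_lte(false_frac, 0.10)
  expect_true(all(c("comparison", "q") %in% names(res$detail)))

  expect_identical(phenotype_degs(lx, co$truth$clusters,
                                  adj_p_threshold = 0)$genes, character(0))
  all_same <- stats::setNames(rep(1, ncol(lx)), colnames(lx))
  expect_error(phenotype_degs(lx, all_same), "2 clusters")
  singleton <- co$truth$clusters
  singleton[1] <- 99
  singleton <- singleton[c(1, which(singleton != 99))]
  expect_error(phenotype_degs(lx, singleton), ">= 2 samples")
})

test_that("score-group DEG thresholds are strict and antisymmetric", {
  set.seed(7)
  n <- 30
  m <- matrix(stats::rnorm(20 * n, 5, 1), 20,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:n)))
  hi <- sprintf("s%02d", 1:15); lo <- sprintf("s%02d", 16:30)
  # force one gene to sit exactly at the fold-change boundary with a tiny p
  m["g01", ] <- rep(c(log2(1.2), 0), c(15, 15))
  x <- expr_matrix(m, "log2tpm")
  # the constant boundary gene triggers limma's zero-variance offset warning
  res <- suppressWarnings(score_group_degs(x, hi, lo))
  expect_false("g01" %in% res$up)   # boundary excluded by strict inequality

  swapped <- suppressWarnings(score_group_degs(x, lo, hi))
  expect_identical(sort(res$up), sort(swapped$down))
  expect_identical(sort(res$down), sort(swapped$up))
})

test_that("score-group DEG screen recovers shifted genes", {
  set.seed(8)
  n_genes <- 200
  m <- matrix(stats::rnorm(n_genes * 40, 5, 1), n_genes,
              dimnames = list(sprintf("g%03d", 1:n_genes),
                              sprintf("s%02d", 1:40)))
  hi <- sprintf("s%02d", 1:20); lo <- sprintf("s%02d", 21:40)
  m[1:30, hi] <- m[1:30, hi] + 1
  res <- score_group_degs(expr_matrix(m, "log2tpm"), hi, lo)
  expect_gte(sum(sprintf("g%03d", 1:30) %in% res$up), 27)
})

test_that("Kruskal-Wallis matches the rank-sum formula and is rank invariant", {
  kw <- kruskal_wallis(c(1, 2, 3, 4, 5, 6, 7, 8, 9),
                       rep(c("a", "b", "c"), each = 3))
  expect_equal(kw$statistic, 7.2, tolerance = 1e-12)
  expect_equal(kw$p, stats::pchisq(7.2, 2, lower.tail = FALSE))

  same <- kruskal_wallis(rep(5, 9), rep(c("a", "b", "c"), each = 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  set.seed(9)
  v <- stats::rnorm(30); g <- rep(1:3, 10)
  perm <- sample(30)
  expect_equal(kruskal_wallis(v, g)$statistic,
               kruskal_wallis(v[perm], g[perm])$statistic)
  expect_error(kruskal_wallis(v, rep(1, 30)), "2 non-empty")
})

test_that("one-way ANOVA provides the same interface", {
  set.seed(10)
  v <- stats::rnorm(30); g <- rep(1:3, 10)
  res <- one_way_anova(v, g)
  ref <- summary(stats::aov(v ~ factor(g)))[[1]]
  expect_equal(res$statistic, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(res$p, ref$`Pr(>F)`[1], tolerance = 1e-10)
})

test_that("Spearman correlation is the Pearson correlation of ranks", {
  expect_equal(spearman_cor(1:10, 1:10), 1)
  expect_equal(spearman_cor(1:10, 10:1), -1)
  expect_equal(spearman_cor(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_error(spearman_cor(c(1, 1, 1), 1:3), "constant")
})

test_that("distance correlation detects linear dependence and honors conventions", {
  set.seed(11)
  x <- stats::rnorm(50)
  expect_equal(distance_correlation(x, 3 * x + 2), 1, tolerance = 1e-10)
  expect_message(d0 <- distance_correlation(x, rep(1, 50)), "constant")
  expect_equal(d0, 0)
  y <- stats::rnorm(200); x2 <- stats::rnorm(200)
  expect_lt(distance_correlation(x2, y), 0.2)
})

test_that("hypergeometric enrichment equals the brute-force tail sum", {
  universe <- sprintf("g%03d", 1:100)
  hits <- universe[1:10]
  sets <- list(allhit = universe[1:5], none = universe[90:95])
  res <- hypergeom_enrichment(hits, universe, sets)
  # brute force: P(overlap >= 5) drawing |set|=5 from urn with 10 hits / 90 non
  brute <- sum(vapply(5:5, function(k) {
    choose(10, k) * choose(90, 5 - k) / choose(100, 5)
  }, numeric(1)))
  expect_equal(res$p[res$set_name == "allhit"], brute, tolerance = 1e-12)
  expect_equal(res$p[res$set_name == "none"], 1)

  # degenerate urn: every universe gene is a hit
  res2 <- hypergeom_enrichment(universe, universe, sets)
  expect_equal(res2$p, c(1, 1))
  expect_error(hypergeom_enrichment(hits, character(0), sets), "empty universe")
})
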