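make_sep_data <- function(n_per = 10, gap = 6, seed = 1) {
  set.seed(seed)
  m <- cbind(matrix(stats::rnorm(2 * n_per, 0, 1), 2),
             matrix(stats::rnorm(2 * n_per, gap, 1), 2))
  dimnames(m) <- list(c("f1", "f2"), sprintf("s%02d", seq_len(2 * n_per)))
  labels <- stats::setNames(rep(c("neg", "pos"), each = n_per), colnames(m))
  list(x = expr_matrix(m, "log2tpm"), labels = labels)
}

test_that("feature selection by score correlation is strict, ordered and order invariant", {
  set.seed(21)
  n <- 40
  score <- stats::rnorm(n)
  m <- matrix(stats::rnorm(20 * n), 20,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:n)))
  m["g05", ] <- score           # the score itself
  m["g09", ] <- -score          # anticorrelated: |rho| counts
  x <- expr_matrix(m, "log2tpm")
  scores <- tibble::tibble(sample_id = colnames(m), m5c_score = score)
  res <- select_features_by_correlation(x, scores, threshold = 0.9)
  expect_setequal(res$genes, c("g05", "g09"))
  expect_equal(abs(res$detail$rho[res$detail$gene_id == "g05"]), 1)
  expect_identical(res$genes,
                   select_features_by_correlation(
                     expr_matrix(m[sample(20), ], "log2tpm"), scores,
                     threshold = 0.9)$genes)
  expect_error(select_features_by_correlation(x, scores, threshold = 1),
               "no gene")
})

test_that("correlated features are recovered against an independent background", {
  set.seed(22)
  n <- 120
  score <- stats::rnorm(n)
  n_bg <- 500
  m <- matrix(stats::rnorm((n_bg + 10) * n), n_bg + 10,
              dimnames = list(sprintf("g%03d", seq_len(n_bg + 10)),
                              sprintf("s%03d", seq_len(n))))
  for (i in 1:10) m[i, ] <- score + stats::rnorm(n, 0, 1)  # r ~ 0.7
  scores <- tibble::tibble(sample_id = colnames(m), m5c_score = score)
  res <- select_features_by_correlation(expr_matrix(m, "log2tpm"), scores,
                                        threshold = 0.4)
  hits <- sprintf("g%03d", 1:10)
  expect_gte(sum(hits %in% res$genes), 9)
  expect_lte(mean(setdiff(rownames(m), hits) %in% res$genes), 0.03)
})

test_that("a separable toy problem is classified perfectly and deterministically", {
  d <- make_sep_data()
  model <- train_classifier(d$x, d$labels, positive_class = "pos")
  ev <- evaluate_classifier(model, d$x, d$labels)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$auc, 1)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$specificity, 1)

  # duplicated training set: identical decision function
  dup <- cbind(unclass(d$x), unclass(d$x))
  colnames(dup) <- c(colnames(d$x), paste0("d_", colnames(d$x)))
  lab_dup <- stats::setNames(rep(d$labels, 2), colnames(dup))
  model2 <- train_classifier(expr_matrix(dup, "log2tpm"), lab_dup,
                             positive_class = "pos")
  expect_equal(predict(model2, d$x)$decision, predict(model, d$x)$decision,
               tolerance = 1e-6)

  expect_error(train_classifier(d$x, d$labels[1:10]), "2 classes")
})

test_that("serialized models restore bit-identical predictions", {
  d <- make_sep_data(seed = 2)
  for (kern in c("linear", "radial")) {
    model <- train_classifier(d$x, d$labels, positive_class = "pos",
                              kernel = kern)
    path <- withr::local_tempfile(fileext = ".json")
    serialize_classifier(model, path)
    restored <- restore_classifier(path)
    expect_identical(predict(restored, d$x)$decision,
                     predict(model, d$x)$decision)
    expect_identical(predict(restored, d$x)$predicted,
                     predict(model, d$x)$predicted)
  }
})

test_that("rank AUC equals the brute-force pairwise ordering fraction", {
  brute_auc <- function(d, y) {
    pos <- d[y]; neg <- d[!y]
    s <- 0
    for (p in pos) for (q in neg) {
      s <- s + (p > q) + 0.5 * (p == q)
    }
    s / (length(pos) * length(neg))
  }
  set.seed(23)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    d <- sample(stats::rnorm(n))
    if (i %% 3 == 0) d <- round(d)   # force ties
    y <- stats::runif(n) > 0.5
    if (!any(y) || all(y)) next
    expect_identical(rank_auc(d, y), brute_auc(d, y))
  }
  expect_equal(rank_auc(rep(1, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  # invariance under strictly increasing transforms
  d <- stats::rnorm(30); y <- stats::runif(30) > 0.4
  expect_equal(rank_auc(exp(d), y), rank_auc(d, y))
})

test_that("rank AUC agrees with the pROC reference", {
  skip_if_not_installed("pROC")
  set.seed(24)
  d <- stats::rnorm(60)
  y <- stats::runif(60) > 0.5
  ref <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = d,
                                        quiet = TRUE, direction = "<")))
  expect_equal(rank_auc(d, y), ref, tolerance = 1e-12)
})

test_that("undefined sensitivity is NA, not zero", {
  d <- make_sep_data(seed = 3)
  model <- train_classifier(d$x, d$labels, positive_class = "pos")
  neg_only <- d$labels[d$labels == "neg"]
  ev <- evaluate_classifier(model, d$x[, names(neg_only)], neg_only)
  expect_true(is.na(ev$sensitivity))
  expect_true(is.na(ev$auc))
  expect_equal(ev$specificity, 1)
})

test_that("tumor/normal classification on the synthetic cohort cross-validates accurately", {
  co <- small_cohort(seed = 25, n_genes = 200, n_samples_tumor = 80,
                     n_samples_normal = 40, tumor_effect = 2,
                     n_phenotype_genes = 10)
  lx <- log2_transform(co$expression)
  labels <- stats::setNames(co$clinical$tissue, co$clinical$sample_id)
  cv <- cross_validate_classifier(lx, labels,
                                  feature_genes = co$truth$phenotype_genes,
                                  positive_class = "tumor", seed = 5)
  expect_gte(cv$accuracy, 0.95)
  expect_identical(nrow(cv$fold_reports), 5L)
})
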