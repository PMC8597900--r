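#' Select feature genes by correlation with the score
#'
#' Per gene, computes the correlation between expression and the per-sample
#' score and retains genes with `|rho|` strictly above `threshold`, ordered by
#' descending `|rho|` (the correlation screen behind the 10-gene diagnostic
#' feature set).
#'
#' @param expr expression matrix.
#' @param scores tibble with `sample_id`, `m5c_score` aligned with `expr`
#'   samples.
#' @param threshold absolute correlation cutoff (strict inequality).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return list with `genes` (ordered character vector) and `detail`
#'   (tibble `gene_id`, `rho`).
#' @export
select_features_by_correlation <- function(expr, scores, threshold = 0.4,
                                           method = c("spearman", "pearson")) {
  method <- match.arg(method)
  common <- intersect(colnames(expr), scores$sample_id)
  if (length(common) < 3L) stop("need >= 3 aligned samples", call. = FALSE)
  s <- scores$m5c_score[match(common, scores$sample_id)]
  x <- expr[, common, drop = FALSE]
  rho <- suppressWarnings(
    as.numeric(stats::cor(t(x), s, method = method))
  )
  detail <- tibble::tibble(gene_id = rownames(expr), rho = rho)
  keep <- detail[!is.na(detail$rho) & abs(detail$rho) > threshold, ]
  keep <- keep[order(-abs(keep$rho)), ]
  if (nrow(keep) == 0L) {
    stop("no gene exceeds |rho| > ", threshold, call. = FALSE)
  }
  list(genes = keep$gene_id, detail = detail)
}

#' Train the diagnostic SVM classifier
#'
#' Standardizes the feature genes by their training mean/SD and fits a
#' soft-margin support-vector classifier (`e1071::svm`). The fitted decision
#' function is stored explicitly (support vectors, coefficients, offset) so a
#' serialized model reproduces predictions bit-identically. The decision
#' value is oriented so larger values favor the positive class.
#'
#' @param expr expression matrix restricted (or restrictable) to the feature
#'   genes.
#' @param labels named binary labels (sample id -> class), both classes with
#'   >= 3 samples.
#' @param feature_genes gene ids used as features.
#' @param positive_class label value treated as positive; defaults to the
#'   first level encountered.
#' @param kernel `"linear"` (default) or `"radial"`.
#' @param c_param soft-margin cost C.
#' @param gamma RBF bandwidth (radial kernel only).
#' @param seed integer seed (the fit itself is deterministic; kept for the
#'   model record).
#' @return an object of class `classifier_model`.
#' @export
train_classifier <- function(expr, labels, feature_genes = rownames(expr),
                             positive_class = NULL,
                             kernel = c("linear", "radial"), c_param = 1,
                             gamma = NULL, seed = 1L) {
  kernel <- match.arg(kernel)
  labels <- labels[names(labels) %in% colnames(expr)]
  classes <- sort(unique(as.character(labels)))
  if (length(classes) != 2L) stop("labels must contain exactly 2 classes",
                                  call. = FALSE)
  if (any(table(labels) < 3L)) stop("both classes need >= 3 samples", call. = FALSE)
  if (is.null(positive_class)) positive_class <- classes[1L]
  if (!positive_class %in% classes) stop("positive_class not among labels",
                                         call. = FALSE)
  negative_class <- setdiff(classes, positive_class)
  missing <- setdiff(feature_genes, rownames(expr))
  if (length(missing)) {
    stop("feature genes absent from matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }

  x <- t(expr[feature_genes, names(labels), drop = FALSE])  # samples x features
  center <- colMeans(x)
  scale <- apply(x, 2L, stats::sd)
  scale[scale == 0] <- 1
  xs <- sweep(sweep(x, 2L, center), 2L, scale, "/")

  y <- factor(as.character(labels), levels = c(positive_class, negative_class))
  if (is.null(gamma)) gamma <- 1 / length(feature_genes)
  set.seed(as.integer(seed))
  fit <- e1071::svm(xs, y, kernel = kernel, cost = c_param, gamma = gamma,
                    scale = FALSE, probability = FALSE)
  model <- list(kernel = kernel, gamma = gamma, sv = unname(fit$SV),
                sv_coefs = as.numeric(fit$coefs), rho = as.numeric(fit$rho))
  # e1071's decision-value sign depends on the internal label order; orient it
  # so positive decisions favor positive_class
  d_train <- decision_values(model, xs)
  if (mean(d_train[y == positive_class]) < mean(d_train[y == negative_class])) {
    model$sv_coefs <- -model$sv_coefs
    model$rho <- -model$rho
  }
  structure(list(
    feature_genes = feature_genes,
    center = center, scale = scale,
    positive_class = positive_class, negative_class = negative_class,
    kernel = kernel, c_param = c_param, gamma = gamma,
    sv = model$sv, sv_coefs = model$sv_coefs, rho = model$rho,
    seed = as.integer(seed)
  ), class = "classifier_model")
}

# decision values for standardized feature rows
decision_values <- function(model, xs) {
  if (model$kernel == "linear") {
    w <- drop(crossprod(model$sv, model$sv_coefs))
    drop(xs %*% w) - model$rho
  } else {
    k <- exp(-model$gamma *
               (outer(rowSums(xs^2), rowSums(model$sv^2), "+") -
                  2 * tcrossprod(xs, model$sv)))
    drop(k %*% model$sv_coefs) - model$rho
  }
}

#' Predict with a diagnostic classifier
#'
#' @param object a `classifier_model`.
#' @param expr expression matrix containing the model's feature genes.
#' @param ... unused.
#' @return tibble with `sample_id`, `decision` (larger favors the positive
#'   class), `predicted`.
#' @export
predict.classifier_model <- function(object, expr, ...) {
  x <- t(expr[object$feature_genes, , drop = FALSE])
  xs <- sweep(sweep(x, 2L, object$center), 2L, object$scale, "/")
  d <- decision_values(object, xs)
  tibble::tibble(
    sample_id = colnames(expr),
    decision = unname(d),
    predicted = ifelse(d > 0, object$positive_class, object$negative_class)
  )
}

#' Serialize and restore a classifier model as JSON
#'
#' Plain-text round trip: `restore_classifier(read(serialize(model)))`
#' reproduces predictions bit-identically.
#'
#' @param model a `classifier_model`.
#' @param path output JSON path.
#' @return `path` invisibly; `restore_classifier` returns the model.
#' @export
serialize_classifier <- function(model, path) {
  obj <- unclass(model)
  # hex floats ("%a") round-trip doubles exactly through text
  num <- c("center", "scale", "sv_coefs", "rho", "c_param", "gamma")
  for (f in num) obj[[f]] <- sprintf("%a", obj[[f]])
  obj$sv_dim <- dim(model$sv)
  obj$sv <- sprintf("%a", as.numeric(model$sv))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname serialize_classifier
#' @export
restore_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  num <- c("center", "scale", "sv_coefs", "rho", "c_param", "gamma")
  for (f in num) obj[[f]] <- as.numeric(obj[[f]])
  obj$sv <- matrix(as.numeric(obj$sv), obj$sv_dim[1], obj$sv_dim[2])
  obj$sv_dim <- NULL
  obj$center <- stats::setNames(obj$center, obj$feature_genes)
  obj$scale <- stats::setNames(obj$scale, obj$feature_genes)
  obj$seed <- as.integer(obj$seed)
  structure(obj, class = "classifier_model")
}

#' Rank-formula AUC
#'
#' Mann-Whitney AUC with tie correction: the probability that a random
#' positive outranks a random negative, counting ties as one half.
#'
#' @param decision continuous decision values.
#' @param truth binary truth (logical or coercible; `TRUE` = positive).
#' @return scalar AUC in \[0, 1\].
#' @export
rank_auc <- function(decision, truth) {
  truth <- as.logical(truth)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(decision)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a classifier against truth labels
#'
#' Confusion matrix, accuracy, sensitivity, specificity, and the rank-formula
#' AUC from the continuous decision values. Undefined rates (e.g. sensitivity
#' with no positives) are reported as `NA`, not 0.
#'
#' @param model a `classifier_model`.
#' @param expr expression matrix.
#' @param truth named vector (sample id -> class label).
#' @return one-row tibble of class `eval_report`: `accuracy`, `sensitivity`,
#'   `specificity`, `auc`, `tp`, `fp`, `tn`, `fn`, `n`.
#' @export
evaluate_classifier <- function(model, expr, truth) {
  truth <- truth[names(truth) %in% colnames(expr)]
  pred <- predict(model, expr[, names(truth), drop = FALSE])
  is_pos <- as.character(truth) == model$positive_class
  pred_pos <- pred$predicted == model$positive_class
  tp <- sum(pred_pos & is_pos); fp <- sum(pred_pos & !is_pos)
  tn <- sum(!pred_pos & !is_pos); fn <- sum(!pred_pos & is_pos)
  n <- length(truth)
  out <- tibble::tibble(
    accuracy = (tp + tn) / n,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    auc = rank_auc(pred$decision, is_pos),
    tp = tp, fp = fp, tn = tn, fn = fn, n = n
  )
  class(out) <- c("eval_report", class(out))
  out
}

#' Cross-validated accuracy of the diagnostic classifier
#'
#' Stratified k-fold cross-validation of [train_classifier()] /
#' [evaluate_classifier()] with a fixed fold assignment derived from `seed`.
#'
#' @inheritParams train_classifier
#' @param n_folds number of folds.
#' @return list with `accuracy` (mean held-out accuracy), `fold_reports`
#'   (tibble of per-fold eval rows).
#' @export
cross_validate_classifier <- function(expr, labels,
                                      feature_genes = rownames(expr),
                                      positive_class = NULL,
                                      kernel = "linear", c_param = 1,
                                      n_folds = 5L, seed = 1L) {
  labels <- labels[names(labels) %in% colnames(expr)]
  set.seed(as.integer(seed))
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  reports <- purrr::map_dfr(seq_len(n_folds), function(f) {
    tr <- names(labels)[folds != f]
    te <- names(labels)[folds == f]
    m <- train_classifier(expr[, tr, drop = FALSE], labels[tr],
                          feature_genes = feature_genes,
                          positive_class = positive_class,
                          kernel = kernel, c_param = c_param, seed = seed)
    ev <- evaluate_classifier(m, expr[, te, drop = FALSE], labels[te])
    dplyr::bind_cols(tibble::tibble(fold = f), ev)
  })
  list(accuracy = mean(reports$accuracy), fold_reports = reports)
}
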