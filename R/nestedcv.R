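# Nested cross-validated classification with leakage-safe preprocessing.
# All preprocessing (median imputation, z-scaling, univariate top-k filter)
# is fit on training folds only and applied to held-out data.

stratified_folds <- function(y, k, seed) {
  n <- length(y)
  for (bump in 0:20) {
    fold <- integer(n)
    with_seed_(child_seed(seed, 100 + bump), {
      for (cls in unique(y)) {
        idx <- sample(which(y == cls))
        fold[idx] <- rep_len(seq_len(k), length(idx))
      }
    })
    counts <- table(factor(fold, levels = seq_len(k)), factor(y))
    if (all(counts > 0) || min(table(y)) < k) {
      if (bump > 0) {
        message(sprintf("fold stratification reseeded (%d bump(s))", bump))
      }
      return(fold)
    }
  }
  fold
}

# Preprocessor: median imputation + z-scaling, fit on training rows.
preproc_fit <- function(X) {
  med <- vapply(X, function(col) stats::median(col, na.rm = TRUE), numeric(1))
  med[is.na(med)] <- 0
  Ximp <- X
  for (j in seq_along(Ximp)) {
    Ximp[[j]][is.na(Ximp[[j]])] <- med[j]
  }
  mu <- vapply(Ximp, mean, numeric(1))
  sd <- vapply(Ximp, stats::sd, numeric(1))
  sd[sd == 0 | is.na(sd)] <- 1
  list(median = med, mean = mu, sd = sd)
}

preproc_apply <- function(pp, X) {
  for (j in seq_along(X)) {
    X[[j]][is.na(X[[j]])] <- pp$median[j]
    X[[j]] <- (X[[j]] - pp$mean[j]) / pp$sd[j]
  }
  as.matrix(X)
}

# One-way ANOVA F score of each column against a binary target.
anova_f_scores <- function(X, y) {
  apply(X, 2, function(col) {
    m <- tapply(col, y, mean)
    n_g <- tapply(col, y, length)
    gm <- mean(col)
    ssb <- sum(n_g * (m - gm)^2)
    ssw <- sum((col - m[as.character(y)])^2)
    dfb <- length(m) - 1
    dfw <- length(col) - length(m)
    if (ssw <= 0 || dfw <= 0) return(Inf)
    (ssb / dfb) / (ssw / dfw)
  })
}

fit_classifier <- function(X, y, classifier, seed) {
  if (classifier == "logistic") {
    df <- as.data.frame(X)
    fit <- suppressWarnings(
      stats::glm(y ~ ., data = cbind(df, y = y), family = stats::binomial())
    )
    list(type = "logistic", fit = fit, cols = colnames(X))
  } else if (classifier == "random_forest") {
    df <- as.data.frame(X)
    df$.y <- factor(y, levels = c(0, 1))
    fit <- ranger::ranger(dependent.variable.name = ".y", data = df,
                          probability = TRUE, num.trees = 500,
                          min.node.size = 5, seed = seed, num.threads = 1)
    list(type = "random_forest", fit = fit, cols = colnames(X))
  } else if (classifier == "gradient_boosting") {
    dtr <- xgboost::xgb.DMatrix(X, label = y)
    fit <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = 0.1, max_depth = 2,
                    subsample = 0.8, nthread = 1, seed = seed),
      data = dtr, nrounds = 100, verbose = 0
    )
    list(type = "gradient_boosting", fit = fit, cols = colnames(X))
  } else {
    stop(sprintf("unknown classifier '%s'", classifier), call. = FALSE)
  }
}

predict_classifier <- function(model, X) {
  X <- X[, model$cols, drop = FALSE]
  if (model$type == "logistic") {
    unname(suppressWarnings(stats::predict(model$fit,
                                           newdata = as.data.frame(X),
                                           type = "response")))
  } else if (model$type == "random_forest") {
    unname(stats::predict(model$fit, data = as.data.frame(X),
                          num.threads = 1)$predictions[, "1"])
  } else {
    unname(stats::predict(model$fit, xgboost::xgb.DMatrix(X)))
  }
}

# Full train/predict pipeline on one split for a fixed k.
pipe_predict <- function(train_X, train_y, test_X, k, classifier, seed) {
  pp <- preproc_fit(train_X)
  Xtr <- preproc_apply(pp, train_X)
  Xte <- preproc_apply(pp, test_X)
  k <- min(k, ncol(Xtr))
  scores <- anova_f_scores(Xtr, train_y)
  top <- order(scores, decreasing = TRUE)[seq_len(k)]
  model <- fit_classifier(Xtr[, top, drop = FALSE], train_y, classifier, seed)
  clip01(predict_classifier(model, Xte[, top, drop = FALSE]))
}

# Inner-CV AUC for each k in the grid; returns the best k (ties -> smaller).
select_k_inner <- function(X, y, k_grid, inner_folds, classifier, seed) {
  k_grid <- k_grid[k_grid <= ncol(X)]
  if (length(k_grid) == 0) k_grid <- ncol(X)
  if (length(k_grid) == 1) return(k_grid)
  fold <- stratified_folds(y, inner_folds, seed)
  auc_k <- vapply(k_grid, function(k) {
    p <- rep(NA_real_, length(y))
    for (f in seq_len(inner_folds)) {
      tr <- fold != f; te <- fold == f
      if (length(unique(y[tr])) < 2 || !any(te)) next
      p[te] <- pipe_predict(X[tr, , drop = FALSE], y[tr],
                            X[te, , drop = FALSE], k, classifier,
                            child_seed(seed, 1000 + f))
    }
    auc_rank(y[!is.na(p)], p[!is.na(p)])
  }, numeric(1))
  auc_k[is.na(auc_k)] <- -Inf
  k_grid[which.max(auc_k)]
}

#' Nested cross-validated classification for a predictor block
#'
#' Outer stratified 5-fold cross-validation produces out-of-fold (OOF)
#' probability predictions; an inner 5-fold loop selects the number of
#' features `k` (ANOVA-F top-k filter) from `k_grid`. Median imputation,
#' z-scaling and selection are all fit inside the training folds only.
#' Reported per classifier: pooled OOF AUC with a 2000-resample percentile
#' bootstrap CI, Brier score, and TRIPOD calibration intercept/slope; the
#' best classifier is chosen by OOF AUC.
#'
#' @param data Modeling tibble from [assemble_model_data()] (columns `y`
#'   plus predictors).
#' @param block A block spec from [assemble_blocks()].
#' @param classifiers Subset of `"logistic"`, `"random_forest"`,
#'   `"gradient_boosting"`.
#' @param k_grid Candidate feature counts (default `c(2, 3, 5)`).
#' @param outer_folds,inner_folds Fold counts (default 5/5).
#' @param n_boot Bootstrap resamples for the AUC CI (default 2000; 0 skips).
#' @param seed Seed controlling folds, classifiers and bootstrap.
#' @return Object of class `prediction_result`: `metrics` tibble (per
#'   classifier: auc, ci, brier, calibration intercept/slope, chosen k per
#'   fold), `oof` tibble of pooled OOF predictions, `best` classifier name.
#' @export
nested_cv <- function(data, block,
                      classifiers = c("logistic", "random_forest",
                                      "gradient_boosting"),
                      k_grid = c(2, 3, 5), outer_folds = 5, inner_folds = 5,
                      n_boot = 2000, seed = 1) {
  y <- data$y
  stopifnot(length(unique(y)) == 2, nrow(data) >= 10)
  X_all <- data[, block$variables, drop = FALSE]
  fold <- stratified_folds(y, outer_folds, seed)
  oof <- list(); metrics <- list()
  for (cl in classifiers) {
    p <- rep(NA_real_, length(y))
    k_chosen <- integer(outer_folds)
    for (f in seq_len(outer_folds)) {
      tr <- fold != f; te <- fold == f
      if (!any(te)) next
      k_best <- select_k_inner(X_all[tr, , drop = FALSE], y[tr], k_grid,
                               inner_folds, cl, child_seed(seed, 10 * f))
      k_chosen[f] <- k_best
      p[te] <- pipe_predict(X_all[tr, , drop = FALSE], y[tr],
                            X_all[te, , drop = FALSE], k_best, cl,
                            child_seed(seed, 10 * f + 1))
    }
    ok <- !is.na(p)
    auc <- auc_rank(y[ok], p[ok])
    ci <- boot_ci(function(idx) auc_rank(y[ok][idx], p[ok][idx]),
                  sum(ok), n_boot, child_seed(seed, 7))
    brier <- mean((p[ok] - y[ok])^2)
    cal <- tryCatch(
      calibration_metrics(y[ok], p[ok], n_boot = 0),
      error = function(e) tibble::tibble(intercept = NA_real_,
                                         slope = NA_real_)
    )
    metrics[[cl]] <- tibble::tibble(
      classifier = cl, target = block$target, block = block$name,
      auc = auc, auc_lo = ci[1], auc_hi = ci[2], brier = brier,
      calib_intercept = cal$intercept[1], calib_slope = cal$slope[1],
      k_chosen = paste(k_chosen, collapse = "/")
    )
    oof[[cl]] <- tibble::tibble(classifier = cl,
                                patient_id = data$patient_id,
                                center = data$center,
                                y = y, p = p, fold = fold)
  }
  metrics <- dplyr::bind_rows(metrics)
  best <- metrics$classifier[which.max(metrics$auc)]
  structure(list(metrics = metrics, oof = dplyr::bind_rows(oof),
                 best = best, block = block$name, target = block$target),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("Nested CV: block %s, target %s (best: %s)\n",
              x$block, x$target, x$best))
  print(x$metrics[, c("classifier", "auc", "auc_lo", "auc_hi", "brier",
                      "calib_slope")])
  invisible(x)
}

#' @export
tidy.prediction_result <- function(x, ...) x$metrics

#' @export
glance.prediction_result <- function(x, ...) {
  best <- x$metrics[x$metrics$classifier == x$best, ]
  tibble::tibble(block = x$block, target = x$target, best = x$best,
                 auc = best$auc, brier = best$brier,
                 calib_slope = best$calib_slope)
}

#' Plot pooled out-of-fold ROC curves
#'
#' @param object A `prediction_result`.
#' @param ... Unused.
#' @return A ggplot with one ROC curve per classifier.
#' @export
autoplot.prediction_result <- function(object, ...) {
  d <- dplyr::filter(object$oof, !is.na(.data$p))
  roc <- d |>
    dplyr::group_by(.data$classifier) |>
    dplyr::arrange(dplyr::desc(.data$p), .by_group = TRUE) |>
    dplyr::mutate(tpr = cumsum(.data$y == 1) / sum(.data$y == 1),
                  fpr = cumsum(.data$y == 0) / sum(.data$y == 0)) |>
    dplyr::ungroup()
  ggplot2::ggplot(roc, ggplot2::aes(.data$fpr, .data$tpr,
                                    colour = .data$classifier)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = 2, colour = "grey60") +
    ggplot2::labs(x = "False-positive rate", y = "True-positive rate",
                  title = sprintf("Block %s, target %s", object$block,
                                  object$target)) +
    ggplot2::theme_minimal()
}
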