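#' Leave-one-center-out cross-validation
#'
#' The strongest internal proxy for external validation in a two-center
#' cohort: the full pipeline (imputation, scaling, inner-CV `k` selection,
#' classifier fit) is trained on one center and predicts the other, in both
#' directions; all out-of-fold predictions are pooled into a single AUC
#' with a 1000-resample percentile bootstrap CI. Test-center rows are never
#' touched during training.
#'
#' @param data Modeling tibble from [assemble_model_data()] (needs a
#'   `center` column).
#' @param block A block spec from [assemble_blocks()].
#' @param classifier Single classifier name (default `"logistic"`).
#' @param k_grid,inner_folds As in [nested_cv()].
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Seed.
#' @return One-row tibble: `block`, `target`, `classifier`, `loco_auc`,
#'   `loco_lo`, `loco_hi`, `n`. If a center lacks an outcome class the AUC
#'   is `NaN` with a warning.
#' @export
loco_cv <- function(data, block, classifier = "logistic",
                    k_grid = c(2, 3, 5), inner_folds = 5, n_boot = 1000,
                    seed = 1) {
  centers <- sort(unique(data$center))
  if (length(centers) != 2) {
    stop("loco_cv expects exactly two centers", call. = FALSE)
  }
  y <- data$y
  block_name <- block$name
  block_target <- block$target
  per_center <- table(data$center, y)
  if (any(per_center == 0)) {
    warning("a center lacks an outcome class; LOCO AUC undefined",
            call. = FALSE)
    return(tibble::tibble(block = block_name, target = block_target,
                          classifier = classifier, loco_auc = NaN,
                          loco_lo = NA_real_, loco_hi = NA_real_,
                          n = nrow(data)))
  }
  X_all <- data[, block$variables, drop = FALSE]
  p <- rep(NA_real_, length(y))
  for (ctr in centers) {
    tr <- data$center != ctr
    te <- data$center == ctr
    k_best <- select_k_inner(X_all[tr, , drop = FALSE], y[tr], k_grid,
                             inner_folds, classifier,
                             child_seed(seed, match(ctr, centers)))
    p[te] <- pipe_predict(X_all[tr, , drop = FALSE], y[tr],
                          X_all[te, , drop = FALSE], k_best, classifier,
                          child_seed(seed, 5 + match(ctr, centers)))
  }
  auc <- auc_rank(y, p)
  ci <- boot_ci(function(idx) auc_rank(y[idx], p[idx]), length(y), n_boot,
                child_seed(seed, 9))
  tibble::tibble(block = block_name, target = block_target,
                 classifier = classifier, loco_auc = auc,
                 loco_lo = ci[1], loco_hi = ci[2], n = length(y))
}
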