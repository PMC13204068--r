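#' Covariate balance check between centers
#'
#' Before harmonizing with center as the batch variable, verifies that
#' biological covariates are balanced across the two centers, so that
#' batch correction does not remove biology: continuous covariates are
#' compared with a two-sided Mann-Whitney U test, binary covariates with
#' Fisher's exact test.
#'
#' @param cohort Cohort tibble with a `center` column.
#' @param covariates Character vector of covariate column names.
#' @param alpha Flagging threshold (default 0.05).
#' @return A tibble: `covariate`, `test`, `p`, `flagged`.
#' @export
balance_check <- function(cohort, covariates, alpha = 0.05) {
  centers <- unique(cohort$center)
  if (length(centers) < 2) {
    stop("balance_check needs at least two centers", call. = FALSE)
  }
  rows <- lapply(covariates, function(cv) {
    x <- cohort[[cv]]
    if (is.null(x)) abort_field(cv, "not a cohort column")
    if (is.factor(x) || is.character(x)) x <- as.integer(factor(x))
    grp <- factor(cohort$center)
    if (length(unique(stats::na.omit(x))) < 2) {
      # constant covariate: perfectly balanced by the tie convention
      p <- 1
      test <- "degenerate"
    } else if (is_binary(x)) {
      tab <- table(factor(x), grp)
      p <- stats::fisher.test(tab)$p.value
      test <- "fisher"
    } else {
      p <- suppressWarnings(
        stats::wilcox.test(x ~ grp, exact = FALSE)$p.value
      )
      test <- "mann-whitney"
    }
    tibble::tibble(covariate = cv, test = test, p = p, flagged = p < alpha)
  })
  dplyr::bind_rows(rows)
}

# Method-of-moments inverse-gamma hyperparameters for the delta^2 prior.
ig_aprior <- function(d2) {
  m <- mean(d2); s2 <- stats::var(d2)
  (2 * s2 + m^2) / s2
}
ig_bprior <- function(d2) {
  m <- mean(d2); s2 <- stats::var(d2)
  (m * s2 + m^3) / s2
}

#' Fit a parametric empirical-Bayes ComBat model
#'
#' Location/scale batch-effect model for multi-center radiomic features,
#' with imaging center as the batch. Features are standardized by their
#' grand mean and pooled variance (no biological covariates in the design:
#' covariate balance is checked separately with [balance_check()]);
#' per-batch location (`gamma`) and scale (`delta^2`) parameters receive a
#' normal and an inverse-gamma prior whose hyperparameters are estimated by
#' method of moments, and the posterior estimates `(gamma*, delta*^2)` are
#' obtained by iterated conditional modes to a stated tolerance. Lesion and
#' pancreas rows are pooled in a single fit so both ROIs of a patient share
#' center parameters.
#'
#' @param data Feature table (stacked-ROI layout or any tibble with a batch
#'   column and numeric feature columns).
#' @param batch Name of the batch (center) column.
#' @param features Feature column names; default [feature_columns()].
#' @param tol Convergence tolerance of the EB iteration (default 1e-6).
#' @param max_iter Iteration cap (default 100).
#' @return An object of class `combat_model`: per-feature grand mean
#'   `alpha`, pooled variance `sigma2`, per-batch `gamma_star` and
#'   `delta2_star` matrices (batches x features), batch sizes, and the list
#'   of zero-variance features passed through unadjusted.
#' @export
combat_fit <- function(data, batch = "center", features = NULL,
                       tol = 1e-6, max_iter = 100) {
  if (is.null(features)) features <- feature_columns(data)
  b <- factor(data[[batch]])
  batches <- levels(b)
  if (length(batches) < 2) {
    warning("single batch: ComBat reduces to the identity transform",
            call. = FALSE)
  }
  nb <- table(b)
  if (any(nb < 2)) {
    stop("each batch needs at least 2 samples", call. = FALSE)
  }
  X <- as.matrix(data[, features, drop = FALSE])
  n <- nrow(X)
  as_bmat <- function(v) {
    if (length(batches) == 1) {
      matrix(v, nrow = 1, dimnames = list(batches, names(v)))
    } else {
      v
    }
  }

  # exclude zero-pooled-variance features, pass them through unadjusted
  batch_means <- as_bmat(apply(X, 2, function(col) tapply(col, b, mean)))
  resid <- X - batch_means[as.integer(b), , drop = FALSE]
  var_pooled <- colSums(resid^2) / n
  dropped <- features[var_pooled <= .Machine$double.eps * 100]
  if (length(dropped) > 0) {
    warning(sprintf("zero-variance feature(s) passed through unadjusted: %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
  }
  keep <- setdiff(features, dropped)
  X <- X[, keep, drop = FALSE]
  var_pooled <- var_pooled[keep]

  # grand mean weighted by batch sizes (standard ComBat "stand mean")
  bm <- batch_means[, keep, drop = FALSE]
  alpha <- colSums(bm * as.numeric(nb) / n)
  Z <- sweep(sweep(X, 2, alpha), 2, sqrt(var_pooled), `/`)

  gamma_hat <- as_bmat(apply(Z, 2, function(col) tapply(col, b, mean)))
  delta2_hat <- as_bmat(apply(Z, 2, function(col) tapply(col, b, stats::var)))
  rownames(gamma_hat) <- rownames(delta2_hat) <- batches

  gamma_star <- gamma_hat
  delta2_star <- delta2_hat
  if (length(batches) == 1) {
    # no batch effect is estimable from one batch: exact identity transform
    gamma_star[] <- 0
    delta2_star[] <- 1
  } else for (bi in seq_along(batches)) {
    g_hat <- gamma_hat[bi, ]
    d2_hat <- delta2_hat[bi, ]
    n_b <- as.numeric(nb[bi])
    g_bar <- mean(g_hat)
    tau2 <- stats::var(g_hat)
    a_pr <- ig_aprior(d2_hat)
    b_pr <- ig_bprior(d2_hat)
    zb <- Z[b == batches[bi], , drop = FALSE]
    g_new <- g_hat
    d2_new <- d2_hat
    for (it in seq_len(max_iter)) {
      g_old <- g_new; d2_old <- d2_new
      g_new <- (n_b * tau2 * g_hat + d2_new * g_bar) / (n_b * tau2 + d2_new)
      ss <- colSums(sweep(zb, 2, g_new)^2)
      d2_new <- (b_pr + 0.5 * ss) / (n_b / 2 + a_pr - 1)
      change <- max(abs(g_new - g_old) / (abs(g_old) + 1e-12),
                    abs(d2_new - d2_old) / (abs(d2_old) + 1e-12))
      if (change < tol) break
    }
    gamma_star[bi, ] <- g_new
    delta2_star[bi, ] <- d2_new
  }

  structure(list(alpha = alpha, sigma2 = var_pooled,
                 gamma_star = gamma_star, delta2_star = delta2_star,
                 gamma_hat = gamma_hat, delta2_hat = delta2_hat,
                 batches = batches, n_per_batch = as.integer(nb),
                 features = keep, dropped = dropped, batch_col = batch),
            class = "combat_model")
}

#' Apply a fitted ComBat model
#'
#' Harmonizes feature values batch by batch:
#' `x* = sigma * (z - gamma*) / delta* + alpha` with
#' `z = (x - alpha) / sigma`. Rows of the same patient (lesion and pancreas)
#' are transformed with the same center parameters because the model carries
#' one parameter pair per batch x feature. Features the model dropped as
#' zero-variance pass through unchanged; unseen batch labels are an error.
#'
#' @param model A [combat_fit()] model.
#' @param data Feature table containing the model's batch column and feature
#'   columns.
#' @return The data with harmonized feature values; a `harmonization`
#'   column, if present, is set to `"combat"`.
#' @export
combat_transform <- function(model, data) {
  b <- as.character(data[[model$batch_col]])
  unseen <- setdiff(unique(b), model$batches)
  if (length(unseen) > 0) {
    stop(sprintf("batch label(s) not seen at fit time: %s",
                 paste(unseen, collapse = ", ")), call. = FALSE)
  }
  feats <- model$features
  X <- as.matrix(data[, feats, drop = FALSE])
  Z <- sweep(sweep(X, 2, model$alpha), 2, sqrt(model$sigma2), `/`)
  bi <- match(b, model$batches)
  Zadj <- (Z - model$gamma_star[bi, , drop = FALSE]) /
    sqrt(model$delta2_star)[bi, , drop = FALSE]
  Xadj <- sweep(sweep(Zadj, 2, sqrt(model$sigma2), `*`), 2, model$alpha, `+`)
  out <- data
  out[, feats] <- tibble::as_tibble(as.data.frame(Xadj))
  if ("harmonization" %in% names(out)) out$harmonization <- "combat"
  out
}

#' @export
print.combat_model <- function(x, ...) {
  cat(sprintf("ComBat model: %d features, %d batch(es) [%s], n = %s\n",
              length(x$features), length(x$batches),
              paste(x$batches, collapse = ", "),
              paste(x$n_per_batch, collapse = "/")))
  if (length(x$dropped) > 0) {
    cat("passed through (zero variance):",
        paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a ComBat model
#'
#' @param x A `combat_model`.
#' @param ... Unused.
#' @return Tibble with one row per batch x feature: shrunk location
#'   (`gamma_star`, standardized scale) and scale (`delta_star`), plus the
#'   naive per-batch estimates.
#' @export
tidy.combat_model <- function(x, ...) {
  grid <- expand.grid(batch = x$batches, feature = x$features,
                      stringsAsFactors = FALSE)
  tibble::tibble(
    batch = grid$batch,
    feature = grid$feature,
    gamma_star = as.vector(x$gamma_star),
    delta_star = sqrt(as.vector(x$delta2_star)),
    gamma_hat = as.vector(x$gamma_hat),
    delta_hat = sqrt(as.vector(x$delta2_hat))
  )
}

#' @rdname tidy.combat_model
#' @export
glance.combat_model <- function(x, ...) {
  tibble::tibble(n_features = length(x$features),
                 n_batches = length(x$batches),
                 n_samples = sum(x$n_per_batch),
                 n_dropped = length(x$dropped))
}

#' Serialize / restore a ComBat model as JSON
#'
#' @param model A `combat_model`.
#' @param path File path.
#' @return `combat_write` invisibly returns the path; `combat_read` returns
#'   the restored model.
#' @export
combat_write <- function(model, path) {
  obj <- lapply(unclass(model), function(el) {
    if (is.matrix(el)) list(values = as.vector(el), dim = dim(el)) else el
  })
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname combat_write
#' @export
combat_read <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("gamma_star", "delta2_star", "gamma_hat", "delta2_hat")) {
    obj[[nm]] <- matrix(obj[[nm]]$values, obj[[nm]]$dim[1], obj[[nm]]$dim[2],
                        dimnames = list(obj$batches, obj$features))
  }
  for (nm in c("alpha", "sigma2")) {
    obj[[nm]] <- stats::setNames(obj[[nm]], obj$features)
  }
  structure(obj, class = "combat_model")
}
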