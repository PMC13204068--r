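# Feature-screening cascade: correlation clustering, baseline-adjusted
# likelihood-ratio testing with BH-FDR, and bootstrap stability selection.

# Connected components by union-find.
union_find_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    root
  }
  if (nrow(edges) > 0) {
    for (r in seq_len(nrow(edges))) {
      a <- find(edges[r, 1]); b <- find(edges[r, 2])
      if (a != b) parent[b] <- a
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Correlation clustering of candidate features
#'
#' Builds a graph with an edge wherever |Spearman rho| meets the threshold,
#' takes connected components as clusters, and picks each cluster's medoid
#' (the member with the highest mean |rho| to the other members; ties broken
#' by feature name) as its representative.
#'
#' @param data Tibble containing the feature columns.
#' @param features Feature column names (default: all numeric columns).
#' @param threshold |Spearman rho| edge threshold (default 0.80).
#' @return List: `clusters` (named list of feature-name vectors),
#'   `representatives` (character), `membership` tibble.
#' @export
correlation_cluster <- function(data, features = NULL, threshold = 0.80) {
  if (is.null(features)) {
    features <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  all_na <- vapply(features, function(f) all(is.na(data[[f]])), logical(1))
  if (any(all_na)) {
    warning(sprintf("all-missing feature(s) dropped: %s",
                    paste(features[all_na], collapse = ", ")), call. = FALSE)
    features <- features[!all_na]
  }
  if (length(features) < 2) {
    return(list(clusters = stats::setNames(as.list(features), features),
                representatives = features,
                membership = tibble::tibble(feature = features,
                                            cluster = seq_along(features),
                                            representative = features)))
  }
  X <- as.matrix(data[, features, drop = FALSE])
  rho <- suppressWarnings(stats::cor(X, method = "spearman",
                                     use = "pairwise.complete.obs"))
  rho[is.na(rho)] <- 0
  adj <- abs(rho) >= threshold
  edges <- which(adj & upper.tri(adj), arr.ind = TRUE)
  comp <- union_find_components(length(features), edges)
  comp <- match(comp, unique(comp))
  clusters <- split(features, comp)
  reps <- vapply(clusters, function(members) {
    if (length(members) == 1) return(members)
    members <- sort(members)
    score <- vapply(members, function(m) {
      mean(abs(rho[m, setdiff(members, m)]))
    }, numeric(1))
    members[which.max(score)]   # which.max takes the first on ties (by name)
  }, character(1))
  names(clusters) <- reps
  list(clusters = clusters, representatives = unname(reps),
       membership = tibble::tibble(feature = features, cluster = comp,
                                   representative = reps[comp]))
}

# Ridge-penalized logistic IRLS; fallback when glm hits separation.
ridge_logistic <- function(X, y, lambda = 1e-3, max_iter = 100) {
  X <- cbind(1, X)
  beta <- rep(0, ncol(X))
  pen <- diag(c(0, rep(lambda, ncol(X) - 1)), ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- clip01(stats::plogis(eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(X * sqrt(w)) + pen, crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < 1e-8) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  eta <- drop(X %*% beta)
  mu <- clip01(stats::plogis(eta))
  list(beta = drop(beta),
       deviance = -2 * sum(y * log(mu) + (1 - y) * log(1 - mu)))
}

fit_logistic_deviance <- function(X, y) {
  df <- as.data.frame(X)
  fit <- tryCatch(
    withCallingHandlers(
      stats::glm(y ~ ., data = cbind(df, y = y), family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities|did not converge",
                  conditionMessage(w))) {
          stop("separation", call. = FALSE)
        }
      }
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    warning("separation detected; ridge-penalized fallback used",
            call. = FALSE)
    return(ridge_logistic(as.matrix(X), y)$deviance)
  }
  fit$deviance
}

#' Baseline-adjusted likelihood-ratio screen
#'
#' For each candidate feature, tests whether adding it to a logistic model
#' of the binary target on the baseline variables improves fit:
#' LRT = deviance(baseline) - deviance(baseline + candidate), p from
#' chi-square with 1 df, BH-FDR across candidates. Complete cases per
#' candidate. On separation a ridge-penalized fit is used with a warning.
#'
#' @param data Tibble with candidates, baseline variables and the target.
#' @param candidates Candidate feature column names.
#' @param baseline_vars Baseline (adjustment) column names.
#' @param target Binary target column name.
#' @return Tibble: `candidate`, `lrt`, `p`, `q` (BH), ordered as given.
#' @export
baseline_adjusted_lrt <- function(data, candidates, baseline_vars, target) {
  y_all <- data[[target]]
  rows <- lapply(candidates, function(cand) {
    ok <- stats::complete.cases(data[, c(cand, baseline_vars, target)])
    if (sum(ok) < length(baseline_vars) + 3 ||
        length(unique(y_all[ok])) < 2) {
      return(tibble::tibble(candidate = cand, lrt = NA_real_, p = NA_real_))
    }
    y <- y_all[ok]
    Xb <- data[ok, baseline_vars, drop = FALSE]
    Xf <- data[ok, c(baseline_vars, cand), drop = FALSE]
    d0 <- fit_logistic_deviance(Xb, y)
    d1 <- fit_logistic_deviance(Xf, y)
    lrt <- max(d0 - d1, 0)
    tibble::tibble(candidate = cand, lrt = lrt,
                   p = stats::pchisq(lrt, 1, lower.tail = FALSE))
  })
  out <- dplyr::bind_rows(rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Bootstrap stability selection on top of the LRT screen
#'
#' Resamples patients with replacement `B` times; within each resample,
#' re-runs [baseline_adjusted_lrt()] and records which candidates pass
#' BH-FDR < `fdr`. A candidate is selected if its selection frequency
#' reaches `threshold`. Degenerate resamples (single outcome class) are
#' redrawn.
#'
#' @param data,candidates,baseline_vars,target As in
#'   [baseline_adjusted_lrt()].
#' @param B Number of bootstrap resamples (default 100).
#' @param fdr FDR threshold inside each resample (default 0.10).
#' @param threshold Selection-frequency threshold (default 0.60).
#' @param seed Seed.
#' @return Tibble: `candidate`, `frequency`, `selected`.
#' @export
stability_selection <- function(data, candidates, baseline_vars, target,
                                B = 100, fdr = 0.10, threshold = 0.60,
                                seed = 1) {
  stopifnot(length(candidates) > 0)
  n <- nrow(data)
  hits <- stats::setNames(rep(0, length(candidates)), candidates)
  n_redrawn <- 0
  with_seed_(seed, {
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(stats::na.omit(data[[target]][idx]))) == 2) break
        n_redrawn <- n_redrawn + 1
      }
      res <- suppressWarnings(
        baseline_adjusted_lrt(data[idx, ], candidates, baseline_vars, target)
      )
      sel <- res$candidate[!is.na(res$q) & res$q < fdr]
      hits[sel] <- hits[sel] + 1
    }
  })
  if (n_redrawn > 0) {
    message(sprintf("%d degenerate bootstrap resample(s) redrawn", n_redrawn))
  }
  freq <- hits / B
  tibble::tibble(candidate = candidates, frequency = unname(freq),
                 selected = unname(freq >= threshold))
}
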