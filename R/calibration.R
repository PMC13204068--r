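#' TRIPOD calibration intercept and slope
#'
#' Fits the logistic recalibration model of the binary outcome on the logit
#' of the predicted probability: `logit P(y = 1) = a + b * logit(p)`.
#' Perfect calibration gives intercept 0 and slope 1; slopes below 1
#' indicate optimistic (over-dispersed) predictions. Also reports the
#' calibration-in-the-large intercept estimated with the slope fixed at 1
#' (offset model). Probabilities are clipped to `[eps, 1 - eps]` before the
#' logit.
#'
#' @param y Binary outcomes (0/1).
#' @param p Predicted probabilities.
#' @param n_boot Percentile-bootstrap resamples for CIs (default 2000;
#'   0 skips the bootstrap).
#' @param seed Bootstrap seed.
#' @param eps Clipping bound (default 1e-6).
#' @return One-row tibble: `intercept`, `slope`, `intercept_fixed_slope`,
#'   and bootstrap CIs when requested.
#' @export
calibration_metrics <- function(y, p, n_boot = 2000, seed = 1, eps = 1e-6) {
  ok <- !is.na(y) & !is.na(p)
  y <- y[ok]; p <- clip01(p[ok], eps)
  lp <- stats::qlogis(p)
  if (stats::var(lp) == 0) {
    stop("constant predictions: calibration slope undefined", call. = FALSE)
  }
  fit_one <- function(yy, ll) {
    fit <- suppressWarnings(
      stats::glm(yy ~ ll, family = stats::binomial())
    )
    unname(stats::coef(fit))
  }
  cf <- fit_one(y, lp)
  fit_off <- suppressWarnings(
    stats::glm(y ~ 1 + offset(lp), family = stats::binomial())
  )
  out <- tibble::tibble(intercept = cf[1], slope = cf[2],
                        intercept_fixed_slope = unname(stats::coef(fit_off))[1])
  if (n_boot > 0) {
    n <- length(y)
    ci_i <- boot_ci(function(idx) {
      if (length(unique(y[idx])) < 2 || stats::var(lp[idx]) == 0) {
        return(NA_real_)
      }
      fit_one(y[idx], lp[idx])[1]
    }, n, n_boot, child_seed(seed, 1))
    ci_s <- boot_ci(function(idx) {
      if (length(unique(y[idx])) < 2 || stats::var(lp[idx]) == 0) {
        return(NA_real_)
      }
      fit_one(y[idx], lp[idx])[2]
    }, n, n_boot, child_seed(seed, 1))
    out$intercept_lo <- ci_i[1]; out$intercept_hi <- ci_i[2]
    out$slope_lo <- ci_s[1]; out$slope_hi <- ci_s[2]
  }
  out
}

#' Reliability diagram of out-of-fold predictions
#'
#' @param y,p Outcomes and predicted probabilities.
#' @param bins Number of equal-width probability bins (default 10).
#' @return A ggplot: observed event fraction versus mean predicted
#'   probability per bin, with the identity line.
#' @export
plot_calibration <- function(y, p, bins = 10) {
  d <- tibble::tibble(y = y, p = p) |>
    dplyr::filter(!is.na(.data$y), !is.na(.data$p)) |>
    dplyr::mutate(bin = cut(.data$p, seq(0, 1, length.out = bins + 1),
                            include.lowest = TRUE)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(pred = mean(.data$p), obs = mean(.data$y),
                     n = dplyr::n(), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(.data$pred, .data$obs, size = .data$n)) +
    ggplot2::geom_abline(linetype = 2, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Predicted probability", y = "Observed fraction",
                  size = "n") +
    ggplot2::theme_minimal()
}
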