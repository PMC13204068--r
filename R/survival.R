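#' Z-standardize over complete cases
#'
#' Centers and scales to unit SD (sample SD, n-1 denominator) over the
#' non-missing values; missing values stay missing. Signatures are
#' standardized this way before entering Cox regression so hazard ratios are
#' per 1-SD increase.
#'
#' @param x Numeric vector.
#' @return Numeric vector of the same length; `NA` preserved. The complete-
#'   case mask is `!is.na()` of the result.
#' @export
z_standardize <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 2) stop("need >= 2 non-missing values", call. = FALSE)
  s <- stats::sd(x[ok])
  if (s == 0) stop("zero standard deviation", call. = FALSE)
  out <- rep(NA_real_, length(x))
  out[ok] <- (x[ok] - mean(x[ok])) / s
  out
}

# Cox partial log-likelihood at a fixed coefficient (Efron ties).
cox_loglik_at <- function(beta, z, time, event) {
  fit <- survival::coxph(survival::Surv(time, event) ~ z, ties = "efron",
                         init = beta,
                         control = survival::coxph.control(iter.max = 0))
  fit$loglik[2]
}

# One-sided profile-likelihood bound by bisection on the LR surface.
profile_bound <- function(beta_hat, ll_max, z, time, event, side,
                          level = 0.95, tol = 1e-6) {
  target <- ll_max - stats::qchisq(level, 1) / 2
  step <- 0.5
  outer_b <- beta_hat
  repeat {
    outer_b <- outer_b + side * step
    ll <- cox_loglik_at(outer_b, z, time, event)
    if (!is.finite(ll)) return(side * Inf)
    if (ll < target) break
    step <- step * 2
    if (abs(outer_b - beta_hat) > 50) return(side * Inf)
  }
  lo <- beta_hat; hi <- outer_b
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    if (cox_loglik_at(mid, z, time, event) >= target) lo <- mid else hi <- mid
    if (abs(hi - lo) < tol) break
  }
  (lo + hi) / 2
}

#' Univariable Cox regression with profile-likelihood intervals
#'
#' Fits a single-covariate Cox proportional-hazards model (Efron tie
#' handling) on the complete cases and reports the hazard ratio per unit of
#' the covariate (per 1-SD when the input is [z_standardize()]d) with a 95%
#' profile-likelihood interval obtained by bisection on the likelihood-ratio
#' surface. Monotone likelihoods (perfect risk separation) yield a flagged
#' result with an infinite bound rather than an error.
#'
#' @param z Covariate (typically z-standardized signature values).
#' @param time,event Right-censored follow-up and event indicator (0/1).
#' @param p_type `"wald"` (default, reported) or `"lrt"`.
#' @param level Confidence level (default 0.95).
#' @return One-row tibble: `n`, `events`, `beta`, `hr_per_sd`, `ci_low`,
#'   `ci_high`, `p`, `p_type`, `monotone` flag.
#' @export
cox_univariable <- function(z, time, event, p_type = c("wald", "lrt"),
                            level = 0.95) {
  p_type <- match.arg(p_type)
  ok <- !is.na(z) & !is.na(time) & !is.na(event)
  z <- z[ok]; time <- time[ok]; event <- event[ok]
  if (sum(event) < 1) stop("need at least one event", call. = FALSE)
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ z, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  monotone <- !is.finite(beta) || abs(beta) > 20 || !is.finite(se)
  ll_max <- fit$loglik[2]
  lo <- profile_bound(beta, ll_max, z, time, event, -1, level)
  hi <- profile_bound(beta, ll_max, z, time, event, +1, level)
  p <- if (p_type == "wald") {
    2 * stats::pnorm(-abs(beta / se))
  } else {
    stats::pchisq(2 * (fit$loglik[2] - fit$loglik[1]), 1, lower.tail = FALSE)
  }
  tibble::tibble(n = length(z), events = sum(event), beta = beta,
                 hr_per_sd = exp(beta), ci_low = exp(lo), ci_high = exp(hi),
                 p = p, p_type = p_type, monotone = monotone)
}

#' Concordance index with bootstrap and permutation inference
#'
#' Harrell's c over usable pairs, oriented so that higher scores predicting
#' earlier events give c > 0.5. The bootstrap CI is percentile over patients
#' (2000 resamples); the permutation p-value permutes the score across
#' patients, keeping (time, event) pairs fixed, and is computed on the
#' direction-free scale `|c| = max(c, 1 - c)`:
#' `p = (1 + #(|c_perm| >= |c_obs|)) / (n_perm + 1)`.
#'
#' @param z Risk score.
#' @param time,event Right-censored outcome.
#' @param n_boot,n_perm Resample counts (defaults 2000 / 1000).
#' @param seed Seed for both resampling streams.
#' @return One-row tibble: `c`, `c_lo`, `c_hi`, `c_abs`, `c_perm_p`.
#' @export
concordance_inference <- function(z, time, event, n_boot = 2000,
                                  n_perm = 1000, seed = 1) {
  ok <- !is.na(z) & !is.na(time) & !is.na(event)
  z <- z[ok]; time <- time[ok]; event <- event[ok]
  n <- length(z)
  cidx <- function(zz, tt, ee) {
    cf <- survival::concordance(survival::Surv(tt, ee) ~ zz, reverse = TRUE)
    if ((cf$count[1] + cf$count[2] + cf$count[3]) == 0) return(NA_real_)
    unname(cf$concordance)
  }
  c_obs <- cidx(z, time, event)
  if (is.na(c_obs)) stop("no comparable pairs", call. = FALSE)
  ci <- boot_ci(function(idx) cidx(z[idx], time[idx], event[idx]),
                n, n_boot, child_seed(seed, 1))
  c_abs_obs <- max(c_obs, 1 - c_obs)
  perm_p <- NA_real_
  if (n_perm > 0) {
    exceed <- with_seed_(child_seed(seed, 2), {
      sum(vapply(seq_len(n_perm), function(b) {
        cp <- cidx(sample(z), time, event)
        !is.na(cp) && max(cp, 1 - cp) >= c_abs_obs
      }, logical(1)))
    })
    perm_p <- (1 + exceed) / (n_perm + 1)
  }
  tibble::tibble(c = c_obs, c_lo = ci[1], c_hi = ci[2],
                 c_abs = c_abs_obs, c_perm_p = perm_p)
}

#' Univariable survival screen of the signature panel
#'
#' For each signature column: z-standardize within its complete-case subset,
#' fit [cox_univariable()], and attach [concordance_inference()]. Reproduces
#' the per-signature complete-case `n`/`events` bookkeeping of the panel
#' summary table.
#'
#' @param signatures Signature tibble (from [compute_signatures()]).
#' @param time,event Outcome vectors aligned with `signatures` rows.
#' @param columns Signature columns to test (default `A1..A7`, `B1..B3`).
#' @param n_boot,n_perm,seed Passed to [concordance_inference()].
#' @return Object of class `signature_cox`: a tibble with one row per
#'   signature (HR per SD, profile CI, p, concordance inference).
#' @export
signature_cox <- function(signatures, time, event,
                          columns = intersect(c(paste0("A", 1:7),
                                                paste0("B", 1:3)),
                                              names(signatures)),
                          n_boot = 2000, n_perm = 1000, seed = 1) {
  rows <- lapply(seq_along(columns), function(k) {
    sig <- columns[k]
    x <- signatures[[sig]]
    ok <- !is.na(x) & !is.na(time) & !is.na(event)
    if (sum(ok & event == 1, na.rm = TRUE) < 1 || sum(ok) < 3) {
      return(tibble::tibble(signature = sig, n = sum(ok),
                            events = sum(event[ok], na.rm = TRUE)))
    }
    z <- z_standardize(ifelse(ok, x, NA))
    cx <- cox_univariable(z[ok], time[ok], event[ok])
    cc <- concordance_inference(z[ok], time[ok], event[ok],
                                n_boot = n_boot, n_perm = n_perm,
                                seed = child_seed(seed, k))
    dplyr::bind_cols(tibble::tibble(signature = sig), cx, cc)
  })
  structure(dplyr::bind_rows(rows), class = c("signature_cox",
                                              class(tibble::tibble())))
}

#' @export
tidy.signature_cox <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.signature_cox <- function(x, ...) {
  tibble::tibble(n_signatures = nrow(x),
                 n_significant = sum(x$p < 0.05, na.rm = TRUE))
}
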