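# Internal helpers shared across modules.

# Evaluate `code` under a local RNG state; the caller's stream is untouched.
with_seed_ <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Derive a child seed from a parent seed; kept within 32-bit integer range.
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + 7919 * stream) %% 2147483647)
}

abort_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

# Rank-based AUC (probability a random positive outranks a random negative;
# ties counted 1/2). Used for fold selection and pooled out-of-fold metrics.
auc_rank <- function(y, p) {
  stopifnot(length(y) == length(p))
  ok <- !is.na(y) & !is.na(p)
  y <- y[ok]; p <- p[ok]
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(p)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Percentile bootstrap CI of a statistic computed on resampled rows.
boot_ci <- function(stat_fn, n, n_boot, seed, level = 0.95) {
  if (n_boot <= 0) return(c(NA_real_, NA_real_))
  vals <- with_seed_(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      stat_fn(idx)
    }, numeric(1))
  })
  vals <- vals[is.finite(vals)]
  if (length(vals) < 2) return(c(NA_real_, NA_real_))
  a <- (1 - level) / 2
  unname(stats::quantile(vals, c(a, 1 - a), na.rm = TRUE, type = 7))
}

clip01 <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

is_binary <- function(x) {
  u <- unique(stats::na.omit(x))
  length(u) <= 2
}
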