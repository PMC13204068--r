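# Independent oracles used across test files. These re-derive quantities by
# brute force / closed form and never call the package code paths they check.

# Efron partial log-likelihood for a single covariate, written from the
# definition (event-time grouping, Efron tie correction).
efron_loglik_oracle <- function(beta, z, time, event) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(event == 1 & time == t)
    R <- which(time >= t)
    d <- length(D)
    sumD <- sum(exp(beta * z[D]))
    sumR <- sum(exp(beta * z[R]))
    ll <- ll + sum(beta * z[D])
    for (l in 0:(d - 1)) {
      ll <- ll - log(sumR - (l / d) * sumD)
    }
  }
  ll
}

# Harrell's c by exhaustive pair enumeration (distinct times assumed).
cindex_oracle <- function(z, time, event) {
  num <- 0; den <- 0
  n <- length(z)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      # i experiences the event first and j is still at risk
      if (event[i] == 1 && time[i] < time[j]) {
        den <- den + 1
        if (z[i] > z[j]) num <- num + 1
        if (z[i] == z[j]) num <- num + 0.5
      }
    }
  }
  num / den
}

# Connected zones of equal gray level (26-connectivity) by repeated
# neighbor scanning over coordinates; independent of the package BFS.
zones_oracle <- function(bins_array) {
  coords <- which(!is.na(bins_array), arr.ind = TRUE)
  lev <- bins_array[coords]
  n <- nrow(coords)
  label <- rep(0L, n)
  nxt <- 0L
  adjacent <- function(a, b) all(abs(coords[a, ] - coords[b, ]) <= 1)
  for (s in seq_len(n)) {
    if (label[s] > 0) next
    nxt <- nxt + 1L
    label[s] <- nxt
    repeat {
      grew <- FALSE
      for (a in which(label == nxt)) {
        for (b in which(label == 0 & lev == lev[s])) {
          if (adjacent(a, b)) {
            label[b] <- nxt
            grew <- TRUE
          }
        }
      }
      if (!grew) break
    }
  }
  data.frame(level = tapply(lev, label, unique),
             size = as.integer(table(label)))
}

# NGTDM p_i, s_i by direct per-voxel loops over the 26-neighborhood.
ngtdm_oracle <- function(bins_array) {
  d <- dim(bins_array)
  coords <- which(!is.na(bins_array), arr.ind = TRUE)
  lev <- bins_array[coords]
  nl <- max(lev)
  s <- numeric(nl); n <- integer(nl)
  for (v in seq_len(nrow(coords))) {
    nb <- c()
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      p <- coords[v, ] + c(dx, dy, dz)
      if (any(p < 1) || any(p > d)) next
      val <- bins_array[p[1], p[2], p[3]]
      if (!is.na(val)) nb <- c(nb, val)
    }
    i <- lev[v]
    n[i] <- n[i] + 1L
    if (length(nb) > 0) s[i] <- s[i] + abs(i - mean(nb))
  }
  list(p = n / sum(n), s = s, n = n)
}

ngtdm_busyness_oracle <- function(bins_array) {
  o <- ngtdm_oracle(bins_array)
  act <- which(o$p > 0)
  den <- sum(abs(outer(act * o$p[act], act * o$p[act], `-`)))
  if (den == 0) return(0)
  sum(o$p[act] * o$s[act]) / den
}

# GLCM from explicit pair enumeration for one direction, symmetrized.
glcm_oracle <- function(bins_array, dir, n_levels) {
  d <- dim(bins_array)
  m <- matrix(0, n_levels, n_levels)
  coords <- which(!is.na(bins_array), arr.ind = TRUE)
  for (v in seq_len(nrow(coords))) {
    p <- coords[v, ] + dir
    if (any(p < 1) || any(p > d)) next
    val <- bins_array[p[1], p[2], p[3]]
    if (is.na(val)) next
    a <- bins_array[coords[v, 1], coords[v, 2], coords[v, 3]]
    m[a, val] <- m[a, val] + 1
  }
  m <- m + t(m)
  m / sum(m)
}

# Small deterministic ROI sample built directly from a bin array.
sample_from_bins <- function(bins_array, bin_width = 25,
                             spacing = c(1, 1, 1)) {
  mask <- !is.na(bins_array)
  structure(list(
    intensities = (bins_array[mask] - 1) * bin_width,
    bins = as.integer(bins_array[mask]),
    bins_array = bins_array,
    mask = mask,
    coords = which(mask, arr.ind = TRUE),
    spacing = spacing,
    n_levels = max(bins_array, na.rm = TRUE),
    bin_width = bin_width
  ), class = "roi_sample")
}

# Simulate a simple survival dataset with a known hazard ratio per SD.
simulate_ph <- function(n, beta, seed, censor = Inf) {
  set.seed(seed)
  z <- rnorm(n)
  t_event <- rexp(n, rate = 0.05 * exp(beta * z))
  t_cens <- if (is.infinite(censor)) rep(Inf, n) else runif(n, 0, censor)
  data.frame(z = z, time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens))
}
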