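# Gray-level texture matrices (GLCM, GLRLM, GLSZM, GLDM, NGTDM) over the
# discretized ROI, 3D with 26-connected neighborhoods, distance 1.
# GLCM/GLRLM are built per direction (13 unique directions) and their
# features averaged over directions.

# 13 unique direction offsets (first nonzero component positive).
texture_directions <- function() {
  rbind(c(1,0,0), c(0,1,0), c(0,0,1),
        c(1,1,0), c(1,-1,0), c(1,0,1), c(1,0,-1),
        c(0,1,1), c(0,1,-1),
        c(1,1,1), c(1,1,-1), c(1,-1,1), c(1,-1,-1))
}

# 26-connected neighbor offsets.
neighbor_offsets26 <- function() {
  g <- expand.grid(x = -1:1, y = -1:1, z = -1:1)
  as.matrix(g[!(g$x == 0 & g$y == 0 & g$z == 0), ])
}

# Shift a 3D array by an offset vector, NA-filling.
shift3 <- function(a, o) {
  d <- dim(a)
  out <- array(a[NA_integer_][1], dim = d)  # NA of matching type
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    n <- d[ax]; oo <- o[ax]
    if (abs(oo) >= n) return(out)
    src[[ax]] <- if (oo >= 0) (1 + oo):n else 1:(n + oo)
    dst[[ax]] <- if (oo >= 0) 1:(n - oo) else (1 - oo):n
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

glcm_one_direction <- function(bins_array, d, n_levels) {
  b2 <- shift3(bins_array, d)
  ok <- !is.na(bins_array) & !is.na(b2)
  if (!any(ok)) return(NULL)
  counts <- table(factor(bins_array[ok], levels = seq_len(n_levels)),
                  factor(b2[ok], levels = seq_len(n_levels)))
  m <- matrix(as.numeric(counts), n_levels, n_levels)
  m <- m + t(m)                       # symmetric co-occurrences
  m / sum(m)
}

glrlm_one_direction <- function(bins_array, d, n_levels) {
  dmax <- max(dim(bins_array))
  prev <- shift3(bins_array, -d)
  start <- !is.na(bins_array) & (is.na(prev) | prev != bins_array)
  idx <- which(start, arr.ind = TRUE)
  if (nrow(idx) == 0) return(matrix(0, n_levels, 1))
  lev <- bins_array[start]
  len <- rep(1L, nrow(idx))
  cur <- idx
  active <- seq_len(nrow(idx))
  dims <- dim(bins_array)
  while (length(active) > 0) {
    nxt <- cur[active, , drop = FALSE] +
      matrix(d, length(active), 3, byrow = TRUE)
    inb <- nxt[, 1] >= 1 & nxt[, 1] <= dims[1] &
      nxt[, 2] >= 1 & nxt[, 2] <= dims[2] &
      nxt[, 3] >= 1 & nxt[, 3] <= dims[3]
    same <- rep(FALSE, length(active))
    if (any(inb)) {
      v <- bins_array[nxt[inb, , drop = FALSE]]
      same[inb] <- !is.na(v) & v == lev[active][inb]
    }
    cont <- active[same]
    len[cont] <- len[cont] + 1L
    cur[cont, ] <- nxt[same, , drop = FALSE]
    active <- cont
  }
  m <- matrix(0, n_levels, max(len))
  for (k in seq_along(lev)) m[lev[k], len[k]] <- m[lev[k], len[k]] + 1
  m
}

glszm_matrix <- function(bins_array, n_levels) {
  pb <- array(NA_integer_, dim = dim(bins_array) + 2L)
  d <- dim(pb)
  pb[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- bins_array
  offs26 <- neighbor_offsets26()
  loffs <- offs26[, 1] + offs26[, 2] * d[1] + offs26[, 3] * d[1] * d[2]
  visited <- rep(FALSE, prod(d))
  roi <- which(!is.na(pb))
  zones <- list(level = integer(0), size = integer(0))
  for (seed in roi) {
    if (visited[seed]) next
    level <- pb[seed]
    visited[seed] <- TRUE
    frontier <- seed
    size <- 1L
    while (length(frontier) > 0) {
      cand <- unique(as.vector(outer(frontier, loffs, `+`)))
      cand <- cand[!visited[cand] & !is.na(pb[cand]) & pb[cand] == level]
      visited[cand] <- TRUE
      size <- size + length(cand)
      frontier <- cand
    }
    zones$level <- c(zones$level, level)
    zones$size <- c(zones$size, size)
  }
  m <- matrix(0, n_levels, max(zones$size))
  for (k in seq_along(zones$level)) {
    m[zones$level[k], zones$size[k]] <- m[zones$level[k], zones$size[k]] + 1
  }
  m
}

gldm_matrix <- function(bins_array, n_levels) {
  offs <- neighbor_offsets26()
  dep <- array(0L, dim = dim(bins_array))
  for (r in seq_len(nrow(offs))) {
    nb <- shift3(bins_array, offs[r, ])
    dep <- dep + (!is.na(nb) & !is.na(bins_array) & nb == bins_array)
  }
  roi <- !is.na(bins_array)
  # dependence size = 1 + number of concordant neighbors (alpha = 0)
  j <- dep[roi] + 1L
  i <- bins_array[roi]
  m <- matrix(0, n_levels, max(j))
  for (k in seq_along(i)) m[i[k], j[k]] <- m[i[k], j[k]] + 1
  m
}

ngtdm_components <- function(bins_array, n_levels) {
  offs <- neighbor_offsets26()
  nsum <- array(0, dim = dim(bins_array))
  ncnt <- array(0L, dim = dim(bins_array))
  for (r in seq_len(nrow(offs))) {
    nb <- shift3(bins_array, offs[r, ])
    ok <- !is.na(nb)
    nsum[ok] <- nsum[ok] + nb[ok]
    ncnt <- ncnt + ok
  }
  roi <- !is.na(bins_array)
  lev <- bins_array[roi]
  cnt <- ncnt[roi]
  avg <- ifelse(cnt > 0, nsum[roi] / cnt, lev)  # isolated voxel: |i - A| = 0
  n_i <- tabulate(lev, nbins = n_levels)
  s_i <- vapply(seq_len(n_levels), function(l) {
    sum(abs(l - avg[lev == l]))
  }, numeric(1))
  list(levels = seq_len(n_levels), n = n_i, p = n_i / sum(n_i), s = s_i,
       n_voxels = sum(n_i))
}

#' Build the texture matrices of an ROI sample
#'
#' @param sample An [rad_preprocess()] ROI sample.
#' @return An object of class `texture_matrices`: per-direction GLCM and
#'   GLRLM lists (13 directions), GLSZM and GLDM matrices (rows = gray
#'   levels), and the NGTDM components (`n`, `p`, `s` per level).
#' @export
rad_texture_matrices <- function(sample) {
  ba <- sample$bins_array
  ng <- sample$n_levels
  dirs <- texture_directions()
  glcm <- list(); glrlm <- list()
  for (r in seq_len(nrow(dirs))) {
    glcm[[r]] <- glcm_one_direction(ba, dirs[r, ], ng)
    glrlm[[r]] <- glrlm_one_direction(ba, dirs[r, ], ng)
  }
  structure(list(glcm = glcm, glrlm = glrlm,
                 glszm = glszm_matrix(ba, ng),
                 gldm = gldm_matrix(ba, ng),
                 ngtdm = ngtdm_components(ba, ng),
                 n_levels = ng),
            class = "texture_matrices")
}

glcm_features_one <- function(P) {
  ng <- nrow(P)
  i <- row(P); j <- col(P)
  pij <- P
  mu_i <- sum(i * pij)
  sd_i <- sqrt(sum((i - mu_i)^2 * pij))
  corr <- if (sd_i > 0) sum((i - mu_i) * (j - mu_i) * pij) / sd_i^2 else 1
  nz <- pij > 0
  c(JointEnergy = sum(pij^2),
    JointEntropy = -sum(pij[nz] * log2(pij[nz])),
    Contrast = sum((i - j)^2 * pij),
    Correlation = corr,
    MaximumProbability = max(pij),
    Id = sum(pij / (1 + abs(i - j))),
    Idm = sum(pij / (1 + (i - j)^2)),
    Idn = sum(pij / (1 + abs(i - j) / ng)),
    Idmn = sum(pij / (1 + (i - j)^2 / ng^2)))
}

glrlm_features_one <- function(R) {
  nr <- sum(R)
  if (nr == 0) return(NULL)
  i <- row(R); j <- col(R)
  np <- sum(R * j)  # voxels covered by runs
  c(ShortRunEmphasis = sum(R / j^2) / nr,
    LongRunEmphasis = sum(R * j^2) / nr,
    GrayLevelNonUniformity = sum(rowSums(R)^2) / nr,
    RunLengthNonUniformity = sum(colSums(R)^2) / nr,
    RunPercentage = nr / np,
    HighGrayLevelRunEmphasis = sum(R * i^2) / nr)
}

glszm_features <- function(Z) {
  nz <- sum(Z)
  i <- row(Z); s <- col(Z)
  nvox <- sum(Z * s)
  p <- Z / nz
  pnz <- p[p > 0]
  c(SmallAreaEmphasis = sum(Z / s^2) / nz,
    LargeAreaEmphasis = sum(Z * s^2) / nz,
    GrayLevelNonUniformity = sum(rowSums(Z)^2) / nz,
    SizeZoneNonUniformity = sum(colSums(Z)^2) / nz,
    SmallAreaHighGrayLevelEmphasis = sum(Z * i^2 / s^2) / nz,
    ZonePercentage = nz / nvox,
    ZoneEntropy = -sum(pnz * log2(pnz)))
}

gldm_features <- function(D) {
  nd <- sum(D)
  i <- row(D); j <- col(D)
  p <- D / nd
  pnz <- p[p > 0]
  c(SmallDependenceEmphasis = sum(D / j^2) / nd,
    LargeDependenceEmphasis = sum(D * j^2) / nd,
    GrayLevelNonUniformity = sum(rowSums(D)^2) / nd,
    DependenceNonUniformity = sum(colSums(D)^2) / nd,
    DependenceEntropy = -sum(pnz * log2(pnz)))
}

ngtdm_features <- function(ng) {
  act <- ng$p > 0
  p <- ng$p[act]; s <- ng$s[act]; lev <- ng$levels[act]
  n_g <- length(lev)
  nvp <- ng$n_voxels
  ps <- sum(p * s)
  # Busyness denominator: full double sum over nonempty levels
  bus_den <- sum(abs(outer(lev * p, lev * p, `-`)))
  busyness <- if (bus_den > 0) ps / bus_den else 0
  coarseness <- if (ps > 0) 1 / ps else 1e6
  if (n_g > 1) {
    ii <- outer(lev, lev, `-`)
    pp <- outer(p, p)
    contrast <- (sum(pp * ii^2) / (n_g * (n_g - 1))) * (sum(s) / nvp)
    psum <- outer(p, p, `+`)
    pssum <- outer(p * s, p * s, `+`)
    complexity <- sum(abs(ii) * pssum / psum) / nvp
    str_den <- sum(s)
    strength <- if (str_den > 0) sum(psum * ii^2) / str_den else 0
  } else {
    contrast <- 0; complexity <- 0; strength <- 0
  }
  c(Coarseness = coarseness, Busyness = busyness, Contrast = contrast,
    Complexity = complexity, Strength = strength)
}

#' Texture features from the matrices
#'
#' GLCM and GLRLM features are computed per direction and averaged; GLSZM,
#' GLDM and NGTDM features come from their single aggregated matrices.
#' Degenerate conventions: a single-gray-level ROI has NGTDM Busyness 0
#' (zero denominator) and GLCM Idmn 1 (all mass on the diagonal).
#'
#' @param matrices A [rad_texture_matrices()] object.
#' @return Named numeric vector with class-prefixed feature names
#'   (`glcm_`, `glrlm_`, `glszm_`, `gldm_`, `ngtdm_`).
#' @export
rad_texture_features <- function(matrices) {
  avg_over_dirs <- function(lst, fn) {
    vals <- lapply(lst, function(m) if (is.null(m)) NULL else fn(m))
    vals <- vals[!vapply(vals, is.null, logical(1))]
    if (length(vals) == 0) return(NULL)
    Reduce(`+`, vals) / length(vals)
  }
  glcm <- avg_over_dirs(matrices$glcm, glcm_features_one)
  glrlm <- avg_over_dirs(matrices$glrlm, glrlm_features_one)
  if (is.null(glcm)) {  # single-voxel ROI: no voxel pairs in any direction
    glcm <- c(JointEnergy = 1, JointEntropy = 0, Contrast = 0, Correlation = 1,
              MaximumProbability = 1, Id = 1, Idm = 1, Idn = 1, Idmn = 1)
  }
  if (is.null(glrlm)) {
    glrlm <- c(ShortRunEmphasis = 1, LongRunEmphasis = 1,
               GrayLevelNonUniformity = 1, RunLengthNonUniformity = 1,
               RunPercentage = 1, HighGrayLevelRunEmphasis = 1)
  }
  out <- c(stats::setNames(glcm, paste0("glcm_", names(glcm))),
           stats::setNames(glrlm, paste0("glrlm_", names(glrlm))),
           stats::setNames(glszm_features(matrices$glszm),
                           paste0("glszm_", names(glszm_features(matrices$glszm)))),
           stats::setNames(gldm_features(matrices$gldm),
                           paste0("gldm_", names(gldm_features(matrices$gldm)))),
           stats::setNames(ngtdm_features(matrices$ngtdm),
                           paste0("ngtdm_", names(ngtdm_features(matrices$ngtdm)))))
  out
}

#' Extract all radiomic features from a volume and ROI masks
#'
#' Runs the preprocessing chain and all feature classes for each ROI mask;
#' shape features are computed from the resampled mask geometry.
#'
#' @param volume 3D HU array.
#' @param masks Named list of logical arrays (e.g.
#'   `list(lesion = ..., pancreas = ...)`).
#' @param spacing Voxel spacing in mm; defaults to the volume's attribute.
#' @param config An [extraction_config()].
#' @return A tibble with one row per ROI: `roi` plus one column per feature.
#'   If the config carries a `feature_inventory`, columns are restricted to
#'   it.
#' @export
extract_features <- function(volume, masks, spacing = attr(volume, "spacing"),
                             config = extraction_config()) {
  stopifnot(is.list(masks), !is.null(names(masks)))
  rows <- lapply(names(masks), function(roi) {
    sample <- rad_preprocess(volume, masks[[roi]], spacing = spacing,
                             config = config, roi = roi)
    feats <- c(rad_first_order(sample),
               rad_shape(sample$mask, sample$spacing),
               rad_texture_features(rad_texture_matrices(sample)))
    dplyr::bind_cols(tibble::tibble(roi = roi),
                     tibble::as_tibble(as.list(feats)))
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(config$feature_inventory)) {
    keep <- intersect(names(out), c("roi", config$feature_inventory))
    out <- out[, keep, drop = FALSE]
  }
  out
}
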