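#' Radiomic extraction settings
#'
#' Preprocessing chain applied before feature computation: isotropic
#' resampling (default 1 mm, cubic B-spline for the image, linear + 0.5
#' threshold for the mask), intensity resegmentation to a HU interval
#' (default [-150, 240]), and fixed-bin-width discretization (default 25 HU,
#' anchored at the in-ROI minimum).
#'
#' @param target_spacing Target voxel spacing in mm (length 1 or 3).
#' @param resegment_range HU interval `c(low, high)`; in-mask voxels outside
#'   it are removed. Use `c(-Inf, Inf)` to disable.
#' @param bin_width Discretization bin width in HU (> 0).
#' @param image_interpolator `"bspline"` (cubic, with prefilter) or
#'   `"linear"`.
#' @param mask_interpolator `"linear"` (linear + 0.5 threshold) or
#'   `"nearest"`.
#' @param bin_anchor `"roi_min"` (default) anchors bin edges at the in-ROI
#'   minimum; `"fixed"` anchors at `resegment_range[1]`.
#' @param feature_inventory Optional character vector restricting the
#'   features returned by [extract_features()].
#' @return An object of class `extraction_config`.
#' @export
extraction_config <- function(target_spacing = c(1, 1, 1),
                              resegment_range = c(-150, 240),
                              bin_width = 25,
                              image_interpolator = c("bspline", "linear"),
                              mask_interpolator = c("linear", "nearest"),
                              bin_anchor = c("roi_min", "fixed"),
                              feature_inventory = NULL) {
  if (bin_width <= 0) abort_field("bin_width", "must be > 0")
  if (resegment_range[1] >= resegment_range[2]) {
    abort_field("resegment_range", "low must be < high")
  }
  structure(list(target_spacing = rep_len(target_spacing, 3),
                 resegment_range = resegment_range,
                 bin_width = bin_width,
                 image_interpolator = match.arg(image_interpolator),
                 mask_interpolator = match.arg(mask_interpolator),
                 bin_anchor = match.arg(bin_anchor),
                 feature_inventory = feature_inventory),
            class = "extraction_config")
}

clamp_idx <- function(i, n) pmin(pmax(i, 1L), n)

# Cubic B-spline prefilter along the rows of a matrix (Unser's recursive
# filter, pole sqrt(3) - 2, mirror boundary), vectorized across columns.
bspline_prefilter <- function(m) {
  n <- nrow(m)
  if (n == 1) return(m)
  z <- sqrt(3) - 2
  m <- m * 6
  horizon <- min(n, ceiling(log(1e-12) / log(abs(z))))
  cp <- m
  cp[1, ] <- drop(z^(seq_len(horizon) - 1) %*% m[seq_len(horizon), , drop = FALSE])
  for (i in 2:n) cp[i, ] <- m[i, ] + z * cp[i - 1, ]
  cm <- cp
  cm[n, ] <- (z / (z * z - 1)) * (cp[n, ] + z * cp[n - 1, ])
  for (i in (n - 1):1) cm[i, ] <- z * (cm[i + 1, ] - cp[i, ])
  cm
}

# Resample one axis of a 3D array to n_out samples (separable kernels).
resample_axis <- function(a, axis, n_out, sp_in, sp_out, method) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  m <- aperm(a, perm)
  dm <- dim(m)
  dim(m) <- c(dm[1], prod(dm[-1]))
  n <- dm[1]
  pos <- ((seq_len(n_out) - 0.5) * sp_out) / sp_in + 0.5
  if (method == "nearest") {
    out <- m[clamp_idx(round(pos), n), , drop = FALSE]
  } else if (method == "linear") {
    i0 <- floor(pos)
    t <- pos - i0
    out <- (1 - t) * m[clamp_idx(i0, n), , drop = FALSE] +
      t * m[clamp_idx(i0 + 1, n), , drop = FALSE]
  } else { # cubic B-spline with prefiltering
    cf <- bspline_prefilter(m)
    i0 <- floor(pos)
    t <- pos - i0
    w <- list(`-1` = (1 - t)^3 / 6,
              `0` = (3 * t^3 - 6 * t^2 + 4) / 6,
              `1` = (-3 * t^3 + 3 * t^2 + 3 * t + 1) / 6,
              `2` = t^3 / 6)
    out <- matrix(0, n_out, ncol(m))
    for (o in -1:2) {
      out <- out + w[[as.character(o)]] * cf[clamp_idx(i0 + o, n), , drop = FALSE]
    }
  }
  dim(out) <- c(n_out, dm[-1])
  aperm(out, order(perm))
}

#' Resample a 3D volume to a target spacing
#'
#' Separable resampling at output voxel centers; `"bspline"` uses the cubic
#' B-spline with its interpolating prefilter, so an identity resampling
#' reproduces the input to numerical precision.
#'
#' @param volume 3D numeric array.
#' @param spacing Input spacing (mm, length 3).
#' @param target Target spacing (mm, length 3).
#' @param method `"bspline"`, `"linear"` or `"nearest"`.
#' @return Resampled array with a `spacing` attribute.
#' @export
resample_volume <- function(volume, spacing, target,
                            method = c("bspline", "linear", "nearest")) {
  method <- match.arg(method)
  spacing <- rep_len(spacing, 3)
  target <- rep_len(target, 3)
  d <- dim(volume)
  n_out <- pmax(1L, as.integer(round(d * spacing / target)))
  out <- volume
  for (axis in 1:3) {
    if (abs(spacing[axis] - target[axis]) < 1e-9 && n_out[axis] == d[axis]) next
    out <- resample_axis(out, axis, n_out[axis], spacing[axis], target[axis],
                         method)
  }
  attr(out, "spacing") <- target
  out
}

#' Preprocess a volume + mask into an ROI sample
#'
#' Applies the full extraction preprocessing chain: resampling of image and
#' mask to the target spacing, intensity resegmentation, and fixed-bin-width
#' discretization with bin index `floor((x - anchor) / bin_width) + 1`.
#'
#' @param volume 3D numeric array (HU).
#' @param mask Logical (or 0/1) array, same dimensions.
#' @param spacing Input voxel spacing in mm; defaults to the volume's
#'   `spacing` attribute.
#' @param config An [extraction_config()].
#' @param roi Label used in error messages.
#' @return An object of class `roi_sample`: `intensities` (in-mask HU after
#'   resegmentation), `bins` (1-based integer gray levels), `bins_array`
#'   (3D array, `NA` outside the ROI), `mask`, `coords` (voxel indices),
#'   `spacing`, `n_levels`, `bin_width`.
#' @export
rad_preprocess <- function(volume, mask, spacing = attr(volume, "spacing"),
                           config = extraction_config(), roi = "roi") {
  if (is.null(spacing)) abort_field("spacing", "unknown; pass it explicitly")
  if (!any(mask)) stop(sprintf("ROI '%s' is empty", roi), call. = FALSE)
  stopifnot(all(dim(volume) == dim(mask)))
  spacing <- rep_len(spacing, 3)
  target <- config$target_spacing
  if (any(abs(spacing - target) > 1e-9)) {
    volume <- resample_volume(volume, spacing, target,
                              method = config$image_interpolator)
    mnum <- resample_volume(array(as.numeric(mask), dim = dim(mask)),
                            spacing, target,
                            method = if (config$mask_interpolator == "nearest")
                              "nearest" else "linear")
    mask <- mnum >= 0.5
  } else {
    mask <- array(as.logical(mask), dim = dim(mask))
  }
  if (!any(mask)) {
    stop(sprintf("ROI '%s' is empty after resampling", roi), call. = FALSE)
  }
  vol <- array(as.numeric(volume), dim = dim(volume))
  keep <- vol >= config$resegment_range[1] & vol <= config$resegment_range[2]
  mask <- mask & keep
  if (!any(mask)) {
    stop(sprintf("ROI '%s' is empty after resegmentation", roi), call. = FALSE)
  }
  x <- vol[mask]
  anchor <- if (config$bin_anchor == "roi_min") min(x) else config$resegment_range[1]
  bins <- as.integer(floor((x - anchor) / config$bin_width)) + 1L
  bins_array <- array(NA_integer_, dim = dim(mask))
  bins_array[mask] <- bins
  structure(list(intensities = x, bins = bins, bins_array = bins_array,
                 mask = mask, coords = which(mask, arr.ind = TRUE),
                 spacing = target, n_levels = max(bins),
                 bin_width = config$bin_width),
            class = "roi_sample")
}
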