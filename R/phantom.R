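#' Specification of a 3D CT-like phantom
#'
#' Defines a synthetic portal-venous-phase-like CT volume containing two
#' disjoint ellipsoidal ROIs (lesion and pancreas). Each ROI has a base
#' attenuation in Hounsfield units plus a Gaussian-random-field texture with
#' a stated amplitude and correlation length; an additive scanner offset
#' shifts the whole volume (emulating calibration differences between
#' scanners) and white voxel noise is added on top.
#'
#' @param volume_shape Integer voxel dimensions, length 3.
#' @param spacing Voxel spacing in mm per axis (> 0).
#' @param lesion_geometry,pancreas_geometry Lists with `semi_axes` (mm,
#'   length 3) and `center` (mm, length 3, in world coordinates with the
#'   volume corner at the origin).
#' @param lesion_texture,pancreas_texture Lists with `base_hu`,
#'   `amplitude_hu`, `correlation_mm`.
#' @param background_hu Attenuation outside both ROIs.
#' @param scanner_offset_hu Additive HU shift applied to the whole volume.
#' @param noise_sd_hu SD of independent voxel noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(volume_shape = c(48L, 48L, 32L),
                         spacing = c(1, 1, 1),
                         lesion_geometry = list(semi_axes = c(8, 6, 5),
                                                center = c(15, 24, 16)),
                         pancreas_geometry = list(semi_axes = c(10, 7, 6),
                                                  center = c(34, 24, 16)),
                         lesion_texture = list(base_hu = 90, amplitude_hu = 20,
                                               correlation_mm = 3),
                         pancreas_texture = list(base_hu = 60, amplitude_hu = 10,
                                                 correlation_mm = 3),
                         background_hu = -30,
                         scanner_offset_hu = 0,
                         noise_sd_hu = 5) {
  if (any(spacing <= 0)) abort_field("spacing", "must be > 0")
  if (any(volume_shape < 1)) abort_field("volume_shape", "must be >= 1")
  structure(list(volume_shape = as.integer(volume_shape), spacing = spacing,
                 lesion_geometry = lesion_geometry,
                 pancreas_geometry = pancreas_geometry,
                 lesion_texture = lesion_texture,
                 pancreas_texture = pancreas_texture,
                 background_hu = background_hu,
                 scanner_offset_hu = scanner_offset_hu,
                 noise_sd_hu = noise_sd_hu),
            class = "phantom_spec")
}

# Voxel-center world coordinates along one axis (corner of volume at 0).
axis_coords <- function(n, sp) (seq_len(n) - 0.5) * sp

ellipsoid_mask <- function(shape, spacing, geometry) {
  cx <- axis_coords(shape[1], spacing[1])
  cy <- axis_coords(shape[2], spacing[2])
  cz <- axis_coords(shape[3], spacing[3])
  a <- geometry$semi_axes; ctr <- geometry$center
  dx2 <- ((cx - ctr[1]) / a[1])^2
  dy2 <- ((cy - ctr[2]) / a[2])^2
  dz2 <- ((cz - ctr[3]) / a[3])^2
  array(outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1, dim = shape)
}

# Shift an array along one axis by `o` voxels, zero-filling.
shift_array <- function(a, o, axis) {
  if (o == 0) return(a)
  d <- dim(a)
  out <- array(0, dim = d)
  n <- d[axis]
  if (abs(o) >= n) return(out)
  src <- if (o > 0) 1:(n - o) else (1 - o):n
  dst <- if (o > 0) (1 + o):n else 1:(n + o)
  idx_src <- idx_dst <- rep(list(quote(expr = )), 3)
  idx_src[[axis]] <- src; idx_dst[[axis]] <- dst
  out_call <- as.call(c(list(quote(`[<-`), quote(out)), idx_dst,
                        as.call(c(list(quote(`[`), quote(a)), idx_src))))
  eval(out_call)
}

# Separable Gaussian smoothing (zero-padded) of a 3D array; sigma in voxels.
gauss_smooth3 <- function(a, sigma) {
  sigma <- rep_len(sigma, 3)
  for (axis in 1:3) {
    s <- sigma[axis]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    w <- stats::dnorm(-r:r, sd = s)
    w <- w / sum(w)
    acc <- array(0, dim = dim(a))
    for (i in seq_along(w)) {
      acc <- acc + w[i] * shift_array(a, (-r:r)[i], axis)
    }
    a <- acc
  }
  a
}

# Stationary Gaussian random field: smoothed white noise rescaled to unit SD.
gaussian_random_field <- function(shape, spacing, correlation_mm) {
  z <- array(stats::rnorm(prod(shape)), dim = shape)
  if (correlation_mm <= 0) return(z)
  sig_vox <- correlation_mm / spacing
  f <- gauss_smooth3(z, sig_vox)
  s <- stats::sd(as.vector(f))
  if (s > 0) f / s else f
}

#' Generate a CT-like phantom volume with lesion and pancreas masks
#'
#' @param spec A [phantom_spec()].
#' @param seed Seed for the texture and noise draws.
#' @return A list with `volume` (3D HU array with a `spacing` attribute),
#'   `lesion_mask`, `pancreas_mask` (logical arrays), and `spacing`.
#' @export
generate_phantom <- function(spec = phantom_spec(), seed = NULL) {
  shape <- spec$volume_shape
  lesion <- ellipsoid_mask(shape, spec$spacing, spec$lesion_geometry)
  pancreas <- ellipsoid_mask(shape, spec$spacing, spec$pancreas_geometry)
  if (any(lesion & pancreas)) {
    stop("lesion and pancreas geometries overlap", call. = FALSE)
  }
  if (!any(lesion)) abort_field("lesion_geometry", "empty mask")
  if (!any(pancreas)) abort_field("pancreas_geometry", "empty mask")
  with_seed_(seed, {
    vol <- array(spec$background_hu, dim = shape)
    vol[lesion] <- spec$lesion_texture$base_hu
    vol[pancreas] <- spec$pancreas_texture$base_hu
    if (spec$lesion_texture$amplitude_hu > 0) {
      f <- gaussian_random_field(shape, spec$spacing,
                                 spec$lesion_texture$correlation_mm)
      vol[lesion] <- vol[lesion] + spec$lesion_texture$amplitude_hu * f[lesion]
    }
    if (spec$pancreas_texture$amplitude_hu > 0) {
      f <- gaussian_random_field(shape, spec$spacing,
                                 spec$pancreas_texture$correlation_mm)
      vol[pancreas] <- vol[pancreas] +
        spec$pancreas_texture$amplitude_hu * f[pancreas]
    }
    if (spec$noise_sd_hu > 0) {
      vol <- vol + array(stats::rnorm(prod(shape), 0, spec$noise_sd_hu),
                         dim = shape)
    }
    vol <- vol + spec$scanner_offset_hu
    attr(vol, "spacing") <- spec$spacing
    list(volume = vol, lesion_mask = lesion, pancreas_mask = pancreas,
         spacing = spec$spacing)
  })
}

#' Write / read a phantom as NIfTI
#'
#' Volumes are written with the voxel spacing carried in the affine, using
#' the standard NIfTI-1 format.
#'
#' @param phantom A list as returned by [generate_phantom()].
#' @param dir Output directory.
#' @param prefix File name prefix.
#' @return Invisibly, the written file paths.
#' @export
write_phantom <- function(phantom, dir, prefix = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- phantom$spacing
  paths <- c(
    volume = file.path(dir, paste0(prefix, "_volume.nii.gz")),
    lesion = file.path(dir, paste0(prefix, "_lesion.nii.gz")),
    pancreas = file.path(dir, paste0(prefix, "_pancreas.nii.gz"))
  )
  as_nii <- function(arr) {
    im <- RNifti::asNifti(arr)
    RNifti::pixdim(im) <- sp
    im
  }
  RNifti::writeNifti(as_nii(unclass(phantom$volume)), paths[["volume"]])
  RNifti::writeNifti(as_nii(array(as.integer(phantom$lesion_mask),
                                  dim = dim(phantom$lesion_mask))),
                     paths[["lesion"]])
  RNifti::writeNifti(as_nii(array(as.integer(phantom$pancreas_mask),
                                  dim = dim(phantom$pancreas_mask))),
                     paths[["pancreas"]])
  invisible(paths)
}

#' @rdname write_phantom
#' @param volume_path,lesion_path,pancreas_path Paths to NIfTI files.
#' @export
read_phantom <- function(volume_path, lesion_path, pancreas_path) {
  vol <- RNifti::readNifti(volume_path)
  sp <- RNifti::pixdim(vol)[1:3]
  v <- array(as.numeric(vol), dim = dim(vol))
  attr(v, "spacing") <- sp
  list(volume = v,
       lesion_mask = array(as.numeric(RNifti::readNifti(lesion_path)) > 0.5,
                           dim = dim(vol)),
       pancreas_mask = array(as.numeric(RNifti::readNifti(pancreas_path)) > 0.5,
                             dim = dim(vol)),
       spacing = sp)
}
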