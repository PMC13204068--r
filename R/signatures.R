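#' Spatial delta-radiomic features
#'
#' Subtracts each patient's contralateral-pancreas feature value from the
#' matched lesion value (after harmonization): the pancreas acts as a
#' per-patient internal control, cancelling the patient- and scanner-level
#' nuisance components shared by the two ROIs of one acquisition. Shape
#' features are excluded because they are dominated by the trivial
#' lesion-vs-pancreas size difference.
#'
#' @param lesion,pancreas Feature tables (one row per patient each), matched
#'   on `patient_id` and carrying the same non-shape feature set. A single
#'   stacked-ROI table can be passed as `lesion` with `pancreas = NULL`, in
#'   which case it is split on its `roi` column.
#' @param prefix Prefix of the output feature columns (default `"delta_"`).
#' @return Tibble: `patient_id` plus one `delta_`-prefixed column per
#'   non-shape feature.
#' @export
delta_features <- function(lesion, pancreas = NULL, prefix = "delta_") {
  if (is.null(pancreas)) {
    stopifnot("roi" %in% names(lesion))
    pancreas <- dplyr::filter(lesion, .data$roi == "pancreas")
    lesion <- dplyr::filter(lesion, .data$roi == "lesion")
  }
  unmatched <- c(setdiff(lesion$patient_id, pancreas$patient_id),
                 setdiff(pancreas$patient_id, lesion$patient_id))
  if (length(unmatched) > 0) {
    stop(sprintf("unmatched patient(s): %s",
                 paste(unique(unmatched), collapse = ", ")), call. = FALSE)
  }
  feats <- intersect(feature_columns(lesion), feature_columns(pancreas))
  feats <- feats[!startsWith(feats, "shape_")]
  if (length(feats) == 0) stop("no shared non-shape features", call. = FALSE)
  pancreas <- pancreas[match(lesion$patient_id, pancreas$patient_id), ]
  d <- as.matrix(lesion[, feats]) - as.matrix(pancreas[, feats])
  colnames(d) <- paste0(prefix, feats)
  dplyr::bind_cols(tibble::tibble(patient_id = lesion$patient_id),
                   tibble::as_tibble(as.data.frame(d)))
}

#' Principal-component summary of the shape features
#'
#' Shape descriptors are strongly collinear; they are summarized by PCA of
#' the correlation matrix (features z-scored; constant features dropped with
#' a warning), retaining the first `n_comp` component scores. Sign
#' convention: the largest-magnitude loading of each component is positive.
#'
#' @param shape_features Tibble with `patient_id` and shape feature columns
#'   (columns starting `shape_`, or all numeric columns if none do).
#' @param n_comp Number of components to retain (default 3).
#' @return List: `scores` (tibble `patient_id`, `shape_pc1`..), loadings
#'   matrix, and `variance_explained` (fractions for all components, summing
#'   to 1).
#' @export
shape_pca <- function(shape_features, n_comp = 3) {
  feats <- names(shape_features)[startsWith(names(shape_features), "shape_")]
  if (length(feats) == 0) feats <- feature_columns(shape_features)
  X <- as.matrix(shape_features[, feats, drop = FALSE])
  complete <- stats::complete.cases(X)
  if (sum(complete) < 4) {
    stop("shape_pca needs >= 4 complete rows", call. = FALSE)
  }
  sds <- apply(X[complete, , drop = FALSE], 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("constant shape feature(s) dropped: %s",
                    paste(feats[sds == 0], collapse = ", ")), call. = FALSE)
    feats <- feats[sds > 0]
    X <- X[, feats, drop = FALSE]
  }
  Z <- scale(X[complete, , drop = FALSE])
  eg <- eigen(stats::cor(X[complete, , drop = FALSE]), symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  load <- eg$vectors
  # sign convention: largest-|loading| entry positive
  for (k in seq_len(ncol(load))) {
    piv <- which.max(abs(load[, k]))
    if (load[piv, k] < 0) load[, k] <- -load[, k]
  }
  n_comp <- min(n_comp, ncol(load))
  scores <- matrix(NA_real_, nrow(X), n_comp)
  scores[complete, ] <- Z %*% load[, seq_len(n_comp), drop = FALSE]
  colnames(scores) <- paste0("shape_pc", seq_len(n_comp))
  rownames(load) <- feats
  list(
    scores = dplyr::bind_cols(
      tibble::tibble(patient_id = shape_features$patient_id),
      tibble::as_tibble(as.data.frame(scores))
    ),
    loadings = load[, seq_len(n_comp), drop = FALSE],
    variance_explained = ev / sum(ev)
  )
}

#' Default mapping of signature inputs to feature columns
#'
#' @return Named character vector mapping the radiomic multiplicands of the
#'   signature panel to feature column names.
#' @export
signature_feature_map <- function() {
  c(entropy = "firstorder_Entropy",
    energy = "firstorder_Energy",
    median_hu = "firstorder_Median",
    busyness = "ngtdm_Busyness",
    surface_to_volume = "shape_SurfaceToVolume",
    sphericity = "shape_Sphericity")
}

#' Encode the clinical multiplicands of the signature panel
#'
#' Ki-67 is converted from percent to a fraction in [0, 1]; grade is encoded
#' 1/2/3 for G1/G2/G3; functional status 0/1; number of metastatic organs as
#' a nonnegative integer.
#'
#' @param cohort Cohort tibble with `ki67_pct`, `grade_numeric`,
#'   `functional`, `n_met_organs`.
#' @return Tibble: `patient_id`, `ki67_fraction`, `grade_numeric`,
#'   `functional`, `n_met_organs`.
#' @export
encode_clinical <- function(cohort) {
  ki <- cohort$ki67_pct
  if (any(!is.na(ki) & (ki < 0 | ki > 100))) {
    stop("ki67_pct outside [0, 100]", call. = FALSE)
  }
  if (!all(stats::na.omit(cohort$grade_numeric) %in% 1:3)) {
    stop("grade_numeric must be 1, 2 or 3", call. = FALSE)
  }
  tibble::tibble(patient_id = cohort$patient_id,
                 ki67_fraction = ki / 100,
                 grade_numeric = cohort$grade_numeric,
                 functional = cohort$functional,
                 n_met_organs = cohort$n_met_organs)
}

#' Compute the prespecified hybrid signature panel
#'
#' Ten biology-informed clinico-radiomic products. Family A (lesion-only,
#' harmonized values): A1 = Entropy x Ki-67(fraction); A2 = (Surface/Volume)
#' x (1 - Sphericity); A3 = (1 - Sphericity) x Functional x Grade;
#' A4 = log(Energy + 1) x Grade x (1 + N metastatic organs); A5 = A1 x A2;
#' A6 = Busyness x Ki-67(fraction); A7 = Median HU x Grade. Family B
#' replaces the lesion radiomic primitive by its delta-feature: B1 =
#' dEntropy x Ki-67; B2 = dBusyness x Ki-67; B3 = dMedianHU x Grade. A
#' missing multiplicand propagates to a missing signature (never zero).
#'
#' @param lesion Harmonized lesion feature table (one row per patient).
#' @param deltas Delta-feature table from [delta_features()].
#' @param clinical Clinical encodings from [encode_clinical()].
#' @param shape_scores Optional `shape_pca()` score tibble to append.
#' @param feature_map Column mapping, see [signature_feature_map()].
#' @return A tibble: `patient_id`, `A1`..`A7`, `B1`..`B3` and, when
#'   provided, `shape_pc*` columns. The `variance_explained` attribute is
#'   carried over from `shape_scores`.
#' @export
compute_signatures <- function(lesion, deltas, clinical, shape_scores = NULL,
                               feature_map = signature_feature_map()) {
  df <- dplyr::left_join(clinical, lesion, by = "patient_id")
  df <- dplyr::left_join(df, deltas, by = "patient_id")
  g <- function(nm) df[[feature_map[[nm]]]]
  gd <- function(nm) df[[paste0("delta_", feature_map[[nm]])]]
  energy <- g("energy")
  log_energy <- ifelse(!is.na(energy) & energy > -1, log(energy + 1), NA_real_)
  if (any(!is.na(energy) & energy <= -1)) {
    warning("Energy <= -1 for some patients; A4 set to missing", call. = FALSE)
  }
  out <- tibble::tibble(
    patient_id = df$patient_id,
    A1 = g("entropy") * df$ki67_fraction,
    A2 = g("surface_to_volume") * (1 - g("sphericity")),
    A3 = (1 - g("sphericity")) * df$functional * df$grade_numeric,
    A4 = log_energy * df$grade_numeric * (1 + df$n_met_organs),
    A6 = g("busyness") * df$ki67_fraction,
    A7 = g("median_hu") * df$grade_numeric,
    B1 = gd("entropy") * df$ki67_fraction,
    B2 = gd("busyness") * df$ki67_fraction,
    B3 = gd("median_hu") * df$grade_numeric
  )
  out$A5 <- out$A1 * out$A2
  out <- out[, c("patient_id", paste0("A", 1:7), paste0("B", 1:3))]
  if (!is.null(shape_scores)) {
    out <- dplyr::left_join(out, shape_scores, by = "patient_id")
  }
  out
}
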