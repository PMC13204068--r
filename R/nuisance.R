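#' Additive nuisance model for paired lesion/pancreas features
#'
#' Variance-component model behind the synthetic feature generator. A
#' measured lesion feature decomposes as
#' `lesion = biology + patient + scanner + eps` and the matched contralateral
#' pancreas as `pancreas = patient + scanner + eps'`, where the patient and
#' scanner terms are shared between the two ROIs of the same patient and the
#' same acquisition. Subtracting the pancreas therefore cancels the shared
#' nuisance components — the rationale for spatial delta-radiomics. The
#' scanner term carries the center-level batch structure that ComBat
#' estimates: an additive per-center shift (`center_gamma`) plus
#' per-center scaling (`center_delta`) of the scanner noise.
#'
#' @param sigma_bio SD of the feature-specific biological residual.
#' @param sigma_patient SD of the per-patient (body habitus / contrast
#'   timing) term shared across all features and both ROIs.
#' @param sigma_scanner SD of the scanner noise before per-center scaling.
#' @param sigma_eps,sigma_eps_prime SDs of the independent measurement noise
#'   of the lesion and pancreas ROI respectively.
#' @param center_gamma Additive batch shift per center: scalar, per-center
#'   vector, or centers-by-features matrix.
#' @param center_delta Multiplicative batch scale per center (> 0), same
#'   shapes accepted.
#' @return An object of class `nuisance_model`.
#' @export
nuisance_model <- function(sigma_bio = 1, sigma_patient = 0.7,
                           sigma_scanner = 0.5, sigma_eps = 0.3,
                           sigma_eps_prime = 0.3,
                           center_gamma = c(A = 0, B = 0.8),
                           center_delta = c(A = 1, B = 1.3)) {
  sig <- c(sigma_bio = sigma_bio, sigma_patient = sigma_patient,
           sigma_scanner = sigma_scanner, sigma_eps = sigma_eps,
           sigma_eps_prime = sigma_eps_prime)
  if (any(sig < 0)) abort_field(names(sig)[which(sig < 0)[1]], "must be >= 0")
  if (any(unlist(center_delta) <= 0)) {
    abort_field("center_delta", "must be > 0")
  }
  structure(list(sigma_bio = sigma_bio, sigma_patient = sigma_patient,
                 sigma_scanner = sigma_scanner, sigma_eps = sigma_eps,
                 sigma_eps_prime = sigma_eps_prime,
                 center_gamma = center_gamma, center_delta = center_delta),
            class = "nuisance_model")
}

# Expand gamma/delta spec into a centers x features matrix.
expand_center_param <- function(x, centers, n_features, field) {
  if (is.matrix(x)) {
    if (nrow(x) != length(centers) || ncol(x) != n_features) {
      abort_field(field, "matrix must be centers x features")
    }
    rownames(x) <- centers
    return(x)
  }
  if (length(x) == 1) x <- stats::setNames(rep(x, length(centers)), centers)
  if (!all(centers %in% names(x))) {
    abort_field(field, paste("missing center:",
                             paste(setdiff(centers, names(x)), collapse = ", ")))
  }
  matrix(rep(unlist(x[centers]), n_features), nrow = length(centers),
         dimnames = list(centers, NULL))
}

# Clinical aggressiveness score: equal-weight standardized grade and log
# Ki-67 (missing components contribute their mean), restandardized to unit
# SD.
biology_score <- function(cohort) {
  g <- scale(cohort$grade_numeric)[, 1]
  k <- scale(log(cohort$ki67_pct))[, 1]
  g[is.na(g)] <- 0
  k[is.na(k)] <- 0
  s <- g + k
  if (stats::sd(s) == 0) return(rep(0, length(s)))
  as.numeric(scale(s))
}

#' Generate paired lesion/pancreas feature tables under the nuisance model
#'
#' For each patient `i` and feature `j` draws
#' `lesion[i, j] = bio[i, j] + patient[i] + scanner[i, j] + eps` and
#' `pancreas[i, j] = patient[i] + scanner[i, j] + eps'`, with
#' `bio[i, j] = effect_spec[j] * biology[i] + sigma_bio * z`, where
#' `biology` is a standardized clinical-aggressiveness score built from
#' grade and log Ki-67, and
#' `scanner[i, j] = center_gamma[c(i), j] + center_delta[c(i), j] * sigma_scanner * u`.
#' Patient and scanner draws are shared between the two ROI rows of a
#' patient, so the lesion-minus-pancreas difference cancels them.
#'
#' @param cohort Cohort tibble from [generate_cohort()].
#' @param model A [nuisance_model()].
#' @param n_features Number of features (>= 1).
#' @param effect_spec Named vector mapping feature names to their coefficient
#'   on the biology score; unnamed features get coefficient 0. Unknown names
#'   raise an error.
#' @param feature_names Feature (column) names; default `feat_01`, ...
#' @param feature_baseline Optional named vector of per-feature baseline
#'   levels added to both ROIs (common-mode, so delta-features are
#'   unaffected); places synthetic features on realistic scales.
#' @param lesion_shift Optional named vector of tumor-specific mean offsets
#'   added to lesion rows only — the systematic lesion-versus-parenchyma
#'   difference (e.g. larger size, higher busyness) that the volcano
#'   analysis detects.
#' @param seed Seed for reproducibility.
#' @return A tibble in "stacked ROI" layout: `patient_id`, `center`, `roi`
#'   (`"lesion"`/`"pancreas"`), `harmonization` (`"raw"`), then one numeric
#'   column per feature.
#' @export
generate_feature_table <- function(cohort, model = nuisance_model(),
                                   n_features = 20,
                                   effect_spec = NULL,
                                   feature_names = NULL,
                                   feature_baseline = NULL,
                                   lesion_shift = NULL,
                                   seed = NULL) {
  if (n_features < 1) abort_field("n_features", "must be >= 1")
  n <- nrow(cohort)
  if (is.null(feature_names)) {
    feature_names <- sprintf("feat_%02d", seq_len(n_features))
  }
  stopifnot(length(feature_names) == n_features)
  beta <- stats::setNames(rep(0, n_features), feature_names)
  if (!is.null(effect_spec)) {
    unknown <- setdiff(names(effect_spec), feature_names)
    if (length(unknown) > 0) {
      abort_field("effect_spec",
                  paste("unknown feature:", paste(unknown, collapse = ", ")))
    }
    beta[names(effect_spec)] <- effect_spec
  }
  base <- stats::setNames(rep(0, n_features), feature_names)
  if (!is.null(feature_baseline)) {
    unknown <- setdiff(names(feature_baseline), feature_names)
    if (length(unknown) > 0) {
      abort_field("feature_baseline",
                  paste("unknown feature:", paste(unknown, collapse = ", ")))
    }
    base[names(feature_baseline)] <- feature_baseline
  }
  lshift <- stats::setNames(rep(0, n_features), feature_names)
  if (!is.null(lesion_shift)) {
    unknown <- setdiff(names(lesion_shift), feature_names)
    if (length(unknown) > 0) {
      abort_field("lesion_shift",
                  paste("unknown feature:", paste(unknown, collapse = ", ")))
    }
    lshift[names(lesion_shift)] <- lesion_shift
  }
  centers <- sort(unique(cohort$center))
  gam <- expand_center_param(model$center_gamma, centers, n_features,
                             "center_gamma")
  del <- expand_center_param(model$center_delta, centers, n_features,
                             "center_delta")
  with_seed_(seed, {
    bio_score <- biology_score(cohort)
    bio <- outer(bio_score, beta) +
      model$sigma_bio * matrix(stats::rnorm(n * n_features), n)
    patient <- stats::rnorm(n, 0, model$sigma_patient)
    u <- matrix(stats::rnorm(n * n_features), n)
    ci <- match(cohort$center, centers)
    scanner <- gam[ci, , drop = FALSE] +
      del[ci, , drop = FALSE] * model$sigma_scanner * u
    base_m <- matrix(base, n, n_features, byrow = TRUE)
    lesion <- base_m + matrix(lshift, n, n_features, byrow = TRUE) +
      bio + patient + scanner +
      model$sigma_eps * matrix(stats::rnorm(n * n_features), n)
    pancreas <- base_m + patient + scanner +
      model$sigma_eps_prime * matrix(stats::rnorm(n * n_features), n)
    colnames(lesion) <- colnames(pancreas) <- feature_names
    dplyr::bind_rows(
      dplyr::bind_cols(
        tibble::tibble(patient_id = cohort$patient_id, center = cohort$center,
                       roi = "lesion", harmonization = "raw"),
        tibble::as_tibble(lesion)
      ),
      dplyr::bind_cols(
        tibble::tibble(patient_id = cohort$patient_id, center = cohort$center,
                       roi = "pancreas", harmonization = "raw"),
        tibble::as_tibble(pancreas)
      )
    )
  })
}

#' Column names of the feature block of a feature table
#'
#' @param data A feature table as returned by [generate_feature_table()],
#'   [extract_features()], or [combat_transform()].
#' @return Character vector of feature column names (numeric columns other
#'   than the bookkeeping columns).
#' @export
feature_columns <- function(data) {
  meta <- c("patient_id", "center", "roi", "harmonization")
  setdiff(names(data)[vapply(data, is.numeric, logical(1))], meta)
}
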