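#' Default end-to-end run configuration
#'
#' Synthetic-mode configuration covering every stage: cohort profile,
#' nuisance model, feature inventory with effect sizes, harmonization
#' toggle, signature panel, survival-inference resample counts, and the
#' prediction study settings. A single global seed is expanded into
#' independent per-stage streams.
#'
#' @param seed Global seed.
#' @param n_boot,n_perm Resamples for concordance inference.
#' @param classifiers Classifier set for the prediction study.
#' @param k_grid SelectKBest-style feature-count grid.
#' @param n_boot_pred Bootstrap resamples for prediction AUC CIs.
#' @param harmonize Apply ComBat before the delta/signature stages.
#' @return A `run_config` list.
#' @export
default_config <- function(seed = 1, n_boot = 2000, n_perm = 1000,
                           classifiers = c("logistic", "random_forest",
                                           "gradient_boosting"),
                           k_grid = c(2, 3, 5), n_boot_pred = 2000,
                           harmonize = TRUE) {
  feature_names <- c("firstorder_Entropy", "firstorder_Energy",
                     "firstorder_Median", "firstorder_TotalEnergy",
                     "firstorder_Range", "firstorder_Mean",
                     "ngtdm_Busyness", "glcm_Idmn",
                     "glszm_SmallAreaHighGrayLevelEmphasis",
                     "glszm_SizeZoneNonUniformity",
                     "gldm_DependenceNonUniformity",
                     "glrlm_RunLengthNonUniformity",
                     "shape_SurfaceToVolume", "shape_Sphericity",
                     "shape_MajorAxisLength", "shape_Flatness",
                     "shape_Maximum3DDiameter", "shape_Volume",
                     "shape_SurfaceArea", "shape_Elongation")
  effect_spec <- c(firstorder_Entropy = 0.8, firstorder_Energy = 0.5,
                   firstorder_Median = 0.6, ngtdm_Busyness = -0.7,
                   glszm_SizeZoneNonUniformity = 0.4,
                   gldm_DependenceNonUniformity = 0.3)
  feature_baseline <- c(firstorder_Entropy = 4, firstorder_Energy = 60,
                        firstorder_Median = 65, firstorder_TotalEnergy = 80,
                        firstorder_Range = 180, firstorder_Mean = 65,
                        ngtdm_Busyness = 6, glcm_Idmn = 10,
                        glszm_SmallAreaHighGrayLevelEmphasis = 30,
                        glszm_SizeZoneNonUniformity = 40,
                        gldm_DependenceNonUniformity = 35,
                        glrlm_RunLengthNonUniformity = 90,
                        shape_SurfaceToVolume = 5, shape_Sphericity = 0.7,
                        shape_MajorAxisLength = 28, shape_Flatness = 3,
                        shape_Maximum3DDiameter = 34, shape_Volume = 15,
                        shape_SurfaceArea = 40, shape_Elongation = 3)
  # systematic lesion-vs-parenchyma differences (shape strongest, then
  # zone/first-order texture), as seen on contrast CT
  lesion_shift <- c(shape_MajorAxisLength = 5.2, shape_Maximum3DDiameter = 4.5,
                    shape_Sphericity = -4.7, shape_Flatness = -4.1,
                    shape_Volume = 4.8, shape_SurfaceArea = 5,
                    firstorder_Energy = 2, firstorder_TotalEnergy = 2,
                    firstorder_Median = 1.8, firstorder_Range = 1.5,
                    glszm_SizeZoneNonUniformity = 1.6, glcm_Idmn = 1.2,
                    gldm_DependenceNonUniformity = 1.3, ngtdm_Busyness = 1.5)
  structure(list(
    mode = "synthetic",
    profile = cohort_profile(seed = child_seed(seed, 1)),
    nuisance = nuisance_model(),
    n_features = length(feature_names),
    feature_names = feature_names,
    effect_spec = effect_spec,
    feature_baseline = feature_baseline,
    lesion_shift = lesion_shift,
    harmonize = harmonize,
    stats = list(n_boot = n_boot, n_perm = n_perm),
    prediction = list(classifiers = classifiers, k_grid = k_grid,
                      n_boot = n_boot_pred, n_boot_loco = 1000),
    seed = seed
  ), class = "run_config")
}

write_stage_csv <- function(x, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  utils::write.csv(x, file.path(out_dir, paste0(name, ".csv")),
                   row.names = FALSE)
}

#' Run the full synthetic-mode pipeline
#'
#' Executes generate -> harmonize -> delta -> signatures -> survival ->
#' prediction -> descriptive stats, collecting a manifest of per-stage
#' status and seeds. With `out_dir` set, writes the cohort, feature,
#' signature, survival and prediction tables as CSV, the metrics as JSON,
#' and the manifest.
#'
#' @param config A [default_config()] list.
#' @param out_dir Optional output directory.
#' @return A list of stage results plus `manifest`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  manifest <- list(seed = config$seed, mode = config$mode, stages = list())
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      if (!is.null(out_dir)) {
        jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                             auto_unbox = TRUE, digits = NA)
      }
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(status = "ok")
    res
  }

  cohort <- stage("cohort", generate_cohort(config$profile))
  write_stage_csv(cohort, out_dir, "cohort")

  features_raw <- stage("features", generate_feature_table(
    cohort, config$nuisance, n_features = config$n_features,
    effect_spec = config$effect_spec, feature_names = config$feature_names,
    feature_baseline = config$feature_baseline,
    lesion_shift = config$lesion_shift,
    seed = child_seed(config$seed, 2)))
  write_stage_csv(features_raw, out_dir, "features_raw")

  balance <- stage("balance_check", balance_check(
    cohort, c("age", "ki67_pct", "size_cm", "grade_numeric", "functional")))

  if (isTRUE(config$harmonize)) {
    cb <- stage("combat", {
      m <- combat_fit(features_raw, batch = "center")
      list(model = m, data = combat_transform(m, features_raw))
    })
    features <- cb$data
    if (!is.null(out_dir)) {
      combat_write(cb$model, file.path(out_dir, "combat_model.json"))
    }
  } else {
    features <- features_raw
    manifest$stages[["combat"]] <- list(status = "skipped",
                                        note = "harmonization disabled")
  }
  write_stage_csv(features, out_dir, "features")

  deltas <- stage("delta", delta_features(features))
  write_stage_csv(deltas, out_dir, "delta_features")

  lesion <- dplyr::filter(features, .data$roi == "lesion")
  shp <- lesion[, c("patient_id",
                    grep("^shape_", names(lesion), value = TRUE))]
  pca <- if (ncol(shp) > 4) stage("shape_pca", shape_pca(shp)) else NULL

  signatures <- stage("signatures", compute_signatures(
    lesion, deltas, encode_clinical(cohort),
    shape_scores = if (!is.null(pca)) pca$scores else NULL))
  write_stage_csv(signatures, out_dir, "signatures")

  surv <- stage("survival", signature_cox(
    signatures[match(cohort$patient_id, signatures$patient_id), ],
    time = cohort$time_progression, event = cohort$progression,
    n_boot = config$stats$n_boot, n_perm = config$stats$n_perm,
    seed = child_seed(config$seed, 3)))
  write_stage_csv(tibble::as_tibble(surv), out_dir, "survival")

  volcano <- stage("descriptive", lesion_vs_pancreas(
    lesion, dplyr::filter(features, .data$roi == "pancreas")))
  write_stage_csv(volcano, out_dir, "volcano")

  prediction <- stage("prediction", {
    res <- list()
    for (tgt in c("progression", "higher_grade")) {
      md <- assemble_model_data(cohort, signatures, tgt)
      blocks <- assemble_blocks(tgt)
      for (b in names(blocks)) {
        key <- paste(tgt, b, sep = "_")
        res[[key]] <- nested_cv(
          md, blocks[[b]], classifiers = config$prediction$classifiers,
          k_grid = config$prediction$k_grid,
          n_boot = config$prediction$n_boot,
          seed = child_seed(config$seed, 40 + match(b, names(blocks)) +
                              10 * (tgt == "higher_grade")))
        loco <- loco_cv(md, blocks[[b]],
                        n_boot = config$prediction$n_boot_loco,
                        seed = child_seed(config$seed, 60 +
                                            match(b, names(blocks))))
        res[[key]]$metrics$loco_auc <- loco$loco_auc
      }
    }
    res
  })
  pred_table <- dplyr::bind_rows(lapply(prediction, function(x) x$metrics))
  write_stage_csv(pred_table, out_dir, "prediction")

  if (!is.null(out_dir)) {
    jsonlite::write_json(
      list(survival = tibble::as_tibble(surv), prediction = pred_table,
           balance = balance),
      file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(cohort = cohort, features_raw = features_raw, features = features,
       balance = balance, deltas = deltas, shape_pca = pca,
       signatures = signatures, survival = surv, volcano = volcano,
       prediction = prediction, prediction_table = pred_table,
       manifest = manifest)
}
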