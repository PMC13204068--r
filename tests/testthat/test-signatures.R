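fake_features <- function(n = 8, roi = "lesion", seed = 1) {
  set.seed(seed)
  tibble::tibble(
    patient_id = sprintf("P%03d", seq_len(n)),
    center = rep(c("A", "B"), length.out = n),
    roi = roi, harmonization = "combat",
    firstorder_Entropy = runif(n, 2, 5),
    firstorder_Energy = runif(n, 50, 150),
    firstorder_Median = runif(n, 40, 90),
    ngtdm_Busyness = runif(n, 1, 10),
    shape_SurfaceToVolume = runif(n, 0.3, 1.2),
    shape_Sphericity = runif(n, 0.4, 0.95)
  )
}

test_that("delta features vanish when lesion equals pancreas and drop shape", {
  les <- fake_features()
  pan <- les; pan$roi <- "pancreas"
  d <- delta_features(les, pan)
  expect_true(all(as.matrix(d[, -1]) == 0))
  expect_false(any(startsWith(names(d), "delta_shape_")))
  expect_true("delta_firstorder_Entropy" %in% names(d))
})

test_that("delta features cancel any per-patient common-mode offset", {
  les <- fake_features(seed = 2)
  pan <- fake_features(seed = 3); pan$roi <- "pancreas"
  offs <- rnorm(nrow(les))
  shift <- function(tb) {
    for (f in feature_columns(tb)) tb[[f]] <- tb[[f]] + offs
    tb
  }
  d0 <- delta_features(les, pan)
  d1 <- delta_features(shift(les), shift(pan))
  expect_equal(d1, d0, tolerance = 1e-12)
})

test_that("unmatched patients are reported by id", {
  les <- fake_features()
  pan <- fake_features(); pan$roi <- "pancreas"
  pan <- pan[-3, ]
  expect_error(delta_features(les, pan), "P003")
})

test_that("stacked-ROI tables split on the roi column", {
  les <- fake_features(seed = 4)
  pan <- fake_features(seed = 5); pan$roi <- "pancreas"
  stacked <- dplyr::bind_rows(les, pan)
  expect_equal(delta_features(stacked), delta_features(les, pan))
})

test_that("shape PCA matches a brute-force eigendecomposition", {
  set.seed(8)
  n <- 20
  latent <- rnorm(n)
  sf <- tibble::tibble(
    patient_id = sprintf("P%03d", 1:n),
    shape_a = latent * 2 + rnorm(n, 0, 0.3),
    shape_b = -latent + rnorm(n, 0, 0.3),
    shape_c = latent * 0.5 + rnorm(n, 0, 0.3),
    shape_d = rnorm(n)
  )
  res <- shape_pca(sf, n_comp = 3)
  expect_equal(sum(res$variance_explained), 1, tolerance = 1e-10)
  # oracle: eigendecomposition of the correlation matrix, scores = Z %*% V
  X <- scale(as.matrix(sf[, -1]))
  eg <- eigen(cor(as.matrix(sf[, -1])))
  for (k in 1:3) {
    ours <- res$scores[[paste0("shape_pc", k)]]
    oracle <- X %*% eg$vectors[, k]
    expect_equal(as.numeric(abs(cor(ours, oracle))), 1, tolerance = 1e-10)
  }
  # sign convention: dominant loading positive
  expect_true(all(apply(res$loadings, 2,
                        function(v) v[which.max(abs(v))] > 0)))
})

test_that("near rank-1 shape data put almost everything on PC1", {
  set.seed(9)
  base <- rnorm(12)
  sf <- tibble::tibble(patient_id = sprintf("P%03d", 1:12),
                       shape_a = base, shape_b = 2 * base + rnorm(12, 0, 1e-3),
                       shape_c = -base + rnorm(12, 0, 1e-3))
  res <- shape_pca(sf)
  expect_gt(res$variance_explained[1], 0.99)
})

test_that("constant shape features are dropped with a warning", {
  sf <- fake_features(seed = 10)[, c("patient_id", "shape_SurfaceToVolume",
                                     "shape_Sphericity")]
  sf$shape_flat <- 3
  expect_warning(res <- shape_pca(sf, n_comp = 2), "constant")
  expect_false("shape_flat" %in% rownames(res$loadings))
})

test_that("signature formulas follow their definitions", {
  les <- fake_features(seed = 11)
  les$firstorder_Entropy[1] <- 3.0
  pan <- fake_features(seed = 12); pan$roi <- "pancreas"
  deltas <- delta_features(les, pan)
  clin <- tibble::tibble(patient_id = les$patient_id,
                         ki67_fraction = c(0.10, rep(0.2, 7)),
                         grade_numeric = rep(c(1, 2), 4),
                         functional = c(0, 1, rep(0, 6)),
                         n_met_organs = rep(c(0, 2), 4))
  sig <- compute_signatures(les, deltas, clin)
  expect_equal(sig$A1[1], 3.0 * 0.10)                       # Entropy x Ki-67
  expect_equal(sig$A2,
               les$shape_SurfaceToVolume * (1 - les$shape_Sphericity))
  expect_equal(sig$A5, sig$A1 * sig$A2)                     # exact identity
  expect_equal(sig$A4, log(les$firstorder_Energy + 1) * clin$grade_numeric *
                 (1 + clin$n_met_organs))
  expect_equal(sig$A7, les$firstorder_Median * clin$grade_numeric)
  expect_equal(sig$B2, deltas$delta_ngtdm_Busyness * clin$ki67_fraction)
  # nonfunctional patients have A3 identically zero
  expect_true(all(sig$A3[clin$functional == 0] == 0))
})

test_that("equal lesion and pancreas busyness zeroes B2 for any Ki-67", {
  les <- fake_features(seed = 13)
  pan <- fake_features(seed = 14); pan$roi <- "pancreas"
  pan$ngtdm_Busyness <- les$ngtdm_Busyness
  clin <- encode_clinical(tibble::tibble(
    patient_id = les$patient_id, ki67_pct = runif(8, 1, 60),
    grade_numeric = rep(2, 8), functional = 0, n_met_organs = 0))
  sig <- compute_signatures(les, delta_features(les, pan), clin)
  expect_true(all(sig$B2 == 0))
})

test_that("missing multiplicands propagate to missing signatures, never zero", {
  les <- fake_features(seed = 15)
  pan <- fake_features(seed = 16); pan$roi <- "pancreas"
  clin <- tibble::tibble(patient_id = les$patient_id,
                         ki67_fraction = 0.2, grade_numeric = 2,
                         functional = 1, n_met_organs = 1)
  clin$ki67_fraction[2] <- NA
  clin$grade_numeric[3] <- NA
  les$firstorder_Entropy[4] <- NA
  sig <- compute_signatures(les, delta_features(les, pan), clin)
  expect_true(is.na(sig$A1[2]) && is.na(sig$B1[2]) && is.na(sig$A6[2]))
  expect_false(is.na(sig$A2[2]))  # no Ki-67 in its formula
  expect_true(is.na(sig$A4[3]) && is.na(sig$A7[3]) && is.na(sig$B3[3]))
  expect_true(is.na(sig$A1[4]) && is.na(sig$A5[4]))
  # missingness holds exactly when a multiplicand is missing
  expect_true(all(is.na(sig$A5) == (is.na(sig$A1) | is.na(sig$A2))))
})

test_that("Ki-67 outside 0-100% is rejected at encoding", {
  co <- tibble::tibble(patient_id = "P1", ki67_pct = 130, grade_numeric = 2,
                       functional = 0, n_met_organs = 0)
  expect_error(encode_clinical(co), "ki67")
})

test_that("the generated cohort reproduces the complete-case n pattern", {
  res <- run_pipeline(default_config(seed = 5, n_boot = 0, n_perm = 0,
                                     classifiers = "logistic",
                                     n_boot_pred = 0))
  tab <- tibble::as_tibble(res$survival)
  n_by_sig <- setNames(tab$n, tab$signature)
  # Ki-67 signatures lose the 5 Ki-67-missing patients, grade signatures
  # the 1 grade-missing patient, A2 only the outcome-missing patient
  expect_equal(unname(n_by_sig["A2"]), 43)
  expect_true(all(n_by_sig[c("A1", "A6", "B1", "B2")] == 38))
  expect_true(all(n_by_sig[c("A4", "A7", "B3")] == 42))
})
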