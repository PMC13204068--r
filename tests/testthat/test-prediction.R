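make_model_data <- function(n = 60, signal = NULL, seed = 1,
                            center_effect = 0) {
  set.seed(seed)
  d <- tibble::tibble(
    patient_id = sprintf("P%03d", seq_len(n)),
    center = rep(c("A", "B"), each = n / 2),
    age = rnorm(n, 60, 8), sex = rbinom(n, 1, 0.5),
    size_cm = rlnorm(n, 1, 0.5), grade_numeric = sample(1:3, n, TRUE),
    ki67_pct = rlnorm(n, 1.5, 0.8), functional = rbinom(n, 1, 0.15)
  )
  for (s in c(paste0("A", 1:7), paste0("B", 1:3))) d[[s]] <- rnorm(n)
  eta <- center_effect * (d$center == "B")
  if (!is.null(signal)) eta <- eta + signal * d$A1
  d$y <- rbinom(n, 1, plogis(eta))
  if (length(unique(d$y)) < 2) d$y[1:2] <- c(0L, 1L)
  d
}

test_that("block assembly applies the higher-grade leakage exclusions", {
  b <- assemble_blocks("higher_grade")
  expect_equal(sort(b$MA$signature_vars), c("A1", "A2", "A5", "A6"))
  expect_equal(sort(b$MB$signature_vars), c("B1", "B2"))
  expect_false("grade_numeric" %in% b$M0$clinical_vars)
  expect_equal(length(b$M0$clinical_vars), 5L)
  bp <- assemble_blocks("progression")
  expect_equal(bp$MA$signature_vars, paste0("A", 1:7))
  expect_equal(bp$MB$signature_vars, paste0("B", 1:3))
  expect_true("grade_numeric" %in% bp$M0$clinical_vars)
})

test_that("a perfectly separating predictor yields OOF AUC 1 and tiny Brier", {
  d <- make_model_data(n = 40, seed = 2)
  d$A1 <- d$y * 10 - 5
  res <- nested_cv(d, assemble_blocks("progression")$MA,
                   classifiers = "logistic", n_boot = 0, seed = 3)
  expect_equal(res$metrics$auc, 1)
  expect_lte(res$metrics$brier, 0.05)
})

test_that("Brier for a constant prediction equals prevalence variance", {
  y <- rep(c(0, 1), c(30, 10))
  p <- rep(mean(y), 40)
  expect_equal(mean((p - y)^2), mean(y) * (1 - mean(y)), tolerance = 1e-12)
  # and the package computes Brier from its OOF predictions the same way
  d <- make_model_data(n = 40, seed = 4)
  res <- nested_cv(d, assemble_blocks("progression")$M0,
                   classifiers = "logistic", n_boot = 0, seed = 5)
  oof <- res$oof[!is.na(res$oof$p), ]
  expect_equal(res$metrics$brier, mean((oof$p - oof$y)^2), tolerance = 1e-12)
})

test_that("every evaluable patient gets exactly one OOF prediction", {
  d <- make_model_data(n = 44, seed = 6)
  res <- nested_cv(d, assemble_blocks("progression")$MB,
                   classifiers = c("logistic", "random_forest"),
                   n_boot = 0, seed = 7)
  for (cl in unique(res$oof$classifier)) {
    oof <- res$oof[res$oof$classifier == cl, ]
    expect_equal(nrow(oof), 44L)
    expect_true(all(!is.na(oof$p)))
    expect_true(all(oof$p > 0 & oof$p < 1))
  }
})

test_that("all three classifiers run and are seed-reproducible", {
  d <- make_model_data(n = 40, signal = 1.5, seed = 8)
  res1 <- nested_cv(d, assemble_blocks("progression")$MA,
                    classifiers = c("logistic", "random_forest",
                                    "gradient_boosting"),
                    n_boot = 0, seed = 9)
  res2 <- nested_cv(d, assemble_blocks("progression")$MA,
                    classifiers = c("logistic", "random_forest",
                                    "gradient_boosting"),
                    n_boot = 0, seed = 9)
  expect_equal(res1$metrics, res2$metrics, tolerance = 1e-12)
  expect_equal(nrow(res1$metrics), 3L)
  expect_true(all(is.finite(res1$metrics$auc)))
})

test_that("permuted labels give chance-level nested-CV AUC (no leakage)", {
  set.seed(10)
  aucs <- vapply(1:25, function(r) {
    d <- make_model_data(n = 44, signal = 2, seed = 100 + r)
    d$y <- sample(d$y)  # break any real association
    nested_cv(d, assemble_blocks("progression")$MA,
              classifiers = "logistic", n_boot = 0,
              seed = 200 + r)$metrics$auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.42)
  expect_lt(mean(aucs), 0.58)
})

test_that("calibration recovers perfect and distorted prediction slopes", {
  set.seed(11)
  p <- runif(2000, 0.05, 0.95)
  y <- rbinom(2000, 1, p)
  cal <- calibration_metrics(y, p, n_boot = 0)
  expect_equal(cal$slope, 1, tolerance = 0.12)
  expect_equal(cal$intercept, 0, tolerance = 0.15)
  # doubling the logit halves the recovered slope
  p_sharp <- plogis(2 * qlogis(p))
  cal2 <- calibration_metrics(y, p_sharp, n_boot = 0)
  expect_equal(cal2$slope, 0.5, tolerance = 0.07)
  expect_error(calibration_metrics(y, rep(0.4, 2000)), "constant")
})

test_that("calibration bootstrap intervals cover the point estimate", {
  set.seed(12)
  p <- runif(300, 0.1, 0.9)
  y <- rbinom(300, 1, p)
  cal <- calibration_metrics(y, p, n_boot = 200, seed = 13)
  expect_lt(cal$slope_lo, cal$slope)
  expect_gt(cal$slope_hi, cal$slope)
})

test_that("LOCO transfers a homogeneous signal but not a center artifact", {
  d <- make_model_data(n = 80, signal = 2.5, seed = 14)
  blocks <- assemble_blocks("progression")
  loco <- loco_cv(d, blocks$MA, seed = 15, n_boot = 0)
  cv <- nested_cv(d, blocks$MA, classifiers = "logistic", n_boot = 0,
                  seed = 16)
  expect_gt(loco$loco_auc, 0.75)
  expect_lt(abs(loco$loco_auc - cv$metrics$auc), 0.1)
  # a predictor that merely encodes the center carries no transferable
  # signal when the outcome is center-independent
  d2 <- make_model_data(n = 80, seed = 17)
  d2$A1 <- as.numeric(d2$center == "B") + rnorm(80, 0, 0.1)
  loco2 <- loco_cv(d2, blocks$MA, seed = 18, n_boot = 0)
  expect_lt(abs(loco2$loco_auc - 0.5), 0.15)
})

test_that("LOCO flags a center missing an outcome class", {
  d <- make_model_data(n = 40, seed = 19)
  d$y[d$center == "A"] <- 0L
  expect_warning(res <- loco_cv(d, assemble_blocks("progression")$M0,
                                seed = 20),
                 "lacks an outcome class")
  expect_true(is.nan(res$loco_auc))
})

test_that("the internal AUC agrees with the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  y <- rbinom(100, 1, 0.4)
  p <- plogis(rnorm(100) + y)
  ours <- pnetrad:::auc_rank(y, p)
  ref <- as.numeric(suppressMessages(pROC::auc(y, p)))
  expect_equal(ours, ref, tolerance = 1e-12)
})
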