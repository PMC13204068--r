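make_batched <- function(n_per = 200, p = 6, gamma = 1, delta = 1.5,
                         seed = 1) {
  set.seed(seed)
  n <- 2 * n_per
  batch <- rep(c("A", "B"), each = n_per)
  X <- matrix(rnorm(n * p), n, p)
  X[batch == "B", ] <- gamma + delta * X[batch == "B", ]
  colnames(X) <- sprintf("f%02d", seq_len(p))
  dplyr::bind_cols(tibble::tibble(patient_id = sprintf("P%04d", seq_len(n)),
                                  center = batch),
                   tibble::as_tibble(as.data.frame(X)))
}

test_that("balance_check runs the right test per covariate type", {
  co <- generate_cohort(cohort_profile(seed = 6))
  res <- balance_check(co, c("age", "ki67_pct", "functional"))
  expect_equal(res$test, c("mann-whitney", "mann-whitney", "fisher"))
  expect_true(all(res$p >= 0 & res$p <= 1))
  # covariate equal to the center indicator: near-minimal p, flagged
  co$leak <- as.numeric(co$center == "B") + rnorm(nrow(co), 0, 1e-3)
  expect_true(balance_check(co, "leak")$flagged)
  # constant covariate: p = 1 under the tie convention
  co$const <- 1
  expect_equal(balance_check(co, "const")$p, 1)
  expect_error(balance_check(co[co$center == "A", ], "age"), "two centers")
})

test_that("null cohorts are flagged at about the nominal 5% rate", {
  set.seed(31)
  flags <- replicate(400, {
    co <- tibble::tibble(center = rep(c("A", "B"), each = 20),
                         x = rnorm(40))
    balance_check(co, "x")$flagged
  })
  expect_lt(abs(mean(flags) - 0.05), 0.035)
})

test_that("single-batch ComBat is the identity (with a warning)", {
  d <- make_batched(seed = 2)
  d$center <- "A"
  expect_warning(m <- combat_fit(d, batch = "center"), "single batch")
  out <- combat_transform(m, d)
  expect_equal(as.matrix(out[, m$features]), as.matrix(d[, m$features]),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("injected location/scale batch effects are recovered within 5%", {
  d <- make_batched(n_per = 500, gamma = 1, delta = 1.5, seed = 3)
  m <- combat_fit(d, batch = "center")
  # on the standardized scale the injected shift/scale appear relative to
  # the pooled SD; compare batch-B to batch-A parameters
  g_b <- m$gamma_star["B", ] - m$gamma_star["A", ]
  d_b <- sqrt(m$delta2_star["B", ] / m$delta2_star["A", ])
  pooled_sd <- sqrt(m$sigma2)
  # mean over features within 5%; single features see Monte-Carlo noise
  expect_lt(abs(mean(g_b * pooled_sd) - 1), 0.05)
  expect_lt(abs(mean(d_b) - 1.5) / 1.5, 0.05)
  expect_true(all(abs(g_b * pooled_sd - 1) < 0.15))
  expect_true(all(abs(d_b - 1.5) / 1.5 < 0.15))
})

test_that("harmonized data have matched batch means and variances", {
  d <- make_batched(n_per = 400, gamma = 2, delta = 2, seed = 4)
  m <- combat_fit(d, batch = "center")
  out <- combat_transform(m, d)
  X <- as.matrix(out[, m$features])
  for (j in seq_len(ncol(X))) {
    expect_lt(abs(mean(X[out$center == "A", j]) -
                    mean(X[out$center == "B", j])), 0.15)
    expect_lt(abs(sd(X[out$center == "A", j]) /
                    sd(X[out$center == "B", j]) - 1), 0.15)
  }
})

test_that("refitting on harmonized output is a near-no-op", {
  d <- make_batched(n_per = 300, gamma = 2, delta = 2, seed = 5)
  m1 <- combat_fit(d, batch = "center")
  h1 <- combat_transform(m1, d)
  m2 <- combat_fit(h1, batch = "center")
  h2 <- combat_transform(m2, h1)
  first_pass <- mean(abs(as.matrix(h1[, m1$features]) -
                           as.matrix(d[, m1$features])))
  second_pass <- mean(abs(as.matrix(h2[, m1$features]) -
                            as.matrix(h1[, m1$features])))
  # the second pass only moves values by the sampling residual of the
  # first fit, far below the batch effect the first pass removed
  expect_lt(second_pass, 0.05 * first_pass)
  # and the refit parameters are near the identity
  expect_true(all(abs(m2$gamma_star) < 0.1))
  expect_true(all(abs(sqrt(m2$delta2_star) - 1) < 0.1))
})

test_that("transform is monotone within batch and keeps patient-ROI pairing", {
  d <- make_batched(n_per = 100, seed = 6)
  m <- combat_fit(d, batch = "center")
  out <- combat_transform(m, d)
  for (b in c("A", "B")) {
    expect_equal(order(d$f01[d$center == b]), order(out$f01[out$center == b]))
  }
  expect_identical(out$patient_id, d$patient_id)
})

test_that("EB shrinkage pulls batch locations toward the prior mean", {
  set.seed(7)
  shrunk <- replicate(30, {
    d <- make_batched(n_per = 20, p = 10, gamma = 0.5, delta = 1, seed = NULL)
    m <- combat_fit(d, batch = "center")
    gb <- mean(m$gamma_hat["B", ])
    mean(abs(m$gamma_star["B", ] - gb) <= abs(m$gamma_hat["B", ] - gb))
  })
  expect_gt(mean(shrunk), 0.7)
})

test_that("zero-variance features pass through; unseen batches error", {
  d <- make_batched(seed = 8)
  d$flat <- 5
  expect_warning(m <- combat_fit(d, batch = "center"), "zero-variance")
  out <- combat_transform(m, d)
  expect_equal(out$flat, d$flat)
  d2 <- d; d2$center[1] <- "C"
  expect_error(combat_transform(m, d2), "not seen")
})

test_that("fit agrees with the reference empirical-Bayes implementation", {
  skip_if_not_installed("sva")
  d <- make_batched(n_per = 60, p = 5, gamma = 1.2, delta = 1.4, seed = 9)
  m <- combat_fit(d, batch = "center")
  ours <- combat_transform(m, d)
  ref <- t(sva::ComBat(t(as.matrix(d[, m$features])), batch = d$center,
                       mod = NULL, par.prior = TRUE))
  expect_equal(as.matrix(ours[, m$features]), ref, tolerance = 0.01,
               ignore_attr = TRUE)
})
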