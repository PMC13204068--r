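test_that("z-standardization uses the sample-SD convention and is idempotent", {
  expect_equal(z_standardize(c(1, 2, 3)), c(-1, 0, 1))
  x <- c(4, NA, 8, 1, 7)
  z <- z_standardize(x)
  expect_true(is.na(z[2]))
  expect_equal(mean(z, na.rm = TRUE), 0, tolerance = 1e-12)
  expect_equal(sd(z, na.rm = TRUE), 1, tolerance = 1e-12)
  expect_equal(z_standardize(z), z, tolerance = 1e-12)
  expect_error(z_standardize(c(2, 2, 2)), "zero standard deviation")
  expect_error(z_standardize(c(1, NA, NA)), ">= 2")
})

test_that("the Cox maximizer matches a grid search of the Efron likelihood", {
  fixtures <- list(
    list(z = c(0.5, -1.2, 2.0, -0.3), time = c(3, 7, 2, 9),
         event = c(1, 1, 1, 0)),
    list(z = c(1, 0, -1, 2, -2, 0.5), time = c(5, 3, 8, 2, 9, 4),
         event = c(1, 1, 0, 1, 0, 1))
  )
  for (fx in fixtures) {
    fit <- cox_univariable(fx$z, fx$time, fx$event)
    grid <- seq(-3, 3, by = 1e-4)
    ll <- vapply(grid, efron_loglik_oracle, numeric(1),
                 z = fx$z, time = fx$time, event = fx$event)
    expect_equal(fit$beta, grid[which.max(ll)], tolerance = 2e-4)
  }
})

test_that("profile-likelihood bounds sit on the chi-square(1) contour", {
  fx <- simulate_ph(60, beta = 0.5, seed = 2)
  fit <- cox_univariable(fx$z, fx$time, fx$event)
  ll_max <- efron_loglik_oracle(fit$beta, fx$z, fx$time, fx$event)
  for (b in c(log(fit$ci_low), log(fit$ci_high))) {
    drop <- 2 * (ll_max - efron_loglik_oracle(b, fx$z, fx$time, fx$event))
    expect_equal(drop, qchisq(0.95, 1), tolerance = 1e-3)
  }
  expect_lt(fit$ci_low, fit$hr_per_sd)
  expect_gt(fit$ci_high, fit$hr_per_sd)
})

test_that("a true hazard ratio of 2 per SD is recovered at n = 2000", {
  fx <- simulate_ph(2000, beta = log(2), seed = 3)
  fit <- cox_univariable(z_standardize(fx$z), fx$time, fx$event)
  expect_equal(fit$hr_per_sd, 2, tolerance = 0.075)
})

test_that("null covariates give near-nominal CI coverage", {
  cover <- vapply(1:150, function(s) {
    fx <- simulate_ph(100, beta = 0, seed = 1000 + s, censor = 40)
    fit <- cox_univariable(fx$z, fx$time, fx$event)
    fit$ci_low <= 1 && fit$ci_high >= 1
  }, logical(1))
  expect_gt(mean(cover), 0.89)
  expect_lt(mean(cover), 0.995)
})

test_that("negating the score inverts the hazard ratio and concordance", {
  fx <- simulate_ph(120, beta = 0.7, seed = 4, censor = 60)
  f1 <- cox_univariable(fx$z, fx$time, fx$event)
  f2 <- cox_univariable(-fx$z, fx$time, fx$event)
  expect_equal(f2$hr_per_sd, 1 / f1$hr_per_sd, tolerance = 1e-6)
  expect_equal(f2$ci_low, 1 / f1$ci_high, tolerance = 1e-4)
  c1 <- concordance_inference(fx$z, fx$time, fx$event, n_boot = 0, n_perm = 0)
  c2 <- concordance_inference(-fx$z, fx$time, fx$event, n_boot = 0, n_perm = 0)
  expect_equal(c2$c, 1 - c1$c, tolerance = 1e-12)
  expect_equal(c2$c_abs, c1$c_abs, tolerance = 1e-12)
  expect_gte(c1$c_abs, 0.5)
})

test_that("concordance matches exhaustive pair counting on small fixtures", {
  set.seed(5)
  for (rep in 1:5) {
    z <- rnorm(6)
    time <- sample(seq(2, 24, by = 2), 6)  # distinct times
    event <- rbinom(6, 1, 0.7)
    if (sum(event) == 0) event[1] <- 1
    got <- concordance_inference(z, time, event, n_boot = 0, n_perm = 0)
    expect_equal(got$c, cindex_oracle(z, time, event))
  }
})

test_that("a perfect risk ranking gives c = 1", {
  time <- c(1, 2, 3, 4, 5)
  z <- 6 - time  # higher score, earlier event
  got <- concordance_inference(z, time, rep(1, 5), n_boot = 0, n_perm = 0)
  expect_equal(got$c, 1)
})

test_that("independent scores give c near 0.5 and uniform-ish permutation p", {
  set.seed(6)
  cs <- replicate(30, {
    fx <- simulate_ph(80, beta = 0, seed = sample.int(1e6, 1), censor = 40)
    concordance_inference(fx$z, fx$time, fx$event, n_boot = 0, n_perm = 0)$c
  })
  expect_lt(abs(mean(cs) - 0.5), 0.03)
  fx <- simulate_ph(60, beta = 0, seed = 7, censor = 40)
  p1 <- concordance_inference(fx$z, fx$time, fx$event, n_boot = 50,
                              n_perm = 200, seed = 1)$c_perm_p
  expect_gt(p1, 0.05)
})

test_that("bootstrap and permutation streams are seed-reproducible", {
  fx <- simulate_ph(50, beta = 0.5, seed = 8, censor = 60)
  a <- concordance_inference(fx$z, fx$time, fx$event, n_boot = 100,
                             n_perm = 100, seed = 9)
  b <- concordance_inference(fx$z, fx$time, fx$event, n_boot = 100,
                             n_perm = 100, seed = 9)
  expect_identical(a, b)
})

test_that("signature_cox reports complete-case n and events per signature", {
  set.seed(10)
  n <- 40
  sig <- tibble::tibble(patient_id = sprintf("P%02d", 1:n),
                        A1 = rnorm(n), B1 = rnorm(n))
  sig$A1[1:6] <- NA
  time <- rexp(n, 0.05); event <- rbinom(n, 1, 0.5)
  res <- signature_cox(sig, time, event, n_boot = 0, n_perm = 0)
  expect_equal(res$n[res$signature == "A1"], n - 6L)
  expect_equal(res$events[res$signature == "A1"],
               sum(event[-(1:6)]))
  expect_equal(res$n[res$signature == "B1"], n)
})

test_that("monotone likelihoods are flagged instead of crashing", {
  # risk score perfectly orders the events: likelihood is monotone in beta
  time <- 1:6
  z <- c(3, 2.5, 2, 1.5, 1, 0.5)
  res <- suppressWarnings(cox_univariable(z, time, rep(1, 6)))
  expect_true(res$monotone || res$ci_high > 100)
})
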