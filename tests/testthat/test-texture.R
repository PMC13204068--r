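random_bins_array <- function(dims, n_levels, seed, p_na = 0.2) {
  set.seed(seed)
  ba <- array(sample.int(n_levels, prod(dims), replace = TRUE), dims)
  ba[runif(prod(dims)) < p_na] <- NA_integer_
  if (all(is.na(ba))) ba[1] <- 1L
  storage.mode(ba) <- "integer"
  ba
}

test_that("GLSZM zones match hand enumeration on the 2x2 plane example", {
  ba <- array(NA_integer_, c(2, 2, 1))
  ba[1, 1, 1] <- 1L; ba[2, 1, 1] <- 1L; ba[1, 2, 1] <- 1L; ba[2, 2, 1] <- 2L
  Z <- pnetrad:::glszm_matrix(ba, 2L)
  expect_equal(sum(Z), 2)           # exactly two zones
  expect_equal(Z[1, 3], 1)          # size-3 zone of level 1
  expect_equal(Z[2, 1], 1)          # size-1 zone of level 2
})

test_that("GLSZM agrees with the flood-fill oracle on random small ROIs", {
  for (seed in 1:6) {
    ba <- random_bins_array(c(4, 4, 3), 3, seed)
    Z <- pnetrad:::glszm_matrix(ba, 3L)
    zo <- zones_oracle(ba)
    Zo <- matrix(0, 3, max(zo$size))
    for (r in seq_len(nrow(zo))) {
      Zo[zo$level[r], zo$size[r]] <- Zo[zo$level[r], zo$size[r]] + 1
    }
    expect_equal(Z[, seq_len(ncol(Zo)), drop = FALSE], Zo)
    # SizeZoneNonUniformity against its definition on the oracle zones
    szn <- sum(table(zo$size)^2) / nrow(zo)
    expect_equal(pnetrad:::glszm_features(Z)[["SizeZoneNonUniformity"]], szn)
  }
})

test_that("NGTDM busyness matches the hand-computed checkerboard value", {
  ba <- array(NA_integer_, c(3, 3, 1))
  ba[, , 1] <- matrix(c(1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L, 1L), 3, 3)
  mats <- rad_texture_matrices(sample_from_bins(ba))
  got <- pnetrad:::ngtdm_features(mats$ngtdm)[["Busyness"]]
  expect_equal(got, ngtdm_busyness_oracle(ba), tolerance = 1e-12)
  # and the p_i / s_i components themselves
  o <- ngtdm_oracle(ba)
  expect_equal(mats$ngtdm$p, o$p)
  expect_equal(mats$ngtdm$s, o$s)
})

test_that("NGTDM and GLCM agree with brute-force oracles on random ROIs", {
  for (seed in 7:10) {
    ba <- random_bins_array(c(4, 4, 4), 3, seed)
    mats <- rad_texture_matrices(sample_from_bins(ba))
    o <- ngtdm_oracle(ba)
    expect_equal(mats$ngtdm$p, o$p)
    expect_equal(mats$ngtdm$s, o$s, tolerance = 1e-12)
    expect_equal(pnetrad:::ngtdm_features(mats$ngtdm)[["Busyness"]],
                 ngtdm_busyness_oracle(ba), tolerance = 1e-12)
    # GLCM for two representative directions
    for (dir in list(c(1, 0, 0), c(1, -1, 1))) {
      ours <- pnetrad:::glcm_one_direction(ba, dir, 3L)
      expect_equal(ours, glcm_oracle(ba, dir, 3L), tolerance = 1e-12)
    }
  }
})

test_that("degenerate single-level ROIs follow the stated conventions", {
  ba <- array(1L, c(3, 3, 2))
  mats <- rad_texture_matrices(sample_from_bins(ba))
  tf <- rad_texture_features(mats)
  expect_equal(tf[["ngtdm_Busyness"]], 0)   # zero-denominator convention
  expect_equal(tf[["glcm_Idmn"]], 1)        # all mass on the diagonal
  expect_equal(tf[["glcm_Contrast"]], 0)
  # single-voxel ROI: one gray level, zero neighborhood sum
  one <- array(NA_integer_, c(3, 3, 3)); one[2, 2, 2] <- 1L
  m1 <- rad_texture_matrices(sample_from_bins(one))
  expect_equal(m1$ngtdm$n, 1L)
  expect_equal(m1$ngtdm$s, 0)
  expect_true(all(is.finite(rad_texture_features(m1))))
})

test_that("GLRLM runs are counted correctly on a hand-checkable line", {
  # one row: levels 1 1 1 2 2 -> along x: runs (1,len3), (2,len2)
  ba <- array(NA_integer_, c(5, 1, 1))
  ba[, 1, 1] <- c(1L, 1L, 1L, 2L, 2L)
  R <- pnetrad:::glrlm_one_direction(ba, c(1, 0, 0), 2L)
  expect_equal(R[1, 3], 1)
  expect_equal(R[2, 2], 1)
  expect_equal(sum(R), 2)
  # perpendicular direction: every voxel is its own run
  R2 <- pnetrad:::glrlm_one_direction(ba, c(0, 1, 0), 2L)
  expect_equal(sum(R2[, 1]), 5)
})

test_that("adding a constant HU shift leaves histogram/texture features alone and moves the median", {
  set.seed(21)
  v <- array(rnorm(6^3, 60, 30), c(6, 6, 6))
  attr(v, "spacing") <- c(1, 1, 1)
  m <- array(TRUE, dim(v))
  cfg <- extraction_config()
  f0 <- extract_features(v, list(roi = m), config = cfg)
  v2 <- v + 40  # stays inside the resegmentation window
  attr(v2, "spacing") <- c(1, 1, 1)
  f1 <- extract_features(v2, list(roi = m), config = cfg)
  expect_equal(f1$firstorder_Entropy, f0$firstorder_Entropy, tolerance = 1e-12)
  for (col in grep("^(glcm|glrlm|glszm|gldm|ngtdm)_", names(f0),
                   value = TRUE)) {
    expect_equal(f1[[col]], f0[[col]], tolerance = 1e-10)
  }
  expect_equal(f1$firstorder_Median, f0$firstorder_Median + 40,
               tolerance = 1e-10)
})

test_that("direction-averaged features are invariant to 90-degree rotation", {
  set.seed(22)
  ba <- random_bins_array(c(5, 5, 5), 4, 30, p_na = 0.3)
  rot <- aperm(ba, c(2, 1, 3))[dim(ba)[2]:1, , ]  # 90 deg about z
  storage.mode(rot) <- "integer"
  f0 <- rad_texture_features(rad_texture_matrices(sample_from_bins(ba)))
  f1 <- rad_texture_features(rad_texture_matrices(sample_from_bins(rot)))
  expect_equal(f1, f0, tolerance = 1e-10)
})

test_that("every feature is finite on every small random ROI", {
  for (seed in 40:44) {
    ba <- random_bins_array(c(4, 4, 4), 5, seed, p_na = 0.5)
    s <- sample_from_bins(ba)
    feats <- c(rad_first_order(s), rad_shape(s$mask, s$spacing),
               rad_texture_features(rad_texture_matrices(s)))
    expect_true(all(is.finite(feats)), info = paste("seed", seed))
  }
})
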