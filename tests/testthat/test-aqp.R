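zmaps_from_rows <- function(zrows, dims = c(2, 1, 1)) {
  # zrows: matrix n_atlas x n_voxels
  lapply(seq_len(nrow(zrows)), function(a) array(zrows[a, ], dims))
}

test_that("vote counts atlases beyond the threshold per direction", {
  brain <- array(TRUE, c(2, 1, 1))
  z <- zmaps_from_rows(cbind(c(-3.5, -3.2, -4.0, -3.1, -1.0, 0.2),
                             c(3.5, 3.5, -3.5, -3.5, 0, 0)))
  v <- vote(z, 3, brain)
  expect_equal(v$votes_low[1, 1, 1], 4)
  expect_equal(v$votes_high[1, 1, 1], 0)
  expect_equal(v$votes_low[2, 1, 1], 2)
  expect_equal(v$votes_high[2, 1, 1], 2)

  z0 <- zmaps_from_rows(matrix(0, 6, 2))
  v0 <- vote(z0, 3, brain)
  expect_true(all(v0$votes_low == 0) && all(v0$votes_high == 0))

  # votes are zeroed outside the brain
  nb <- array(c(FALSE, TRUE), c(2, 1, 1))
  vz <- vote(z, 3, nb)
  expect_equal(vz$votes_low[1, 1, 1], 0)
})

test_that("classify_voxels applies the K-of-N rule and discards ties", {
  mk <- function(low, high) {
    structure(list(votes_low = array(low, c(1, 1, 1)),
                   votes_high = array(high, c(1, 1, 1)), N = 6L),
              class = "vote_map")
  }
  expect_true(classify_voxels(mk(4, 0), 4)$low_raw[1])
  expect_false(classify_voxels(mk(3, 0), 4)$low_raw[1])
  tie <- classify_voxels(mk(2, 2), 2)
  expect_false(tie$low_raw[1] || tie$high_raw[1])
})

test_that("classify_voxels matches exhaustive counting on random vote grids", {
  set.seed(99)
  dims <- c(8, 8, 8)
  N <- 6
  zr <- matrix(rnorm(N * prod(dims), 0, 2.5), N)
  brain <- array(TRUE, dims)
  v <- vote(zmaps_from_rows(zr, dims), 3, brain)
  for (K in 1:N) {
    got <- classify_voxels(v, K)
    for (i in sample(prod(dims), 50)) {
      nl <- sum(zr[, i] < -3); nh <- sum(zr[, i] > 3)
      expect_identical(got$low_raw[i], nl >= K && nl > nh)
      expect_identical(got$high_raw[i], nh >= K && nh > nl)
    }
  }
})

test_that("CSF margin excludes high voxels under 3 mm but keeps 3 mm and low voxels", {
  dims <- c(9, 5, 5)
  csf <- array(FALSE, dims); csf[1, , ] <- TRUE
  brain <- array(TRUE, dims)
  tis <- tissue_masks(brain, csf)
  low <- array(FALSE, dims); high <- array(FALSE, dims)
  high[3, 3, 3] <- TRUE    # 2 mm from CSF -> excluded
  high[4, 3, 3] <- TRUE    # exactly 3 mm  -> retained (strict <)
  high[1, 2, 2] <- TRUE    # inside CSF    -> excluded
  low[2, 3, 3] <- TRUE     # 1 mm from CSF, low class -> retained
  ex <- apply_exclusions(low, high, tis, c(1, 1, 1), 3)
  expect_false(ex$high[3, 3, 3])
  expect_true(ex$high[4, 3, 3])
  expect_false(ex$high[1, 2, 2])
  expect_true(ex$low[2, 3, 3])
  # diagonal case: sqrt(6) = 2.45 mm < 3 -> excluded
  high2 <- array(FALSE, dims); high2[3, 4, 4] <- TRUE
  csf2 <- array(FALSE, dims); csf2[1, 3, 3] <- TRUE
  ex2 <- apply_exclusions(low, high2, tissue_masks(brain, csf2), c(1, 1, 1), 3)
  expect_false(ex2$high[3, 4, 4])
})

test_that("minimum-size filter is inclusive at the class thresholds", {
  dims <- c(40, 30, 20)
  mk_comp <- function(mask, n, x0) {
    # a compact bar of exactly n voxels starting at x-plane x0
    filled <- 0
    for (x in x0:(x0 + 9)) for (y in 1:15) for (z in 1:5) {
      if (filled < n) { mask[x, y, z] <- TRUE; filled <- filled + 1 }
    }
    mask
  }
  m119 <- mk_comp(array(FALSE, dims), 119, 1)
  m120 <- mk_comp(array(FALSE, dims), 120, 14)
  low <- m119 | m120
  f_low <- filter_components(low, c(1, 1, 1), 0.12)
  expect_equal(sum(f_low$mask), 120)
  expect_equal(nrow(f_low$components), 1)
  expect_equal(f_low$components$volume_ml, 0.120)

  m159 <- mk_comp(array(FALSE, dims), 159, 1)
  m160 <- mk_comp(array(FALSE, dims), 160, 14)
  f_high <- filter_components(m159 | m160, c(1, 1, 1), 0.16)
  expect_equal(sum(f_high$mask), 160)

  empty <- filter_components(array(FALSE, dims), c(1, 1, 1), 0.12)
  expect_equal(sum(empty$mask), 0)
  expect_equal(nrow(empty$components), 0)
})

# shared small-scale detection setting for the end-to-end tests
aqp_fixture <- function(seed = 81, ...) {
  sp <- small_spec(seed = seed, ...)
  ctr <- make_controls(sp, 3)
  tis <- ctr[[1]]$tissues
  atl <- make_atlas_set(tis$brain, sp$spacing_mm, n_atlases = 6, seed = 4)
  mod <- fit_normative(lapply(ctr, `[[`, "md"), tis, atl)
  list(sp = sp, tis = tis, atl = atl, mod = mod)
}

test_that("a single strong high-MD lesion yields exactly one high component at the right place", {
  fx <- aqp_fixture(seed = 82, n_lesions_low = 0, n_lesions_high = 1,
                    coeff_high_range = c(1.8, 1.8),
                    target_lesion_fraction = 0.02)
  sp_i <- fx$sp; sp_i$seed <- 991L
  ph <- make_brain(sp_i)
  les <- insert_lesions(ph$md, ph$tissues, fx$sp, seed = 991L)
  res <- run_aqp(les$md, ph$tissues, fx$atl, fx$mod)
  expect_equal(sum(res$components$class == "low"), 0)
  expect_equal(sum(res$components$class == "high"), 1)
  cen <- unlist(res$components[1, c("centroid_x_mm", "centroid_y_mm", "centroid_z_mm")])
  gt_cen <- unlist(les$gt$lesions[1, c("centroid_x_mm", "centroid_y_mm", "centroid_z_mm")])
  expect_lt(sqrt(sum((cen - gt_cen)^2)), 5)
  expect_gt(overlap_metrics(res$high_mask, les$gt$high_mask)$dice, 0.5)
  # volume bookkeeping invariants
  expect_equal(res$volume_total_ml, res$volume_low_ml + res$volume_high_ml,
               tolerance = 1e-9)
  expect_equal(res$brain_fraction_pct,
               100 * res$volume_total_ml / res$brain_volume_ml)
})

test_that("detected volume is monotone non-increasing in z threshold and K", {
  fx <- aqp_fixture(seed = 83)
  sp_i <- fx$sp; sp_i$seed <- 992L
  ph <- make_brain(sp_i)
  les <- insert_lesions(ph$md, ph$tissues, fx$sp, seed = 992L)
  vols <- matrix(NA_real_, 3, 3)
  zs <- c(2.5, 3, 3.5); Ks <- c(3, 4, 5)
  for (i in seq_along(zs)) for (j in seq_along(Ks)) {
    res <- run_aqp(les$md, ph$tissues, fx$atl, fx$mod,
                   aqp_config(z_threshold = zs[i], K = Ks[j]))
    vols[i, j] <- res$volume_total_ml
  }
  for (j in 1:3) expect_true(all(diff(vols[, j]) <= 1e-12))
  for (i in 1:3) expect_true(all(diff(vols[i, ]) <= 1e-12))
})

test_that("run_aqp is deterministic/idempotent and masks are disjoint and CSF-free", {
  fx <- aqp_fixture(seed = 84)
  sp_i <- fx$sp; sp_i$seed <- 993L
  ph <- make_brain(sp_i)
  les <- insert_lesions(ph$md, ph$tissues, fx$sp, seed = 993L)
  r1 <- run_aqp(les$md, ph$tissues, fx$atl, fx$mod)
  r2 <- run_aqp(les$md, ph$tissues, fx$atl, fx$mod)
  expect_identical(r1$low_mask, r2$low_mask)
  expect_identical(r1$high_mask, r2$high_mask)
  expect_equal(r1$components, r2$components)
  expect_false(any(r1$low_mask & r1$high_mask))
  expect_false(any((r1$low_mask | r1$high_mask) & ph$tissues$csf))
  # tidy/glance accessors
  expect_s3_class(tidy(r1), "tbl_df")
  expect_equal(glance(r1)$volume_total_ml, r1$volume_total_ml)
})
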