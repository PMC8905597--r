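test_that("overlap metrics follow the set-count definitions and conventions", {
  dims <- c(6, 6, 6)
  a <- array(FALSE, dims); a[2:3, 2, 2] <- TRUE; a[2:3, 3, 2] <- TRUE  # 4 voxels
  b <- array(FALSE, dims); b[2:3, 3, 2] <- TRUE; b[2:3, 4, 2] <- TRUE  # 4, overlap 2
  m <- overlap_metrics(a, b)
  expect_equal(m$dice, 0.5)
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 0.5)
  expect_equal(overlap_metrics(a, a)$dice, 1)
  d <- array(FALSE, dims); d[5, 5, 5] <- TRUE
  expect_equal(overlap_metrics(a, d)$dice, 0)
  e <- array(FALSE, dims)
  both <- overlap_metrics(e, e)
  expect_equal(both$dice, 1); expect_true(both$both_empty)
  expect_equal(overlap_metrics(a, e)$dice, 0)
})

test_that("surface distances: identity, two-point closed form, symmetry", {
  dims <- c(8, 8, 8)
  a <- array(FALSE, dims); a[2, 2, 2] <- TRUE
  b <- array(FALSE, dims); b[5, 2, 2] <- TRUE
  sd1 <- surface_distances(a, b, c(1, 1, 1))
  expect_equal(sd1$hd_mm, 3)
  expect_equal(sd1$assd_mm, 3)
  self <- surface_distances(a, a, c(1, 1, 1))
  expect_equal(self$hd_mm, 0); expect_equal(self$assd_mm, 0)
  # anisotropic spacing
  sd2 <- surface_distances(a, b, c(2, 1, 1))
  expect_equal(sd2$hd_mm, 6)
  expect_error(surface_distances(a, array(FALSE, dims), c(1, 1, 1)), "empty")
})

test_that("distance metrics agree with the brute-force oracle on random masks", {
  set.seed(7)
  for (i in 1:10) {
    a <- random_mask(); b <- random_mask()
    spacing <- c(1, 1.2, 0.8)
    got <- surface_distances(a, b, spacing)
    ref <- oracle_surface_distances(a, b, spacing)
    expect_equal(got$hd_mm, ref$hd, tolerance = 1e-9)
    expect_equal(got$assd_mm, ref$assd, tolerance = 1e-9)
    # symmetry under argument exchange
    rev <- surface_distances(b, a, spacing)
    expect_equal(rev$hd_mm, got$hd_mm)
    expect_equal(rev$assd_mm, got$assd_mm)
    # dice symmetric; precision(test, ref) = recall(ref, test)
    expect_equal(overlap_metrics(a, b)$dice, overlap_metrics(b, a)$dice)
    expect_equal(overlap_metrics(a, b)$precision, overlap_metrics(b, a)$recall)
  }
})

test_that("ICC(2,1) matches the ANOVA oracle and its limit cases", {
  x <- c(9.1, 8.2, 7.3, 6.4, 5.5)
  expect_equal(icc(cbind(x, x))$icc, 1)
  expect_lt(icc(cbind(1:5, 5:1))$icc, 0)
  set.seed(3)
  m <- matrix(rnorm(10, 10, 2), 5, 2)
  expect_equal(icc(m)$icc, oracle_icc21(m), tolerance = 1e-12)
  m2 <- matrix(rnorm(21, 5, 1), 7, 3)
  expect_equal(icc(m2)$icc, oracle_icc21(m2), tolerance = 1e-12)
  expect_error(icc(matrix(1, 4, 2)), "zero total variance")
  expect_error(icc(matrix(1:2, 1, 2)), ">= 2 subjects")
})

test_that("Bland-Altman bias and limits follow the closed form", {
  eq <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(eq$bias, 0); expect_equal(eq$lower_loa, 0); expect_equal(eq$upper_loa, 0)
  ba <- bland_altman(c(1, 0), c(0, 1))   # d = +1, -1
  expect_equal(ba$bias, 0)
  expect_equal(ba$upper_loa, 1.96 * sqrt(2))
  shift <- bland_altman(c(1, 2, 3) + 5, c(1, 2, 3))
  expect_equal(shift$bias, 5)
  expect_error(bland_altman(1, 1), ">= 2 pairs")
})

test_that("volume error is the signed relative difference in percent", {
  expect_equal(volume_error(35, 31), 100 * 4 / 31)
  expect_equal(round(volume_error(35, 31), 1), 12.9)
  expect_equal(volume_error(31, 31), 0)
  expect_equal(volume_error(1022, 1000), 2.2)
  expect_error(volume_error(1, 0), "> 0")
})

test_that("evaluate_segmentation assembles a complete report row", {
  dims <- c(10, 10, 10)
  a <- array(FALSE, dims); a[3:6, 3:6, 3:6] <- TRUE
  b <- array(FALSE, dims); b[4:7, 3:6, 3:6] <- TRUE
  row <- evaluate_segmentation(a, b, c(1, 1, 1))
  expect_named(row, c("dice", "hd_mm", "assd_mm", "precision", "recall",
                      "test_ml", "reference_ml", "volume_error_pct"))
  expect_equal(row$test_ml, 64 / 1000)
  expect_equal(row$volume_error_pct, 0)
  empty <- evaluate_segmentation(array(FALSE, dims), b, c(1, 1, 1))
  expect_true(is.na(empty$hd_mm))
  expect_equal(empty$dice, 0)
})

test_that("group comparison wrappers dispatch to the right test", {
  set.seed(1)
  v <- c(rnorm(10), rnorm(10, 3), rnorm(10, 6))
  g3 <- rep(c("a", "b", "c"), each = 10)
  kw <- compare_groups(v, g3)
  expect_match(kw$method, "Kruskal")
  mw <- compare_groups(v[1:20], g3[1:20])
  expect_match(mw$method, "Wilcoxon")
  expect_lt(mw$p_value, 0.01)
})
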