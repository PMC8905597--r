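make_iso_dwi <- function(md_true, dims = c(4, 4, 4), b = 1000, s0 = 1000) {
  dirs <- mdaqp:::dti_directions(6)
  nvol <- 7
  data <- array(0, c(dims, nvol))
  data[, , , 1] <- s0
  for (j in 2:nvol) data[, , , j] <- s0 * exp(-b * md_true)
  dwi_set(data, c(0, rep(b, 6)), cbind(c(0, 0, 0), dirs))
}

test_that("isotropic signal recovers MD exactly and MD = trace/3 identically", {
  dwi <- make_iso_dwi(8e-4)
  mask <- array(TRUE, c(4, 4, 4))
  fit <- fit_tensor(dwi, mask)
  expect_lt(max(abs(fit$md$data - 8e-4)), 1e-9)
  trace3 <- colMeans(fit$tensor[1:3, , drop = FALSE])
  expect_equal(unname(fit$md$data[fit$voxel_index]), unname(trace3),
               tolerance = 1e-15)
})

test_that("anisotropic tensor fit recovers trace/3 from forward-simulated signals", {
  # diag(1.7, 0.3, 0.3)e-3: MD = 7.666...e-4 regardless of anisotropy
  Dtrue <- diag(c(1.7e-3, 0.3e-3, 0.3e-3))
  dirs <- mdaqp:::dti_directions(6)
  b <- 1000; s0 <- 1000
  dims <- c(3, 3, 3)
  data <- array(0, c(dims, 7))
  data[, , , 1] <- s0
  for (j in 1:6) {
    g <- dirs[, j]
    adc <- as.numeric(t(g) %*% Dtrue %*% g)
    data[, , , j + 1] <- s0 * exp(-b * adc)
  }
  dwi <- dwi_set(data, c(0, rep(b, 6)), cbind(c(0, 0, 0), dirs))
  fit <- fit_tensor(dwi, array(TRUE, dims))
  expect_equal(unname(fit$md$data[1, 1, 1]), sum(diag(Dtrue)) / 3,
               tolerance = 1e-12)
})

test_that("voxels with zero b0 signal are dropped from the fit mask, not fatal", {
  dwi <- make_iso_dwi(8e-4)
  dwi$data[1, 1, 1, ] <- 0
  fit <- fit_tensor(dwi, array(TRUE, c(4, 4, 4)))
  expect_false(fit$fit_mask[1, 1, 1])
  expect_equal(sum(fit$fit_mask), 63)
})

test_that("rank-deficient gradient schemes are rejected", {
  dims <- c(3, 3, 3)
  data <- array(1000, c(dims, 7))
  g <- c(1, 0, 0)
  dirs <- matrix(rep(g, 6), nrow = 3)   # collinear
  expect_error(dwi_set(data, c(0, rep(1000, 6)), cbind(c(0, 0, 0), dirs)),
               "non-collinear")
})

test_that("Rician noise at SNR 40 keeps median MD error under 5%", {
  sp <- phantom_spec(shape = c(16, 16, 16), seed = 9)
  md_true <- 8e-4
  md_vol <- image_volume(array(md_true, c(16, 16, 16)), sp$spacing_mm)
  brain <- array(TRUE, c(16, 16, 16))
  dwi <- synthesize_dwi(md_vol, brain, b = 1000, n_dirs = 12, snr = 40, seed = 5)
  fit <- fit_tensor(dwi, brain)
  err <- abs(fit$md$data[fit$fit_mask] - md_true) / md_true
  expect_lt(median(err), 0.05)
})

test_that("SNR is brain mean over background sd and is scale invariant", {
  vol <- array(0, c(6, 6, 6))
  brain <- array(FALSE, c(6, 6, 6)); brain[2:5, 2:5, 2:5] <- TRUE
  vol[brain] <- 100
  set.seed(1)
  bg <- rnorm(sum(!brain), 0, 5)
  vol[!brain] <- bg
  expect_equal(compute_snr(vol, brain), 100 / sd(bg))
  expect_equal(compute_snr(vol * 2, brain), compute_snr(vol, brain))
  vol[!brain] <- 7   # constant background
  expect_error(compute_snr(vol, brain), "zero variance")
})

test_that("corrupted-slice detector flags the zeroed slice and nothing else", {
  sp <- phantom_spec(shape = c(32, 32, 32), seed = 3)
  ph <- make_brain(sp)
  dwi <- synthesize_dwi(ph$md, ph$tissues$brain, b = 1000, n_dirs = 6,
                        snr = 60, seed = 2)
  clean <- detect_corrupted_slices(dwi, ph$tissues$brain, z_threshold = 4)
  expect_equal(nrow(clean), 0)

  dwi$data[, , 16, 3] <- 0
  bad <- detect_corrupted_slices(dwi, ph$tissues$brain, z_threshold = 4)
  expect_true(any(bad$volume == 3 & bad$slice == 16))
  expect_true(all(bad$volume == 3))

  none <- detect_corrupted_slices(dwi, ph$tissues$brain, z_threshold = Inf)
  expect_equal(nrow(none), 0)

  qc <- qc_report(dwi, ph$tissues$brain)
  expect_false(qc$passed)
})
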