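test_that("make_brain builds a plausible geometry deterministically", {
  sp <- phantom_spec(seed = 7)
  ph <- make_brain(sp)
  expect_true(any(ph$tissues$brain))
  expect_true(all(ph$tissues$brain[ph$tissues$csf]))   # CSF inside brain
  wm <- ph$tissue_labels == 1L
  expect_gt(median(ph$md$data[ph$tissues$csf]), median(ph$md$data[wm]))
  # determinism: same spec + seed, bit identical
  ph2 <- make_brain(sp)
  expect_identical(ph$md$data, ph2$md$data)
  expect_identical(ph$tissues$csf, ph2$tissues$csf)
})

test_that("zero tissue sd gives exactly piecewise-constant MD", {
  sp <- small_spec(tissue_md = list(WM = c(0.75e-3, 0), GM = c(0.85e-3, 0),
                                    CSF = c(3.0e-3, 0)))
  ph <- make_brain(sp)
  expect_setequal(unique(ph$md$data[ph$tissue_labels == 1L]), 0.75e-3)
  expect_setequal(unique(ph$md$data[ph$tissue_labels == 2L]), 0.85e-3)
  expect_setequal(unique(ph$md$data[ph$tissue_labels == 3L]), 3.0e-3)
})

test_that("grids too small for ventricles are refused", {
  expect_error(make_brain(phantom_spec(shape = c(16, 16, 16))), "24 mm")
})

test_that("lesion insertion respects the multiplicative model and halo truncation", {
  sp <- small_spec(seed = 21, n_lesions_low = 0, n_lesions_high = 1,
                   coeff_high_range = c(2.0, 2.0),
                   target_lesion_fraction = 0.01)
  ph <- make_brain(sp)
  les <- insert_lesions(ph$md, ph$tissues, sp)
  core <- les$gt$high_mask
  expect_true(any(core))
  # strictly raised inside the core
  expect_true(all(les$md$data[core] > ph$md$data[core]))
  # untouched beyond 3 x FWHM of the support (kernel truncation)
  far <- distance_to_mm(core, sp$spacing_mm) > 3 * sp$smoothing_fwhm_mm
  expect_lt(max(abs(les$md$data[far] - ph$md$data[far])), 1e-12)
  # ground-truth bookkeeping
  expect_equal(les$gt$lesions$volume_ml,
               sum(core) * prod(sp$spacing_mm) / 1000, tolerance = 1e-9)
})

test_that("a coefficient at 1 leaves the MD map (numerically) unchanged", {
  eps <- 1e-9
  sp <- small_spec(seed = 22, n_lesions_low = 0, n_lesions_high = 1,
                   coeff_high_range = c(1 + eps, 1 + eps),
                   target_lesion_fraction = 0.01)
  ph <- make_brain(sp)
  les <- insert_lesions(ph$md, ph$tissues, sp)
  # change is bounded by w * (c - 1) * MD <= eps * max(MD)
  expect_lt(max(abs(les$md$data - ph$md$data)), eps * max(ph$md$data) * 1.01)
})

test_that("low cores strictly decrease and high cores strictly increase MD, disjoint and CSF-free", {
  for (s in c(31, 32)) {
    sp <- small_spec(seed = s)
    ph <- make_brain(sp)
    les <- insert_lesions(ph$md, ph$tissues, sp)
    gt <- les$gt
    expect_false(any(gt$low_mask & gt$high_mask))
    expect_false(any((gt$low_mask | gt$high_mask) & ph$tissues$csf))
    expect_true(all(ph$tissues$brain[gt$low_mask | gt$high_mask]))
    expect_true(all(les$md$data[gt$low_mask] < ph$md$data[gt$low_mask]))
    expect_true(all(les$md$data[gt$high_mask] > ph$md$data[gt$high_mask]))
  }
})

test_that("lesion load is calibrated to the 2.2% target across seeds", {
  fr <- vapply(1:5, function(s) {
    sp <- phantom_spec(seed = 100 + s)
    ph <- make_brain(sp)
    les <- insert_lesions(ph$md, ph$tissues, sp)
    sum(les$gt$low_mask | les$gt$high_mask) / sum(ph$tissues$brain)
  }, numeric(1))
  expect_gt(mean(fr), 0.022 - 0.005)
  expect_lt(mean(fr), 0.022 + 0.005)
})

test_that("controls share geometry but differ in MD; degenerate case equals make_brain", {
  sp <- small_spec(seed = 41)
  ctr <- make_controls(sp, 3)
  expect_length(ctr, 3)
  expect_identical(ctr[[1]]$tissues$brain, ctr[[2]]$tissues$brain)
  expect_false(identical(ctr[[1]]$md$data, ctr[[2]]$md$data))
  expect_false(identical(ctr[[2]]$md$data, ctr[[3]]$md$data))
  one <- make_controls(sp, 1, scale_pct = 0)
  expect_identical(one[[1]]$md$data, make_brain(sp)$md$data)
})

test_that("control WM MD stays within 10% of the tissue mean", {
  sp <- small_spec(seed = 51)
  base <- make_brain(sp)
  wm <- base$tissue_labels == 1L
  for (ctl in make_controls(sp, 8)) {
    expect_lt(abs(mean(ctl$md$data[wm]) - sp$tissue_md$WM[1]),
              0.10 * sp$tissue_md$WM[1])
  }
})

test_that("synthesized DWI round-trips MD and is reproducible", {
  sp <- phantom_spec(shape = c(20, 20, 20), seed = 13)
  md <- image_volume(array(runif(20^3, 3e-4, 2e-3), c(20, 20, 20)),
                     sp$spacing_mm)
  brain <- array(TRUE, c(20, 20, 20))
  dwi <- synthesize_dwi(md, brain, snr = Inf, seed = 1)
  fit <- fit_tensor(dwi, brain)
  expect_lt(max(abs(fit$md$data - md$data)), 1e-9)

  n1 <- synthesize_dwi(md, brain, snr = 40, seed = 4)
  n2 <- synthesize_dwi(md, brain, snr = 40, seed = 4)
  expect_identical(n1$data, n2$data)
  n3 <- synthesize_dwi(md, brain, snr = 40, seed = 5)
  expect_false(identical(n1$data, n3$data))

  # MD = 0 voxels keep S = S0 in noiseless mode
  md0 <- image_volume(array(0, c(20, 20, 20)), sp$spacing_mm)
  d0 <- synthesize_dwi(md0, brain, snr = Inf, seed = 1)
  expect_equal(d0$data[, , , 2], d0$data[, , , 1])
})
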