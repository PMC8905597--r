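# hand-built single-atlas set on an arbitrary grid
tiny_atlas <- function(lab) {
  structure(list(parcellations = list(lab), names = "atlas01", n = 1L),
            class = "atlas_set")
}

test_that("atlas sets cover the brain, are deterministic, and have >= 20 regions", {
  sp <- phantom_spec(seed = 2)
  ph <- make_brain(sp)
  atl <- make_atlas_set(ph$tissues$brain, sp$spacing_mm, n_atlases = 6, seed = 1)
  expect_length(atl$parcellations, 6)
  for (p in atl$parcellations) {
    expect_true(all(p[ph$tissues$brain] > 0L))       # full coverage
    expect_true(all(p[!ph$tissues$brain] == 0L))     # label 0 outside
    expect_gte(max(p), 20L)
    counts <- tabulate(p[p > 0L])
    expect_true(all(counts[counts > 0] >= 10))       # small regions merged
  }
  atl2 <- make_atlas_set(ph$tissues$brain, sp$spacing_mm, n_atlases = 6, seed = 1)
  expect_identical(atl$parcellations, atl2$parcellations)
  expect_false(identical(
    atl$parcellations[[1]],
    make_atlas_set(ph$tissues$brain, sp$spacing_mm, 6, seed = 2)$parcellations[[1]]))
})

test_that("normative pooling reproduces hand-computed region statistics", {
  lab <- array(1L, c(3, 1, 1))
  md <- image_volume(array(c(0.7e-3, 0.8e-3, 0.9e-3), c(3, 1, 1)))
  tis <- tissue_masks(array(TRUE, c(3, 1, 1)), array(FALSE, c(3, 1, 1)))
  mod <- fit_normative(list(md), tis, tiny_atlas(lab))
  expect_equal(mod$stats[[1]]$mean[1], 0.8e-3)
  expect_equal(mod$stats[[1]]$sd[1], 1.0e-4)
  expect_equal(mod$stats[[1]]$n[1], 3L)

  # three identical controls: same mean, same sd (pooled values identical)
  mod3 <- fit_normative(list(md, md, md), tis, tiny_atlas(lab))
  expect_equal(mod3$stats[[1]]$mean[1], 0.8e-3)
  expect_equal(mod3$stats[[1]]$sd[1], sd(rep(c(0.7e-3, 0.8e-3, 0.9e-3), 3)))
  expect_equal(mod3$stats[[1]]$n[1], 9L)
})

test_that("CSF voxels never enter the normative pool", {
  lab <- array(1L, c(3, 1, 1))
  md <- image_volume(array(c(0.7e-3, 0.8e-3, 3e-3), c(3, 1, 1)))
  csf <- array(c(FALSE, FALSE, TRUE), c(3, 1, 1))
  tis <- tissue_masks(array(TRUE, c(3, 1, 1)), csf)
  mod <- fit_normative(list(md), tis, tiny_atlas(lab))
  expect_equal(mod$stats[[1]]$mean[1], 0.75e-3)
  expect_equal(mod$stats[[1]]$n[1], 2L)
})

test_that("fit_normative is permutation-invariant in control order", {
  sp <- small_spec(seed = 61)
  ctr <- make_controls(sp, 3)
  tis <- ctr[[1]]$tissues
  atl <- make_atlas_set(tis$brain, sp$spacing_mm, n_atlases = 3, seed = 5)
  m1 <- fit_normative(lapply(ctr, `[[`, "md"), tis, atl)
  m2 <- fit_normative(lapply(ctr[c(3, 1, 2)], `[[`, "md"), tis, atl)
  expect_equal(m1$stats, m2$stats)
})

test_that("z-scores are exact at the mean and at mean + 3 sd, with sd = 0 sentinel", {
  lab <- array(1L, c(4, 1, 1))
  md_ctrl <- image_volume(array(c(0.7e-3, 0.8e-3, 0.9e-3, 0.8e-3), c(4, 1, 1)))
  tis <- tissue_masks(array(TRUE, c(4, 1, 1)), array(FALSE, c(4, 1, 1)))
  atl <- tiny_atlas(lab)
  mod <- fit_normative(list(md_ctrl), tis, atl)
  mu <- mod$stats[[1]]$mean[1]; s <- mod$stats[[1]]$sd[1]
  subj <- image_volume(array(c(mu, mu + 3 * s, mu - 3 * s, mu + s), c(4, 1, 1)))
  z <- zscore_map(subj, atl, mod)[[1]]
  expect_equal(as.vector(z), c(0, 3, -3, 1))

  # all-identical controls: sd = 0, deviation triggers the infinite sentinel
  md_c <- image_volume(array(0.8e-3, c(4, 1, 1)))
  mod0 <- fit_normative(list(md_c), tis, atl)
  subj0 <- image_volume(array(c(0.8e-3, 0.9e-3, 0.7e-3, 0.8e-3), c(4, 1, 1)))
  z0 <- zscore_map(subj0, atl, mod0)[[1]]
  expect_equal(as.vector(z0), c(0, Inf, -Inf, 0))
})

test_that("normative model JSON round-trips", {
  sp <- small_spec(seed = 62)
  ctr <- make_controls(sp, 2)
  tis <- ctr[[1]]$tissues
  atl <- make_atlas_set(tis$brain, sp$spacing_mm, n_atlases = 2, seed = 5)
  mod <- fit_normative(lapply(ctr, `[[`, "md"), tis, atl)
  path <- tempfile(fileext = ".json")
  write_normative_json(mod, path)
  back <- read_normative_json(path)
  expect_equal(back$stats[[1]]$mean, mod$stats[[1]]$mean)
  expect_equal(back$stats[[2]]$sd, mod$stats[[2]]$sd)
  expect_equal(back$K, mod$K)
  unlink(path)
})

test_that("on lesion-free phantoms, single-atlas |z| > 3 fraction stays below 1%", {
  sp <- small_spec(seed = 71)
  ctr <- make_controls(sp, 3)
  tis <- ctr[[1]]$tissues
  atl <- make_atlas_set(tis$brain, sp$spacing_mm, n_atlases = 6, seed = 6)
  mod <- fit_normative(lapply(ctr, `[[`, "md"), tis, atl)
  for (s in 1:5) {
    sp_i <- sp; sp_i$seed <- 500L + s
    ph <- make_brain(sp_i)
    z <- zscore_map(ph$md, atl, mod)
    for (za in z) {
      frac <- sum(abs(za[tis$brain & !tis$csf]) > 3) / sum(tis$brain & !tis$csf)
      expect_lt(frac, 0.01)
    }
  }
})
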