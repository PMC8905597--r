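#' Specification of a digital TBI phantom
#'
#' Collects every tunable of the phantom generator: grid geometry, tissue MD
#' statistics, lesion counts, the multiplicative-coefficient ranges for
#' cellular (low-MD) and vasogenic (high-MD) edema, the Gaussian edge
#' smoothing width, and the target lesion load as a fraction of brain volume.
#'
#' Defaults state the simulated world: WM/GM/CSF mean diffusivities of
#' 0.75e-3 / 0.85e-3 / 3.0e-3 mm^2/s with spatial variability of about 4-7%,
#' lesion coefficients drawn uniformly from (0.41, 0.91) for low MD and
#' (1.10, 2.10) for high MD, 3 mm (FWHM) Gaussian edge smoothing, and a
#' lesion load of 2.2% of brain volume.
#'
#' @param shape grid shape, 3 positive integers (default 64^3).
#' @param spacing_mm voxel spacing in mm (default 1 mm isotropic).
#' @param tissue_md named list `WM`, `GM`, `CSF`, each `c(mean, sd)` in
#'   mm^2/s.
#' @param n_lesions_low,n_lesions_high number of lesions per class.
#' @param coeff_low_range,coeff_high_range multiplicative coefficient ranges;
#'   low must lie in (0,1), high in (1, Inf).
#' @param smoothing_fwhm_mm Gaussian edge filter width, mm.
#' @param smoothing_width_is `"fwhm"` (default) or `"hwhm"`: how
#'   `smoothing_fwhm_mm` is interpreted when converting to the Gaussian sigma.
#' @param target_lesion_fraction total ground-truth lesion volume as a
#'   fraction of brain volume, in \[0, 0.2\].
#' @param low_volume_share fraction of the lesion load assigned to the
#'   low-MD class (vasogenic edema dominates the load in trauma).
#' @param field_corr_mm correlation length (FWHM) of the smooth spatial MD
#'   variation, mm (>= 4).
#' @param seed integer root seed; generation is a pure function of
#'   (spec, seed).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 64),
                         spacing_mm = c(1, 1, 1),
                         tissue_md = list(WM = c(0.75e-3, 0.03e-3),
                                          GM = c(0.85e-3, 0.04e-3),
                                          CSF = c(3.0e-3, 0.2e-3)),
                         n_lesions_low = 1L,
                         n_lesions_high = 2L,
                         coeff_low_range = c(0.41, 0.91),
                         coeff_high_range = c(1.10, 2.10),
                         smoothing_fwhm_mm = 3.0,
                         smoothing_width_is = c("fwhm", "hwhm"),
                         target_lesion_fraction = 0.022,
                         low_volume_share = 0.3,
                         field_corr_mm = 6,
                         seed = 1L) {
  smoothing_width_is <- match.arg(smoothing_width_is)
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape > 0), length(spacing_mm) == 3L,
            all(spacing_mm > 0))
  if (!(coeff_low_range[1] > 0 && coeff_low_range[2] < 1 &&
        coeff_low_range[1] <= coeff_low_range[2]))
    stop_mdaqp("coeff_low_range must lie inside (0, 1)")
  if (!(coeff_high_range[1] > 1 && coeff_high_range[1] <= coeff_high_range[2]))
    stop_mdaqp("coeff_high_range must lie inside (1, Inf)")
  if (!(smoothing_fwhm_mm > 0)) stop_mdaqp("smoothing_fwhm_mm must be > 0")
  if (target_lesion_fraction < 0 || target_lesion_fraction > 0.2)
    stop_mdaqp("target_lesion_fraction must be in [0, 0.2]")
  stopifnot(all(c("WM", "GM", "CSF") %in% names(tissue_md)))
  structure(list(shape = shape, spacing_mm = as.numeric(spacing_mm),
                 tissue_md = tissue_md,
                 n_lesions_low = as.integer(n_lesions_low),
                 n_lesions_high = as.integer(n_lesions_high),
                 coeff_low_range = coeff_low_range,
                 coeff_high_range = coeff_high_range,
                 smoothing_fwhm_mm = smoothing_fwhm_mm,
                 smoothing_width_is = smoothing_width_is,
                 target_lesion_fraction = target_lesion_fraction,
                 low_volume_share = low_volume_share,
                 field_corr_mm = field_corr_mm,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

lesion_sigma_mm <- function(spec) {
  w <- spec$smoothing_fwhm_mm
  if (spec$smoothing_width_is == "hwhm") w <- 2 * w
  w * FWHM_TO_SIGMA
}

# Ellipsoid indicator on the voxel grid; centre and semi-axes in mm
# (grid coordinates: (index - 1) * spacing).
ellipsoid_mask <- function(shape, spacing_mm, centre_mm, semi_mm) {
  x <- ((seq_len(shape[1]) - 1) * spacing_mm[1] - centre_mm[1]) / semi_mm[1]
  y <- ((seq_len(shape[2]) - 1) * spacing_mm[2] - centre_mm[2]) / semi_mm[2]
  z <- ((seq_len(shape[3]) - 1) * spacing_mm[3] - centre_mm[3]) / semi_mm[3]
  r2 <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  r2 <= 1
}

#' Generate a lesion-free brain-shaped MD map
#'
#' Builds an ellipsoidal brain with a cortical GM shell, a WM interior and two
#' ellipsoidal lateral ventricles labelled CSF. MD is drawn per tissue as
#' mean + sd x (smooth Gaussian random field + white noise), mixing the two
#' noise sources 0.8/0.6 so the total per-voxel standard deviation equals the
#' tissue sd. The smooth field mimics slowly varying biological/coil
#' variation; the white part mimics measurement noise.
#'
#' @param spec a [phantom_spec].
#' @return A list with `md` ([image_volume]), `tissues` ([tissue_masks]) and
#'   `tissue_labels` (integer array: 0 outside, 1 WM, 2 GM, 3 CSF).
#' @export
make_brain <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  extent <- spec$shape * spec$spacing_mm
  if (any(extent < 24))
    stop_mdaqp("grid extent %s mm too small to contain ventricles (need >= 24 mm per axis)",
               paste(round(extent), collapse = "x"))
  centre <- (spec$shape - 1) / 2 * spec$spacing_mm
  semi_brain <- 0.45 * extent
  brain <- ellipsoid_mask(spec$shape, spec$spacing_mm, centre, semi_brain)
  inner <- ellipsoid_mask(spec$shape, spec$spacing_mm, centre, 0.88 * semi_brain)
  sc <- extent / 64   # ventricle geometry scales with the grid
  vent_l <- ellipsoid_mask(spec$shape, spec$spacing_mm,
                           centre + c(-7, 0, 2) * sc, c(4, 11, 5) * sc)
  vent_r <- ellipsoid_mask(spec$shape, spec$spacing_mm,
                           centre + c(7, 0, 2) * sc, c(4, 11, 5) * sc)
  csf <- (vent_l | vent_r) & inner
  labels <- array(0L, spec$shape)
  labels[brain] <- 2L           # GM shell by default
  labels[inner] <- 1L           # WM interior
  labels[csf] <- 3L

  md <- array(0, spec$shape)
  means <- c(spec$tissue_md$WM[1], spec$tissue_md$GM[1], spec$tissue_md$CSF[1])
  sds <- c(spec$tissue_md$WM[2], spec$tissue_md$GM[2], spec$tissue_md$CSF[2])
  sigma_field <- spec$field_corr_mm * FWHM_TO_SIGMA
  with_seed(derive_seed(spec$seed, "brain-field"), {
    G <- smooth_gaussian(array(rnorm(prod(spec$shape)), spec$shape),
                         sigma_field, spec$spacing_mm, renormalize = TRUE)
    G <- (G - mean(G[brain])) / sd(G[brain])
    W <- array(rnorm(prod(spec$shape)), spec$shape)
    inb <- which(labels > 0L)
    t <- labels[inb]
    md[inb] <- means[t] + sds[t] * (0.8 * G[inb] + 0.6 * W[inb])
  })
  md <- pmax(md, 1e-5 * min(means))   # diffusivity is physically positive
  md <- array(md, spec$shape)
  list(md = image_volume(md, spacing_mm = spec$spacing_mm),
       tissues = tissue_masks(brain, csf, spec$spacing_mm),
       tissue_labels = labels)
}

# Sample one voxel index uniformly from a logical mask.
sample_voxel <- function(mask) {
  idx <- which(mask)
  if (length(idx) == 0L) return(NA_integer_)
  idx[sample.int(length(idx), 1L)]
}

sphere_at <- function(shape, spacing_mm, centre_idx, radius_mm) {
  ci <- arrayInd(centre_idx, shape)
  ellipsoid_mask(shape, spacing_mm, (as.numeric(ci) - 1) * spacing_mm,
                 rep(radius_mm, 3))
}

#' Insert low- and high-MD lesions into an MD map
#'
#' Implements the lesion insertion protocol: each lesion is a blob-shaped
#' support (union of random spheres) placed in parenchyma away from CSF; a
#' multiplicative coefficient is drawn uniformly from the class range (low-MD
#' in (0.41, 0.91), high-MD in (1.10, 2.10)); the binary support is smoothed
#' with a 3 mm (FWHM) Gaussian and rescaled to peak 1, giving a weight map w;
#' the map becomes MD x (1 + w (c - 1)). Only the MD map is modified — the
#' tissue masks are untouched. The ground-truth mask of a lesion is its
#' w >= 0.5 core, and total core volume is driven toward
#' `target_lesion_fraction` x brain volume.
#'
#' @param md an [image_volume] MD map (from [make_brain] or real data).
#' @param tissues the matching [tissue_masks].
#' @param spec a [phantom_spec]; lesion counts, coefficient ranges, smoothing
#'   and lesion load are read from it.
#' @param seed integer; defaults to `spec$seed`.
#' @return A list with `md` (lesioned [image_volume]) and `gt`, an object of
#'   class `ground_truth` holding `low_mask`, `high_mask` (disjoint, CSF-free)
#'   and a per-lesion tibble `lesions` (id, class, coefficient, volume_ml,
#'   centroid in mm).
#' @export
insert_lesions <- function(md, tissues, spec, seed = spec$seed) {
  stopifnot(inherits(md, "image_volume"), inherits(tissues, "tissue_masks"),
            inherits(spec, "phantom_spec"))
  shape <- md$shape
  sp <- md$spacing_mm
  brain <- tissues$brain
  csf <- tissues$csf
  voxvol <- voxel_volume_mm3(sp)
  d_csf <- distance_to_mm(csf, sp)
  d_out <- distance_to_mm(!brain, sp)
  # parenchymal placement: supports keep clear of CSF (so cores survive the
  # detector's 3 mm CSF margin) and of the brain edge
  paren <- brain & d_csf > 4 & d_out > 2
  seedable <- brain & d_csf > 6 & d_out > 4

  n_low <- spec$n_lesions_low
  n_high <- spec$n_lesions_high
  n_tot <- n_low + n_high
  target_total_mm3 <- spec$target_lesion_fraction * sum(brain) * voxvol
  share_low <- if (n_low > 0 && n_high > 0) spec$low_volume_share
               else if (n_low > 0) 1 else 0
  per_target <- c(rep(share_low * target_total_mm3 / max(n_low, 1L), n_low),
                  rep((1 - share_low) * target_total_mm3 / max(n_high, 1L), n_high))
  classes <- c(rep("low", n_low), rep("high", n_high))

  sigma <- lesion_sigma_mm(spec)
  md_out <- md$data
  occupied <- array(FALSE, shape)     # dilated union of all supports so far
  low_mask <- array(FALSE, shape)
  high_mask <- array(FALSE, shape)
  records <- list()

  with_seed(derive_seed(seed, "lesions"), {
    for (li in seq_len(n_tot)) {
      cls <- classes[li]
      target_mm3 <- per_target[li]
      target_vox <- target_mm3 / voxvol
      r1 <- min(10, max(3, (3 * target_mm3 / (4 * pi))^(1 / 3)))
      support <- NULL
      for (try in seq_len(200L)) {
        c0 <- sample_voxel(seedable & !occupied)
        if (is.na(c0)) next
        cand <- sphere_at(shape, sp, c0, r1) & paren & !occupied
        if (sum(cand) >= 0.3 * target_vox) { support <- cand; break }
      }
      if (is.null(support))
        stop_mdaqp("cannot place disjoint lesion %d (%s) after 200 retries; %d free parenchymal voxels",
                   li, cls, sum(paren & !occupied))
      # grow with satellite spheres until the smoothed core reaches target
      core <- NULL
      for (round in seq_len(12L)) {
        w <- smooth_gaussian(support * 1.0, sigma, sp)
        w <- w / max(w)
        core <- w >= 0.5
        if (sum(core) >= target_vox || round == 12L) break
        c1 <- sample_voxel(border_mask(support))
        if (is.na(c1)) break
        rs <- runif(1, 0.4, 0.8) * r1
        add <- sphere_at(shape, sp, c1, rs) & paren & !occupied
        support <- support | add
      }
      coeff <- if (cls == "low") runif(1, spec$coeff_low_range[1], spec$coeff_low_range[2])
               else runif(1, spec$coeff_high_range[1], spec$coeff_high_range[2])
      md_out <- md_out * (1 + w * (coeff - 1))
      if (cls == "low") low_mask <- low_mask | core else high_mask <- high_mask | core
      occupied <- occupied | dilate_ball(support, sp, 4)
      records[[li]] <- tibble(
        id = li, class = cls, coefficient = coeff,
        volume_ml = sum(core) * voxvol / 1000,
        centroid_x_mm = mask_centroid_mm(core, sp)[1],
        centroid_y_mm = mask_centroid_mm(core, sp)[2],
        centroid_z_mm = mask_centroid_mm(core, sp)[3])
    }
  })

  stopifnot(!any(low_mask & high_mask), !any(low_mask & csf),
            !any(high_mask & csf), all(brain[low_mask | high_mask]))
  lesions <- if (length(records) > 0) do.call(rbind, records)
             else tibble(id = integer(), class = character(),
                         coefficient = numeric(), volume_ml = numeric(),
                         centroid_x_mm = numeric(), centroid_y_mm = numeric(),
                         centroid_z_mm = numeric())
  gt <- structure(list(low_mask = low_mask, high_mask = high_mask,
                       lesions = lesions, spacing_mm = sp),
                  class = "ground_truth")
  list(md = image_volume(array(md_out, shape), spacing_mm = sp), gt = gt)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth: %d lesion(s), low %.2f ml, high %.2f ml>\n",
              nrow(x$lesions), mask_volume_ml(x$low_mask, x$spacing_mm),
              mask_volume_ml(x$high_mask, x$spacing_mm)))
  invisible(x)
}

#' Generate a cohort of lesion-free control brains
#'
#' Controls share the spec's geometry (identical brain/CSF masks) but have
#' independent smooth-field and white-noise draws plus a global MD scale
#' jitter of +/- `scale_pct` percent, emulating inter-subject and
#' inter-acquisition variability.
#'
#' @param spec a [phantom_spec].
#' @param n number of controls (>= 1).
#' @param scale_pct half-width of the uniform global scale jitter, percent
#'   (default 3; 0 disables it).
#' @param seeds optional integer vector of per-control seeds; defaults to
#'   `spec$seed + 0:(n-1)` so `n = 1` with `scale_pct = 0` reproduces
#'   [make_brain] exactly.
#' @return A list of `n` elements, each as returned by [make_brain] with an
#'   added `scale` element.
#' @export
make_controls <- function(spec, n, scale_pct = 3, seeds = NULL) {
  stopifnot(inherits(spec, "phantom_spec"), n >= 1)
  seeds <- seeds %||% (spec$seed + seq_len(n) - 1L)
  stopifnot(length(seeds) == n)
  lapply(seq_len(n), function(i) {
    sp_i <- spec
    sp_i$seed <- as.integer(seeds[i])
    ph <- make_brain(sp_i)
    scale <- if (scale_pct > 0)
      with_seed(derive_seed(seeds[i], "control-scale"),
                runif(1, 1 - scale_pct / 100, 1 + scale_pct / 100))
    else 1
    ph$md <- image_volume(ph$md$data * scale, spacing_mm = spec$spacing_mm)
    ph$scale <- scale
    ph
  })
}

# Deterministic roughly-uniform unit directions (golden-angle spiral); the
# first 6 are the classic icosahedral-pair scheme used in clinical DTI.
dti_directions <- function(n_dirs) {
  base <- cbind(c(1, 1, 0), c(1, -1, 0), c(1, 0, 1),
                c(1, 0, -1), c(0, 1, 1), c(0, 1, -1)) / sqrt(2)
  if (n_dirs <= 6L) return(base[, seq_len(n_dirs), drop = FALSE])
  k <- seq_len(n_dirs - 6L)
  zc <- 1 - 2 * (k - 0.5) / (n_dirs - 6L)
  th <- k * pi * (3 - sqrt(5))
  extra <- rbind(sqrt(1 - zc^2) * cos(th), sqrt(1 - zc^2) * sin(th), zc)
  cbind(base, extra)
}

#' Synthesize a DWI acquisition from an MD map
#'
#' Treats each voxel as isotropic with diffusivity MD, so the signal is
#' S = S0 exp(-b MD) for every direction, plus Rician noise at the requested
#' SNR (sigma = S0 / SNR). S0 is constant inside the brain and 0 outside, so
#' the background holds pure noise. One b = 0 volume is prepended. Lets the
#' tensor-fitting module be tested end to end: a noiseless round trip must
#' return MD exactly.
#'
#' @param md an [image_volume] MD map.
#' @param brain logical brain mask.
#' @param b b-value, s/mm^2 (> 0).
#' @param n_dirs number of gradient directions (>= 6).
#' @param snr signal-to-noise ratio; `Inf` for noiseless.
#' @param seed integer seed for the noise draw.
#' @param s0 baseline signal amplitude (default 1000).
#' @return A [dwi_set] with `n_dirs + 1` volumes.
#' @export
synthesize_dwi <- function(md, brain, b = 1000, n_dirs = 6, snr = Inf,
                           seed = 1L, s0 = 1000) {
  stopifnot(inherits(md, "image_volume"), is_logical_grid(brain))
  if (!(b > 0)) stop_mdaqp("b must be > 0")
  if (n_dirs < 6L) stop_mdaqp("need n_dirs >= 6 for tensor fitting")
  if (!(snr > 0)) stop_mdaqp("snr must be > 0 (use Inf for noiseless)")
  shape <- md$shape
  S0 <- array(0, shape); S0[brain] <- s0
  att <- exp(-b * md$data)
  nvol <- n_dirs + 1L
  data <- array(0, c(shape, nvol))
  data[, , , 1L] <- S0
  for (j in seq_len(n_dirs)) data[, , , j + 1L] <- S0 * att
  if (is.finite(snr)) {
    sigma <- s0 / snr
    with_seed(derive_seed(seed, "dwi-noise"), {
      n <- length(data)
      data <- sqrt((data + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
      data <- array(data, c(shape, nvol))
    })
  }
  dwi_set(data, bvals = c(0, rep(b, n_dirs)),
          bvecs = cbind(c(0, 0, 0), dti_directions(n_dirs)),
          spacing_mm = md$spacing_mm)
}
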