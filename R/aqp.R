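#' Detector configuration
#'
#' Parameters of the atlas-vote lesion detector. Defaults: abnormality in at least 4 of 6 parcellations,
#' minimum lesion sizes of 0.12 ml (low MD) and 0.16 ml (high MD), and
#' exclusion of high-MD voxels closer than 3 mm to CSF (partial-volume
#' guard). The z threshold formalising "outside the normal range" defaults
#' to 3.
#'
#' @param z_threshold z cutoff per atlas/region (default 3).
#' @param K vote threshold, number of atlases that must agree (default 4).
#' @param min_low_ml minimum low-MD lesion volume, ml (default 0.12).
#' @param min_high_ml minimum high-MD lesion volume, ml (default 0.16).
#' @param csf_margin_mm high-MD voxels strictly closer than this to CSF are
#'   discarded (default 3 mm).
#' @param connectivity component connectivity, 6/18/26 (default 26).
#' @return A list of class `aqp_config`.
#' @export
aqp_config <- function(z_threshold = 3, K = 4, min_low_ml = 0.12,
                       min_high_ml = 0.16, csf_margin_mm = 3,
                       connectivity = 26) {
  stopifnot(z_threshold > 0, K >= 1, min_low_ml > 0, min_high_ml > 0,
            csf_margin_mm >= 0, connectivity %in% c(6, 18, 26))
  structure(list(z_threshold = z_threshold, K = as.integer(K),
                 min_low_ml = min_low_ml, min_high_ml = min_high_ml,
                 csf_margin_mm = csf_margin_mm,
                 connectivity = as.integer(connectivity)),
            class = "aqp_config")
}

#' Count abnormality votes across atlases
#'
#' A voxel receives a low vote from every atlas whose z-score falls below
#' `-z_threshold` and a high vote from every atlas above `+z_threshold`.
#' Votes are zeroed outside the brain mask.
#'
#' @param z_maps list of per-atlas z-score arrays (from [zscore_map]).
#' @param z_threshold z cutoff (> 0).
#' @param brain logical brain mask.
#' @return A list of class `vote_map` with integer arrays `votes_low`,
#'   `votes_high` and the atlas count `N`.
#' @export
vote <- function(z_maps, z_threshold, brain) {
  stopifnot(length(z_maps) >= 1, is_logical_grid(brain))
  dims <- dim(z_maps[[1]])
  votes_low <- array(0L, dims)
  votes_high <- array(0L, dims)
  for (z in z_maps) {
    votes_low <- votes_low + (z < -z_threshold)
    votes_high <- votes_high + (z > z_threshold)
  }
  votes_low[!brain] <- 0L
  votes_high[!brain] <- 0L
  structure(list(votes_low = votes_low, votes_high = votes_high,
                 N = length(z_maps)),
            class = "vote_map")
}

#' Classify voxels from the vote map
#'
#' A voxel is low-abnormal when it collected at least `K` low votes and
#' strictly more low than high votes; symmetrically for high. Ties (possible
#' only when `K <= N/2`) are discarded: a voxel that cannot be typed is not
#' reported.
#'
#' @param votes a `vote_map` from [vote()].
#' @param K vote threshold, `1 <= K <= N`.
#' @return List with logical arrays `low_raw`, `high_raw`.
#' @export
classify_voxels <- function(votes, K) {
  stopifnot(inherits(votes, "vote_map"), K >= 1, K <= votes$N)
  low_raw <- votes$votes_low >= K & votes$votes_low > votes$votes_high
  high_raw <- votes$votes_high >= K & votes$votes_high > votes$votes_low
  list(low_raw = low_raw, high_raw = high_raw)
}

#' CSF and partial-volume exclusions
#'
#' Both classes lose voxels inside the CSF/ventricle mask. High-MD voxels
#' additionally lose any voxel whose Euclidean distance (spacing-aware, in
#' mm) to the nearest CSF voxel is strictly less than `csf_margin_mm` — the
#' partial-volume guard: CSF bleeding into neighbouring parenchyma mimics
#' vasogenic edema. Low-MD voxels near CSF are kept.
#'
#' @param low_raw,high_raw logical arrays from [classify_voxels].
#' @param tissues [tissue_masks].
#' @param spacing_mm voxel spacing, mm.
#' @param csf_margin_mm margin (default 3); 0 disables the distance rule.
#' @return List with logical arrays `low`, `high`.
#' @export
apply_exclusions <- function(low_raw, high_raw, tissues, spacing_mm,
                             csf_margin_mm = 3) {
  stopifnot(inherits(tissues, "tissue_masks"), csf_margin_mm >= 0)
  low <- low_raw & tissues$brain & !tissues$csf
  high <- high_raw & tissues$brain & !tissues$csf
  if (csf_margin_mm > 0 && any(tissues$csf) && any(high)) {
    d <- distance_to_mm(tissues$csf, spacing_mm)
    high <- high & !(d < csf_margin_mm - 1e-9)   # strict: exactly 3 mm is kept
  }
  list(low = low, high = high)
}

#' Minimum-size filtering of connected components
#'
#' Removes connected components smaller than `min_volume_ml`; the threshold
#' is inclusive (a component exactly at the minimum is kept).
#'
#' @param mask logical array.
#' @param spacing_mm voxel spacing, mm.
#' @param min_volume_ml minimum component volume, ml (> 0).
#' @param connectivity 6/18/26 (default 26).
#' @return List with `mask` (filtered) and `components`, a tibble with one
#'   row per retained component: `component`, `n_voxels`, `volume_ml`,
#'   `centroid_x_mm`, `centroid_y_mm`, `centroid_z_mm`.
#' @export
filter_components <- function(mask, spacing_mm, min_volume_ml,
                              connectivity = 26) {
  stopifnot(is_logical_grid(mask), min_volume_ml > 0)
  voxvol <- voxel_volume_mm3(spacing_mm)
  lab <- label_components(mask, connectivity)
  if (lab$n == 0L)
    return(list(mask = mask,
                components = tibble(component = integer(), n_voxels = integer(),
                                    volume_ml = numeric(), centroid_x_mm = numeric(),
                                    centroid_y_mm = numeric(), centroid_z_mm = numeric())))
  counts <- tabulate(lab$labels[lab$labels > 0L], nbins = lab$n)
  vols <- counts * voxvol / 1000
  keep <- which(vols >= min_volume_ml)
  out <- array(FALSE, dim(mask))
  rows <- lapply(seq_along(keep), function(i) {
    sel <- lab$labels == keep[i]
    out[sel] <<- TRUE
    cen <- mask_centroid_mm(sel, spacing_mm)
    tibble(component = i, n_voxels = counts[keep[i]],
           volume_ml = vols[keep[i]],
           centroid_x_mm = cen[1], centroid_y_mm = cen[2], centroid_z_mm = cen[3])
  })
  comps <- if (length(rows) > 0) do.call(rbind, rows)
           else tibble(component = integer(), n_voxels = integer(),
                       volume_ml = numeric(), centroid_x_mm = numeric(),
                       centroid_y_mm = numeric(), centroid_z_mm = numeric())
  list(mask = out, components = comps)
}

#' Run the full lesion detector
#'
#' The complete pipeline on one subject: per-atlas z-scores against the
#' normative model, abnormality voting, voxel typing, CSF/partial-volume
#' exclusions, then per-class minimum-size filtering (low 0.12 ml, high
#' 0.16 ml by default). Volumes are reported in ml and as a percentage of
#' the brain-mask volume, which stands in for the supratentorial volume in
#' the synthetic setting (a supratentorial mask may be passed for real data).
#'
#' @param md [image_volume] MD map of the subject.
#' @param tissues [tissue_masks].
#' @param atlases `atlas_set` (see [make_atlas_set()]).
#' @param model `normative_model` (see [fit_normative()]).
#' @param config [aqp_config].
#' @param supratentorial optional logical mask used as the denominator of the
#'   brain-fraction percentage; defaults to the brain mask.
#' @return An object of class `lesion_result`: disjoint logical masks
#'   `low_mask`, `high_mask`, a per-lesion tibble `components` (with `class`
#'   column), `volume_low_ml`, `volume_high_ml`, `volume_total_ml`,
#'   `brain_fraction_pct`, and the `config` used.
#' @export
#' @examples
#' sp <- phantom_spec(shape = c(48, 48, 48), seed = 3)
#' ctr <- make_controls(sp, 3)
#' ph <- make_brain(sp)
#' les <- insert_lesions(ph$md, ph$tissues, sp)
#' atl <- make_atlas_set(ph$tissues$brain, sp$spacing_mm, seed = 1)
#' mod <- fit_normative(ctr, ph$tissues, atl)
#' res <- run_aqp(les$md, ph$tissues, atl, mod)
#' res$volume_total_ml
run_aqp <- function(md, tissues, atlases, model, config = aqp_config(),
                    supratentorial = NULL) {
  stopifnot(inherits(md, "image_volume"), inherits(tissues, "tissue_masks"),
            inherits(config, "aqp_config"))
  if (!identical(md$shape, dim(tissues$brain)))
    stop_mdaqp("MD map and tissue masks differ in shape")
  K <- min(config$K, model$N)

  z <- zscore_map(md, atlases, model)
  v <- vote(z, config$z_threshold, tissues$brain)
  cls <- classify_voxels(v, K)
  excl <- apply_exclusions(cls$low_raw, cls$high_raw, tissues, md$spacing_mm,
                           config$csf_margin_mm)
  flow <- filter_components(excl$low, md$spacing_mm, config$min_low_ml,
                            config$connectivity)
  fhigh <- filter_components(excl$high, md$spacing_mm, config$min_high_ml,
                             config$connectivity)

  comp_low <- flow$components
  comp_high <- fhigh$components
  if (nrow(comp_low) > 0) comp_low <- cbind(tibble(class = "low"), comp_low)
  if (nrow(comp_high) > 0) comp_high <- cbind(tibble(class = "high"), comp_high)
  components <- rbind(
    if (nrow(comp_low) > 0) comp_low else NULL,
    if (nrow(comp_high) > 0) comp_high else NULL)
  if (is.null(components))
    components <- tibble(class = character(), component = integer(),
                         n_voxels = integer(), volume_ml = numeric(),
                         centroid_x_mm = numeric(), centroid_y_mm = numeric(),
                         centroid_z_mm = numeric())

  denom <- supratentorial %||% tissues$brain
  vol_low <- mask_volume_ml(flow$mask, md$spacing_mm)
  vol_high <- mask_volume_ml(fhigh$mask, md$spacing_mm)
  brain_ml <- mask_volume_ml(denom, md$spacing_mm)
  structure(list(low_mask = flow$mask, high_mask = fhigh$mask,
                 components = as_tibble(components),
                 volume_low_ml = vol_low, volume_high_ml = vol_high,
                 volume_total_ml = vol_low + vol_high,
                 brain_volume_ml = brain_ml,
                 brain_fraction_pct = 100 * (vol_low + vol_high) / brain_ml,
                 spacing_mm = md$spacing_mm,
                 config = config),
            class = "lesion_result")
}

#' @export
print.lesion_result <- function(x, ...) {
  cat(sprintf(paste0("<lesion_result: %d component(s); low %.2f ml, high %.2f ml, ",
                     "total %.2f ml (%.2f%% of brain)>\n"),
              nrow(x$components), x$volume_low_ml, x$volume_high_ml,
              x$volume_total_ml, x$brain_fraction_pct))
  invisible(x)
}

#' @export
#' @rdname run_aqp
#' @param x a `lesion_result`.
#' @param ... unused.
tidy.lesion_result <- function(x, ...) x$components

#' @export
#' @rdname run_aqp
glance.lesion_result <- function(x, ...) {
  tibble(volume_low_ml = x$volume_low_ml, volume_high_ml = x$volume_high_ml,
         volume_total_ml = x$volume_total_ml,
         brain_volume_ml = x$brain_volume_ml,
         brain_fraction_pct = x$brain_fraction_pct,
         n_components = nrow(x$components))
}
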