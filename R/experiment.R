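#' Configuration of the phantom validation experiment
#'
#' Bundles everything [run_phantom_experiment] needs: the phantom spec, the
#' cohort sizes (5 lesioned phantoms, 3 controls by default), the detector
#' parameters, the simulated-rater panel and one root seed from which every
#' stochastic stage derives its own named substream.
#'
#' @param spec a [phantom_spec]; its `seed` is ignored in favour of `seed`.
#' @param n_phantoms number of lesioned phantom cases (default 5).
#' @param n_controls number of lesion-free controls (default 3).
#' @param aqp an [aqp_config].
#' @param n_atlases number of stand-in parcellations (default 6).
#' @param include_raters simulate a rater panel and fuse it with STAPLE?
#' @param n_raters panel size (default 5).
#' @param rater_model see [simulate_raters].
#' @param seed integer root seed.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(spec = phantom_spec(), n_phantoms = 5,
                              n_controls = 3, aqp = aqp_config(),
                              n_atlases = 6, include_raters = TRUE,
                              n_raters = 5, rater_model = rater_error_model(),
                              seed = 20240101) {
  stopifnot(inherits(spec, "phantom_spec"), n_phantoms >= 1, n_controls >= 1,
            inherits(aqp, "aqp_config"))
  structure(list(spec = spec, n_phantoms = as.integer(n_phantoms),
                 n_controls = as.integer(n_controls), aqp = aqp,
                 n_atlases = as.integer(n_atlases),
                 include_raters = include_raters,
                 n_raters = as.integer(n_raters), rater_model = rater_model,
                 seed = as.integer(seed %% 2147483647)),
            class = "experiment_config")
}

#' Error model of a simulated expert rater
#'
#' @param jitter_fwhm_mm width of the boundary smoothing that blurs lesion
#'   edges before thresholding, mm.
#' @param dice_band target band for each rater's pooled Dice against ground
#'   truth; the noise amplitude is calibrated per rater to land inside it
#'   (default 0.70-0.80, the range expert neuroradiologists typically reach
#'   on trauma lesions).
#' @param miss_rate probability that a rater misses a whole small lesion
#'   (below `miss_max_ml`); experts overlook small foci, not large edema.
#' @param miss_max_ml size cap for missable lesions, ml.
#' @param false_blob_rate probability that a rater adds a false component.
#' @return A list of class `rater_error_model`.
#' @export
rater_error_model <- function(jitter_fwhm_mm = 2, dice_band = c(0.70, 0.80),
                              miss_rate = 0.1, false_blob_rate = 0.1,
                              miss_max_ml = 0.5) {
  stopifnot(jitter_fwhm_mm >= 0, length(dice_band) == 2,
            dice_band[1] <= dice_band[2])
  structure(list(jitter_fwhm_mm = jitter_fwhm_mm, dice_band = dice_band,
                 miss_rate = miss_rate, false_blob_rate = false_blob_rate,
                 miss_max_ml = miss_max_ml),
            class = "rater_error_model")
}

# one perturbed copy of (low, high) masks for a given noise amplitude
perturb_rater <- function(gt_low, gt_high, amp, sigma_mm, spacing_mm, field,
                          allowed) {
  th <- function(m) {
    u <- smooth_gaussian(m * 1.0, sigma_mm, spacing_mm) + amp * field
    out <- u >= 0.5
    out & allowed
  }
  list(low = th(gt_low), high = th(gt_high))
}

#' Simulate a panel of expert raters
#'
#' Each simulated rater is the ground truth degraded by three error sources:
#' boundary jitter (the lesion indicator is blurred and re-thresholded after
#' adding a smooth noise field whose amplitude is calibrated so the rater's
#' pooled Dice against ground truth falls in `model$dice_band`), whole-lesion
#' misses, and occasional false components. With a zero error model the
#' raters equal the ground truth exactly.
#'
#' @param gt a `ground_truth` (from [insert_lesions]).
#' @param tissues [tissue_masks] (raters only draw inside brain, outside CSF).
#' @param n_raters panel size.
#' @param model a [rater_error_model].
#' @param seed integer seed.
#' @return An object of class `rater_set`: `raters` (list of per-rater lists
#'   with `low`, `high`, `pooled` masks), `dice` (calibrated pooled Dice per
#'   rater), `amplitudes`.
#' @export
simulate_raters <- function(gt, tissues, n_raters = 5,
                            model = rater_error_model(), seed = 1L) {
  stopifnot(inherits(gt, "ground_truth"), inherits(tissues, "tissue_masks"),
            n_raters >= 1)
  sp <- gt$spacing_mm
  allowed <- tissues$brain & !tissues$csf
  zero_model <- model$jitter_fwhm_mm == 0 && model$miss_rate == 0 &&
    model$false_blob_rate == 0
  if (zero_model) {
    raters <- replicate(n_raters, list(low = gt$low_mask, high = gt$high_mask,
                                       pooled = gt$low_mask | gt$high_mask),
                        simplify = FALSE)
    return(structure(list(raters = raters, dice = rep(1, n_raters),
                          amplitudes = rep(0, n_raters)),
                     class = "rater_set"))
  }
  sigma <- model$jitter_fwhm_mm * FWHM_TO_SIGMA
  gt_pool <- gt$low_mask | gt$high_mask
  shape <- dim(gt_pool)
  d_gt <- distance_to_mm(gt_pool, sp)
  raters <- vector("list", n_raters)
  dice_out <- numeric(n_raters)
  amps <- numeric(n_raters)
  for (j in seq_len(n_raters)) {
    with_seed(derive_seed(seed, "rater", j), {
      # per-rater reading of the lesions: misses and false components
      low_j <- gt$low_mask; high_j <- gt$high_mask
      for (li in seq_len(nrow(gt$lesions))) {
        if (gt$lesions$volume_ml[li] < model$miss_max_ml &&
            runif(1) < model$miss_rate) {
          rec <- gt$lesions[li, ]
          cen_idx <- round(c(rec$centroid_x_mm, rec$centroid_y_mm,
                             rec$centroid_z_mm) / sp) + 1
          comp <- label_components(if (rec$class == "low") gt$low_mask else gt$high_mask)
          lab_at <- comp$labels[cen_idx[1], cen_idx[2], cen_idx[3]]
          if (lab_at > 0) {
            drop <- comp$labels == lab_at
            if (rec$class == "low") low_j <- low_j & !drop
            else high_j <- high_j & !drop
          }
        }
      }
      if (runif(1) < model$false_blob_rate) {
        far <- allowed & d_gt > 10
        c0 <- sample_voxel(far)
        if (!is.na(c0)) {
          blob <- sphere_at(shape, sp, c0, runif(1, 3, 5)) & allowed
          if (runif(1) < 0.5) low_j <- low_j | blob else high_j <- high_j | blob
        }
      }
      field <- smooth_gaussian(array(rnorm(prod(shape)), shape), 2 * sigma, sp,
                               renormalize = TRUE)
      field <- field / sd(field)
      # calibrate the jitter amplitude to the target Dice band
      band <- model$dice_band
      dice_of <- function(a) {
        r <- perturb_rater(low_j, high_j, a, sigma, sp, field, allowed)
        overlap_metrics(r$low | r$high, gt_pool)$dice
      }
      lo <- 0; hi <- 0.45
      d_lo <- dice_of(lo)
      if (d_lo < band[1])
        stop_mdaqp("rater %d: Dice %.2f at zero jitter already below band [%g, %g]",
                   j, d_lo, band[1], band[2])
      a <- if (d_lo <= band[2]) lo else {
        while (dice_of(hi) > band[2] && hi < 3) hi <- hi * 1.6
        for (it in 1:25) {
          mid <- (lo + hi) / 2
          dm <- dice_of(mid)
          if (dm >= band[1] && dm <= band[2]) { lo <- mid; break }
          if (dm > band[2]) lo <- mid else hi <- mid
        }
        lo
      }
      dm <- dice_of(a)
      if (dm < band[1] - 0.05 || dm > band[2] + 0.05)
        stop_mdaqp("rater %d: calibration infeasible (Dice %.2f outside [%g, %g])",
                   j, dm, band[1], band[2])
      r <- perturb_rater(low_j, high_j, a, sigma, sp, field, allowed)
      raters[[j]] <- list(low = r$low, high = r$high, pooled = r$low | r$high)
      dice_out[j] <- dm
      amps[j] <- a
    })
  }
  structure(list(raters = raters, dice = dice_out, amplitudes = amps),
            class = "rater_set")
}

#' @export
print.rater_set <- function(x, ...) {
  cat(sprintf("<rater_set: %d raters, pooled Dice vs GT %s>\n",
              length(x$raters),
              paste(sprintf("%.2f", x$dice), collapse = "/")))
  invisible(x)
}

#' Run the full phantom validation experiment
#'
#' Reproduces the phantom validation at desk scale: generate `n_controls`
#' lesion-free controls and `n_phantoms` lesioned phantoms sharing the same
#' geometry, fit the normative model on the controls, run the detector on
#' every phantom, optionally simulate an expert panel fused with STAPLE, and
#' evaluate everything against the inserted ground truth. Fully reproducible
#' from the config's root seed.
#'
#' @param config an [experiment_config].
#' @param out_dir optional directory; when given, writes `per_case.csv`,
#'   `summary.json` and (with `write_volumes = TRUE`) the NIfTI volumes of
#'   each case.
#' @param write_volumes also write MD maps and masks as `.nii.gz`?
#' @return An object of class `phantom_experiment`: `per_case` (one tibble
#'   row per phantom with AQP-vs-GT and consensus-vs-GT metrics), `summary`
#'   (median and IQR per metric), `rater_dice`, `icc_consensus_aqp`
#'   (volume agreement across cases, when raters are simulated), `config`.
#' @export
run_phantom_experiment <- function(config = experiment_config(),
                                   out_dir = NULL, write_volumes = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  spec <- config$spec
  root <- config$seed
  t0 <- Sys.time()

  controls <- make_controls(spec, config$n_controls,
                            seeds = vapply(seq_len(config$n_controls),
                                           function(i) derive_seed(root, "control", i),
                                           integer(1)))
  tissues <- controls[[1]]$tissues
  atlases <- make_atlas_set(tissues$brain, spec$spacing_mm,
                            n_atlases = config$n_atlases,
                            seed = derive_seed(root, "atlas"))
  model <- fit_normative(lapply(controls, `[[`, "md"), tissues, atlases,
                         z_threshold = config$aqp$z_threshold, K = config$aqp$K)

  rows <- vector("list", config$n_phantoms)
  rater_dice <- list()
  cons_ml <- aqp_ml <- gt_ml <- numeric(config$n_phantoms)
  for (i in seq_len(config$n_phantoms)) {
    sp_i <- spec
    sp_i$seed <- derive_seed(root, "phantom", i)
    base <- make_brain(sp_i)
    les <- insert_lesions(base$md, base$tissues, spec,
                          seed = derive_seed(root, "lesion", i))
    res <- run_aqp(les$md, base$tissues, atlases, model, config$aqp)
    gt_pool <- les$gt$low_mask | les$gt$high_mask
    aqp_pool <- res$low_mask | res$high_mask
    ev <- evaluate_segmentation(aqp_pool, gt_pool, spec$spacing_mm)
    gt_ml[i] <- mask_volume_ml(gt_pool, spec$spacing_mm)
    aqp_ml[i] <- res$volume_total_ml

    row <- tibble(case = i,
                  gt_ml = gt_ml[i],
                  gt_low_ml = mask_volume_ml(les$gt$low_mask, spec$spacing_mm),
                  gt_high_ml = mask_volume_ml(les$gt$high_mask, spec$spacing_mm),
                  aqp_ml = aqp_ml[i],
                  aqp_low_ml = res$volume_low_ml,
                  aqp_high_ml = res$volume_high_ml,
                  brain_fraction_pct = res$brain_fraction_pct,
                  dice = ev$dice, hd_mm = ev$hd_mm, assd_mm = ev$assd_mm,
                  precision = ev$precision, recall = ev$recall,
                  volume_error_pct = ev$volume_error_pct)

    if (config$include_raters) {
      panel <- simulate_raters(les$gt, base$tissues, config$n_raters,
                               config$rater_model,
                               seed = derive_seed(root, "raters", i))
      st_low <- run_staple(lapply(panel$raters, `[[`, "low"), spec$spacing_mm)
      st_high <- run_staple(lapply(panel$raters, `[[`, "high"), spec$spacing_mm)
      cons <- st_low$consensus | st_high$consensus
      evc <- evaluate_segmentation(cons, gt_pool, spec$spacing_mm)
      cons_ml[i] <- mask_volume_ml(cons, spec$spacing_mm)
      rater_dice[[i]] <- tibble(case = i, rater = seq_along(panel$dice),
                                dice = panel$dice)
      row <- cbind(row, tibble(consensus_ml = cons_ml[i],
                               consensus_dice = evc$dice,
                               consensus_precision = evc$precision,
                               consensus_recall = evc$recall,
                               consensus_volume_error_pct = evc$volume_error_pct))
    }
    rows[[i]] <- row
  }
  per_case <- as_tibble(do.call(rbind, rows))

  med_iqr <- function(x) {
    q <- unname(quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, type = 7))
    tibble(median = q[2], q25 = q[1], q75 = q[3])
  }
  metric_cols <- setdiff(names(per_case), "case")
  summary <- do.call(rbind, lapply(metric_cols, function(cn)
    cbind(tibble(metric = cn), med_iqr(per_case[[cn]]))))
  summary <- as_tibble(summary)

  icc_val <- NULL
  if (config$include_raters && config$n_phantoms >= 2) {
    icc_val <- tryCatch(icc(cbind(consensus = cons_ml, aqp = aqp_ml))$icc,
                        error = function(e) NA_real_)
  }
  out <- structure(list(
    per_case = per_case, summary = summary,
    rater_dice = if (length(rater_dice) > 0) as_tibble(do.call(rbind, rater_dice)) else NULL,
    icc_consensus_aqp = icc_val,
    brain_volume_ml = mask_volume_ml(tissues$brain, spec$spacing_mm),
    runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    config = config), class = "phantom_experiment")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(per_case, file.path(out_dir, "per_case.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(summary = summary, icc_consensus_aqp = icc_val,
           brain_volume_ml = out$brain_volume_ml,
           runtime_s = out$runtime_s, seed = root,
           files = list(per_case = "per_case.csv")),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows")
    if (write_volumes) {
      # regenerate case volumes for writing (kept out of memory above)
      for (i in seq_len(config$n_phantoms)) {
        sp_i <- spec; sp_i$seed <- derive_seed(root, "phantom", i)
        base <- make_brain(sp_i)
        les <- insert_lesions(base$md, base$tissues, spec,
                              seed = derive_seed(root, "lesion", i))
        write_nifti(les$md, file.path(out_dir, sprintf("case%02d_md.nii.gz", i)))
        write_nifti(image_volume(les$gt$low_mask | les$gt$high_mask,
                                 spec$spacing_mm, kind = "mask"),
                    file.path(out_dir, sprintf("case%02d_gt.nii.gz", i)))
      }
    }
  }
  out
}

#' @export
print.phantom_experiment <- function(x, ...) {
  g <- function(m) x$summary$median[x$summary$metric == m]
  cat(sprintf(paste0("<phantom_experiment: %d cases; median Dice %.3f, ",
                     "precision %.3f, volume error %+.1f%%; %.1f s>\n"),
              nrow(x$per_case), g("dice"), g("precision"),
              g("volume_error_pct"), x$runtime_s))
  invisible(x)
}

#' @rdname run_phantom_experiment
#' @param x a `phantom_experiment`.
#' @param ... unused.
#' @export
tidy.phantom_experiment <- function(x, ...) x$per_case

#' @rdname run_phantom_experiment
#' @export
glance.phantom_experiment <- function(x, ...) {
  g <- function(m) x$summary$median[x$summary$metric == m]
  tibble(n_cases = nrow(x$per_case), median_dice = g("dice"),
         median_precision = g("precision"), median_recall = g("recall"),
         median_volume_error_pct = g("volume_error_pct"),
         icc_consensus_aqp = x$icc_consensus_aqp %||% NA_real_,
         runtime_s = x$runtime_s)
}
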