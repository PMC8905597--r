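#' Fit the diffusion tensor and compute mean diffusivity
#'
#' Ordinary (unweighted) log-linear least-squares fit of the six unique
#' diffusion tensor components per voxel, from which the mean diffusivity
#' MD = trace(D)/3 is derived. The model is
#' \deqn{\ln(S_i/S_0) = -b_i \, g_i^T D \, g_i}
#' solved over all b > 0 volumes; \eqn{S_0} is the mean of the b = 0 volumes.
#' Signals \eqn{\le 0} are clamped to \eqn{10^{-6} S_0} before the log.
#' Negative MD estimates (possible under noise) are clamped to 0 and counted.
#'
#' @param dwi a [dwi_set].
#' @param mask logical 3D array of voxels to fit (non-empty).
#' @param keep_tensor keep the 6 fitted components per voxel (Dxx, Dyy, Dzz,
#'   Dxy, Dxz, Dyz)?
#' @return A list of class `tensor_fit` with elements `md` ([image_volume],
#'   mm^2/s, 0 outside `fit_mask`), `fit_mask` (voxels actually fitted:
#'   `mask` minus voxels whose b0 signal is entirely zero), `tensor`
#'   (6 x n matrix over `which(fit_mask)`, or `NULL`), and `n_negative_md`.
#' @export
#' @examples
#' sp <- phantom_spec(shape = c(16, 16, 16))
#' ph <- make_brain(sp)
#' dwi <- synthesize_dwi(ph$md, ph$tissues$brain, b = 1000, n_dirs = 6, snr = Inf, seed = 1)
#' fit <- fit_tensor(dwi, ph$tissues$brain)
#' max(abs(fit$md$data[ph$tissues$brain] - ph$md$data[ph$tissues$brain]))
fit_tensor <- function(dwi, mask, keep_tensor = TRUE) {
  stopifnot(inherits(dwi, "dwi_set"), is_logical_grid(mask))
  if (!any(mask)) stop_mdaqp("fit mask is empty")
  dims <- dim(dwi$data)[1:3]
  if (!identical(dim(mask), dims)) stop_mdaqp("mask shape does not match DWI grid")

  nvol <- length(dwi$bvals)
  flat <- matrix(dwi$data, nrow = prod(dims), ncol = nvol)
  idx <- which(mask)
  b0_cols <- which(dwi$bvals == 0)
  dw_cols <- which(dwi$bvals > 0)
  S0 <- rowMeans(flat[idx, b0_cols, drop = FALSE])

  fit_ok <- S0 > 0
  idx <- idx[fit_ok]
  S0 <- S0[fit_ok]
  if (length(idx) == 0L) stop_mdaqp("no voxel has positive b0 signal inside the mask")

  g <- dwi$bvecs[, dw_cols, drop = FALSE]
  b <- dwi$bvals[dw_cols]
  X <- cbind(g[1, ]^2, g[2, ]^2, g[3, ]^2,
             2 * g[1, ] * g[2, ], 2 * g[1, ] * g[3, ], 2 * g[2, ] * g[3, ]) * b
  if (qr(X)$rank < 6L)
    stop_mdaqp("gradient scheme is rank-deficient: < 6 usable directions")

  S <- flat[idx, dw_cols, drop = FALSE]
  S <- pmax(S, 1e-6 * S0)            # clamp non-positive signals before log
  Y <- -log(S / S0)                  # n_vox x n_dw
  D <- t(solve(crossprod(X), crossprod(X, t(Y))))  # n_vox x 6
  md_vals <- (D[, 1] + D[, 2] + D[, 3]) / 3
  n_neg <- sum(md_vals < 0)
  md_vals <- pmax(md_vals, 0)

  md_grid <- array(0, dim = dims)
  md_grid[idx] <- md_vals
  fit_mask <- array(FALSE, dim = dims)
  fit_mask[idx] <- TRUE
  structure(list(
    md = image_volume(md_grid, spacing_mm = dwi$spacing_mm),
    fit_mask = fit_mask,
    tensor = if (keep_tensor) t(D) else NULL,
    voxel_index = idx,
    n_negative_md = n_neg
  ), class = "tensor_fit")
}

#' @export
print.tensor_fit <- function(x, ...) {
  cat(sprintf("<tensor_fit: %d voxels, median MD %.3g mm^2/s, %d negative-MD clamped>\n",
              sum(x$fit_mask), median(x$md$data[x$fit_mask]), x$n_negative_md))
  invisible(x)
}

#' Signal-to-noise ratio of a volume
#'
#' SNR = mean(signal inside brain) / sd(signal outside brain), with the
#' sample (n-1) standard deviation. A simple single-number quality check;
#' the background must show some variation.
#'
#' @param volume an [image_volume] or 3D array.
#' @param brain logical brain mask (non-empty, with non-empty complement).
#' @return SNR as a single number.
#' @export
compute_snr <- function(volume, brain) {
  data <- if (inherits(volume, "image_volume")) volume$data else volume
  stopifnot(is_logical_grid(brain))
  if (!any(brain)) stop_mdaqp("brain mask is empty")
  if (all(brain)) stop_mdaqp("background (non-brain) region is empty")
  bg_sd <- sd(data[!brain])
  if (bg_sd == 0) stop_mdaqp("background has zero variance; SNR undefined")
  mean(data[brain]) / bg_sd
}

#' Detect corrupted slices in a DWI acquisition
#'
#' Dropout/spike detector. For each axial slice the mean intensity within the
#' brain mask is computed per volume; within each group of volumes sharing a
#' b-value, a slice's intensity is divided by the median of the same slice
#' across the group's volumes, which cancels anatomy (slice means legitimately
#' vary across the brain). Slices whose robust z-score (median / MAD across
#' the slices of that volume, on these normalised ratios) exceeds
#' `z_threshold` in absolute value *and* whose normalised intensity deviates
#' by more than `min_deviation` (a 2% wobble on a thin edge slice is not
#' corruption, however many MADs it spans) are flagged. Volumes whose b-value
#' group has fewer than 3 members have no reliable same-slice reference and
#' are skipped, as are slices with no brain voxels.
#'
#' @param dwi a [dwi_set].
#' @param brain logical brain mask.
#' @param z_threshold robust z cutoff (> 0), default 4.
#' @param min_deviation minimum relative deviation of the normalised slice
#'   intensity (default 0.1, i.e. 10%).
#' @return A tibble with columns `volume`, `slice` (1-based), `zscore`;
#'   zero rows when the acquisition is clean.
#' @export
detect_corrupted_slices <- function(dwi, brain, z_threshold = 4,
                                    min_deviation = 0.1) {
  stopifnot(inherits(dwi, "dwi_set"), is_logical_grid(brain))
  if (!(z_threshold > 0)) stop_mdaqp("z_threshold must be > 0")
  dims <- dim(dwi$data)[1:3]
  nz <- dims[3]
  slice_n <- vapply(seq_len(nz), function(z) sum(brain[, , z]), numeric(1))
  usable <- which(slice_n > 0)
  nvol <- length(dwi$bvals)
  m <- matrix(NA_real_, nvol, length(usable))   # volume x usable slice means
  for (v in seq_len(nvol)) {
    vol <- dwi$data[, , , v]
    m[v, ] <- vapply(usable, function(z) mean(vol[, , z][brain[, , z]]),
                     numeric(1))
  }
  out <- list()
  for (b in unique(dwi$bvals)) {
    grp <- which(dwi$bvals == b)
    if (length(grp) < 3L) next
    ref <- apply(m[grp, , drop = FALSE], 2, median)
    ok <- ref > 0
    for (v in grp) {
      r <- m[v, ok] / ref[ok]
      med <- median(r)
      s <- mad(r)                    # 1.4826 * MAD, robust scale
      z <- if (s == 0) ifelse(r == med, 0, Inf * sign(r - med)) else (r - med) / s
      hit <- which(abs(z) > z_threshold & abs(r - med) > min_deviation)
      if (length(hit) > 0)
        out[[length(out) + 1L]] <- tibble(volume = v,
                                          slice = usable[ok][hit],
                                          zscore = z[hit])
    }
  }
  if (length(out) == 0)
    return(tibble(volume = integer(), slice = integer(), zscore = numeric()))
  do.call(rbind, out)
}

#' Quality-control report for a DWI acquisition
#'
#' Combines the SNR check (on the first b = 0 volume) and the corrupted-slice
#' scan. `passed` is true iff no slice is flagged and SNR is at or above the
#' floor.
#'
#' @param dwi a [dwi_set].
#' @param brain logical brain mask.
#' @param snr_floor minimum acceptable SNR (default 10).
#' @param z_threshold corrupted-slice robust z cutoff (default 4).
#' @return A list of class `qc_report` with `snr`, `corrupted_slices`, `passed`.
#' @export
qc_report <- function(dwi, brain, snr_floor = 10, z_threshold = 4) {
  b0 <- dwi$data[, , , which(dwi$bvals == 0)[1L]]
  snr <- compute_snr(b0, brain)
  bad <- detect_corrupted_slices(dwi, brain, z_threshold)
  structure(list(snr = snr, corrupted_slices = bad,
                 passed = nrow(bad) == 0 && snr >= snr_floor,
                 snr_floor = snr_floor),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report: SNR %.1f (floor %g), %d corrupted slice(s), %s>\n",
              x$snr, x$snr_floor, nrow(x$corrupted_slices),
              if (x$passed) "PASSED" else "FAILED"))
  invisible(x)
}
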