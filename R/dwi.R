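#' Diffusion-weighted acquisition
#'
#' A `dwi_set` holds a 4D signal array (x, y, z, volume) together with the
#' b-value (s/mm\eqn{^2}) and unit gradient direction of each volume, in the
#' FSL bval/bvec convention. At least one b = 0 reference volume and at least
#' six distinct, non-collinear b > 0 directions are required, the minimum for
#' fitting the six unique components of the diffusion tensor.
#'
#' @param data 4D numeric array, arbitrary signal units.
#' @param bvals numeric vector of b-values, one per volume.
#' @param bvecs 3 x n numeric matrix of gradient directions (columns); the
#'   zero vector is allowed (and ignored) where b = 0, unit norm (tolerance
#'   1e-3) is required where b > 0.
#' @param spacing_mm voxel spacing of the grid, mm.
#' @return An object of class `dwi_set`.
#' @export
dwi_set <- function(data, bvals, bvecs, spacing_mm = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop_mdaqp("dwi_set needs a 4D array")
  nvol <- dim(data)[4L]
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3L) stop_mdaqp("bvecs must be a 3 x n matrix (FSL convention)")
  if (length(bvals) != nvol || ncol(bvecs) != nvol)
    stop_mdaqp("volume count mismatch: %d volumes, %d bvals, %d bvecs",
               nvol, length(bvals), ncol(bvecs))
  if (!any(bvals == 0)) stop_mdaqp("no b = 0 reference volume present")
  norms <- sqrt(colSums(bvecs^2))
  bad <- which(bvals > 0 & abs(norms - 1) > 1e-3)
  if (length(bad) > 0)
    stop_mdaqp("bvec column %d has norm %.4f (must be unit for b > 0)",
               bad[1L], norms[bad[1L]])
  dw <- which(bvals > 0)
  # distinct non-collinear directions: dedupe up to sign
  if (length(dw) >= 1L) {
    dirs <- bvecs[, dw, drop = FALSE]
    key <- apply(round(dirs, 6), 2L, function(g) {
      nz <- which(g != 0)
      if (length(nz) > 0 && g[nz[1L]] < 0) g <- -g
      paste(g, collapse = ",")
    })
    if (length(unique(key)) < 6L)
      stop_mdaqp("need >= 6 distinct non-collinear b > 0 directions, got %d",
                 length(unique(key)))
  } else stop_mdaqp("need >= 6 b > 0 volumes, got 0")
  structure(list(data = data, bvals = bvals, bvecs = bvecs,
                 spacing_mm = as.numeric(spacing_mm)),
            class = "dwi_set")
}

#' @export
print.dwi_set <- function(x, ...) {
  cat(sprintf("<dwi_set %s, %d volumes (%d b0, %d DW), b up to %g s/mm^2>\n",
              paste(dim(x$data)[1:3], collapse = "x"), length(x$bvals),
              sum(x$bvals == 0), sum(x$bvals > 0), max(x$bvals)))
  invisible(x)
}

#' Read a DWI acquisition (NIfTI + FSL bval/bvec)
#'
#' @param nifti_path 4D NIfTI-1 file.
#' @param bval_path whitespace-delimited b-values, one row.
#' @param bvec_path whitespace-delimited gradients, 3 rows x n columns (FSL).
#' @return A [dwi_set].
#' @export
read_dwi <- function(nifti_path, bval_path, bvec_path) {
  raw <- read_nifti_raw(nifti_path)
  if (raw$ndim != 4L)
    stop_mdaqp("expected a 4D DWI volume, got %dD in %s", raw$ndim, nifti_path)
  bvals <- scan(bval_path, what = numeric(), quiet = TRUE)
  bvec_rows <- utils::read.table(bvec_path)
  bvecs <- as.matrix(bvec_rows)
  if (nrow(bvecs) != 3L) stop_mdaqp("bvec file must have 3 rows, got %d", nrow(bvecs))
  dimnames(bvecs) <- NULL
  dwi_set(raw$data, bvals, bvecs, spacing_mm = raw$spacing_mm)
}

#' Write a DWI acquisition to NIfTI + bval/bvec
#'
#' @param dwi a [dwi_set].
#' @param nifti_path,bval_path,bvec_path output paths.
#' @return Invisibly, `nifti_path`.
#' @export
write_dwi <- function(dwi, nifti_path, bval_path, bvec_path) {
  stopifnot(inherits(dwi, "dwi_set"))
  write_nifti_array(dwi$data, dwi$spacing_mm, nifti_path, dt = 64L)
  writeLines(paste(format(dwi$bvals, scientific = FALSE, trim = TRUE),
                   collapse = " "), bval_path)
  writeLines(apply(dwi$bvecs, 1L, function(r)
    paste(format(r, digits = 17, trim = TRUE), collapse = " ")), bvec_path)
  invisible(nifti_path)
}
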