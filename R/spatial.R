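# Spatial primitives on 3D grids: separable Gaussian smoothing, connected
# components, exact Euclidean distance transform, border extraction.

FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))   # sigma = FWHM * this

# Dense 1D convolution matrix for a truncated Gaussian, zero padding outside
# the grid. Kernel support is cut at `truncate` sigmas, so influence beyond
# that radius is exactly zero.
gaussian_band_matrix <- function(n, sigma_vox, truncate = 4) {
  if (sigma_vox <= 0) return(diag(n))
  r <- ceiling(truncate * sigma_vox)
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  k <- k / sum(k)
  K <- matrix(0, n, n)
  for (j in seq_len(n)) {
    lo <- max(1L, j - r); hi <- min(n, j + r)
    K[lo:hi, j] <- k[(lo - j + r + 1L):(hi - j + r + 1L)]
  }
  K
}

# Separable 3D Gaussian smoothing, sigma given in mm (scalar), anisotropic
# spacing honoured. `renormalize` divides by the smoothed all-ones volume so
# constants stay constant near edges (used for random fields).
smooth_gaussian <- function(arr, sigma_mm, spacing_mm, truncate = 4,
                            renormalize = FALSE) {
  dims <- dim(arr)
  out <- arr
  for (axis in 1:3) {
    K <- gaussian_band_matrix(dims[axis], sigma_mm / spacing_mm[axis], truncate)
    out <- apply_along(out, axis, K)
  }
  if (renormalize) {
    ones <- array(1, dims)
    for (axis in 1:3) {
      K <- gaussian_band_matrix(dims[axis], sigma_mm / spacing_mm[axis], truncate)
      ones <- apply_along(ones, axis, K)
    }
    out <- out / ones
  }
  out
}

# Multiply a band matrix along one axis of a 3D array.
apply_along <- function(arr, axis, K) {
  dims <- dim(arr)
  if (axis == 1L) {
    array(K %*% matrix(arr, dims[1], dims[2] * dims[3]), dims)
  } else if (axis == 2L) {
    p <- aperm(arr, c(2, 1, 3))
    p <- array(K %*% matrix(p, dims[2], dims[1] * dims[3]), c(dims[2], dims[1], dims[3]))
    aperm(p, c(2, 1, 3))
  } else {
    p <- aperm(arr, c(3, 1, 2))
    p <- array(K %*% matrix(p, dims[3], dims[1] * dims[2]), c(dims[3], dims[1], dims[2]))
    aperm(p, c(2, 3, 1))
  }
}

#' Label connected components of a 3D mask
#'
#' @param mask logical 3D array.
#' @param connectivity 6, 18 or 26 (default 26, the standard for 3D lesions).
#' @return A list with `labels` (integer array, 0 = background) and `n`
#'   (number of components).
#' @export
label_components <- function(mask, connectivity = 26) {
  stopifnot(is_logical_grid(mask), connectivity %in% c(6, 18, 26))
  lab <- cc_label_cpp(as.vector(mask), dim(mask), as.integer(connectivity))
  list(labels = array(lab, dim(mask)), n = if (length(lab)) max(lab) else 0L)
}

#' Euclidean distance to the nearest mask voxel
#'
#' Exact anisotropic distance transform (voxel-centre to voxel-centre, in mm).
#' Voxels inside the seed mask get distance 0; if the seed mask is empty all
#' distances are `Inf`.
#'
#' @param seed_mask logical 3D array of target voxels.
#' @param spacing_mm voxel spacing, mm.
#' @return Numeric 3D array of distances in mm.
#' @export
distance_to_mm <- function(seed_mask, spacing_mm) {
  stopifnot(is_logical_grid(seed_mask))
  d2 <- edt_sq_cpp(as.vector(seed_mask), dim(seed_mask), as.numeric(spacing_mm))
  array(sqrt(d2), dim(seed_mask))
}

# Shift a 3D logical array by one voxel along `axis` (+1/-1); vacated planes
# filled with `fill`.
shift1 <- function(mask, axis, step, fill = FALSE) {
  dims <- dim(mask)
  out <- array(fill, dims)
  n <- dims[axis]
  src <- if (step > 0) 1:(n - 1) else 2:n
  dst <- if (step > 0) 2:n else 1:(n - 1)
  ix <- list(seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]))
  sx <- ix; sx[[axis]] <- src
  dx <- ix; dx[[axis]] <- dst
  out[dx[[1]], dx[[2]], dx[[3]]] <- mask[sx[[1]], sx[[2]], sx[[3]]]
  out
}

# Border voxels: in the mask with at least one face neighbour outside it
# (out-of-grid counts as outside).
border_mask <- function(mask) {
  interior <- mask
  for (axis in 1:3) for (step in c(-1, 1)) {
    interior <- interior & shift1(mask, axis, step, fill = FALSE)
  }
  mask & !interior
}

# Binary dilation by a spacing-aware ball of radius `radius_mm`
# (strict/non-strict controlled by `include_boundary`).
dilate_ball <- function(mask, spacing_mm, radius_mm, include_boundary = TRUE) {
  d <- distance_to_mm(mask, spacing_mm)
  if (include_boundary) d <= radius_mm else d < radius_mm - 1e-9
}
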