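#' Image volumes
#'
#' An `image_volume` is the package's carrier for any 3D scalar grid: a mean
#' diffusivity (MD) map in mm\eqn{^2}/s, a binary tissue mask, or an integer
#' parcellation. It stores the voxel data as a plain 3D array together with the
#' physical voxel spacing in mm. All spatial computations in the package
#' (volumes in ml, surface distances, CSF margins) are voxel-index arithmetic
#' scaled by this spacing; no affine resampling is performed and volumes that
#' must interoperate are required to share shape and spacing exactly.
#'
#' @param data 3D numeric, integer or logical array.
#' @param spacing_mm numeric length-3, voxel edge lengths in mm (all > 0).
#' @param kind one of `"scalar"`, `"mask"`, `"label"`. Scalar volumes must be
#'   finite everywhere; mask/label volumes must hold non-negative integers
#'   (logical arrays are accepted for masks).
#'
#' @return An object of class `image_volume`: a list with elements `data`,
#'   `shape`, `spacing_mm` and `kind`.
#' @export
#' @examples
#' v <- image_volume(array(0.8e-3, c(8, 8, 8)), spacing_mm = c(2, 2, 2))
#' volume_ml(v$data > 0, v$spacing_mm)
image_volume <- function(data, spacing_mm = c(1, 1, 1), kind = c("scalar", "mask", "label")) {
  kind <- match.arg(kind)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_mdaqp("image_volume needs a 3D array, got %s dimension(s)",
               if (is.array(data)) length(dim(data)) else "no")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop_mdaqp("spacing_mm must be 3 positive finite numbers")
  if (kind == "scalar") {
    bad <- sum(!is.finite(data))
    if (bad > 0)
      stop_mdaqp("scalar volume has %d non-finite voxel(s) (NaN/Inf)", bad)
  } else {
    if (is.logical(data)) {
      if (anyNA(data)) stop_mdaqp("mask volume contains NA voxels")
    } else {
      if (any(!is.finite(data)) || any(data < 0) || any(data != round(data)))
        stop_mdaqp("%s volume must contain non-negative integers", kind)
    }
  }
  structure(list(data = data, shape = dim(data), spacing_mm = spacing_mm, kind = kind),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume [%s] %s, spacing %s mm, range [%g, %g]>\n",
              x$kind, paste(x$shape, collapse = "x"),
              paste(signif(x$spacing_mm, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Verify that volumes live on the same voxel grid
#'
#' All per-subject inputs (MD map, brain and CSF masks, parcellations) must
#' share shape and spacing; the package never resamples. Spacing is compared
#' to 1e-4 mm.
#'
#' @param ... two or more `image_volume` objects (or bare 3D arrays, which are
#'   assumed to share the first volume's spacing).
#' @return Invisibly `TRUE`; errors naming the first offending pair otherwise.
#' @export
check_same_grid <- function(...) {
  vols <- list(...)
  if (length(vols) < 2L) stop_mdaqp("check_same_grid needs at least 2 volumes")
  ref <- vols[[1L]]
  ref_shape <- if (inherits(ref, "image_volume")) ref$shape else dim(ref)
  ref_sp <- if (inherits(ref, "image_volume")) ref$spacing_mm else NULL
  for (i in seq_along(vols)[-1L]) {
    v <- vols[[i]]
    shape <- if (inherits(v, "image_volume")) v$shape else dim(v)
    if (!identical(as.integer(shape), as.integer(ref_shape)))
      stop_mdaqp("grid mismatch between volume 1 and volume %d: shapes %s vs %s",
                 i, paste(ref_shape, collapse = "x"), paste(shape, collapse = "x"))
    sp <- if (inherits(v, "image_volume")) v$spacing_mm else NULL
    if (!is.null(ref_sp) && !is.null(sp) && any(abs(sp - ref_sp) > 1e-4))
      stop_mdaqp("grid mismatch between volume 1 and volume %d: spacings (%s) vs (%s) mm",
                 i, paste(ref_sp, collapse = ","), paste(sp, collapse = ","))
  }
  invisible(TRUE)
}

#' Tissue masks for one subject
#'
#' Bundles the brain mask and the CSF/ventricle mask used by the detector's
#' exclusion rules. Both must live on the same grid; the brain mask must be
#' non-empty.
#'
#' @param brain,csf logical 3D arrays.
#' @param spacing_mm voxel spacing in mm.
#' @return An object of class `tissue_masks`.
#' @export
tissue_masks <- function(brain, csf, spacing_mm = c(1, 1, 1)) {
  stopifnot(is_logical_grid(brain), is_logical_grid(csf))
  if (!identical(dim(brain), dim(csf)))
    stop_mdaqp("brain and csf masks differ in shape")
  if (!any(brain)) stop_mdaqp("brain mask is empty")
  structure(list(brain = brain, csf = csf, spacing_mm = as.numeric(spacing_mm)),
            class = "tissue_masks")
}

#' Volume of a binary mask in millilitres
#'
#' @param mask logical 3D array.
#' @param spacing_mm voxel spacing in mm.
#' @return Volume in ml (= voxel count x voxel volume mm^3 / 1000).
#' @export
volume_ml <- function(mask, spacing_mm) {
  stopifnot(is_logical_grid(mask))
  mask_volume_ml(mask, as.numeric(spacing_mm))
}
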