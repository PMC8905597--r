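#' Voxel-overlap agreement metrics
#'
#' Dice = 2TP / (2TP + FP + FN), precision = TP / (TP + FP) and recall
#' (sensitivity) = TP / (TP + FN), counted voxel-wise on a common grid.
#' Convention: if both masks are empty all three are 1 (perfect agreement on
#' absence, needed for lesion-free specificity runs, and flagged via
#' `both_empty`); if exactly one is empty all three are 0.
#'
#' @param test,reference logical 3D arrays on the same grid.
#' @return A tibble row: `dice`, `precision`, `recall`, `tp`, `fp`, `fn`,
#'   `both_empty`.
#' @export
overlap_metrics <- function(test, reference) {
  stopifnot(is_logical_grid(test), is_logical_grid(reference))
  if (!identical(dim(test), dim(reference)))
    stop_mdaqp("test and reference masks differ in shape")
  tp <- sum(test & reference)
  fp <- sum(test & !reference)
  fn <- sum(!test & reference)
  if (tp + fp + fn == 0L) {
    return(tibble(dice = 1, precision = 1, recall = 1,
                  tp = 0L, fp = 0L, fn = 0L, both_empty = TRUE))
  }
  dice <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  tibble(dice = dice, precision = precision, recall = recall,
         tp = tp, fp = fp, fn = fn, both_empty = FALSE)
}

#' Surface distance metrics (Hausdorff and ASSD)
#'
#' Surfaces are the border voxels of each mask (a mask voxel with at least
#' one face neighbour outside the mask, grid edges counting as outside);
#' distances are Euclidean between voxel centres, scaled by the spacing.
#' HD is the maximum over both directed maxima; ASSD is the mean of all
#' surface-voxel nearest distances pooled over both directions — the
#' conventions of the ISLES challenge reference implementation.
#'
#' @param test,reference non-empty logical 3D arrays on a common grid.
#' @param spacing_mm voxel spacing, mm.
#' @return A tibble row: `hd_mm`, `assd_mm`.
#' @export
surface_distances <- function(test, reference, spacing_mm) {
  stopifnot(is_logical_grid(test), is_logical_grid(reference))
  if (!identical(dim(test), dim(reference)))
    stop_mdaqp("test and reference masks differ in shape")
  if (!any(test) || !any(reference))
    stop_mdaqp("surface distances are undefined for an empty mask")
  bt <- border_mask(test)
  br <- border_mask(reference)
  # directed nearest-surface distances via the exact distance transform
  d_to_ref <- distance_to_mm(br, spacing_mm)[bt]
  d_to_test <- distance_to_mm(bt, spacing_mm)[br]
  tibble(hd_mm = max(max(d_to_ref), max(d_to_test)),
         assd_mm = mean(c(d_to_ref, d_to_test)))
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC from
#' the standard ANOVA mean squares:
#' \deqn{ICC(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with \eqn{MS_R} the between-subject, \eqn{MS_C} the between-rater and
#' \eqn{MS_E} the residual mean square over an n subjects x k raters table.
#'
#' @param measurements numeric matrix or data frame, subjects in rows,
#'   raters/methods in columns; no missing cells.
#' @return An object of class `icc_result`: `icc`, mean squares, `n`, `k`.
#' @export
icc <- function(measurements) {
  m <- as.matrix(measurements)
  if (anyNA(m)) stop_mdaqp("ICC requires a complete table (no missing cells)")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop_mdaqp("ICC needs >= 2 subjects and >= 2 raters")
  grand <- mean(m)
  if (all(m == grand)) stop_mdaqp("zero total variance; ICC undefined")
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  ms_r <- ss_rows / (n - 1)
  ms_c <- ss_cols / (k - 1)
  ms_e <- ss_err / ((n - 1) * (k - 1))
  val <- (ms_r - ms_e) / (ms_r + (k - 1) * ms_e + k * (ms_c - ms_e) / n)
  structure(list(icc = val, ms_rows = ms_r, ms_cols = ms_c, ms_error = ms_e,
                 n = n, k = k, model = "ICC(2,1) absolute agreement"),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result: %s = %.3f (n = %d subjects, k = %d raters)>\n",
              x$model, x$icc, x$n, x$k))
  invisible(x)
}

#' @rdname icc
#' @param x an `icc_result`.
#' @param ... unused.
#' @export
glance.icc_result <- function(x, ...) {
  tibble(icc = x$icc, ms_rows = x$ms_rows, ms_cols = x$ms_cols,
         ms_error = x$ms_error, n = x$n, k = x$k, model = x$model)
}

#' Bland-Altman agreement summary
#'
#' Differences d = a - b; bias = mean(d), limits of agreement =
#' bias +/- 1.96 sd(d).
#'
#' @param a,b paired numeric vectors (>= 2 pairs).
#' @return A tibble row: `bias`, `lower_loa`, `upper_loa`, `sd_diff`, `n`.
#' @export
bland_altman <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) < 2) stop_mdaqp("Bland-Altman needs >= 2 pairs")
  d <- a - b
  bias <- mean(d)
  s <- sd(d)
  tibble(bias = bias, lower_loa = bias - 1.96 * s, upper_loa = bias + 1.96 * s,
         sd_diff = s, n = length(a))
}

#' Signed relative volume error
#'
#' 100 x (test - reference) / reference, percent; positive means
#' overestimation by the test method.
#'
#' @param test_ml,reference_ml volumes in ml; reference must be > 0.
#' @return Signed percent error.
#' @export
volume_error <- function(test_ml, reference_ml) {
  if (any(reference_ml <= 0)) stop_mdaqp("reference volume must be > 0")
  100 * (test_ml - reference_ml) / reference_ml
}

#' Full agreement report between two masks
#'
#' Combines overlap metrics, surface distances (NA when either mask is
#' empty) and volumes into one tibble row, the shape used by segmentation
#' comparison tables.
#'
#' @param test,reference logical 3D arrays.
#' @param spacing_mm voxel spacing, mm.
#' @return A tibble row with `dice`, `hd_mm`, `assd_mm`, `precision`,
#'   `recall`, `test_ml`, `reference_ml`, `volume_error_pct`.
#' @export
evaluate_segmentation <- function(test, reference, spacing_mm) {
  ov <- overlap_metrics(test, reference)
  sdist <- if (any(test) && any(reference))
    surface_distances(test, reference, spacing_mm)
  else tibble(hd_mm = NA_real_, assd_mm = NA_real_)
  test_ml <- mask_volume_ml(test, spacing_mm)
  ref_ml <- mask_volume_ml(reference, spacing_mm)
  tibble(dice = ov$dice, hd_mm = sdist$hd_mm, assd_mm = sdist$assd_mm,
         precision = ov$precision, recall = ov$recall,
         test_ml = test_ml, reference_ml = ref_ml,
         volume_error_pct = if (ref_ml > 0) volume_error(test_ml, ref_ml) else NA_real_)
}

#' Thin wrappers for the report-level hypothesis tests
#'
#' Kruskal-Wallis across groups and Mann-Whitney (Wilcoxon rank-sum) between
#' two groups, returned as tidy one-row tibbles. These are standard tests
#' included only for report tables.
#'
#' @param values numeric vector of measurements.
#' @param groups factor of group labels (same length).
#' @return A tibble row: `statistic`, `p_value`, `method`.
#' @export
compare_groups <- function(values, groups) {
  groups <- as.factor(groups)
  stopifnot(length(values) == length(groups))
  if (nlevels(groups) == 2L) {
    h <- wilcox.test(values ~ groups, exact = FALSE)
  } else {
    h <- kruskal.test(values, groups)
  }
  tibble(statistic = unname(h$statistic), p_value = h$p.value,
         method = h$method)
}
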