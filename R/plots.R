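utils::globalVariables(c("x", "y", "md", "case", "metric", "value", "diff"))

# ggplot2 report figures. ggplot2 is suggested, not imported: each function
# checks for it at call time.

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_mdaqp("ggplot2 is required for plotting")
}

#' Plot an axial slice of an MD map with lesion outlines
#'
#' @param md an [image_volume].
#' @param z slice index (default: middle slice).
#' @param low_mask,high_mask optional logical arrays overlaid as filled tiles.
#' @return A ggplot object.
#' @export
plot_md_slice <- function(md, z = NULL, low_mask = NULL, high_mask = NULL) {
  need_ggplot()
  z <- z %||% ceiling(md$shape[3] / 2)
  df <- expand.grid(x = seq_len(md$shape[1]), y = seq_len(md$shape[2]))
  df$md <- as.vector(md$data[, , z])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = md)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 name = "MD (mm²/s)") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("MD map, axial slice %d", z))
  overlay <- function(p, mask, colour, lab) {
    sel <- which(mask[, , z], arr.ind = TRUE)
    if (nrow(sel) == 0) return(p)
    p + ggplot2::annotate("tile", x = sel[, 1], y = sel[, 2],
                          fill = colour, alpha = 0.45)
  }
  if (!is.null(low_mask)) p <- overlay(p, low_mask, "#2ca02c", "low")
  if (!is.null(high_mask)) p <- overlay(p, high_mask, "#d62728", "high")
  p
}

#' Per-case metric plot for a phantom experiment
#'
#' @param object a `phantom_experiment`.
#' @param ... unused.
#' @return A ggplot object: Dice, precision and recall per case.
#' @exportS3Method ggplot2::autoplot
autoplot.phantom_experiment <- function(object, ...) {
  need_ggplot()
  pc <- object$per_case
  long <- rbind(
    data.frame(case = pc$case, metric = "dice", value = pc$dice),
    data.frame(case = pc$case, metric = "precision", value = pc$precision),
    data.frame(case = pc$case, metric = "recall", value = pc$recall))
  ggplot2::ggplot(long, ggplot2::aes(x = factor(case), y = value,
                                     fill = metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "phantom case", y = NULL,
                  title = "Detector agreement with inserted ground truth")
}

#' Bland-Altman plot of two volume series
#'
#' @param a,b paired volumes (ml).
#' @param labels axis annotation, length 2.
#' @return A ggplot object with bias and limits of agreement.
#' @export
plot_bland_altman <- function(a, b, labels = c("method A", "method B")) {
  need_ggplot()
  ba <- bland_altman(a, b)
  df <- data.frame(mean = (a + b) / 2, diff = a - b)
  ggplot2::ggplot(df, ggplot2::aes(x = mean, y = diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = ba$bias, linetype = 1) +
    ggplot2::geom_hline(yintercept = c(ba$lower_loa, ba$upper_loa),
                        linetype = 2) +
    ggplot2::labs(x = sprintf("mean of %s and %s (ml)", labels[1], labels[2]),
                  y = sprintf("%s - %s (ml)", labels[1], labels[2]),
                  title = "Bland-Altman agreement")
}
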