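#' Fuse rater segmentations with STAPLE
#'
#' Binary Simultaneous Truth and Performance Level Estimation: an EM
#' algorithm that treats the latent true segmentation as missing data and
#' alternates between (E) computing the per-voxel posterior probability
#' W of being lesion given the current rater sensitivities p_j and
#' specificities q_j, and (M) re-estimating p_j and q_j from W:
#' \deqn{W_i = \frac{\pi \prod_j p_j^{D_{ij}} (1-p_j)^{1-D_{ij}}}
#'   {\pi \prod_j p_j^{D_{ij}} (1-p_j)^{1-D_{ij}} +
#'    (1-\pi) \prod_j (1-q_j)^{D_{ij}} q_j^{1-D_{ij}}}}
#' \deqn{p_j = \frac{\sum_i W_i D_{ij}}{\sum_i W_i}, \quad
#'       q_j = \frac{\sum_i (1-W_i)(1-D_{ij})}{\sum_i (1-W_i)}}
#'
#' Computation is restricted to a region of interest (the union of rater
#' masks dilated by one voxel) plus a background sample of equal size:
#' running EM over a whole brain of agreed-background voxels drives
#' specificity to 1 and degrades the fusion — the classic STAPLE pitfall.
#' The prior \eqn{\pi} is the mean rater foreground fraction within the ROI.
#' The observed-data log-likelihood is checked to be non-decreasing at every
#' iteration.
#'
#' @param raters list of logical 3D arrays, one per rater (one class at a
#'   time); a single rater returns its own mask as consensus.
#' @param spacing_mm voxel spacing, mm.
#' @param tol convergence tolerance on max |change| in p, q (default 1e-6).
#' @param max_iter maximum EM iterations (default 100).
#' @param bg_seed seed for the deterministic background sample.
#' @return An object of class `staple_result`: `posterior` (array in \[0,1\]),
#'   `consensus` (logical array, posterior >= 0.5), `p` and `q` per rater,
#'   `n_iterations`, `converged`, `log_likelihood` trace.
#' @export
run_staple <- function(raters, spacing_mm = c(1, 1, 1), tol = 1e-6,
                       max_iter = 100, bg_seed = 2023L) {
  stopifnot(is.list(raters), length(raters) >= 1)
  lapply(raters, function(r) stopifnot(is_logical_grid(r)))
  dims <- dim(raters[[1]])
  for (r in raters) stopifnot(identical(dim(r), dims))
  J <- length(raters)
  eps <- 1e-6

  union <- Reduce(`|`, raters)
  if (!any(union)) {
    return(structure(list(posterior = array(0, dims),
                          consensus = array(FALSE, dims),
                          p = rep(NA_real_, J), q = rep(NA_real_, J),
                          n_iterations = 0L, converged = TRUE,
                          log_likelihood = numeric(0)),
                     class = "staple_result"))
  }
  if (J == 1L) {
    post <- array(0, dims); post[raters[[1]]] <- 1
    return(structure(list(posterior = post, consensus = raters[[1]],
                          p = 1 - eps, q = 1 - eps, n_iterations = 0L,
                          converged = TRUE, log_likelihood = numeric(0)),
                     class = "staple_result"))
  }

  roi_core <- dilate_ball(union, spacing_mm, max(spacing_mm) + 1e-6)
  outside <- which(!roi_core)
  n_bg <- min(length(outside), sum(union))
  bg <- if (n_bg > 0)
    with_seed(bg_seed, sort(outside[sample.int(length(outside), n_bg)]))
  else integer(0)
  roi <- sort(c(which(roi_core), bg))

  D <- vapply(raters, function(r) as.numeric(r[roi]), numeric(length(roi)))
  pi0 <- mean(colMeans(D))
  p <- rep(0.9, J); q <- rep(0.9, J)
  clamp <- function(x) pmin(pmax(x, eps), 1 - eps)
  ll_trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  W <- NULL
  while (it < max_iter) {
    it <- it + 1L
    # E-step in log space
    la <- log(pi0) + D %*% log(p) + (1 - D) %*% log(1 - p)
    lb <- log(1 - pi0) + D %*% log(1 - q) + (1 - D) %*% log(q)
    m <- pmax(la, lb)
    denom <- exp(la - m) + exp(lb - m)
    W <- as.vector(exp(la - m) / denom)
    ll <- sum(m + log(denom))
    if (length(ll_trace) > 0 && ll < tail(ll_trace, 1) - 1e-8)
      stop_mdaqp("STAPLE log-likelihood decreased (%.6g -> %.6g)",
                 tail(ll_trace, 1), ll)
    ll_trace <- c(ll_trace, ll)
    # M-step
    sw <- sum(W); swc <- sum(1 - W)
    p_new <- clamp(as.vector(crossprod(D, W)) / sw)
    q_new <- clamp(as.vector(crossprod(1 - D, 1 - W)) / swc)
    delta <- max(abs(c(p_new - p, q_new - q)))
    p <- p_new; q <- q_new
    if (delta < tol) { converged <- TRUE; break }
  }
  posterior <- array(0, dims)
  posterior[roi] <- W
  structure(list(posterior = posterior, consensus = posterior >= 0.5,
                 p = p, q = q, n_iterations = it, converged = converged,
                 log_likelihood = ll_trace),
            class = "staple_result")
}

#' @export
print.staple_result <- function(x, ...) {
  cat(sprintf("<staple_result: %d iter (%s), consensus %d voxel(s), p in [%.3f, %.3f]>\n",
              x$n_iterations, if (x$converged) "converged" else "max_iter",
              sum(x$consensus),
              if (all(is.na(x$p))) NA else min(x$p), if (all(is.na(x$p))) NA else max(x$p)))
  invisible(x)
}

#' @rdname run_staple
#' @param x a `staple_result`.
#' @param ... unused.
#' @export
tidy.staple_result <- function(x, ...) {
  tibble(rater = seq_along(x$p), sensitivity = x$p, specificity = x$q)
}

#' @rdname run_staple
#' @export
glance.staple_result <- function(x, ...) {
  tibble(n_iterations = x$n_iterations, converged = x$converged,
         consensus_voxels = sum(x$consensus),
         log_likelihood = if (length(x$log_likelihood)) tail(x$log_likelihood, 1) else NA_real_)
}

#' Volume of the STAPLE consensus
#'
#' @param result a `staple_result`.
#' @param spacing_mm voxel spacing, mm.
#' @return Consensus volume in ml.
#' @export
consensus_volume <- function(result, spacing_mm) {
  stopifnot(inherits(result, "staple_result"))
  mask_volume_ml(result$consensus, spacing_mm)
}
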