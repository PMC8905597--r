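# Independent oracles, deliberately written as naive loops so they share no
# code path with the package implementation.

# --- brute-force surface distances -----------------------------------------

# border voxels by explicit neighbour loops (face connectivity, grid edge
# counts as outside); returns an n x 3 matrix of voxel indices
oracle_border <- function(mask) {
  dims <- dim(mask)
  out <- list()
  for (x in seq_len(dims[1])) for (y in seq_len(dims[2])) for (z in seq_len(dims[3])) {
    if (!mask[x, y, z]) next
    nb <- list(c(x - 1, y, z), c(x + 1, y, z), c(x, y - 1, z),
               c(x, y + 1, z), c(x, y, z - 1), c(x, y, z + 1))
    isb <- FALSE
    for (p in nb) {
      if (any(p < 1) || p[1] > dims[1] || p[2] > dims[2] || p[3] > dims[3] ||
          !mask[p[1], p[2], p[3]]) { isb <- TRUE; break }
    }
    if (isb) out[[length(out) + 1L]] <- c(x, y, z)
  }
  do.call(rbind, out)
}

# all-pairs O(n^2) Hausdorff and average symmetric surface distance
oracle_surface_distances <- function(test, reference, spacing) {
  sa <- oracle_border(test)
  sb <- oracle_border(reference)
  pa <- sweep(sa, 2, spacing, `*`)
  pb <- sweep(sb, 2, spacing, `*`)
  d_ab <- apply(pa, 1, function(p) min(sqrt(colSums((t(pb) - p)^2))))
  d_ba <- apply(pb, 1, function(p) min(sqrt(colSums((t(pa) - p)^2))))
  list(hd = max(max(d_ab), max(d_ba)), assd = mean(c(d_ab, d_ba)))
}

# --- independent STAPLE EM --------------------------------------------------

# Scalar-probability EM over an explicit voxel index set, looped per rater.
# Same conventions as the package (init 0.9/0.9, clamp 1e-6, prior = mean
# foreground fraction) but a separate arithmetic path (no log space, loops).
oracle_staple <- function(rater_masks, roi_idx, tol = 1e-6, max_iter = 100) {
  J <- length(rater_masks)
  D <- sapply(rater_masks, function(m) as.numeric(m[roi_idx]))
  n <- nrow(D)
  p <- rep(0.9, J); q <- rep(0.9, J)
  pi0 <- mean(D)
  clamp <- function(x) pmin(pmax(x, 1e-6), 1 - 1e-6)
  W <- numeric(n)
  for (it in seq_len(max_iter)) {
    for (i in seq_len(n)) {
      a <- pi0; b <- 1 - pi0
      for (j in seq_len(J)) {
        if (D[i, j] == 1) { a <- a * p[j]; b <- b * (1 - q[j]) }
        else { a <- a * (1 - p[j]); b <- b * q[j] }
      }
      W[i] <- a / (a + b)
    }
    p_new <- numeric(J); q_new <- numeric(J)
    for (j in seq_len(J)) {
      p_new[j] <- clamp(sum(W * D[, j]) / sum(W))
      q_new[j] <- clamp(sum((1 - W) * (1 - D[, j])) / sum(1 - W))
    }
    delta <- max(abs(c(p_new - p, q_new - q)))
    p <- p_new; q <- q_new
    if (delta < tol) break
  }
  list(W = W, p = p, q = q, n_iterations = it)
}

# Reproduce the package's ROI selection (dilated union + seeded background
# sample) so the EM comparison is voxel-for-voxel.
oracle_staple_roi <- function(rater_masks, spacing, bg_seed = 2023L) {
  union <- Reduce(`|`, rater_masks)
  roi_core <- distance_to_mm(union, spacing) <= max(spacing) + 1e-6
  outside <- which(!roi_core)
  n_bg <- min(length(outside), sum(union))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(bg_seed)
  bg <- sort(outside[sample.int(length(outside), n_bg)])
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  sort(c(which(roi_core), bg))
}

# --- ICC(2,1) by explicit ANOVA summation ----------------------------------

oracle_icc21 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- sum(m) / (n * k)
  ssr <- 0; ssc <- 0; sst <- 0
  for (i in seq_len(n)) ssr <- ssr + k * (mean(m[i, ]) - grand)^2
  for (j in seq_len(k)) ssc <- ssc + n * (mean(m[, j]) - grand)^2
  for (i in seq_len(n)) for (j in seq_len(k)) sst <- sst + (m[i, j] - grand)^2
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# --- shared fixtures --------------------------------------------------------

# small phantom spec used across tests to keep runtimes low
small_spec <- function(seed = 11L, ...) {
  phantom_spec(shape = c(56, 56, 56), seed = seed, ...)
}

# random blobby mask on a small grid (for metric property tests)
random_mask <- function(dims = c(12, 12, 12), p = 0.2) {
  m <- array(runif(prod(dims)) < p, dims)
  if (!any(m)) m[ceiling(dims[1] / 2), ceiling(dims[2] / 2), ceiling(dims[3] / 2)] <- TRUE
  m
}
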