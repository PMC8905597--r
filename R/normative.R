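#' Build a set of stand-in parcellation atlases
#'
#' The detector votes across several parcellations whose region boundaries
#' are decorrelated. Anatomical atlases are not distributed with the package;
#' for synthetic data it builds brain-restricted rectangular block partitions
#' at two block scales (default 12 and 20 mm, alternating across atlases)
#' with per-atlas random offsets, which reproduces the essential property:
#' each voxel is judged against several differently-bounded neighbourhoods.
#' Regions smaller than `min_region_vox` voxels are merged into their most
#' frequent neighbouring region.
#'
#' @param brain logical brain mask.
#' @param spacing_mm voxel spacing, mm.
#' @param n_atlases number of parcellations (default 6).
#' @param seed integer seed for the offsets.
#' @param block_mm the two block scales in mm.
#' @param min_region_vox minimum region size before merging (default 10).
#' @return An object of class `atlas_set`: list of integer label arrays
#'   (0 outside brain, regions numbered from 1), plus names.
#' @export
make_atlas_set <- function(brain, spacing_mm, n_atlases = 6, seed = 1L,
                           block_mm = c(12, 20), min_region_vox = 10) {
  stopifnot(is_logical_grid(brain), n_atlases >= 1)
  shape <- dim(brain)
  coords <- lapply(1:3, function(a) (seq_len(shape[a]) - 1) * spacing_mm[a])
  parcs <- with_seed(derive_seed(seed, "atlas-offsets"), {
    lapply(seq_len(n_atlases), function(a) {
      s <- block_mm[(a - 1L) %% length(block_mm) + 1L]
      off <- runif(3, 0, s)
      bx <- floor((coords[[1]] + off[1]) / s)
      by <- floor((coords[[2]] + off[2]) / s)
      bz <- floor((coords[[3]] + off[3]) / s)
      nbx <- max(bx) + 1L; nby <- max(by) + 1L
      block <- outer(outer(bx, by * nbx, `+`), bz * nbx * nby, `+`)
      lab <- array(0L, shape)
      lab[brain] <- as.integer(factor(block[brain]))
      merge_small_regions(lab, brain, min_region_vox)
    })
  })
  nreg <- vapply(parcs, function(p) max(p), integer(1))
  if (any(nreg < 20L))
    stop_mdaqp("brain too small: atlas %d has only %d regions (>= 20 required)",
               which.min(nreg), min(nreg))
  structure(list(parcellations = parcs,
                 names = sprintf("atlas%02d", seq_len(n_atlases)),
                 n = n_atlases),
            class = "atlas_set")
}

# Merge regions below `min_vox` voxels into their most frequent >0 neighbour
# (6-connectivity); repeats until stable.
merge_small_regions <- function(lab, brain, min_vox) {
  for (pass in 1:10) {
    counts <- tabulate(lab[lab > 0L])
    small <- which(counts > 0L & counts < min_vox)
    if (length(small) == 0L) break
    # neighbour labels via face shifts
    for (s in small) {
      sel <- lab == s
      nb <- integer(0)
      for (axis in 1:3) for (step in c(-1, 1)) {
        sh <- shift1(sel, axis, step)
        nb <- c(nb, lab[sh & lab > 0L & lab != s])
      }
      if (length(nb) > 0L) {
        lab[sel] <- as.integer(names(which.max(table(nb))))
      }
    }
    # relabel consecutively
    lab[brain] <- as.integer(factor(lab[brain]))
  }
  lab
}

#' @export
print.atlas_set <- function(x, ...) {
  cat(sprintf("<atlas_set: %d parcellations, %s regions>\n", x$n,
              paste(vapply(x$parcellations, max, integer(1)), collapse = "/")))
  invisible(x)
}

#' Fit the normative MD model from control subjects
#'
#' For every atlas and region, pools the MD values of all non-CSF brain
#' voxels across all controls and stores the mean, the sample (n-1) standard
#' deviation and the pooled voxel count. The per-region mean +/- z sd interval
#' is the "normal range" the detector tests against. Regions pooling fewer
#' than `min_pool` voxels are flagged low-confidence.
#'
#' @param controls list of [image_volume] MD maps (or [make_brain] outputs).
#' @param masks a [tissue_masks] shared by all controls, or a list of one per
#'   control. CSF voxels never enter the pool.
#' @param atlases an `atlas_set` (see [make_atlas_set()]) on the same grid.
#' @param z_threshold the z cutoff defining "outside the normal range"
#'   (default 3).
#' @param K vote threshold: abnormality must be seen in >= K atlases
#'   (default 4, clamped to the atlas count).
#' @param min_pool low-confidence flag threshold on pooled voxels (default 25).
#' @return An object of class `normative_model`.
#' @export
fit_normative <- function(controls, masks, atlases, z_threshold = 3, K = 4,
                          min_pool = 25) {
  stopifnot(inherits(atlases, "atlas_set"), length(controls) >= 1)
  controls <- lapply(controls, function(x) if (inherits(x, "image_volume")) x else x$md)
  if (inherits(masks, "tissue_masks")) masks <- rep(list(masks), length(controls))
  stopifnot(length(masks) == length(controls))
  for (i in seq_along(controls))
    check_same_grid(controls[[1]], controls[[i]])

  stats <- lapply(seq_len(atlases$n), function(a) {
    lab <- atlases$parcellations[[a]]
    labs <- integer(0); vals <- numeric(0)
    for (i in seq_along(controls)) {
      sel <- masks[[i]]$brain & !masks[[i]]$csf & lab > 0L
      labs <- c(labs, lab[sel])
      vals <- c(vals, controls[[i]]$data[sel])
    }
    nmax <- max(lab)
    n <- tabulate(labs, nbins = nmax)
    if (any(n == 0L)) {
      # a region may be entirely CSF: every brain voxel must map somewhere
      empty <- which(n == 0L)
      covered <- unique(lab[lab > 0L])
      truly <- intersect(empty, covered)
      if (length(truly) > 0L)
        stop_mdaqp("atlas %d region %d pooled zero voxels (all CSF?)", a, truly[1L])
    }
    s1 <- rowsum(vals, labs)[, 1]
    s2 <- rowsum(vals^2, labs)[, 1]
    reg <- as.integer(rownames(rowsum(vals, labs)))
    mean_v <- rep(NA_real_, nmax); sd_v <- rep(NA_real_, nmax)
    mean_v[reg] <- s1 / n[reg]
    var_v <- (s2 - s1^2 / n[reg]) / pmax(n[reg] - 1L, 1L)
    sd_v[reg] <- sqrt(pmax(var_v, 0))
    list(mean = mean_v, sd = sd_v, n = n)
  })
  low_conf <- do.call(rbind, lapply(seq_along(stats), function(a) {
    idx <- which(stats[[a]]$n > 0L & stats[[a]]$n < min_pool)
    if (length(idx) == 0L) return(NULL)
    tibble(atlas = a, region = idx, n = stats[[a]]$n[idx])
  }))
  structure(list(stats = stats, z_threshold = z_threshold,
                 N = atlases$n, K = min(as.integer(K), atlases$n),
                 n_controls = length(controls),
                 low_confidence = low_conf %||%
                   tibble(atlas = integer(), region = integer(), n = integer())),
            class = "normative_model")
}

#' @export
print.normative_model <- function(x, ...) {
  cat(sprintf("<normative_model: %d atlases, %d controls, z = %g, K = %d/%d, %d low-confidence region(s)>\n",
              length(x$stats), x$n_controls, x$z_threshold, x$K, x$N,
              nrow(x$low_confidence)))
  invisible(x)
}

#' Per-atlas z-score maps of an MD volume
#'
#' z(v) = (MD(v) - mean(region(v))) / sd(region(v)) per atlas. Regions with
#' sd = 0 yield z = 0 where MD equals the mean and +/- Inf otherwise (such a
#' voxel always counts as abnormal). Voxels outside the brain (label 0) get
#' z = 0.
#'
#' @param md [image_volume] MD map of the subject.
#' @param atlases `atlas_set` (see [make_atlas_set()]).
#' @param model `normative_model` (see [fit_normative()]) fitted on the same atlases.
#' @return List of numeric 3D arrays, one per atlas.
#' @export
zscore_map <- function(md, atlases, model) {
  stopifnot(inherits(md, "image_volume"), inherits(atlases, "atlas_set"),
            inherits(model, "normative_model"))
  if (length(model$stats) != atlases$n)
    stop_mdaqp("model has %d atlases, atlas set has %d", length(model$stats), atlases$n)
  lapply(seq_len(atlases$n), function(a) {
    lab <- atlases$parcellations[[a]]
    st <- model$stats[[a]]
    inb <- lab > 0L
    if (max(lab) > length(st$mean) || anyNA(st$mean[lab[inb]]))
      stop_mdaqp("atlas %d contains region(s) missing from the normative model", a)
    z <- array(0, dim(lab))
    mu <- st$mean[lab[inb]]
    sdv <- st$sd[lab[inb]]
    diff <- md$data[inb] - mu
    zi <- ifelse(sdv > 0, diff / sdv, ifelse(diff == 0, 0, Inf * sign(diff)))
    z[inb] <- zi
    z
  })
}

#' Serialise a normative model to JSON
#'
#' @param model a `normative_model` (see [fit_normative()]).
#' @param path output JSON path.
#' @return Invisibly, `path`.
#' @export
write_normative_json <- function(model, path) {
  out <- list(z_threshold = model$z_threshold, N = model$N, K = model$K,
              n_controls = model$n_controls,
              atlases = lapply(model$stats, function(st) {
                reg <- which(st$n > 0L)
                list(region = reg, mean = st$mean[reg], sd = st$sd[reg],
                     n = st$n[reg])
              }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a normative model from JSON
#'
#' @param path JSON path written by [write_normative_json].
#' @return A `normative_model` (see [fit_normative()]).
#' @export
read_normative_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  stats <- lapply(seq_len(x$N), function(a) {
    at <- if (is.data.frame(x$atlases)) x$atlases[a, ] else x$atlases[[a]]
    reg <- unlist(at$region); nmax <- max(reg)
    mean_v <- rep(NA_real_, nmax); sd_v <- rep(NA_real_, nmax)
    n <- integer(nmax)
    mean_v[reg] <- unlist(at$mean); sd_v[reg] <- unlist(at$sd)
    n[reg] <- unlist(at$n)
    list(mean = mean_v, sd = sd_v, n = n)
  })
  structure(list(stats = stats, z_threshold = x$z_threshold, N = x$N,
                 K = x$K, n_controls = x$n_controls,
                 low_confidence = tibble(atlas = integer(), region = integer(),
                                         n = integer())),
            class = "normative_model")
}
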