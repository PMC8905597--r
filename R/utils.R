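# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic sub-seed derivation: every stochastic stage draws from its own
# named substream so that adding a stage never perturbs the others.
# Kept strictly below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(root, stream, index = 0L) {
  stopifnot(is.numeric(root), length(root) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  s <- (abs(root) * 2654435761 + h * 97 + index * 1000003) %% 2147483629
  as.integer(s)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

stop_mdaqp <- function(msg, ..., class = "mdaqp_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

is_logical_grid <- function(x) is.array(x) && length(dim(x)) == 3L && is.logical(x)

# voxel volume in mm^3
voxel_volume_mm3 <- function(spacing) prod(spacing)

# mask voxel count -> millilitres
mask_volume_ml <- function(mask, spacing) sum(mask) * voxel_volume_mm3(spacing) / 1000

# voxel-index (1-based) centroid of a mask, in mm (0-based index * spacing)
mask_centroid_mm <- function(mask, spacing) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(c(NA_real_, NA_real_, NA_real_))
  (colMeans(idx) - 1) * spacing
}
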