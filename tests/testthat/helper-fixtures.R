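# Small deterministic fixtures shared across test files.

const_volume <- function(value, dims = c(8, 8, 8), spacing = c(1, 1, 1)) {
  volume(array(value, dims), spacing = spacing)
}

noise_volume <- function(dims = c(12, 12, 12), seed = 1, spacing = c(1, 1, 1)) {
  set.seed(seed)
  volume(array(rnorm(prod(dims), 100, 10), dims), spacing = spacing)
}

sphere_mask <- function(radius_mm, dims, spacing = c(1, 1, 1),
                        center = NULL) {
  if (is.null(center)) center <- (dims - 1) / 2 * spacing
  ax <- arrayInd(seq_len(prod(dims)), dims)
  d2 <- ((ax[, 1] - 1) * spacing[1] - center[1])^2 +
        ((ax[, 2] - 1) * spacing[2] - center[2])^2 +
        ((ax[, 3] - 1) * spacing[3] - center[3])^2
  region_mask(array(d2 <= radius_mm^2, dims), spacing = spacing)
}

cube_mask <- function(dims, lo, hi, spacing = c(1, 1, 1)) {
  a <- array(FALSE, dims)
  a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  region_mask(a, spacing = spacing)
}

# A tiny rendered cohort for plumbing tests (fast; not tuned for habitat
# recovery).
tiny_cohort_config <- function(n = 3, seed = 1, grid = 36) {
  cohort_config(n_patients = n, grid_dim = grid,
                tumor_radius_range_mm = list(low = c(6, 8), high = c(7, 9)),
                seed = seed)
}

# Synthetic local_feature_map built directly from a point cloud, for habitat
# model tests that do not need image rendering.
fake_feature_map <- function(values, dims = c(50, 50, 50)) {
  n <- nrow(values)
  colnames(values) <- local_channel_names()
  structure(list(values = values, valid = rep(TRUE, n), index = seq_len(n),
                 support = rep(125L, n), window = 5L, dim = as.integer(dims),
                 spacing = c(1, 1, 1), channel_names = local_channel_names()),
            class = "local_feature_map")
}

blob_points <- function(n_per, centers, sd = 0.5, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    matrix(rnorm(n_per * ncol(centers), mean = rep(centers[i, ], each = n_per),
                 sd = sd), n_per)))
}
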