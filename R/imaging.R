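#' Resample a volume (and its masks) to isotropic spacing
#'
#' Images are interpolated trilinearly, masks by nearest neighbor, onto a grid
#' with the requested spacing covering the same physical extent. Standard first
#' step of the preprocessing chain so that ring distances, window sizes and
#' shape features are comparable across patients.
#'
#' @param vol a [volume()].
#' @param masks a named list of [region_mask()] objects on the same grid (may
#'   be empty).
#' @param target_spacing_mm target isotropic voxel size (default 1 mm).
#' @return list with elements `volume` and `masks` on the new grid.
#' @export
resample_isotropic <- function(vol, masks = list(), target_spacing_mm = 1.0) {
  stopifnot(inherits(vol, "hab_volume"), target_spacing_mm > 0)
  d <- dim(vol$array)
  if (any(d < 1)) stop("degenerate volume: zero extent")
  extent <- (d - 1) * vol$spacing
  out_dim <- pmax(as.integer(floor(extent / target_spacing_mm)) + 1L, 1L)
  out_sp <- rep(target_spacing_mm, 3)
  arr <- resample_cpp(as.numeric(vol$array), d, vol$spacing, vol$origin,
                      out_dim, out_sp, vol$origin, nearest = FALSE)
  new_vol <- volume(array(arr, out_dim), spacing = out_sp, origin = vol$origin)
  new_masks <- lapply(masks, function(m) {
    stopifnot(inherits(m, "hab_mask"))
    a <- resample_cpp(as.numeric(m$array), d, m$spacing, m$origin,
                      out_dim, out_sp, m$origin, nearest = TRUE)
    region_mask(array(a > 0.5, out_dim), spacing = out_sp, origin = m$origin,
                role = m$role)
  })
  list(volume = new_vol, masks = new_masks)
}

#' Estimate and remove a smooth multiplicative bias field
#'
#' Default backend: a low-order (degree <= 3) polynomial is fitted to the log
#' intensities over the body region and divided out, normalised to mean one so
#' the overall intensity scale is preserved. An external correction (e.g. a
#' full N4 implementation) can be plugged in via `backend`.
#'
#' @param vol a [volume()].
#' @param mask [region_mask()] of the region over which the field is fitted
#'   (typically the body mask).
#' @param degree polynomial degree of the fitted field (<= 3).
#' @param backend `"polynomial"` or a function `(vol, mask) -> hab_volume`.
#' @return Corrected `hab_volume`.
#' @export
correct_bias <- function(vol, mask, degree = 3, backend = "polynomial") {
  stopifnot(inherits(vol, "hab_volume"), inherits(mask, "hab_mask"))
  if (mask_count(mask) == 0) stop("bias correction requires a nonempty mask")
  if (is.function(backend)) return(backend(vol, mask))
  stopifnot(identical(backend, "polynomial"), degree >= 1, degree <= 3)

  arr <- vol$array
  shift <- 0
  inside <- which(mask$array)
  if (any(arr[inside] <= 0)) {
    shift <- -min(arr[inside]) + 1e-3 * max(abs(arr[inside]), 1)
    warning("non-positive intensities in mask; shifting before log-domain fit")
  }
  d <- dim(arr)
  # fit on an evenly strided subsample of mask voxels (deterministic)
  fit_idx <- inside
  if (length(fit_idx) > 2e4)
    fit_idx <- fit_idx[unique(round(seq(1, length(fit_idx),
                                        length.out = 2e4)))]
  coords <- arrayInd(fit_idx, d)
  # normalized coordinates in [-1, 1] keep the monomial basis well-conditioned
  nc <- sweep(sweep(coords, 2, (d + 1) / 2), 2, pmax((d - 1) / 2, 1), "/")
  basis <- poly_basis_3d(nc, degree)
  y <- log(arr[fit_idx] + shift)
  fit <- lm.fit(basis, y)
  logfield <- eval_poly3d(d, fit$coefficients, degree)
  logfield <- logfield - mean(logfield[inside])
  corrected <- (arr + shift) / array(exp(logfield), d) - shift
  volume(corrected, spacing = vol$spacing, origin = vol$origin)
}

poly_terms_3d <- function(degree) {
  terms <- list(c(0, 0, 0))
  for (i in 0:degree) for (j in 0:degree) for (k in 0:degree) {
    if (i + j + k == 0 || i + j + k > degree) next
    terms[[length(terms) + 1L]] <- c(i, j, k)
  }
  terms
}

poly_basis_3d <- function(nc, degree) {
  do.call(cbind, lapply(poly_terms_3d(degree), function(t)
    nc[, 1]^t[1] * nc[, 2]^t[2] * nc[, 3]^t[3]))
}

# Evaluate the fitted polynomial over a full grid using axis separability.
eval_poly3d <- function(d, coef, degree) {
  axn <- lapply(1:3, function(a)
    ((seq_len(d[a]) - (d[a] + 1) / 2) / max((d[a] - 1) / 2, 1)))
  terms <- poly_terms_3d(degree)
  out <- numeric(prod(d))
  xi <- rep_len(seq_len(d[1]), prod(d))
  yi <- rep(rep(seq_len(d[2]), each = d[1]), times = d[3])
  zi <- rep(seq_len(d[3]), each = d[1] * d[2])
  for (u in seq_along(terms)) {
    t <- terms[[u]]
    out <- out + coef[u] * (axn[[1]]^t[1])[xi] * (axn[[2]]^t[2])[yi] *
      (axn[[3]]^t[3])[zi]
  }
  out
}

#' Z-score intensity normalization over a region
#'
#' Normalizes the whole volume with the mean and SD computed over `mask`
#' (typically the body region, so habitat intensity contrasts stay comparable
#' across patients), then rescales by `scale`. With the default `scale = 100`
#' the fixed bin width of 25 used for texture discretization spans the
#' intensity distribution in a few dozen bins.
#'
#' @param vol a [volume()].
#' @param mask normalization region.
#' @param scale multiplier applied after z-scoring (default 100).
#' @return Normalized `hab_volume`.
#' @export
normalize_intensity <- function(vol, mask, scale = 100) {
  stopifnot(inherits(vol, "hab_volume"), inherits(mask, "hab_mask"))
  v <- vol$array[mask$array]
  s <- sd(v)
  if (!is.finite(s) || s == 0)
    stop("cannot normalize: zero intensity SD over region '", mask$role, "'")
  volume((vol$array - mean(v)) / s * scale, spacing = vol$spacing,
         origin = vol$origin)
}

#' Body (non-air) mask by Otsu thresholding
#'
#' @param vol a [volume()].
#' @param n_breaks histogram resolution.
#' @return A `hab_mask` with role `"body"`.
#' @export
body_mask <- function(vol, n_breaks = 256) {
  x <- as.numeric(vol$array)
  thr <- otsu_threshold(x, n_breaks)
  region_mask(array(vol$array > thr, dim(vol$array)), spacing = vol$spacing,
              origin = vol$origin, role = "body")
}

otsu_threshold <- function(x, n_breaks = 256) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = n_breaks + 1)
  h <- tabulate(findInterval(x, br, all.inside = TRUE), nbins = n_breaks)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_breaks]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Peritumoral ring mask at a physical distance
#'
#' The ring holds every voxel outside the tumor whose center lies within
#' `distance_mm` (inclusive) of the nearest tumor voxel center, measured as
#' Euclidean distance in physical mm via an exact distance transform. Rings
#' are disjoint from the tumor and clipped at the image boundary; rings nest
#' monotonically in distance.
#'
#' @param tumor_mask a [region_mask()] with nonempty foreground.
#' @param distance_mm outward distance in mm (> 0); the study grid is
#'   1–5 mm.
#' @param clip_mask optional mask (e.g. body) the ring is intersected with.
#' @return A `hab_mask` with role `"ring_<d>mm"`.
#' @export
peritumoral_ring <- function(tumor_mask, distance_mm, clip_mask = NULL) {
  stopifnot(inherits(tumor_mask, "hab_mask"))
  if (distance_mm <= 0) stop("ring distance must be positive")
  if (mask_count(tumor_mask) == 0) stop("tumor mask is empty")
  d2 <- edt_sq_cpp(as.logical(tumor_mask$array), dim(tumor_mask$array),
                   tumor_mask$spacing)
  ring <- array(d2 > 0 & d2 <= distance_mm^2 + 1e-9, dim(tumor_mask$array))
  if (!is.null(clip_mask)) ring <- ring & clip_mask$array
  region_mask(ring, spacing = tumor_mask$spacing, origin = tumor_mask$origin,
              role = sprintf("ring_%gmm", distance_mm))
}

#' Standard preprocessing chain
#'
#' Bias correction, isotropic resampling, then intensity normalization, in
#' that fixed order. Returns the processed volume, resampled masks and a
#' provenance record of the steps applied.
#'
#' @param vol a [volume()].
#' @param masks named list of masks on the same grid.
#' @param target_spacing_mm isotropic target (default 1 mm).
#' @param bias_degree polynomial degree for [correct_bias()].
#' @param normalize_scale passed to [normalize_intensity()].
#' @return list(volume, masks, body, provenance)
#' @export
preprocess_volume <- function(vol, masks = list(), target_spacing_mm = 1.0,
                              bias_degree = 3, normalize_scale = 100) {
  body0 <- body_mask(vol)
  v1 <- correct_bias(vol, body0, degree = bias_degree)
  rs <- resample_isotropic(v1, masks, target_spacing_mm)
  body <- body_mask(rs$volume)
  v2 <- normalize_intensity(rs$volume, body, scale = normalize_scale)
  list(volume = v2, masks = rs$masks, body = body,
       provenance = list(order = c("bias", "resample", "normalize"),
                         target_spacing_mm = target_spacing_mm,
                         bias_degree = bias_degree,
                         normalize_scale = normalize_scale))
}
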