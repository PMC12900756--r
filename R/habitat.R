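#' The 19 sliding-window first-order channels
#' @return Character vector of channel names, in storage order.
#' @export
local_channel_names <- function() {
  c("Energy", "TotalEnergy", "Entropy", "Minimum", "10Percentile",
    "90Percentile", "Maximum", "Mean", "Median", "InterquartileRange",
    "Range", "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
    "RootMeanSquared", "StandardDeviation", "Skewness", "Kurtosis",
    "Variance", "Uniformity")
}

#' Voxel-wise local first-order feature map
#'
#' For every tumor voxel, 19 first-order statistics are computed over the
#' intensities of the in-window, in-mask neighborhood (window 5x5x5 by
#' default). Voxels with fewer than `min_support` in-mask neighbors are
#' flagged invalid and excluded from model fitting; they are later labeled
#' from their nearest valid neighbor.
#'
#' @param vol preprocessed [volume()].
#' @param tumor_mask [region_mask()], nonempty.
#' @param window odd window edge length in voxels (default 5).
#' @param bin_width fixed bin width for the entropy/uniformity histogram
#'   (default 25, on the package's x100 normalized intensity scale).
#' @param min_support minimum in-mask neighbor count for a valid voxel.
#' @return A `local_feature_map`: list with `values` (n_voxels x 19 matrix),
#'   `valid` (logical), `index` (linear voxel indices into the grid), `dim`,
#'   `spacing`, `channel_names`.
#' @export
local_feature_maps <- function(vol, tumor_mask, window = 5, bin_width = 25,
                               min_support = 8) {
  stopifnot(inherits(vol, "hab_volume"), inherits(tumor_mask, "hab_mask"))
  if (window %% 2 == 0) stop("window must be odd")
  if (mask_count(tumor_mask) == 0) stop("tumor mask is empty")
  res <- local_stats_cpp(as.numeric(vol$array), as.logical(tumor_mask$array),
                         dim(vol$array), as.integer(window), bin_width,
                         as.integer(min_support), voxel_volume_mm3(vol))
  colnames(res$values) <- local_channel_names()
  structure(list(values = res$values, valid = res$valid, index = res$index,
                 support = res$support, window = as.integer(window),
                 dim = dim(vol$array), spacing = vol$spacing,
                 channel_names = local_channel_names()),
            class = "local_feature_map")
}

#' Calinski-Harabasz index
#'
#' `CH = (B / (k - 1)) / (W / (n - k))` with `B` the between-cluster and `W`
#' the within-cluster sum of squared deviations. Used to pick the cluster
#' count for habitat segmentation.
#'
#' @param points numeric matrix (n x d) or vector.
#' @param labels cluster assignment, one per row; >= 2 nonempty clusters.
#' @return The CH score; `Inf` when `W = 0`.
#' @export
calinski_harabasz <- function(points, labels) {
  points <- as.matrix(points)
  labels <- as.factor(labels)
  n <- nrow(points)
  k <- nlevels(labels)
  if (k < 2) stop("CH index requires at least 2 clusters")
  if (any(tabulate(labels) == 0)) stop("every cluster must be nonempty")
  if (n <= k) stop("need more points than clusters")
  gmean <- colMeans(points)
  W <- 0; B <- 0
  for (lv in levels(labels)) {
    sub <- points[labels == lv, , drop = FALSE]
    cm <- colMeans(sub)
    W <- W + sum(sweep(sub, 2, cm)^2)
    B <- B + nrow(sub) * sum((cm - gmean)^2)
  }
  if (W == 0) return(Inf)
  (B / (k - 1)) / (W / (n - k))
}

#' Fit a cohort-level habitat model
#'
#' Pools the valid voxels of the training patients' local feature maps,
#' z-scores each channel with pooled statistics, subsamples voxels, and fits
#' K-means (k-means++-style multi-start via `nstart`) for every k in
#' `k_range`. The k maximizing the CH index on the subsample is selected.
#' Clusters are relabeled H1..Hk by descending center value of the windowed
#' Mean channel, so H1 is the strongest-enhancing habitat.
#'
#' @param feature_maps list of `local_feature_map` objects (training
#'   patients).
#' @param k_range candidate cluster counts (default 2:10).
#' @param voxel_subsample cap on pooled voxels used for fitting (default
#'   2e4).
#' @param n_init K-means restarts (default 10).
#' @param fit_support minimum in-window neighbor count for a voxel to enter
#'   the fit and to receive a direct (nearest-center) label during
#'   assignment; the default 0 uses every valid voxel.
#' @param seed RNG seed.
#' @return A `habitat_model`: k, centers (k x 19, standardized space),
#'   scaler (center/scale per channel), label_order, ch_scores, seed.
#' @export
fit_habitat_model <- function(feature_maps, k_range = 2:10,
                              voxel_subsample = 2e4, n_init = 10,
                              fit_support = 0, seed = 1L) {
  stopifnot(all(k_range >= 2), all(k_range <= 10))
  pooled <- do.call(rbind, lapply(feature_maps, function(fm) {
    keep <- fm$valid & fm$support >= fit_support
    if (!any(keep)) keep <- fm$valid  # tiny tumors: fall back to all valid
    fm$values[keep, , drop = FALSE]
  }))
  if (nrow(pooled) < max(k_range) * 50)
    stop("insufficient valid voxels to fit a habitat model")
  ctr <- colMeans(pooled)
  scl <- apply(pooled, 2, sd)
  scl[scl == 0] <- 1
  z <- sweep(sweep(pooled, 2, ctr), 2, scl, "/")

  set.seed(seed)
  if (nrow(z) > voxel_subsample)
    z <- z[sample.int(nrow(z), voxel_subsample), , drop = FALSE]

  ch <- setNames(numeric(length(k_range)), k_range)
  fits <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    set.seed(seed + k)
    fits[[i]] <- kmeans(z, centers = k, nstart = n_init, iter.max = 100)
    ch[i] <- calinski_harabasz(z, fits[[i]]$cluster)
  }
  best <- which.max(ch)
  fit <- fits[[best]]
  k <- k_range[best]
  # H1..Hk by descending windowed-mean-intensity center
  ord <- order(fit$centers[, "Mean"], decreasing = TRUE)
  centers <- fit$centers[ord, , drop = FALSE]
  rownames(centers) <- paste0("h", seq_len(k))
  structure(list(k = k, centers = centers,
                 scaler = list(center = ctr, scale = scl),
                 label_order = ord, ch_scores = ch, seed = seed,
                 fit_support = fit_support,
                 channel_names = colnames(pooled)),
            class = "habitat_model")
}

#' @export
print.habitat_model <- function(x, ...) {
  cat("<habitat_model> k =", x$k, "(CH-selected over",
      paste(range(as.integer(names(x$ch_scores))), collapse = "-"), ")\n")
  invisible(x)
}

#' Assign habitat labels to a patient
#'
#' Voxels whose window support meets the model's fitting threshold go to the
#' nearest model center (Euclidean distance in the standardized channel
#' space); invalid and partial-window voxels — whose sum-type channels carry
#' a support artifact the centers never saw — inherit the label of their
#' nearest directly-assigned neighbor by breadth-first propagation. The
#' result partitions the tumor mask.
#'
#' @param model a fitted [fit_habitat_model()] object.
#' @param feature_map the patient's [local_feature_maps()].
#' @param tumor_mask the patient's tumor mask.
#' @param assign_support minimum window support for direct nearest-center
#'   assignment (default: the complete window). Voxels below it — the
#'   mask-edge band, whose truncated windows sample asymmetrically inward —
#'   inherit labels from their nearest directly-assigned neighbor.
#' @return A `habitat_map`: `labels` (integer array, 0 background, 1..k),
#'   `counts`, `fractions`.
#' @export
assign_habitats <- function(model, feature_map, tumor_mask,
                            assign_support = NULL) {
  if (is.null(assign_support)) assign_support <- feature_map$window^3
  stopifnot(inherits(model, "habitat_model"),
            inherits(feature_map, "local_feature_map"),
            identical(feature_map$dim, dim(tumor_mask$array)))
  if (mask_count(tumor_mask) == 0) stop("tumor mask is empty")
  z <- sweep(sweep(feature_map$values, 2, model$scaler$center), 2,
             model$scaler$scale, "/")
  # squared distance to each center: ||z||^2 - 2 z.c + ||c||^2
  cc <- rowSums(model$centers^2)
  d2 <- -2 * z %*% t(model$centers)
  d2 <- sweep(d2, 2, cc, "+")
  lab <- max.col(-d2, ties.method = "first")

  direct <- feature_map$valid & feature_map$support >= assign_support
  if (!any(direct)) direct <- feature_map$valid
  labels <- integer(prod(feature_map$dim))
  labels[feature_map$index[direct]] <- lab[direct]
  labels <- array(labels, feature_map$dim)
  labels <- array(label_fill_cpp(as.integer(labels),
                                 as.logical(tumor_mask$array),
                                 feature_map$dim), feature_map$dim)
  counts <- setNames(tabulate(labels[labels > 0], nbins = model$k),
                     rownames(model$centers))
  structure(list(labels = labels, counts = counts,
                 fractions = counts / sum(counts)),
            class = "habitat_map")
}

#' Per-habitat region masks from a habitat map
#' @param habitat_map from [assign_habitats()].
#' @param tumor_mask the tumor mask supplying grid geometry.
#' @return Named list of `hab_mask` objects (`h1`, `h2`, ...), possibly with
#'   empty foregrounds for absent habitats.
#' @export
habitat_masks <- function(habitat_map, tumor_mask) {
  k <- length(habitat_map$counts)
  out <- lapply(seq_len(k), function(h)
    region_mask(habitat_map$labels == h, spacing = tumor_mask$spacing,
                origin = tumor_mask$origin, role = paste0("habitat_h", h)))
  names(out) <- paste0("h", seq_len(k))
  out
}
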