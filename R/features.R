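#' Extraction configuration
#'
#' Fixes the filter bank and discretization so that the feature count per
#' region is a pure function of this object: 14 shape features plus 91
#' intensity features (18 first-order + 22 GLCM + 16 GLRLM + 16 GLSZM +
#' 5 NGTDM + 14 GLDM) on each of 11 image types (original, 8 stationary
#' 3-D Haar wavelet sub-bands, LoG at two sigmas) = 1,015 features.
#'
#' @param bin_width fixed bin width for gray-level discretization (default
#'   25, on the x100 normalized intensity scale).
#' @param log_sigmas_mm LoG scales in mm (default `c(2, 3)`).
#' @param min_voxels masks smaller than this yield a missing-flagged vector.
#' @param gldm_alpha gray-level tolerance for GLDM dependence.
#' @return An `extraction_config` list.
#' @export
extraction_config <- function(bin_width = 25, log_sigmas_mm = c(2, 3),
                              min_voxels = 10, gldm_alpha = 0) {
  structure(list(bin_width = bin_width, log_sigmas_mm = log_sigmas_mm,
                 min_voxels = min_voxels, gldm_alpha = gldm_alpha),
            class = "extraction_config")
}

feature_class_names <- function() {
  list(
    shape = c("MeshVolume", "VoxelVolume", "SurfaceArea", "SurfaceVolumeRatio",
              "Sphericity", "Maximum3DDiameter", "Maximum2DDiameterSlice",
              "Maximum2DDiameterColumn", "Maximum2DDiameterRow",
              "MajorAxisLength", "MinorAxisLength", "LeastAxisLength",
              "Elongation", "Flatness"),
    firstorder = setdiff(local_channel_names(), "StandardDeviation"),
    glcm = c("Autocorrelation", "JointAverage", "ClusterProminence",
             "ClusterShade", "ClusterTendency", "Contrast", "Correlation",
             "DifferenceAverage", "DifferenceEntropy", "DifferenceVariance",
             "JointEnergy", "JointEntropy", "Imc1", "Imc2", "Idm", "Idmn",
             "Id", "Idn", "InverseVariance", "MaximumProbability",
             "SumEntropy", "SumSquares"),
    glrlm = c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
              "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
              "RunLengthNonUniformityNormalized", "RunPercentage",
              "GrayLevelVariance", "RunVariance", "RunEntropy",
              "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
              "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
              "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis"),
    glszm = c("SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
              "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
              "SizeZoneNonUniformityNormalized", "ZonePercentage",
              "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
              "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
              "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
              "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis"),
    ngtdm = c("Coarseness", "Contrast", "Busyness", "Complexity", "Strength"),
    gldm = c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
             "GrayLevelNonUniformity", "DependenceNonUniformity",
             "DependenceNonUniformityNormalized", "GrayLevelVariance",
             "DependenceVariance", "DependenceEntropy", "LowGrayLevelEmphasis",
             "HighGrayLevelEmphasis", "SmallDependenceLowGrayLevelEmphasis",
             "SmallDependenceHighGrayLevelEmphasis",
             "LargeDependenceLowGrayLevelEmphasis",
             "LargeDependenceHighGrayLevelEmphasis"))
}

filter_tags <- function(config) {
  c("original",
    paste0("wavelet-", c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")),
    sprintf("log-sigma-%g-mm", config$log_sigmas_mm))
}

#' Feature names produced by a configuration
#'
#' Names follow `region|filter|class|name`; shape features appear only under
#' the `original` filter. [parse_feature_name()] round-trips them.
#'
#' @param config an [extraction_config()].
#' @param region region tag prefixed to every name.
#' @return Character vector (length 1,015 with the default bank).
#' @export
feature_names <- function(config = extraction_config(), region = "intra") {
  cls <- feature_class_names()
  out <- paste("original", "shape", cls$shape, sep = "|")
  for (ft in filter_tags(config))
    for (cl in setdiff(names(cls), "shape"))
      out <- c(out, paste(ft, cl, cls[[cl]], sep = "|"))
  paste(region, out, sep = "|")
}

#' @rdname feature_names
#' @param x character vector of feature names.
#' @return `parse_feature_name`: data.frame with columns `region`,
#'   `image_filter`, `feature_class`, `base_name`.
#' @export
parse_feature_name <- function(x) {
  parts <- strsplit(x, "|", fixed = TRUE)
  if (any(lengths(parts) != 4)) stop("malformed feature name")
  data.frame(region = vapply(parts, `[`, "", 1),
             image_filter = vapply(parts, `[`, "", 2),
             feature_class = vapply(parts, `[`, "", 3),
             base_name = vapply(parts, `[`, "", 4),
             stringsAsFactors = FALSE)
}

feature_region <- function(x) {
  vapply(strsplit(x, "|", fixed = TRUE), `[`, "", 1)
}

# ---------------------------------------------------------------------------
# Discretization and per-class feature computation
# ---------------------------------------------------------------------------

discretize_levels <- function(values, bin_width) {
  b <- floor(values / bin_width)
  as.integer(b - min(b) + 1L)
}

firstorder_features <- function(values, voxvol, bin_width) {
  n <- length(values)
  mean_v <- mean(values)
  m2 <- mean((values - mean_v)^2)
  m3 <- mean((values - mean_v)^3)
  m4 <- mean((values - mean_v)^4)
  qs <- quantile(values, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE)
  inr <- values >= qs[1] & values <= qs[5]
  rmad <- if (any(inr)) mean(abs(values[inr] - mean(values[inr]))) else 0
  lev <- discretize_levels(values, bin_width)
  p <- tabulate(lev) / n
  p <- p[p > 0]
  c(Energy = sum(values^2),
    TotalEnergy = sum(values^2) * voxvol,
    Entropy = -sum(p * log2(p)),
    Minimum = min(values),
    `10Percentile` = qs[1],
    `90Percentile` = qs[5],
    Maximum = max(values),
    Mean = mean_v,
    Median = qs[3],
    InterquartileRange = qs[4] - qs[2],
    Range = max(values) - min(values),
    MeanAbsoluteDeviation = mean(abs(values - mean_v)),
    RobustMeanAbsoluteDeviation = rmad,
    RootMeanSquared = sqrt(mean(values^2)),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2))
}

glcm_features <- function(level_arr, dims, ng) {
  counts <- glcm_counts_cpp(level_arr, dims, ng)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  kdiff <- abs(i - j)
  kdv <- as.vector(kdiff) + 1L           # groups 1..ng
  ksv <- as.vector(i + j) - 1L           # groups 1..2ng-1
  feats <- matrix(NA_real_, 13, 22)
  for (d in 1:13) {
    P <- matrix(counts[, , d], ng, ng)
    tot <- sum(P)
    if (tot == 0) next
    p <- P / tot
    px <- rowSums(p)
    mu <- sum(i * p)
    sig2 <- sum((i - mu)^2 * p)
    pd <- p[p > 0]
    hxy <- -sum(pd * log2(pd))
    hx <- -sum(px[px > 0] * log2(px[px > 0]))
    ppxy <- outer(px, px)
    ok <- p > 0 & ppxy > 0
    hxy1 <- -sum(p[ok] * log2(ppxy[ok]))
    ok2 <- ppxy > 0
    hxy2 <- -sum(ppxy[ok2] * log2(ppxy[ok2]))
    pv <- as.vector(p)
    pxmy <- numeric(ng)
    tmp <- rowsum(pv, kdv)
    pxmy[as.integer(rownames(tmp))] <- tmp
    pxpy <- numeric(2 * ng - 1)
    tmp <- rowsum(pv, ksv)
    pxpy[as.integer(rownames(tmp))] <- tmp
    da <- sum((0:(ng - 1)) * pxmy)
    imc1 <- if (max(hx, hx) > 0) (hxy - hxy1) / hx else 0
    imc2v <- 1 - exp(-2 * (hxy2 - hxy))
    feats[d, ] <- c(
      sum(i * j * p),                               # Autocorrelation
      mu,                                           # JointAverage
      sum((i + j - 2 * mu)^4 * p),                  # ClusterProminence
      sum((i + j - 2 * mu)^3 * p),                  # ClusterShade
      sum((i + j - 2 * mu)^2 * p),                  # ClusterTendency
      sum((i - j)^2 * p),                           # Contrast
      if (sig2 > 0) (sum(i * j * p) - mu^2) / sig2 else 1,  # Correlation
      da,                                           # DifferenceAverage
      -sum(pxmy[pxmy > 0] * log2(pxmy[pxmy > 0])),  # DifferenceEntropy
      sum(((0:(ng - 1)) - da)^2 * pxmy),            # DifferenceVariance
      sum(p^2),                                     # JointEnergy
      hxy,                                          # JointEntropy
      imc1,                                         # Imc1
      if (imc2v > 0) sqrt(imc2v) else 0,            # Imc2
      sum(p / (1 + (i - j)^2)),                     # Idm
      sum(p / (1 + ((i - j) / ng)^2)),              # Idmn
      sum(p / (1 + abs(i - j))),                    # Id
      sum(p / (1 + abs(i - j) / ng)),               # Idn
      sum(p[i != j] / (i - j)[i != j]^2),           # InverseVariance
      max(p),                                       # MaximumProbability
      -sum(pxpy[pxpy > 0] * log2(pxpy[pxpy > 0])),  # SumEntropy
      sig2)                                         # SumSquares
  }
  setNames(colMeans(feats, na.rm = TRUE), feature_class_names()$glcm)
}

rl_matrix_features <- function(P, np, names) {
  # shared engine for GLRLM (runs) and GLSZM (zones): P is ng x max_size
  ns <- sum(P)
  ng <- nrow(P)
  i <- matrix(seq_len(ng), ng, ncol(P))
  r <- t(matrix(seq_len(ncol(P)), ncol(P), ng))
  p <- P / ns
  mu_i <- sum(i * p)
  mu_r <- sum(r * p)
  pg <- rowSums(P)
  pr <- colSums(P)
  pd <- p[p > 0]
  setNames(c(
    sum(P / r^2) / ns,                     # Short emphasis
    sum(P * r^2) / ns,                     # Long emphasis
    sum(pg^2) / ns,                        # GrayLevelNonUniformity
    sum(pg^2) / ns^2,                      # GLN normalized
    sum(pr^2) / ns,                        # Size/run nonuniformity
    sum(pr^2) / ns^2,                      # normalized
    ns / np,                               # Percentage
    sum(p * (i - mu_i)^2),                 # GrayLevelVariance
    sum(p * (r - mu_r)^2),                 # Run/zone variance
    -sum(pd * log2(pd)),                   # Entropy
    sum(P / i^2) / ns,                     # Low gray emphasis
    sum(P * i^2) / ns,                     # High gray emphasis
    sum(P / (i^2 * r^2)) / ns,             # Short+low
    sum(P * i^2 / r^2) / ns,               # Short+high
    sum(P * r^2 / i^2) / ns,               # Long+low
    sum(P * r^2 * i^2) / ns), names)
}

glrlm_features <- function(level_arr, dims, ng, np) {
  counts <- glrlm_counts_cpp(level_arr, dims, ng)
  nr <- dim(counts)[2]
  feats <- matrix(NA_real_, 13, 16)
  for (d in 1:13) {
    P <- matrix(counts[, , d], ng, nr)
    if (sum(P) == 0) next
    feats[d, ] <- rl_matrix_features(P, np, feature_class_names()$glrlm)
  }
  setNames(colMeans(feats, na.rm = TRUE), feature_class_names()$glrlm)
}

glszm_features <- function(level_arr, dims, ng, np) {
  zones <- glszm_zones_cpp(level_arr, dims)
  smax <- max(zones[, 2])
  P <- matrix(0, ng, smax)
  for (u in seq_len(nrow(zones))) P[zones[u, 1], zones[u, 2]] <-
      P[zones[u, 1], zones[u, 2]] + 1
  rl_matrix_features(P, np, feature_class_names()$glszm)
}

ngtdm_features <- function(level_arr, dims, ng) {
  M <- ngtdm_cpp(level_arr, dims, ng)
  n_i <- M[, 1]; s_i <- M[, 2]
  nv <- sum(n_i)
  p_i <- n_i / nv
  pres <- which(p_i > 0)
  ngp <- length(pres)
  iv <- seq_len(ng)
  coarse_den <- sum(p_i * s_i)
  coarseness <- if (coarse_den > 0) 1 / coarse_den else 1e6
  if (ngp > 1) {
    pi_p <- p_i[pres]; ii <- iv[pres]; si <- s_i[pres]
    dif2 <- outer(ii, ii, function(a, b) (a - b)^2)
    contrast <- sum(outer(pi_p, pi_p) * dif2) / (ngp * (ngp - 1)) * sum(s_i) / nv
    bus_den <- sum(abs(outer(ii * pi_p, ii * pi_p, "-")))
    busyness <- if (bus_den > 0) sum(pi_p * si) / bus_den else 0
    absdif <- abs(outer(ii, ii, "-"))
    psum <- outer(pi_p, pi_p, "+")
    pss <- outer(pi_p * si, pi_p * si, "+")
    complexity <- sum(absdif * pss / psum) / nv
    strength_num <- sum(psum * dif2)
    strength <- if (sum(s_i) > 0) strength_num / sum(s_i) else 0
  } else {
    contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
  }
  setNames(c(coarseness, contrast, busyness, complexity, strength),
           feature_class_names()$ngtdm)
}

gldm_features <- function(level_arr, dims, ng, alpha) {
  P <- gldm_counts_cpp(level_arr, dims, ng, as.integer(alpha))
  # dependence count d runs 0..26; use d+1 in the size role
  keep <- which(colSums(P) > 0 | seq_len(ncol(P)) <= 1)
  P <- P[, seq_len(max(keep)), drop = FALSE]
  nz <- sum(P)
  i <- matrix(seq_len(ng), ng, ncol(P))
  dd <- t(matrix(seq_len(ncol(P)), ncol(P), ng))  # = dependence + 1
  p <- P / nz
  mu_i <- sum(i * p); mu_d <- sum(dd * p)
  pg <- rowSums(P); pdp <- colSums(P)
  pnz <- p[p > 0]
  setNames(c(
    sum(P / dd^2) / nz,
    sum(P * dd^2) / nz,
    sum(pg^2) / nz,
    sum(pdp^2) / nz,
    sum(pdp^2) / nz^2,
    sum(p * (i - mu_i)^2),
    sum(p * (dd - mu_d)^2),
    -sum(pnz * log2(pnz)),
    sum(P / i^2) / nz,
    sum(P * i^2) / nz,
    sum(P / (i^2 * dd^2)) / nz,
    sum(P * i^2 / dd^2) / nz,
    sum(P * dd^2 / i^2) / nz,
    sum(P * dd^2 * i^2) / nz), feature_class_names()$gldm)
}

shape_features <- function(mask) {
  full <- dim(mask$array)
  bbidx <- which(mask$array, arr.ind = TRUE)
  bb <- apply(bbidx, 2, range)
  lo <- pmax(bb[1, ] - 6L, 1L); hi <- pmin(bb[2, ] + 6L, full)
  arr <- mask$array[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  d <- dim(arr)
  sp <- mask$spacing
  voxvol <- prod(sp)
  idx <- which(arr)
  n <- length(idx)
  coords <- sweep(arrayInd(idx, d), 2, lo - 1L, "+")
  phys <- sweep(sweep(coords - 1, 2, sp, "*"), 2, mask$origin, "+")

  # boundary voxels: any 6-neighbor outside the mask (or at image edge)
  pad <- array(FALSE, d + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- arr
  inner <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] & pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] & pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] & pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  boundary <- arr & !inner

  # smooth-indicator representation: its integral is the mesh-volume
  # estimate, its gradient magnitude integrates to the surface area
  # (co-area formula)
  sm <- gaussian_smooth(array(as.numeric(arr), d), sp, 1.2 * min(sp))
  mesh_volume <- sum(sm) * voxvol
  gx <- array(conv_axis_cpp(as.numeric(sm), d, c(-1, 0, 1) / (2 * sp[1]), 0L), d)
  gy <- array(conv_axis_cpp(as.numeric(sm), d, c(-1, 0, 1) / (2 * sp[2]), 1L), d)
  gz <- array(conv_axis_cpp(as.numeric(sm), d, c(-1, 0, 1) / (2 * sp[3]), 2L), d)
  surface <- sum(sqrt(gx^2 + gy^2 + gz^2)) * voxvol

  bphys <- phys[boundary[idx], , drop = FALSE]
  if (nrow(bphys) < 2) bphys <- phys
  max3d <- max_pairwise_dist_cpp(bphys)
  max2d <- function(plane_cols, along) {
    best <- 0
    for (v in unique(bphys[, along])) {
      sub <- bphys[bphys[, along] == v, plane_cols, drop = FALSE]
      if (nrow(sub) >= 2) best <- max(best, max_pairwise_dist_cpp(sub))
    }
    best
  }

  cv <- cov(phys) * (n - 1) / n
  ev <- sort(pmax(eigen(cv, symmetric = TRUE, only.values = TRUE)$values, 0),
             decreasing = TRUE)
  axes <- 4 * sqrt(ev)

  sph <- (36 * pi * mesh_volume^2)^(1 / 3) / surface
  setNames(c(mesh_volume, n * voxvol, surface, surface / mesh_volume, sph,
             max3d, max2d(1:2, 3), max2d(c(1, 3), 2), max2d(2:3, 1),
             axes[1], axes[2], axes[3],
             if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0,
             if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0),
           feature_class_names()$shape)
}

#' Extract the radiomic feature vector of one region
#'
#' Computes the 7-class feature set (shape from original geometry; first-order
#' and the five texture families on every image type of the filter bank).
#' Undersized or empty masks return a missing-flagged vector rather than an
#' error, so absent habitats flow into KNN imputation.
#'
#' @param vol preprocessed [volume()].
#' @param mask [region_mask()] of the region.
#' @param config an [extraction_config()].
#' @param region region tag used in the feature names.
#' @param bank optional precomputed [filter_bank()] of `vol` (reused across
#'   regions of one patient).
#' @return Named numeric vector of length 1,015 (default bank); all-`NA` with
#'   `attr(, "missing") = TRUE` when the mask is below `min_voxels`.
#' @export
extract_features <- function(vol, mask, config = extraction_config(),
                             region = "intra", bank = NULL) {
  nm <- feature_names(config, region)
  if (mask_count(mask) < config$min_voxels) {
    out <- setNames(rep(NA_real_, length(nm)), nm)
    attr(out, "missing") <- TRUE
    return(out)
  }
  if (is.null(bank)) bank <- filter_bank(vol, config$log_sigmas_mm)
  voxvol <- voxel_volume_mm3(vol)

  # texture matrices only see within-region pairs, so everything past shape
  # runs on the region's bounding box
  bbidx <- which(mask$array, arr.ind = TRUE)
  bb <- apply(bbidx, 2, range)
  cx <- bb[1, 1]:bb[2, 1]; cy <- bb[1, 2]:bb[2, 2]; cz <- bb[1, 3]:bb[2, 3]
  cmask <- mask$array[cx, cy, cz, drop = FALSE]
  dims <- dim(cmask)
  sel <- which(cmask)
  np <- length(sel)

  out <- shape_features(mask)
  names(out) <- paste("original", "shape", names(out), sep = "|")
  for (ft in filter_tags(config)) {
    img <- bank[[ft]][cx, cy, cz, drop = FALSE]
    vals <- img[sel]
    lev <- integer(length(img))
    lev[sel] <- discretize_levels(vals, config$bin_width)
    ng <- max(lev)
    fo <- firstorder_features(vals, voxvol, config$bin_width)
    tex <- c(glcm = list(glcm_features(lev, dims, ng)),
             glrlm = list(glrlm_features(lev, dims, ng, np)),
             glszm = list(glszm_features(lev, dims, ng, np)),
             ngtdm = list(ngtdm_features(lev, dims, ng)),
             gldm = list(gldm_features(lev, dims, ng, config$gldm_alpha)))
    block <- c(setNames(fo, paste(ft, "firstorder", names(fo), sep = "|")),
               unlist(lapply(names(tex), function(cl)
                 setNames(tex[[cl]], paste(ft, cl, names(tex[[cl]]), sep = "|")))))
    out <- c(out, block)
  }
  out <- setNames(as.numeric(out), paste(region, names(out), sep = "|"))
  stopifnot(identical(names(out), nm))
  out
}

#' Integrated habitat feature vector
#'
#' Concatenates the three per-habitat vectors under the
#' `habitat_integrated` region tag, suffixing each base name with its habitat
#' of origin. Missing habitats propagate as missing blocks.
#'
#' @param h1_vec,h2_vec,h3_vec per-habitat vectors from [extract_features()]
#'   with region tags `h1`, `h2`, `h3` (possibly missing-flagged).
#' @return Named vector of length `3 * 1015` = 3,045 with the default bank.
#' @export
integrated_habitat_features <- function(h1_vec, h2_vec, h3_vec) {
  vecs <- list(h1 = h1_vec, h2 = h2_vec, h3 = h3_vec)
  out <- unlist(lapply(names(vecs), function(h) {
    v <- vecs[[h]]
    p <- parse_feature_name(names(v))
    setNames(as.numeric(v),
             paste("habitat_integrated", p$image_filter, p$feature_class,
                   paste0(p$base_name, "_", h), sep = "|"))
  }))
  out
}

# ---------------------------------------------------------------------------
# Feature tables, imputation, ICC filtering
# ---------------------------------------------------------------------------

#' Assemble a feature table from per-patient vectors
#' @param vectors named list (by patient id) of equal-named feature vectors.
#' @return data.frame with an `id` column and one column per feature.
#' @export
feature_table <- function(vectors) {
  mat <- do.call(rbind, vectors)
  df <- data.frame(id = names(vectors), mat, check.names = FALSE,
                   row.names = NULL, stringsAsFactors = FALSE)
  colnames(df) <- c("id", colnames(mat))
  df
}

feature_matrix <- function(table) {
  m <- as.matrix(table[, setdiff(colnames(table), "id"), drop = FALSE])
  rownames(m) <- table$id
  m
}

#' KNN imputation of missing habitat features
#'
#' The imputer is fitted on training rows only (column means/SDs and the
#' neighbor pool) and applied to all rows. Distances are computed on the
#' standardized mutually-observed features, scaled by the number of shared
#' columns; each missing cell takes the mean of the `k_neighbors` nearest
#' training rows observed in that column. Observed cells are never altered.
#'
#' @param table feature table (data.frame with `id` column) containing `NA`s.
#' @param k_neighbors neighborhood size (default 5).
#' @param train_ids ids of rows the imputer may learn from (default: all).
#' @return The completed table.
#' @export
knn_impute <- function(table, k_neighbors = 5, train_ids = NULL) {
  m <- feature_matrix(table)
  if (is.null(train_ids)) train_ids <- table$id
  tr <- m[table$id %in% train_ids, , drop = FALSE]
  fully_missing <- colnames(m)[colSums(!is.na(tr)) == 0]
  if (length(fully_missing) > 0)
    stop("columns with no observed training values: ",
         paste(head(fully_missing, 5), collapse = ", "),
         if (length(fully_missing) > 5) " ..." else "")
  if (!anyNA(m)) return(table)
  ctr <- colMeans(tr, na.rm = TRUE)
  scl <- apply(tr, 2, sd, na.rm = TRUE)
  scl[is.na(scl) | scl == 0] <- 1
  zs <- function(x) sweep(sweep(x, 2, ctr), 2, scl, "/")
  ztr <- zs(tr)
  zm <- zs(m)
  for (r in which(rowSums(is.na(m)) > 0)) {
    obs <- !is.na(zm[r, ])
    dif <- sweep(ztr[, obs, drop = FALSE], 2, zm[r, obs], "-")
    shared <- rowSums(!is.na(dif))
    d2 <- rowSums(dif^2, na.rm = TRUE) / pmax(shared, 1)
    d2[shared == 0] <- Inf
    d2[rownames(ztr) == rownames(zm)[r]] <- Inf  # never self-impute
    ord <- order(d2)
    for (cc in which(is.na(m[r, ]))) {
      donors <- ord[!is.na(tr[ord, cc])]
      use <- head(donors, k_neighbors)
      m[r, cc] <- mean(tr[use, cc])
    }
  }
  out <- table
  out[, colnames(m)] <- m
  out
}

#' Two-way random-effects single-measure ICC, absolute agreement
#'
#' ICC(2,1) from the two-way ANOVA decomposition (subjects x raters), the
#' standard reliability index for radiomic feature reproducibility.
#'
#' @param reader1,reader2 numeric vectors of the same feature measured by two
#'   readers on the same n >= 3 subjects.
#' @return The ICC estimate.
#' @export
icc_two_way <- function(reader1, reader2) {
  stopifnot(length(reader1) == length(reader2), length(reader1) >= 3)
  x <- cbind(reader1, reader2)
  n <- nrow(x); k <- 2
  gm <- mean(x)
  if (sum((x - gm)^2) == 0) stop("zero total variance: ICC undefined")
  rm_ <- rowMeans(x); cm_ <- colMeans(x)
  ssr <- k * sum((rm_ - gm)^2)
  ssc <- n * sum((cm_ - gm)^2)
  sst <- sum((x - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Drop features with poor inter-reader reproducibility
#'
#' Computes ICC(2,1) per feature between the two readers' tables and drops
#' non-exempt features below the threshold. Habitat-region features come from
#' unsupervised clustering with no second-reader counterpart and are always
#' retained (exempt).
#'
#' @param table reader-1 feature table (with `id` column).
#' @param reader2_table reader-2 table; must cover all non-exempt columns.
#' @param threshold retention threshold (default 0.75).
#' @param exempt_regions region tags exempt from ICC filtering.
#' @return list(table = filtered table, report = per-feature data.frame with
#'   columns feature, region, icc, kept).
#' @export
filter_by_icc <- function(table, reader2_table, threshold = 0.75,
                          exempt_regions = c("h1", "h2", "h3",
                                             "habitat_integrated")) {
  feats <- setdiff(colnames(table), "id")
  regions <- feature_region(feats)
  exempt <- regions %in% exempt_regions
  need <- feats[!exempt]
  missing2 <- setdiff(need, colnames(reader2_table))
  if (length(missing2) > 0)
    stop("reader-2 data missing for non-exempt features: ",
         paste(head(missing2, 3), collapse = ", "))
  r2 <- reader2_table[match(table$id, reader2_table$id), , drop = FALSE]
  icc <- rep(NA_real_, length(feats))
  for (u in which(!exempt)) {
    icc[u] <- tryCatch(icc_two_way(table[[feats[u]]], r2[[feats[u]]]),
                       error = function(e) NA_real_)
  }
  kept <- exempt | (!is.na(icc) & icc >= threshold)
  report <- data.frame(feature = feats, region = regions, icc = icc,
                       exempt = exempt, kept = kept, stringsAsFactors = FALSE)
  list(table = table[, c("id", feats[kept]), drop = FALSE], report = report)
}
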