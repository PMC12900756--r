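test_that("feature arithmetic: 1,015 per region with the documented breakdown", {
  nm <- feature_names()
  expect_length(nm, 1015)
  parsed <- parse_feature_name(nm)
  counts <- table(parsed$feature_class)
  expect_equal(as.numeric(counts[c("shape", "firstorder", "glcm", "glrlm",
                                   "glszm", "ngtdm", "gldm")]),
               c(14, 198, 242, 176, 176, 55, 154))
  # 11 image types; shape only under the original filter
  expect_length(unique(parsed$image_filter), 11)
  expect_true(all(parsed$image_filter[parsed$feature_class == "shape"] ==
                    "original"))
  expect_equal(sum(parsed$image_filter == "wavelet-HHL" &
                     parsed$feature_class != "shape"), 91)
  # names round-trip
  rebuilt <- with(parsed, paste(region, image_filter, feature_class,
                                base_name, sep = "|"))
  expect_identical(rebuilt, nm)
})

test_that("extraction returns 1,015 finite values, deterministically", {
  co <- generate_cohort(tiny_cohort_config(1, seed = 6, grid = 40))
  p <- co[[1]]
  pp <- preprocess_volume(p$volume, masks = list(m1 = p$mask_reader1))
  fv <- extract_features(pp$volume, pp$masks$m1, region = "intra")
  expect_length(fv, 1015)
  expect_true(all(is.finite(fv)))
  expect_identical(names(fv), feature_names(region = "intra"))
  fv2 <- extract_features(pp$volume, pp$masks$m1, region = "intra")
  expect_identical(fv, fv2)

  # undersized masks flow to imputation as missing, not as an error
  tiny <- region_mask(array(seq_len(prod(dim(pp$volume$array))) <= 4,
                            dim(pp$volume$array)))
  mv <- extract_features(pp$volume, tiny)
  expect_true(all(is.na(mv)))
  expect_true(isTRUE(attr(mv, "missing")))
})

test_that("shape features: a sphere is spherical, sizes are physical", {
  dims <- c(26, 26, 26)
  m <- sphere_mask(9, dims)
  v <- const_volume(1, dims)
  sf <- extract_features(v, m, region = "intra")
  g <- function(n) unname(sf[paste0("intra|original|shape|", n)])
  expect_gt(g("Sphericity"), 0.95)
  expect_lt(g("Sphericity"), 1.05)
  true_vol <- 4 / 3 * pi * 9^3
  expect_lt(abs(g("VoxelVolume") - true_vol) / true_vol, 0.05)
  expect_lt(abs(g("Maximum3DDiameter") - 18) / 18, 0.1)
  expect_gt(g("Flatness"), 0.9)  # isotropic body
  expect_lt(abs(g("MajorAxisLength") - 2 * 9 * sqrt(16 / 20)) / 18, 0.15)
})

test_that("constant-region first-order features take their closed-form values", {
  dims <- c(12, 12, 12)
  m <- cube_mask(dims, c(3, 3, 3), c(9, 9, 9))
  v <- const_volume(42, dims)
  fv <- extract_features(v, m)
  g <- function(f) unname(fv[paste0("intra|original|firstorder|", f)])
  expect_equal(g("Mean"), 42)
  expect_equal(g("Variance"), 0)
  expect_equal(g("Entropy"), 0)
  expect_equal(g("Uniformity"), 1)
  expect_equal(g("Energy"), 343 * 42^2)
})

test_that("GLCM counts equal a brute-force pair enumeration", {
  glcm_oracle <- function(lev, dims, ng) {
    dirs <- rbind(c(1,0,0), c(0,1,0), c(0,0,1), c(1,1,0), c(1,-1,0),
                  c(1,0,1), c(1,0,-1), c(0,1,1), c(0,1,-1), c(1,1,1),
                  c(1,1,-1), c(1,-1,1), c(1,-1,-1))
    arr <- array(lev, dims)
    out <- array(0, c(ng, ng, 13))
    ax <- arrayInd(seq_len(prod(dims)), dims)
    for (d in 1:13) for (t in seq_len(nrow(ax))) {
      a <- arr[ax[t, 1], ax[t, 2], ax[t, 3]]
      q <- ax[t, ] + dirs[d, ]
      if (any(q < 1) || any(q > dims)) next
      b <- arr[q[1], q[2], q[3]]
      if (a > 0 && b > 0) {
        out[a, b, d] <- out[a, b, d] + 1
        out[b, a, d] <- out[b, a, d] + 1
      }
    }
    out
  }
  set.seed(21)
  for (i in 1:5) {
    dims <- c(5, 4, 3)
    lev <- sample(0:3, prod(dims), replace = TRUE)
    ng <- 3
    got <- glcm_counts_cpp(as.integer(lev), dims, ng)
    expect_equal(unclass(got), unclass(glcm_oracle(lev, dims, ng)),
                 ignore_attr = TRUE)
  }
})

test_that("GLRLM counts equal a brute-force run enumeration", {
  # hand case: a single x-run of length 3 at level 1
  dims <- c(5, 1, 1)
  lev <- c(1L, 1L, 1L, 0L, 2L)
  got <- glrlm_counts_cpp(lev, dims, 2L)
  expect_equal(got[1, 3, 1], 1)  # level 1, run length 3, x-direction
  expect_equal(got[2, 1, 1], 1)  # level 2, run length 1
  expect_equal(sum(got[, , 1]), 2)

  # random arrays: total run-length mass equals voxel count per direction
  set.seed(22)
  dims <- c(6, 5, 4)
  lev <- sample(0:3, prod(dims), replace = TRUE)
  got <- glrlm_counts_cpp(as.integer(lev), dims, 3L)
  runlens <- matrix(seq_len(dim(got)[2]), nrow = 3, ncol = dim(got)[2],
                    byrow = TRUE)
  for (d in 1:13)
    expect_equal(sum(got[, , d] * runlens), sum(lev > 0))
})

test_that("GLSZM zones are 26-connected components per gray level", {
  dims <- c(6, 6, 1)
  lev <- array(0L, dims)
  lev[1:2, 1:2, 1] <- 1L          # one 4-voxel zone of level 1
  lev[5, 5, 1] <- 1L              # isolated level-1 voxel
  lev[4, 4, 1] <- 2L              # level 2 touches nothing of level 2
  zones <- glszm_zones_cpp(as.integer(lev), dims)
  zl <- zones[order(zones[, 1], zones[, 2]), , drop = FALSE]
  expect_equal(nrow(zl), 3)
  expect_equal(zl[zl[, 1] == 2, 2], 1)
  expect_setequal(zl[zl[, 1] == 1, 2], c(1, 4))
})

test_that("integrated habitat vector concatenates to 3,045 with provenance", {
  co <- generate_cohort(tiny_cohort_config(1, seed = 12, grid = 40))
  p <- co[[1]]
  pp <- preprocess_volume(p$volume, masks = list(m1 = p$mask_reader1))
  h1 <- extract_features(pp$volume, pp$masks$m1, region = "h1")
  h2 <- extract_features(pp$volume, pp$masks$m1, region = "h2")
  empty <- region_mask(array(FALSE, dim(pp$volume$array)))
  h3 <- extract_features(pp$volume, empty, region = "h3")
  intg <- integrated_habitat_features(h1, h2, h3)
  expect_length(intg, 3045)
  expect_equal(sum(is.na(intg)), 1015)  # the absent habitat's block
  parsed <- parse_feature_name(names(intg))
  expect_true(all(parsed$region == "habitat_integrated"))
  expect_equal(sum(endsWith(parsed$base_name, "_h2")), 1015)
})

test_that("KNN imputation recovers planted missing values without touching observed ones", {
  # identical rows: imputed value equals the shared value
  tab <- data.frame(id = c("a", "b", "c"), f1 = c(5, 5, 5), f2 = c(2, 2, NA),
                    check.names = FALSE)
  out <- knn_impute(tab, k_neighbors = 2)
  expect_equal(out$f2, c(2, 2, 2))

  # complete tables pass through unchanged
  full <- data.frame(id = c("a", "b"), x = c(1, 2))
  expect_identical(knn_impute(full), full)

  # mask-and-recover: RMSE under the column SD
  set.seed(31)
  n <- 60; pfe <- 8
  base <- matrix(rnorm(n), n, pfe) + matrix(rnorm(n * pfe, sd = 0.3), n)
  colnames(base) <- paste0("f", seq_len(pfe))
  tab2 <- data.frame(id = sprintf("p%02d", 1:n), base, check.names = FALSE)
  holes <- matrix(runif(n * pfe) < 0.1, n, pfe)
  tab_missing <- tab2
  tab_missing[, -1][holes] <- NA
  rec <- knn_impute(tab_missing)
  expect_false(anyNA(rec))
  rmse <- sqrt(mean((as.matrix(rec[, -1])[holes] - base[holes])^2))
  expect_lt(rmse, mean(apply(base, 2, sd)))
  # observed entries untouched
  expect_identical(as.matrix(rec[, -1])[!holes], base[!holes])

  tab3 <- data.frame(id = c("a", "b"), x = c(NA, NA))
  expect_error(knn_impute(tab3), "no observed")
})

test_that("ICC(2,1) matches the ANOVA decomposition and behaves at the extremes", {
  x <- c(9, 6, 8, 7, 10)
  expect_equal(icc_two_way(x, x), 1)

  # independent oracle via aov mean squares
  icc_oracle <- function(r1, r2) {
    n <- length(r1)
    df <- data.frame(y = c(r1, r2),
                     subj = factor(rep(seq_len(n), 2)),
                     rater = factor(rep(1:2, each = n)))
    ms <- summary(aov(y ~ subj + rater, df))[[1]][, "Mean Sq"]
    msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
    (msr - mse) / (msr + mse + 2 * (msc - mse) / n)
  }
  set.seed(41)
  for (i in 1:5) {
    r1 <- rnorm(5, 10, 2)
    r2 <- r1 + rnorm(5, 0.5, 1)
    expect_equal(icc_two_way(r1, r2), icc_oracle(r1, r2), tolerance = 1e-10)
  }

  # unrelated readers: ICC near zero
  set.seed(42)
  a <- rnorm(200); b <- rnorm(200)
  expect_lt(abs(icc_two_way(a, b)), 0.15)

  # invariance to a common affine rescaling
  expect_equal(icc_two_way(2 * a + 3, 2 * b + 3), icc_two_way(a, b),
               tolerance = 1e-10)
  expect_error(icc_two_way(rep(1, 5), rep(1, 5)), "zero total variance")
})

test_that("ICC filtering drops noise features but never habitat features", {
  set.seed(51)
  n <- 100
  ids <- sprintf("p%03d", 1:n)
  signal <- matrix(rnorm(n * 10), n)
  noise1 <- matrix(rnorm(n * 10), n)
  noise2 <- matrix(rnorm(n * 10), n)
  habcol <- rnorm(n)
  t1 <- data.frame(id = ids, signal, noise1, habcol, check.names = FALSE)
  t2 <- data.frame(id = ids, signal + rnorm(n * 10, sd = 0.15), noise2,
                   rnorm(n), check.names = FALSE)
  nms <- c(paste0("intra|original|firstorder|S", 1:10),
           paste0("intra|original|firstorder|N", 1:10),
           "h1|original|firstorder|X")
  colnames(t1)[-1] <- colnames(t2)[-1] <- nms
  res <- filter_by_icc(t1, t2)
  kept <- setdiff(colnames(res$table), "id")
  expect_gte(sum(startsWith(kept, "intra|original|firstorder|S")), 9)
  expect_lte(sum(startsWith(kept, "intra|original|firstorder|N")), 1)
  expect_true("h1|original|firstorder|X" %in% kept)  # exempt despite ICC ~ 0
  expect_true(all(res$report$exempt[res$report$region == "h1"]))

  # identical tables: nothing dropped
  res2 <- filter_by_icc(t1, t1)
  expect_equal(ncol(res2$table), ncol(t1))
  # missing reader-2 coverage for a non-exempt region errors
  expect_error(filter_by_icc(t1, t2[, 1:5]), "reader-2")
})
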