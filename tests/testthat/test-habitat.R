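test_that("local feature maps have 19 channels with sane degenerate values", {
  dims <- c(14, 14, 14)
  m <- cube_mask(dims, c(3, 3, 3), c(12, 12, 12))
  v <- const_volume(50, dims)
  fm <- local_feature_maps(v, m)
  expect_equal(ncol(fm$values), 19)
  expect_identical(colnames(fm$values), local_channel_names())
  expect_true(all(abs(fm$values[, "Mean"] - 50) < 1e-10))
  expect_true(all(fm$values[, "Variance"] == 0))
  expect_true(all(fm$values[, "Entropy"] == 0))
  expect_error(local_feature_maps(v, m, window = 4), "odd")
})

test_that("interior window statistics match a brute-force neighborhood oracle", {
  dims <- c(11, 11, 11)
  v <- noise_volume(dims, seed = 8)
  m <- region_mask(array(TRUE, dims))
  fm <- local_feature_maps(v, m)
  center <- which(fm$index == (5 + 11 * (5 + 11 * 5) + 1))  # voxel (6,6,6)
  nb <- v$array[4:8, 4:8, 4:8]
  expect_equal(unname(fm$values[center, "Mean"]), mean(nb), tolerance = 1e-12)
  expect_equal(unname(fm$values[center, "Variance"]),
               mean((nb - mean(nb))^2), tolerance = 1e-10)
  expect_equal(unname(fm$values[center, "Maximum"]), max(nb))
  expect_equal(unname(fm$values[center, "Energy"]), sum(nb^2), tolerance = 1e-8)
  expect_equal(fm$support[center], 125L)

  # corner voxel of the full-cube mask: support < 8^3 but >= min_support
  corner <- which(fm$index == 1)
  expect_equal(fm$support[corner], 27L)
  expect_true(fm$valid[corner])
})

test_that("Calinski-Harabasz matches hand and textbook-formula oracles", {
  expect_equal(calinski_harabasz(c(0, 1, 10, 11), c("a", "a", "b", "b")), 200)
  expect_equal(calinski_harabasz(c(0, 0, 5, 5), c(1, 1, 2, 2)), Inf)
  expect_error(calinski_harabasz(1:5, rep(1, 5)), "at least 2")

  # independent oracle: B computed as total SS minus within SS
  ch_oracle <- function(x, g) {
    x <- as.matrix(x); g <- as.factor(g)
    n <- nrow(x); k <- nlevels(g)
    tot <- sum(scale(x, scale = FALSE)^2)
    w <- sum(unlist(lapply(levels(g), function(l)
      sum(scale(x[g == l, , drop = FALSE], scale = FALSE)^2))))
    ((tot - w) / (k - 1)) / (w / (n - k))
  }
  set.seed(3)
  for (i in 1:100) {
    n <- sample(6:30, 1); d <- sample(1:4, 1); k <- sample(2:3, 1)
    x <- matrix(rnorm(n * d), n)
    g <- sample(rep_len(seq_len(k), n))
    expect_equal(calinski_harabasz(x, g), ch_oracle(x, g),
                 tolerance = 1e-10)
  }

  # separated blobs: true labels beat random labels
  pts <- blob_points(40, rbind(rep(0, 3), rep(8, 3), c(0, 8, 0)), seed = 5)
  truth <- rep(1:3, each = 40)
  set.seed(6)
  expect_gt(calinski_harabasz(pts, truth),
            calinski_harabasz(pts, sample(truth)))
})

test_that("habitat model selects the planted cluster count on point clouds", {
  # three well-separated blobs across all 19 channels
  centers <- rbind(rep(0, 19), rep(6, 19), rep(-6, 19))
  vals <- blob_points(400, centers, sd = 1, seed = 2)
  fm <- fake_feature_map(vals)
  hm <- fit_habitat_model(list(fm), k_range = 2:6, seed = 1)
  expect_equal(hm$k, 3)
  expect_equal(hm$k, as.integer(names(which.max(hm$ch_scores))))
  # H1..Hk ordered by descending windowed-mean center
  expect_true(all(diff(hm$centers[, "Mean"]) < 0))

  # determinism
  hm2 <- fit_habitat_model(list(fm), k_range = 2:6, seed = 1)
  expect_identical(hm$centers, hm2$centers)
  expect_identical(hm$label_order, hm2$label_order)

  # narrowed range is respected
  hm3 <- fit_habitat_model(list(fm), k_range = 2:3, seed = 1)
  expect_true(hm3$k %in% 2:3)
  expect_error(fit_habitat_model(list(fake_feature_map(vals[1:20, ]))),
               "insufficient")
})

test_that("two-level phantom splits perfectly at k = 2", {
  # two disconnected constant-intensity cubes: every window is pure
  dims <- c(20, 10, 10)
  m <- array(FALSE, dims)
  m[2:8, 2:8, 2:8] <- TRUE
  m[13:19, 2:8, 2:8] <- TRUE
  arr <- array(0, dims)
  arr[13:19, 2:8, 2:8] <- 100
  v <- volume(arr)
  msk <- region_mask(m)
  fm <- local_feature_maps(v, msk)
  hm <- fit_habitat_model(list(fm), k_range = 2, voxel_subsample = 1e5,
                          seed = 1)
  am <- assign_habitats(hm, fm, msk)
  truth <- (arr > 50)[m] + 1
  expect_equal(mclust::adjustedRandIndex(truth, am$labels[m]), 1)
})

test_that("habitat assignment partitions the tumor and is idempotent", {
  centers <- rbind(rep(2, 19), rep(-2, 19))
  vals <- blob_points(300, centers, sd = 0.4, seed = 9)
  fm <- fake_feature_map(vals)
  hm <- fit_habitat_model(list(fm), k_range = 2, seed = 4)

  dims <- c(30, 30, 30)
  fm <- fake_feature_map(vals, dims = dims)
  msk <- region_mask(array(seq_len(prod(dims)) <= 600, dims))
  am <- assign_habitats(hm, fm, msk)
  expect_true(all((am$labels > 0) == msk$array))
  expect_equal(sum(am$fractions), 1)
  expect_equal(sum(am$counts), 600)

  # a voxel whose features sit exactly at a center goes to that cluster
  probe <- vals
  probe[1, ] <- hm$scaler$center + hm$centers[2, ] * hm$scaler$scale
  am2 <- assign_habitats(hm, fake_feature_map(probe, dims = dims), msk)
  expect_equal(am2$labels[1], 2)

  # idempotence: reassignment changes nothing
  am3 <- assign_habitats(hm, fm, msk)
  expect_identical(am$labels, am3$labels)

  hmasks <- habitat_masks(am, msk)
  expect_length(hmasks, hm$k)
  expect_equal(sum(hmasks$h1$array) + sum(hmasks$h2$array), 600)
})
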