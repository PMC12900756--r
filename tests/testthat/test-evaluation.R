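test_that("AUC equals the pair-counting oracle, exactly", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(0:1, 5)), 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")

  pair_oracle <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    g <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
    mean(g)
  }
  set.seed(81)
  for (i in 1:1000) {
    n <- sample(6:20, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # plenty of ties
    expect_identical(roc_auc(s, y), pair_oracle(s, y))
  }
})

test_that("DeLong CI and test agree with the independent pROC implementation", {
  set.seed(82)
  y <- rbinom(60, 1, 0.4)
  y[1:2] <- c(0, 1)
  s1 <- y + rnorm(60)
  s2 <- y + rnorm(60, sd = 2)

  ci <- delong_ci(s1, y)
  expect_equal(ci$auc, roc_auc(s1, y))
  pr <- pROC::ci.auc(pROC::roc(y, s1, quiet = TRUE), method = "delong")
  expect_equal(ci$lower, max(0, pr[1]), tolerance = 1e-6)
  expect_equal(ci$upper, min(1, pr[3]), tolerance = 1e-6)

  dl <- delong_test(s1, s2, y)
  pt <- pROC::roc.test(pROC::roc(y, s1, quiet = TRUE),
                       pROC::roc(y, s2, quiet = TRUE), method = "delong")
  expect_equal(dl$p, pt$p.value, tolerance = 1e-6)

  # self-comparison and antisymmetry
  expect_equal(delong_test(s1, s1, y)$p, 1)
  expect_equal(delong_test(s1, s1, y)$z, 0)
  expect_equal(delong_test(s2, s1, y)$z, -dl$z, tolerance = 1e-12)
})

test_that("DeLong CI width shrinks like 1/sqrt(n)", {
  width_at <- function(n, seed) {
    set.seed(seed)
    y <- rep(0:1, each = n / 2)
    s <- y + rnorm(n)
    ci <- delong_ci(s, y)
    ci$upper - ci$lower
  }
  w100 <- mean(vapply(1:20, function(s) width_at(100, s), 0))
  w400 <- mean(vapply(1:20, function(s) width_at(400, s), 0))
  expect_gt(w100 / w400, 1.6)
  expect_lt(w100 / w400, 2.6)
})

test_that("threshold metrics reproduce the confusion-matrix definitions", {
  # 2x2 table TP=9 FN=2 FP=5 TN=30 at threshold 0.5
  scores <- c(rep(0.9, 9), rep(0.1, 2), rep(0.9, 5), rep(0.1, 30))
  labels <- c(rep(1, 11), rep(0, 35))
  tm <- threshold_metrics(scores, labels, 0.5)
  expect_equal(tm$sensitivity, 9 / 11)
  expect_equal(tm$specificity, 30 / 35)
  expect_equal(tm$ppv, 9 / 14)
  expect_equal(tm$npv, 30 / 32)
  expect_equal(tm$accuracy, 39 / 46)

  perfect <- threshold_metrics(labels, labels, 0.5)
  expect_true(all(unlist(perfect[c("accuracy", "sensitivity", "specificity",
                                   "ppv", "npv")]) == 1))

  # brute-force oracle on random data
  set.seed(83)
  for (i in 1:20) {
    y <- c(0, 1, rbinom(18, 1, 0.5))
    s <- runif(20)
    thr <- runif(1)
    tm2 <- threshold_metrics(s, y, thr)
    pred <- as.numeric(s >= thr)
    expect_equal(tm2$accuracy, mean(pred == y))
    expect_equal(tm2$sensitivity, sum(pred & y) / sum(y))
  }

  # Youden threshold maximizes sensitivity + specificity - 1
  set.seed(84)
  y <- rep(0:1, each = 25)
  s <- y + rnorm(50)
  thr <- youden_threshold(s, y)
  j_at <- function(t) mean(s[y == 1] >= t) + mean(s[y == 0] < t) - 1
  expect_true(all(j_at(thr) >= vapply(sort(unique(s)), j_at, 0) - 1e-12))
})

test_that("calibration curves and the Brier score behave as advertised", {
  # the always-0.5 predictor has Brier 0.25
  set.seed(85)
  y <- rbinom(400, 1, 0.5)
  cal <- calibration_curve(rep(0.5, 400), y)
  expect_equal(cal$brier, 0.25)
  expect_equal(nrow(cal$bins), 1)
  expect_lt(abs(cal$bins$observed - mean(y)), 1e-12)

  # labels drawn from the stated probabilities: bins fall near the diagonal
  p <- runif(5000)
  yy <- rbinom(5000, 1, p)
  cal2 <- calibration_curve(p, yy)
  expect_lt(max(abs(cal2$bins$mean_predicted - cal2$bins$observed)), 0.05)

  expect_warning(calibration_curve(runif(5), rbinom(5, 1, 0.5), n_bins = 10),
                 "reducing")
  expect_error(calibration_curve(c(-0.1, 0.5), c(0, 1)))
})

test_that("decision curves match the closed-form reference strategies", {
  set.seed(86)
  n <- 400
  y <- rbinom(n, 1, 0.25)
  prev <- mean(y)
  p <- plogis(qlogis(prev) + 2 * (y - 0.5) + rnorm(n))
  dc <- decision_curve(p, y)
  expect_true(all(dc$treat_none == 0))
  # treat-all at p_t equal to prevalence has zero net benefit
  expect_equal(dc$treat_all[abs(dc$threshold - 0.25) < 1e-9],
               prev - (1 - prev) * 0.25 / 0.75, tolerance = 1e-12)

  # a perfect predictor earns the prevalence below the minimum positive score
  perfect <- decision_curve(y * 0.8 + 0.1, y)
  low <- perfect$threshold < 0.9 & perfect$threshold > 0.1
  expect_true(all(abs(perfect$model[low] - prev) < 1e-12))
  # no model beats the hard 0/1 perfect predictor anywhere
  hard <- decision_curve(y, y)
  expect_true(all(hard$model == prev))
  expect_true(all(dc$model <= hard$model + 1e-12))
})

test_that("Shapley attributions are exactly locally accurate and sign-faithful", {
  # additive linear-logit model via the nomogram class
  nomo <- structure(list(coefficients = c(f1 = 2, f2 = -3), intercept = 0.5,
                         points = NULL, inputs = c("f1", "f2")),
                    class = "nomogram_model")
  set.seed(87)
  rows <- data.frame(id = 1:6, f1 = rnorm(6), f2 = rnorm(6),
                     check.names = FALSE)
  bg <- data.frame(id = 1:20, f1 = rnorm(20), f2 = rnorm(20),
                   check.names = FALSE)
  att <- attribution_summary(nomo, rows, bg, n_perm = 8, seed = 1)

  # local accuracy: attributions + base value reproduce the prediction
  preds <- predict_probability(nomo, rows)
  resid <- abs(rowSums(att$attributions) + att$base_value - preds)
  expect_true(all(resid < 1e-6))

  # sign of each attribution follows the coefficient sign
  expect_true(all(sign(att$attributions[, "f1"]) ==
                    sign(rows$f1 - mean(bg$f1))))
  expect_true(all(att$attributions[, "f2"] *
                    (rows$f2 - mean(bg$f2)) <= 1e-9))
  expect_named(att$importance)

  # constant model: all attributions vanish
  flat <- structure(list(coefficients = c(f1 = 0, f2 = 0), intercept = 1,
                         points = NULL, inputs = c("f1", "f2")),
                    class = "nomogram_model")
  att0 <- attribution_summary(flat, rows, bg, n_perm = 2, seed = 1)
  expect_true(all(att0$attributions == 0))
  expect_error(attribution_summary(nomo, rows, bg[0, ]), "nonempty")
})

test_that("baseline comparisons pick the right test and match exact oracles", {
  # Fisher on {1,9; 8,2} vs the hypergeometric enumeration
  x <- c(rep("A", 10), rep("B", 10))
  y <- c(rep(1, 1), rep(0, 9), rep(1, 8), rep(0, 2))
  res <- baseline_comparison(data.frame(id = 1:20, grp = x), y)
  expect_equal(res$test, "fisher")  # expected counts < 5
  fisher_oracle <- sum(vapply(0:9, function(k) {
    p <- dhyper(k, 9, 11, 10)
    if (p <= dhyper(1, 9, 11, 10) + 1e-12) p else 0
  }, 0))
  expect_equal(res$p, fisher_oracle, tolerance = 1e-9)

  # identical groups: p = 1
  same <- baseline_comparison(data.frame(id = 1:20, v = rep(2.5, 20)), y)
  expect_equal(same$p, 1)

  # large balanced categorical table goes through chi-square
  set.seed(88)
  big <- data.frame(id = 1:400, g = sample(c("A", "B"), 400, TRUE))
  yy <- rbinom(400, 1, 0.5)
  res2 <- baseline_comparison(big, yy)
  expect_equal(res2$test, "chisq")
  expect_equal(res2$p,
               suppressWarnings(chisq.test(table(big$g, yy),
                                           correct = FALSE)$p.value))

  # continuous covariates get the normality-gated two-sample test
  cont <- data.frame(id = 1:40, v = c(rnorm(20), rnorm(20, 1)))
  res3 <- baseline_comparison(cont, rep(0:1, each = 20))
  expect_true(res3$test %in% c("t", "MWU"))
})

test_that("evaluation reports are complete and internally consistent", {
  set.seed(89)
  n <- 80
  y <- rep(0:1, each = n / 2)
  scores <- list(good = plogis(2 * y + rnorm(n)),
                 weak = plogis(0.3 * y + rnorm(n)))
  thr <- vapply(scores, youden_threshold, 0, labels = y)
  rep1 <- eval_report(scores, y, thr)
  expect_equal(rep1$metrics$model, c("good", "weak"))
  expect_true(all(rep1$metrics$ci_lower <= rep1$metrics$auc &
                    rep1$metrics$auc <= rep1$metrics$ci_upper))
  expect_equal(rep1$delong_p, t(rep1$delong_p))
  expect_true(all(diag(rep1$delong_p) == 1))
  # pure: identical inputs give identical reports
  rep2 <- eval_report(scores, y, thr)
  expect_identical(rep1, rep2)
})
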