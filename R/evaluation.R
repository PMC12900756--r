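#' Area under the ROC curve
#'
#' Mann-Whitney pair-counting statistic: the fraction of
#' (positive, negative) pairs ranked concordantly, ties counted 1/2.
#'
#' @param scores numeric risk scores.
#' @param labels binary labels (1 = positive).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  y <- as.numeric(labels)
  if (length(unique(y)) < 2) stop("both classes required for AUC")
  r <- rank(scores)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong placement values: V10 (per positive) and V01 (per negative).
delong_placements <- function(scores, labels) {
  y <- as.numeric(labels)
  xs <- scores[y == 1]
  ys <- scores[y == 0]
  v10 <- vapply(xs, function(x) mean((x > ys) + 0.5 * (x == ys)), 0)
  v01 <- vapply(ys, function(x) mean((xs > x) + 0.5 * (xs == x)), 0)
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong confidence interval for a single AUC
#'
#' Variance from the placement-value decomposition; normal-approximation CI
#' truncated to \[0, 1\]. Perfect separation gives zero variance and a
#' degenerate (flagged) interval.
#'
#' @param scores,labels as in [roc_auc()].
#' @param level confidence level (default 0.95).
#' @return list(auc, lower, upper, se, degenerate).
#' @export
delong_ci <- function(scores, labels, level = 0.95) {
  y <- as.numeric(labels)
  stopifnot(sum(y == 1) >= 2, sum(y == 0) >= 2)
  pl <- delong_placements(scores, labels)
  v <- var(pl$v10) / length(pl$v10) + var(pl$v01) / length(pl$v01)
  z <- qnorm(1 - (1 - level) / 2)
  se <- sqrt(v)
  list(auc = pl$auc,
       lower = max(0, pl$auc - z * se),
       upper = min(1, pl$auc + z * se),
       se = se, degenerate = v == 0)
}

#' DeLong test comparing two correlated AUCs
#'
#' Paired comparison of models A and B scored on the same patients, using the
#' covariance of their placement values.
#'
#' @param scores_a,scores_b paired score vectors.
#' @param labels shared binary labels.
#' @return list(auc_a, auc_b, z, p).
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  stopifnot(length(scores_a) == length(scores_b))
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  n1 <- length(pa$v10); n0 <- length(pa$v01)
  s10 <- cov(cbind(pa$v10, pb$v10))
  s01 <- cov(cbind(pa$v01, pb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  d <- pa$auc - pb$auc
  z <- if (v <= 0) { if (d == 0) 0 else sign(d) * Inf } else d / sqrt(v)
  list(auc_a = pa$auc, auc_b = pb$auc, z = z,
       p = if (is.infinite(z)) 0 else 2 * pnorm(-abs(z)))
}

#' Youden-optimal threshold
#' @param scores,labels training scores and labels.
#' @return Threshold maximizing sensitivity + specificity - 1.
#' @export
youden_threshold <- function(scores, labels) {
  y <- as.numeric(labels)
  cand <- sort(unique(scores))
  j <- vapply(cand, function(t) {
    mean(scores[y == 1] >= t) + mean(scores[y == 0] < t) - 1
  }, 0)
  cand[which.max(j)]
}

#' Threshold (confusion-matrix) metrics
#'
#' The threshold is fixed upstream — by default Youden-optimal on training
#' scores, then applied unchanged to test scores. Empty predicted classes
#' give `NaN` PPV/NPV, flagged in the result.
#'
#' @param scores,labels evaluation scores and labels.
#' @param threshold classification cutoff (predict positive when score >=
#'   threshold).
#' @return list(accuracy, sensitivity, specificity, ppv, npv, threshold,
#'   confusion).
#' @export
threshold_metrics <- function(scores, labels, threshold) {
  y <- as.numeric(labels)
  if (length(unique(y)) < 2) stop("both classes required")
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & y == 1); fn <- sum(pred == 0 & y == 1)
  fp <- sum(pred == 1 & y == 0); tn <- sum(pred == 0 & y == 0)
  list(accuracy = (tp + tn) / length(y),
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       ppv = if (tp + fp > 0) tp / (tp + fp) else NaN,
       npv = if (tn + fn > 0) tn / (tn + fn) else NaN,
       threshold = threshold,
       confusion = c(tp = tp, fn = fn, fp = fp, tn = tn))
}

#' Calibration curve and Brier score
#'
#' Equal-frequency bins of predicted probability; per bin the mean prediction
#' and observed event fraction. Brier score is the mean squared error of the
#' probabilities.
#'
#' @param probabilities predictions in \[0, 1\].
#' @param labels binary outcomes.
#' @param n_bins requested bins (default 10; reduced with a warning when
#'   there are fewer samples or distinct values).
#' @return list(bins = data.frame(mean_predicted, observed, n), brier).
#' @export
calibration_curve <- function(probabilities, labels, n_bins = 10) {
  stopifnot(all(probabilities >= 0 & probabilities <= 1))
  y <- as.numeric(labels)
  n <- length(y)
  if (n_bins > n) {
    warning("more bins than samples; reducing")
    n_bins <- n
  }
  qs <- unique(quantile(probabilities, seq(0, 1, length.out = n_bins + 1)))
  if (length(qs) < 2) qs <- c(qs, qs + 1e-12)
  bin <- cut(probabilities, qs, include.lowest = TRUE)
  bins <- data.frame(
    mean_predicted = as.numeric(tapply(probabilities, bin, mean)),
    observed = as.numeric(tapply(y, bin, mean)),
    n = as.numeric(table(bin)))
  bins <- bins[bins$n > 0, , drop = FALSE]
  list(bins = bins, brier = mean((probabilities - y)^2))
}

#' Decision curve analysis (net benefit)
#'
#' Net benefit at threshold probability `p_t` is
#' `TP/n - (FP/n) * p_t / (1 - p_t)`, with treat-all and treat-none
#' reference strategies.
#'
#' @param probabilities model predictions in \[0, 1\].
#' @param labels binary outcomes.
#' @param thresholds threshold grid on (0, 1); values of 1 are excluded.
#' @return data.frame(threshold, model, treat_all, treat_none).
#' @export
decision_curve <- function(probabilities, labels,
                           thresholds = seq(0.01, 0.99, by = 0.01)) {
  stopifnot(all(probabilities >= 0 & probabilities <= 1))
  thresholds <- thresholds[thresholds > 0 & thresholds < 1]
  y <- as.numeric(labels)
  n <- length(y)
  prev <- mean(y)
  nb <- vapply(thresholds, function(pt) {
    pred <- probabilities >= pt
    tp <- sum(pred & y == 1) / n
    fp <- sum(pred & y == 0) / n
    tp - fp * pt / (1 - pt)
  }, 0)
  all_nb <- prev - (1 - prev) * thresholds / (1 - thresholds)
  data.frame(threshold = thresholds, model = nb, treat_all = all_nb,
             treat_none = 0)
}

#' Shapley attribution summary
#'
#' Sampling-based Shapley values with a background (reference) set: for each
#' sampled feature permutation the telescoping marginal contributions sum
#' exactly to `f(x) - base`, so local accuracy holds to numerical precision
#' for any number of permutations. Global importance ranks features by mean
#' absolute attribution.
#'
#' @param model object with a [predict_probability()] method.
#' @param feature_table rows to explain (data.frame with `id`).
#' @param background reference table drawn from the training data.
#' @param n_perm sampled permutations per row (default 16; exact for up to
#'   ~8 features when `exhaustive = TRUE`).
#' @param exhaustive use all permutations (feasible for few features).
#' @param seed RNG seed.
#' @return list(attributions = matrix rows x features, base_value,
#'   importance = sorted mean |attribution|).
#' @export
attribution_summary <- function(model, feature_table, background,
                                n_perm = 16, exhaustive = FALSE, seed = 1L) {
  if (is.null(background) || nrow(background) == 0)
    stop("background set must be nonempty")
  feats <- setdiff(colnames(feature_table), "id")
  x <- as.matrix(feature_table[, feats, drop = FALSE])
  bg <- as.matrix(background[, feats, drop = FALSE])
  p <- ncol(x)
  predfun <- function(m) {
    df <- data.frame(id = seq_len(nrow(m)), m, check.names = FALSE)
    colnames(df) <- c("id", feats)
    predict_probability(model, df)
  }
  base_value <- mean(predfun(bg))
  perms <- if (exhaustive && p <= 8) {
    all_permutations(p)
  } else {
    set.seed(seed)
    lapply(seq_len(n_perm), function(i) sample.int(p))
  }
  phi <- matrix(0, nrow(x), p, dimnames = list(feature_table$id, feats))
  for (r in seq_len(nrow(x))) {
    acc <- numeric(p)
    for (pm in perms) {
      cur <- bg
      prev <- mean(predfun(cur))
      for (f in pm) {
        cur[, f] <- x[r, f]
        now <- mean(predfun(cur))
        acc[f] <- acc[f] + (now - prev)
        prev <- now
      }
    }
    phi[r, ] <- acc / length(perms)
  }
  importance <- sort(colMeans(abs(phi)), decreasing = TRUE)
  list(attributions = phi, base_value = base_value, importance = importance)
}

all_permutations <- function(p) {
  if (p == 1) return(list(1L))
  out <- list()
  for (sub in all_permutations(p - 1))
    for (pos in 0:(p - 1))
      out[[length(out) + 1L]] <- append(sub, p, after = pos)
  out
}

#' Baseline-table group comparisons
#'
#' Continuous covariates: Shapiro-gated Welch t-test or Mann-Whitney U.
#' Categorical covariates: chi-square, or Fisher's exact test when any
#' expected cell count is below 5. Two-sided p values throughout.
#'
#' @param clinical_table data.frame of covariates (plus `id`, ignored).
#' @param labels binary group labels.
#' @return data.frame(variable, type, test, p).
#' @export
baseline_comparison <- function(clinical_table, labels) {
  covs <- setdiff(colnames(clinical_table), c("id", "grade"))
  y <- as.numeric(labels)
  rows <- lapply(covs, function(v) {
    x <- clinical_table[[v]]
    categorical <- is.character(x) || is.factor(x) || is.logical(x) ||
      length(unique(x)) <= 4
    if (!categorical) {
      if (length(unique(x)) == 1) {
        return(data.frame(variable = v, type = "continuous", test = "t",
                          p = 1))
      }
      a <- x[y == 1]; b <- x[y == 0]
      stopifnot(length(a) >= 2, length(b) >= 2)
      normal <- function(z) length(unique(z)) >= 3 && length(z) >= 3 &&
        shapiro.test(z)$p.value >= 0.05
      if (normal(a) && normal(b)) {
        data.frame(variable = v, type = "continuous", test = "t",
                   p = t.test(a, b)$p.value)
      } else {
        data.frame(variable = v, type = "continuous", test = "MWU",
                   p = mann_whitney_p(a, b))
      }
    } else {
      tab <- table(factor(x), factor(y))
      tab <- tab[rowSums(tab) > 0, , drop = FALSE]
      if (nrow(tab) < 2 || ncol(tab) < 2) {
        return(data.frame(variable = v, type = "categorical",
                          test = "chisq", p = 1))
      }
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5)) {
        data.frame(variable = v, type = "categorical", test = "fisher",
                   p = fisher.test(tab)$p.value)
      } else {
        data.frame(variable = v, type = "categorical", test = "chisq",
                   p = suppressWarnings(chisq.test(tab, correct = FALSE)$p.value))
      }
    }
  })
  do.call(rbind, rows)
}

#' Evaluation report for a set of models on one cohort
#'
#' @param scores named list of score vectors (one per model) on the same
#'   patients.
#' @param labels binary labels of the cohort.
#' @param thresholds named thresholds per model (typically Youden on the
#'   training cohort).
#' @return list(metrics = data.frame per model, delong_p = model x model
#'   matrix, calibration, dca) — the Table-3-shaped summary for one cohort.
#' @export
eval_report <- function(scores, labels, thresholds) {
  models <- names(scores)
  metrics <- do.call(rbind, lapply(models, function(m) {
    ci <- tryCatch(delong_ci(scores[[m]], labels), error = function(e)
      list(auc = tryCatch(roc_auc(scores[[m]], labels),
                          error = function(e2) NA_real_),
           lower = NA_real_, upper = NA_real_))
    tm <- threshold_metrics(scores[[m]], labels, thresholds[[m]])
    data.frame(model = m, auc = ci$auc, ci_lower = ci$lower,
               ci_upper = ci$upper, accuracy = tm$accuracy,
               sensitivity = tm$sensitivity, specificity = tm$specificity,
               ppv = tm$ppv, npv = tm$npv, threshold = tm$threshold,
               stringsAsFactors = FALSE)
  }))
  dl <- matrix(1, length(models), length(models),
               dimnames = list(models, models))
  if (length(models) > 1) {
    for (i in seq_along(models)) for (j in seq_along(models)) {
      if (i < j) {
        p <- tryCatch(delong_test(scores[[i]], scores[[j]], labels)$p,
                      error = function(e) NA_real_)
        dl[i, j] <- dl[j, i] <- p
      }
    }
  }
  list(metrics = metrics, delong_p = dl,
       calibration = lapply(scores, calibration_curve, labels = labels),
       dca = lapply(scores, decision_curve, labels = labels))
}
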