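#' Z-score standardization fitted on training rows
#'
#' Centers and scales every feature with the training mean and population SD;
#' other tables are transformed with the same parameters. Training columns
#' with zero SD carry no information and are dropped with a warning.
#'
#' @param train_table training feature table (data.frame with `id`).
#' @param other_tables named list of tables transformed with training
#'   parameters (e.g. the test set).
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return list(train, others, params) with `params$center` / `params$scale`.
#' @export
zscore_fit_apply <- function(train_table, other_tables = list(),
                             sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  m <- feature_matrix(train_table)
  ctr <- colMeans(m)
  scl <- apply(m, 2, sd)
  if (sd_type == "population") scl <- scl * sqrt((nrow(m) - 1) / nrow(m))
  dead <- which(!is.finite(scl) | scl == 0)
  if (length(dead) > 0) {
    warning("dropping ", length(dead), " zero-variance feature(s)")
    m <- m[, -dead, drop = FALSE]
    ctr <- ctr[-dead]; scl <- scl[-dead]
  }
  apply_z <- function(tab) {
    mm <- feature_matrix(tab)[, names(ctr), drop = FALSE]
    z <- sweep(sweep(mm, 2, ctr), 2, scl, "/")
    data.frame(id = tab$id, z, check.names = FALSE, row.names = NULL,
               stringsAsFactors = FALSE)
  }
  train <- data.frame(id = train_table$id,
                      sweep(sweep(m, 2, ctr), 2, scl, "/"),
                      check.names = FALSE, row.names = NULL,
                      stringsAsFactors = FALSE)
  list(train = train, others = lapply(other_tables, apply_z),
       params = list(center = ctr, scale = scl))
}

#' Univariate two-group filtering
#'
#' Per feature: Shapiro-Wilk normality within each class at alpha 0.05 decides
#' between a Welch t-test (both classes normal) and a two-sided Mann-Whitney U
#' test (normal approximation with tie correction). Features with p < `alpha`
#' survive.
#'
#' @param table feature table.
#' @param labels binary outcome aligned with `table` rows.
#' @param alpha retention threshold (default 0.05).
#' @return list(survivors = names, p_values, test = "t" or "MWU" per feature).
#' @export
univariate_filter <- function(table, labels, alpha = 0.05) {
  if (length(unique(labels)) < 2) stop("both classes must be present")
  m <- feature_matrix(table)
  g1 <- labels == sort(unique(labels))[1]
  p <- numeric(ncol(m)); tst <- character(ncol(m))
  for (u in seq_len(ncol(m))) {
    a <- m[g1, u]; b <- m[!g1, u]
    normal <- function(x) {
      if (length(unique(x)) < 3 || length(x) < 3 || length(x) > 5000) return(FALSE)
      shapiro.test(x)$p.value >= 0.05
    }
    if (normal(a) && normal(b)) {
      tst[u] <- "t"
      p[u] <- tryCatch(t.test(a, b)$p.value, error = function(e) 1)
    } else {
      tst[u] <- "MWU"
      p[u] <- mann_whitney_p(a, b)
    }
  }
  names(p) <- names(tst) <- colnames(m)
  list(survivors = colnames(m)[p < alpha], p_values = p, test = tst)
}

# Two-sided Mann-Whitney U with normal approximation and tie correction.
mann_whitney_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  n <- n1 + n2
  ties <- table(r)
  sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sig2 <= 0) return(1)
  cc <- sign(u - mu) * 0.5  # continuity correction
  z <- (u - mu - cc) / sqrt(sig2)
  min(1, 2 * pnorm(-abs(z)))
}

#' Greedy correlation pruning
#'
#' Features are visited in order of ascending univariate p; any later feature
#' with |Pearson r| above the threshold to an already-kept feature is dropped,
#' so the final set is pairwise |r| <= threshold and each correlated pair
#' keeps its more discriminative member.
#'
#' @param table feature table.
#' @param survivors candidate feature names.
#' @param p_values univariate p per feature (ordering key).
#' @param r_threshold default 0.9.
#' @return list(survivors, pruned_pairs = data.frame(kept, dropped, r)).
#' @export
correlation_prune <- function(table, survivors, p_values,
                              r_threshold = 0.9) {
  if (length(survivors) == 0) return(list(survivors = character(0),
                                          pruned_pairs = NULL))
  ordv <- survivors[order(p_values[survivors])]
  m <- feature_matrix(table)[, ordv, drop = FALSE]
  keep <- character(0)
  pairs <- list()
  for (f in ordv) {
    if (length(keep) == 0) { keep <- f; next }
    r <- suppressWarnings(abs(cor(m[, f], m[, keep, drop = FALSE])))
    r[is.na(r)] <- 0
    if (any(r > r_threshold)) {
      w <- which.max(r)
      pairs[[length(pairs) + 1L]] <-
        data.frame(kept = keep[w], dropped = f, r = r[w])
    } else keep <- c(keep, f)
  }
  list(survivors = keep,
       pruned_pairs = if (length(pairs)) do.call(rbind, pairs) else NULL)
}

#' LASSO logistic feature selection with cross-validated lambda
#'
#' L1-penalized logistic regression over a log-spaced lambda grid; lambda is
#' chosen by minimum mean cross-validated binomial deviance on stratified
#' folds (the one-standard-error rule is available via `rule = "1se"`).
#' Features with nonzero coefficients at the chosen lambda are selected.
#'
#' @param table feature table restricted to the candidate features.
#' @param labels binary outcome.
#' @param n_folds CV folds (default 10); reduced with a warning when a class
#'   has fewer members than folds.
#' @param lambda_grid optional lambda sequence (glmnet's default otherwise).
#' @param rule `"min"` (default) or `"1se"`.
#' @param seed fold-assignment seed.
#' @return A `selection_result`: selected names + coefficients, chosen
#'   lambda, CV path (lambda, mean deviance, SD).
#' @export
lasso_select <- function(table, labels, n_folds = 10, lambda_grid = NULL,
                         rule = c("min", "1se"), seed = 1L) {
  rule <- match.arg(rule)
  x <- feature_matrix(table)
  y <- as.numeric(labels)
  if (ncol(x) < 2) {
    # the L1 path needs >= 2 columns; a single candidate passes through
    return(structure(list(selected = colnames(x),
                          coefficients = setNames(rep(NA_real_, ncol(x)),
                                                  colnames(x)),
                          intercept = NA_real_, lasso_lambda = NA_real_,
                          lasso_path = NULL, n_folds = n_folds, seed = seed),
                     class = "selection_result"))
  }
  mc <- min(table(y))
  if (mc < 3) {
    warning("too few samples per class for cross-validated LASSO; ",
            "keeping all candidate features")
    return(structure(list(selected = colnames(x),
                          coefficients = setNames(rep(NA_real_, ncol(x)),
                                                  colnames(x)),
                          intercept = NA_real_, lasso_lambda = NA_real_,
                          lasso_path = NULL, n_folds = n_folds, seed = seed),
                     class = "selection_result"))
  }
  if (mc < n_folds) {
    warning("reducing CV folds from ", n_folds, " to ", max(3, mc),
            " (smallest class size)")
    n_folds <- max(3, mc)  # cv.glmnet needs at least 3 folds
  }
  set.seed(seed)
  foldid <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    foldid[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  cv <- glmnet::cv.glmnet(x, y, family = "binomial", foldid = foldid,
                          lambda = lambda_grid, standardize = FALSE,
                          type.measure = "deviance")
  lam <- if (rule == "min") cv$lambda.min else cv$lambda.1se
  co <- coef(cv, s = lam)
  sel <- rownames(co)[-1][as.numeric(co)[-1] != 0]
  if (length(sel) == 0) warning("LASSO selected no features at chosen lambda")
  structure(list(selected = sel,
                 coefficients = setNames(as.numeric(co)[-1][as.numeric(co)[-1] != 0], sel),
                 intercept = as.numeric(co)[1],
                 lasso_lambda = lam,
                 lasso_path = data.frame(lambda = cv$lambda, cvm = cv$cvm,
                                         cvsd = cv$cvsd),
                 n_folds = n_folds, seed = seed),
            class = "selection_result")
}

#' The full feature-selection cascade of one region
#'
#' Fixed, logged order: ICC filtering (done upstream), z-score, univariate
#' filter, correlation pruning, LASSO. Every stage is fitted on training rows
#' only; the test table is transformed/subset by training decisions.
#'
#' @param train_table,test_table imputed (and, for reader-covered regions,
#'   ICC-filtered) feature tables.
#' @param labels_train binary training outcome.
#' @param alpha,r_threshold,n_folds cascade thresholds (defaults 0.05 / 0.9
#'   / 10).
#' @param seed seed for the LASSO folds.
#' @return list(train, test, selection) where the tables hold only selected
#'   (standardized) features.
#' @export
select_cascade <- function(train_table, test_table, labels_train,
                           alpha = 0.05, r_threshold = 0.9, n_folds = 10,
                           seed = 1L) {
  z <- zscore_fit_apply(train_table, list(test = test_table))
  uni <- univariate_filter(z$train, labels_train, alpha)
  if (length(uni$survivors) == 0)
    return(list(train = z$train[, "id", drop = FALSE],
                test = z$others$test[, "id", drop = FALSE],
                selection = list(selected = character(0), univariate = uni)))
  pr <- correlation_prune(z$train, uni$survivors, uni$p_values, r_threshold)
  lt <- z$train[, c("id", pr$survivors), drop = FALSE]
  ls <- lasso_select(lt, labels_train, n_folds = n_folds, seed = seed)
  sel <- if (length(ls$selected) > 0) ls$selected else pr$survivors
  list(train = z$train[, c("id", sel), drop = FALSE],
       test = z$others$test[, c("id", sel), drop = FALSE],
       selection = list(selected = sel, zscore_params = z$params,
                        univariate = uni, pruned_pairs = pr$pruned_pairs,
                        lasso = ls))
}
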