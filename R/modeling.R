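#' Screen clinical covariates by univariate / multivariate logistic regression
#'
#' Each covariate is tested in a univariate logistic model (OR, 95% Wald CI,
#' p); covariates with univariate p below `entry_alpha` enter one multivariate
#' model, and those with multivariate p < 0.05 are returned as independent
#' predictors. Perfect separation is flagged and the affected fit is
#' ridge-stabilized.
#'
#' @param clinical_table data.frame with `id` and covariate columns.
#' @param labels binary outcome aligned with rows.
#' @param entry_alpha multivariate entry threshold (default 0.05).
#' @return list(univariate, multivariate, independent) — the first two are OR
#'   tables, the last the independent predictor names.
#' @export
screen_clinical <- function(clinical_table, labels, entry_alpha = 0.05) {
  covs <- setdiff(colnames(clinical_table), c("id", "grade"))
  if (length(covs) == 0) stop("no covariates to screen")
  if (length(unique(labels)) < 2) stop("both classes must be present")
  y <- as.numeric(labels)

  uni_row <- function(v) {
    df <- data.frame(y = y, x = clinical_table[[v]])
    fit <- suppressWarnings(glm(y ~ x, data = df, family = binomial()))
    separated <- any(abs(coef(fit)[-1]) > 15, na.rm = TRUE)
    if (separated) {
      x <- model.matrix(~x, df)[, -1, drop = FALSE]
      rg <- glmnet::glmnet(cbind(x, 0), y, family = "binomial", alpha = 0,
                           lambda = 0.1)
      beta <- as.numeric(coef(rg))[2]
      data.frame(covariate = v, or = exp(beta), lower = NA, upper = NA,
                 p = NA, separated = TRUE, stringsAsFactors = FALSE)
    } else {
      s <- summary(fit)$coefficients
      beta <- s[2, 1]; se <- s[2, 2]; p <- s[2, 4]
      data.frame(covariate = v, or = exp(beta),
                 lower = exp(beta - 1.96 * se), upper = exp(beta + 1.96 * se),
                 p = p, separated = FALSE, stringsAsFactors = FALSE)
    }
  }
  uni <- do.call(rbind, lapply(covs, uni_row))

  entered <- uni$covariate[!is.na(uni$p) & uni$p < entry_alpha]
  multi <- NULL
  independent <- character(0)
  if (length(entered) > 0) {
    df <- data.frame(y = y, clinical_table[entered], check.names = FALSE)
    fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
    s <- summary(fit)$coefficients
    s <- s[-1, , drop = FALSE]
    multi <- data.frame(term = rownames(s), or = exp(s[, 1]),
                        lower = exp(s[, 1] - 1.96 * s[, 2]),
                        upper = exp(s[, 1] + 1.96 * s[, 2]), p = s[, 4],
                        row.names = NULL, stringsAsFactors = FALSE)
    sig_terms <- multi$term[multi$p < 0.05]
    independent <- entered[vapply(entered, function(v)
      any(startsWith(sig_terms, v)), TRUE)]
  }
  list(univariate = uni, multivariate = multi, independent = independent)
}

# ---------------------------------------------------------------------------
# Five-algorithm classifier interface
# ---------------------------------------------------------------------------

#' The fixed algorithm set and default hyperparameter grids
#'
#' Five algorithms behind one fit/predict interface: logistic regression,
#' SVM (Platt-calibrated probabilities), random forest, extremely randomized
#' trees, and gradient-boosted trees ("GBM", backed by xgboost). Grids are
#' deliberately small and logged with the fitted model.
#'
#' @return Named list of algorithm descriptors in the fixed tie-break order
#'   LR < SVM < RF < ExtraTrees < GBM.
#' @export
algorithm_set <- function() {
  expand_named <- function(...) {
    g <- expand.grid(..., stringsAsFactors = FALSE)
    lapply(seq_len(nrow(g)), function(i) as.list(g[i, , drop = FALSE]))
  }
  list(
    LR = list(grid = list(list())),
    SVM = list(grid = expand_named(kernel = c("linear", "radial"),
                                   cost = c(0.1, 1, 10))),
    RF = list(grid = expand_named(ntree = c(100, 300))),
    ExtraTrees = list(grid = expand_named(num.trees = c(100, 300))),
    GBM = list(grid = expand_named(nrounds = c(50, 150), max_depth = c(3, 5)))
  )
}

fit_algorithm <- function(algorithm, x, y, params, seed) {
  set.seed(seed)
  switch(algorithm,
    LR = {
      df <- data.frame(y = y, x)
      suppressWarnings(glm(y ~ ., data = df, family = binomial()))
    },
    SVM = {
      yf <- factor(y, levels = c(0, 1))
      fit <- tryCatch(
        e1071::svm(x, yf, kernel = params$kernel, cost = params$cost,
                   probability = TRUE, scale = FALSE),
        error = function(e) NULL)
      if (is.null(fit)) {
        # internal Platt CV can fail on very small folds; fall back to a
        # logistic sigmoid fitted on the decision values
        fit <- e1071::svm(x, yf, kernel = params$kernel, cost = params$cost,
                          scale = FALSE)
        dv <- as.numeric(attr(predict(fit, x, decision.values = TRUE),
                              "decision.values"))
        attr(fit, "platt") <- suppressWarnings(
          glm(y ~ dv, family = binomial(), data = data.frame(y = y, dv = dv)))
      }
      fit
    },
    RF = randomForest::randomForest(x, factor(y, levels = c(0, 1)),
                                    ntree = params$ntree),
    ExtraTrees = ranger::ranger(
      x = x, y = factor(y, levels = c(0, 1)), num.trees = params$num.trees,
      splitrule = "extratrees", probability = TRUE, seed = seed,
      num.threads = 1),
    GBM = xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = params$max_depth,
                    eta = 0.1, nthread = 1, seed = seed),
      data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
      nrounds = params$nrounds, verbose = 0),
    stop("unknown algorithm: ", algorithm))
}

predict_algorithm <- function(algorithm, fit, x) {
  switch(algorithm,
    LR = as.numeric(predict(fit, data.frame(x), type = "response")),
    SVM = {
      if (!is.null(attr(fit, "platt"))) {
        dv <- as.numeric(attr(predict(fit, x, decision.values = TRUE),
                              "decision.values"))
        as.numeric(predict(attr(fit, "platt"),
                           newdata = data.frame(dv = dv), type = "response"))
      } else {
        pr <- attr(predict(fit, x, probability = TRUE), "probabilities")
        as.numeric(pr[, "1"])
      }
    },
    RF = as.numeric(predict(fit, x, type = "prob")[, "1"]),
    ExtraTrees = {
      pr <- predict(fit, data = x)$predictions
      if ("1" %in% colnames(pr)) as.numeric(pr[, "1"])
      else as.numeric(1 - pr[, "0"])
    },
    GBM = as.numeric(predict(fit, xgboost::xgb.DMatrix(x, nthread = 1))))
}

stratified_folds <- function(y, n_folds, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  fold
}

#' Train one region model with cross-validated hyperparameter tuning
#'
#' Grid search maximizing out-of-fold AUC on stratified training folds, then
#' a refit on the full training set at the best configuration. The model's
#' radscore is its predicted probability of high grade.
#'
#' @param features feature table (data.frame with `id`) of selected features.
#' @param labels binary training outcome.
#' @param algorithm one of `names(algorithm_set())`.
#' @param cv_folds tuning folds (default 5, reduced if a class is smaller).
#' @param seed RNG seed.
#' @return A `trained_model` (algorithm, params, fit, cv_auc, feature names).
#' @export
train_region_model <- function(features, labels, algorithm, cv_folds = 5,
                               seed = 1L) {
  x <- feature_matrix(features)
  if (ncol(x) == 0) stop("empty feature set")
  y <- as.numeric(labels)
  cv_folds <- max(2, min(cv_folds, min(table(y))))
  spec <- algorithm_set()[[algorithm]]
  if (is.null(spec)) stop("unknown algorithm: ", algorithm)
  fold <- stratified_folds(y, cv_folds, seed)
  cv_auc <- vapply(spec$grid, function(params) {
    oof <- rep(NA_real_, length(y))
    for (f in seq_len(cv_folds)) {
      tr <- fold != f
      fit <- tryCatch(
        fit_algorithm(algorithm, x[tr, , drop = FALSE], y[tr], params,
                      seed = seed + 1000L * f),
        error = function(e) NULL)
      if (!is.null(fit))
        oof[!tr] <- predict_algorithm(algorithm, fit, x[!tr, , drop = FALSE])
    }
    ok <- !is.na(oof)
    tryCatch(roc_auc(oof[ok], y[ok]), error = function(e) 0.5)
  }, 0)
  best <- which.max(cv_auc)  # ties: first (grid order is fixed)
  fit <- fit_algorithm(algorithm, x, y, spec$grid[[best]], seed = seed)
  structure(list(algorithm = algorithm, params = spec$grid[[best]],
                 fit = fit, cv_auc = cv_auc[best], cv_auc_grid = cv_auc,
                 features = colnames(x), cv_folds = cv_folds, seed = seed),
            class = "trained_model")
}

#' Predicted probability of high grade (the radscore)
#' @param model a `trained_model` or `nomogram_model`.
#' @param features feature table or data.frame of model inputs.
#' @return Numeric vector in \[0, 1\].
#' @export
predict_probability <- function(model, features) {
  UseMethod("predict_probability")
}

#' @export
predict_probability.trained_model <- function(model, features) {
  x <- feature_matrix(features)[, model$features, drop = FALSE]
  p <- predict_algorithm(model$algorithm, model$fit, x)
  pmin(pmax(p, 0), 1)
}

#' Pick the best algorithm for a region
#'
#' Policy `"cv"` (default, leakage-free) takes the candidate with the highest
#' tuning CV AUC. Policy `"paper_faithful"` takes the highest test-set AUC —
#' the selection rule of the original workflow — and emits a selection-bias
#' warning, since that step reads test labels. Ties break by the fixed
#' algorithm order LR < SVM < RF < ExtraTrees < GBM.
#'
#' @param models named list of `trained_model`s (one per algorithm).
#' @param evaluation_scores named AUC per model, matching `names(models)`;
#'   required (and used) only for `policy = "paper_faithful"`.
#' @param policy `"cv"` or `"paper_faithful"`.
#' @return list(model, algorithm, score, policy).
#' @export
select_best_algorithm <- function(models, evaluation_scores = NULL,
                                  policy = c("cv", "paper_faithful")) {
  policy <- match.arg(policy)
  stopifnot(length(models) >= 1)
  order_ref <- names(algorithm_set())
  algs <- names(models)
  scores <- if (policy == "paper_faithful") {
    warning("paper_faithful policy selects on test-set AUC; ",
            "reported performance is optimistically biased")
    evaluation_scores[algs]
  } else {
    vapply(models, `[[`, 0, "cv_auc")
  }
  ord <- order(-scores, match(algs, order_ref))
  best <- algs[ord[1]]
  list(model = models[[best]], algorithm = best, score = scores[[best]],
       policy = policy)
}

#' Build the combined nomogram model
#'
#' Logistic regression of grade on the independent clinical predictor(s) and
#' the training radscores of the frozen intratumoral, 2-mm peritumoral and
#' integrated-habitat models, plus a 0-100 points-scale mapping per input.
#'
#' @param inputs_train data.frame with `id`, the clinical predictor columns
#'   and one radscore column per region model.
#' @param labels_train binary training outcome.
#' @return A `nomogram_model` (glm coefficients, points table, input names).
#' @export
build_nomogram <- function(inputs_train, labels_train) {
  vars <- setdiff(colnames(inputs_train), "id")
  x <- as.matrix(inputs_train[, vars, drop = FALSE])
  rs <- x[, grep("radscore", vars), drop = FALSE]
  ridge <- FALSE
  if (ncol(rs) >= 2) {
    cc <- abs(cor(rs))
    diag(cc) <- 0
    if (any(cc > 0.999)) {
      warning("near-collinear radscores; ridge-stabilized fit")
      ridge <- TRUE
    }
  }
  y <- as.numeric(labels_train)
  if (ridge) {
    fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0, lambda = 1e-3)
    beta <- setNames(as.numeric(coef(fit))[-1], vars)
    intercept <- as.numeric(coef(fit))[1]
  } else {
    df <- data.frame(y = y, x, check.names = FALSE)
    fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
    beta <- setNames(coef(fit)[-1], vars)
    intercept <- coef(fit)[1]
  }
  rng <- apply(x, 2, function(v) range(v))
  span <- abs(beta) * (rng[2, ] - rng[1, ])
  ref <- max(span, 1e-12)
  points <- data.frame(
    input = vars, coefficient = beta,
    low = rng[1, ], high = rng[2, ],
    points_per_unit = 100 * abs(beta) / ref,
    max_points = 100 * span / ref, row.names = NULL)
  structure(list(coefficients = beta, intercept = intercept,
                 points = points, inputs = vars),
            class = "nomogram_model")
}

#' @export
predict_probability.nomogram_model <- function(model, features) {
  x <- as.matrix(features[, model$inputs, drop = FALSE])
  plogis(model$intercept + drop(x %*% model$coefficients))
}
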