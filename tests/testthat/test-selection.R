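test_that("z-score standardization uses training parameters everywhere", {
  train <- data.frame(id = c("a", "b", "c"), f = c(1, 2, 3), k = c(5, 5, 5))
  test <- data.frame(id = "d", f = 2, k = 5)
  expect_warning(z <- zscore_fit_apply(train, list(test = test)),
                 "zero-variance")
  # population SD of {1,2,3} is sqrt(2/3); standardized values +-sqrt(3/2)
  expect_equal(z$train$f, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_false("k" %in% colnames(z$train))
  # a test value equal to the training mean maps to 0
  expect_equal(z$others$test$f, 0)
})

test_that("univariate filter gates on normality and drops uninformative features", {
  set.seed(61)
  n <- 50
  labels <- rep(0:1, each = n)
  tab <- data.frame(
    id = sprintf("p%03d", 1:(2 * n)),
    shifted = c(rnorm(n), rnorm(n, 2)),          # 2-SD shift: strong signal
    flat = rep(3, 2 * n),                        # identical in both classes
    skewed = c(rexp(n), rexp(n) + 1.5),          # non-normal: MWU branch
    check.names = FALSE)
  res <- univariate_filter(tab, labels)
  expect_true("shifted" %in% res$survivors)
  expect_lt(res$p_values["shifted"], 0.001)
  expect_false("flat" %in% res$survivors)
  expect_equal(unname(res$p_values["flat"]), 1)
  expect_equal(unname(res$test["skewed"]), "MWU")
  expect_error(univariate_filter(tab, rep(1, 2 * n)), "both classes")
})

test_that("Mann-Whitney normal approximation tracks the exact enumeration", {
  # exact p by enumerating all C(10,5) label assignments of the U statistic
  exact_mwu <- function(a, b) {
    vals <- c(a, b)
    combs <- utils::combn(10, 5)
    u_of <- function(idx) {
      r <- rank(vals)
      sum(r[idx]) - 5 * 6 / 2
    }
    u_obs <- u_of(1:5)
    us <- apply(combs, 2, u_of)
    mean(abs(us - 12.5) >= abs(u_obs - 12.5) - 1e-9)
  }
  set.seed(62)
  for (i in 1:5) {
    a <- rnorm(5); b <- rnorm(5, 1)
    p_approx <- habitomics:::mann_whitney_p(a, b)
    expect_lt(abs(p_approx - exact_mwu(a, b)), 0.05)
  }
})

test_that("correlation pruning keeps the more discriminative of a correlated pair", {
  set.seed(63)
  n <- 40
  x <- rnorm(n)
  tab <- data.frame(id = sprintf("p%02d", 1:n), a = x, b = x,
                    c = rnorm(n), check.names = FALSE)
  p_values <- c(a = 0.001, b = 0.01, c = 0.02)
  res <- correlation_prune(tab, c("a", "b", "c"), p_values)
  expect_setequal(res$survivors, c("a", "c"))  # duplicate: only smaller-p kept
  expect_equal(res$pruned_pairs$kept, "a")
  expect_equal(res$pruned_pairs$dropped, "b")

  # mutually uncorrelated features pass through unchanged
  tab2 <- data.frame(id = sprintf("p%02d", 1:n),
                     matrix(rnorm(n * 4), n, dimnames = list(NULL, letters[1:4])),
                     check.names = FALSE)
  res2 <- correlation_prune(tab2, letters[1:4], setNames(runif(4), letters[1:4]))
  expect_setequal(res2$survivors, letters[1:4])
})

test_that("pruned sets are pairwise below the threshold (brute-force check)", {
  set.seed(64)
  for (rep in 1:3) {
    n <- 30; pfe <- 12
    base <- matrix(rnorm(n * 4), n)
    m <- base[, sample(4, pfe, replace = TRUE)] + matrix(rnorm(n * pfe, sd = 0.2), n)
    colnames(m) <- paste0("f", seq_len(pfe))
    tab <- data.frame(id = sprintf("p%02d", 1:n), m, check.names = FALSE)
    pv <- setNames(runif(pfe), colnames(m))
    surv <- correlation_prune(tab, colnames(m), pv, r_threshold = 0.9)$survivors
    if (length(surv) > 1) {
      cc <- abs(cor(m[, surv]))
      diag(cc) <- 0
      expect_lte(max(cc), 0.9)
    }
  }
})

test_that("LASSO selection respects the penalty limits", {
  set.seed(65)
  n <- 80
  x <- matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("f", 1:5)))
  eta <- 1.5 * x[, 1] - 1.5 * x[, 2]
  y <- rbinom(n, 1, plogis(eta))
  tab <- data.frame(id = sprintf("p%02d", 1:n), x, check.names = FALSE)

  # a huge penalty shrinks every coefficient to zero
  expect_warning(
    res_inf <- lasso_select(tab, y, n_folds = 5, lambda_grid = c(100, 99)),
    "no features")
  expect_length(res_inf$selected, 0)

  # lambda -> 0 recovers the unpenalized logistic fit
  res0 <- lasso_select(tab, y, n_folds = 5, lambda_grid = c(1e-5, 1e-6),
                       seed = 2)
  fit <- glm(y ~ ., data = data.frame(y = y, x), family = binomial())
  expect_equal(unname(res0$coefficients[paste0("f", 1:5)]),
               unname(coef(fit)[paste0("f", 1:5)]), tolerance = 1e-2)

  # stability: identical seed, identical selection
  r1 <- lasso_select(tab, y, n_folds = 5, seed = 7)
  r2 <- lasso_select(tab, y, n_folds = 5, seed = 7)
  expect_identical(r1$selected, r2$selected)
  expect_identical(r1$lasso_lambda, r2$lasso_lambda)
  expect_true(r1$lasso_lambda %in% r1$lasso_path$lambda)
})

test_that("the cascade is fitted on training rows and transforms test rows", {
  set.seed(66)
  n <- 60
  y <- rep(0:1, each = n / 2)
  x <- cbind(matrix(rnorm(n * 3), n), y + rnorm(n, sd = 0.5))
  colnames(x) <- paste0("f", 1:4)
  tr <- data.frame(id = sprintf("tr%02d", 1:n), x, check.names = FALSE)
  te <- data.frame(id = sprintf("te%02d", 1:10),
                   matrix(rnorm(40), 10, dimnames = list(NULL, paste0("f", 1:4))),
                   check.names = FALSE)
  res <- suppressWarnings(select_cascade(tr, te, y, n_folds = 5, seed = 1))
  expect_true("f4" %in% res$selection$selected)
  expect_identical(colnames(res$train), colnames(res$test))
  # test standardized with training parameters
  mu <- res$selection$zscore_params$center["f4"]
  sg <- res$selection$zscore_params$scale["f4"]
  expect_equal(res$test$f4, (te$f4 - mu) / sg, ignore_attr = TRUE)
})
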