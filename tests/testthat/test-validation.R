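test_that("noiseless linear structure cross-validates perfectly", {
  set.seed(1)
  x <- matrix(rnorm(15 * 4), 15, 4)
  y <- as.vector(x %*% c(2, -1, 0.5, 0))
  cv <- loo_cv(x, y, ncomp_max = 4, scale = FALSE)
  expect_gte(cv$q2, 0.999)
  expect_gte(cv$r2, cv$q2 - 1e-9)
  # deterministic: identical inputs, bit-identical residuals
  cv2 <- loo_cv(x, y, ncomp_max = 4, scale = FALSE)
  expect_identical(cv$cv_residuals, cv2$cv_residuals)
})

test_that("single-predictor LOO equals the hat-matrix regression oracle", {
  # PLS1 with one component on one predictor is simple linear regression,
  # so LOO predictions follow the exact e/(1 - h) identity
  set.seed(2)
  x <- matrix(runif(8, 1, 10), 8, 1)
  y <- 3 + 2 * x[, 1] + rnorm(8, sd = 0.4)
  cv <- loo_cv(x, y, ncomp_max = 1, scale = TRUE)
  fit <- lm(y ~ x[, 1])
  h <- hatvalues(fit)
  press_oracle <- residuals(fit) / (1 - h)
  expect_equal(as.vector(cv$cv_residuals), unname(press_oracle),
               tolerance = 1e-9)
  q2_oracle <- 1 - sum(press_oracle^2) / sum((y - mean(y))^2)
  expect_equal(cv$q2, q2_oracle, tolerance = 1e-9)
})

test_that("r2_q2 matches a worked five-point example", {
  x <- matrix(c(1, 2, 3, 4, 5), 5, 1)
  y <- c(1.1, 1.9, 3.2, 3.9, 5.1)
  cv <- loo_cv(x, y, ncomp_max = 1)
  out <- r2_q2(y, cv$fitted, cv$cv_pred)
  fit <- lm(y ~ x[, 1])
  press <- sum((residuals(fit) / (1 - hatvalues(fit)))^2)
  sstot <- sum((y - mean(y))^2)
  expect_equal(out$r2, summary(fit)$r.squared, tolerance = 1e-9)
  expect_equal(out$q2, 1 - press / sstot, tolerance = 1e-9)
  expect_equal(r2_q2(y, y, y)$r2, 1)
  expect_equal(r2_q2(y, rep(mean(y), 5), y)$r2, 0)
  expect_error(r2_q2(rep(1, 5), y, y), "zero total")
})

test_that("shuffled responses give non-positive predictive power", {
  set.seed(3)
  q2s <- replicate(20, {
    x <- matrix(rnorm(15 * 10), 15, 10)
    y <- sample(as.vector(x %*% rnorm(10)))
    loo_cv(x, y, ncomp_max = 2, scale = FALSE)$q2
  })
  expect_lt(median(q2s), 0)
})

test_that("component selection applies the parsimony rule", {
  mk <- function(rmsecv) {
    tibble::tibble(ncomp = seq_along(rmsecv), rmsec = rmsecv,
                   rmsecv = rmsecv)
  }
  expect_equal(select_components(mk(c(5, 4, 3, 2))), 4L)   # strictly decreasing
  expect_equal(select_components(mk(c(2, 2, 2))), 1L)      # flat
  # minimum at 3 but component 2 within 1%
  expect_equal(select_components(mk(c(3, 1.005, 1.0))), 2L)
  expect_equal(select_components(mk(c(3, 1.2, 1.0))), 3L)
})

test_that("minimal n = 3 cross-validation returns three residuals", {
  x <- matrix(c(1, 2, 3, 2, 1, 3), 3, 2)
  y <- c(1, 2, 3.2)
  cv <- loo_cv(x, y, ncomp_max = 1, scale = FALSE)
  expect_equal(length(cv$cv_residuals), 3L)
  expect_true(all(is.finite(cv$cv_residuals)))
  expect_error(loo_cv(x[1:2, ], y[1:2], 1), "n >= 3")
})

test_that("permutation p-values respect their estimator arithmetic", {
  set.seed(4)
  x <- matrix(rnorm(12 * 6), 12, 6)
  y <- as.vector(x %*% rnorm(6))

  p1 <- permutation_test(x, y, ncomp = 2, n_perm = 1, seed = 1,
                         paired_tests = FALSE)
  expect_true(p1$empirical_p %in% c(0.5, 1))

  p19 <- permutation_test(x, y, ncomp = 2, n_perm = 19, seed = 1)
  expect_gte(p19$empirical_p, 1 / 20)
  expect_lte(p19$empirical_p, 1)
  expect_true(all(c(p19$p_wilcoxon, p19$p_sign, p19$p_ttest) > 0))
  expect_error(permutation_test(x, y, 2, n_perm = 0, seed = 1), "n_perm")
  expect_error(permutation_test(x, y, 2, n_perm = 9), "seed")
})

test_that("a strong planted signal is never beaten by permutations", {
  sim <- simulate_dataset(sim_config(seed = 23))
  pre <- run_preprocess(sim$feeding)
  xg <- glog(pre$normalized)
  y <- build_y(xg$samples, sim$growth[sim$growth$group == "B",
                                      c("day", "diameter_cm")],
               "diameter", "log")
  pt <- permutation_test(xg$values, y$values, ncomp = 3, n_perm = 199,
                         seed = 12)
  expect_equal(pt$empirical_p, 1 / 200)
  expect_lt(pt$p_wilcoxon, 0.05)
})

test_that("ROC handles separation, chance and degenerate inputs", {
  truth <- rep(c(FALSE, TRUE), each = 10)
  sep <- c(rnorm(10, 0, 0.1), rnorm(10, 10, 0.1))
  r <- roc_auc(sep, truth)
  expect_equal(r$auc, 1)
  expect_equal(r$youden$sensitivity, 1)
  expect_equal(r$youden$specificity, 1)

  flat <- roc_auc(rep(1, 20), truth)
  expect_equal(flat$auc, 0.5)

  set.seed(6)
  rnd <- roc_auc(rnorm(200), rep(c(TRUE, FALSE), 100))
  expect_gt(rnd$auc, 0.4)
  expect_lt(rnd$auc, 0.6)

  expect_error(roc_auc(rnorm(5), rep(TRUE, 5)), "both classes")
  # curve is monotone non-decreasing
  expect_true(all(diff(r$curve$tpr) >= 0))
})

test_that("PLS-DA ROC summarises every class and the confusion matrix", {
  sim <- simulate_dataset(sim_config(seed = 29))
  pre <- run_preprocess(sim$feeding)
  xg <- glog(pre$normalized)
  enc <- plsda_encode(xg$samples, merges = list(c(8, 12)))
  fit <- pls_nipals(xg$values, enc$Y, ncomp = 6, scale = TRUE)
  roc <- plsda_roc(fit, xg$values, enc)
  expect_equal(nrow(roc$per_class), 4L)
  expect_true(all(roc$per_class$auc >= 0.9))
  expect_equal(sum(roc$confusion), 15)
  expect_equal(roc$accuracy, 1)
})
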