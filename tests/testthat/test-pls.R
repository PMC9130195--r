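test_that("a single perfect predictor is fit exactly", {
  x <- matrix(c(1, 2, 3), 3, 1)
  y <- c(2, 4, 6)
  fit <- pls_nipals(x, y, ncomp = 1)
  expect_equal(as.vector(fit$fitted), y, tolerance = 1e-12)
  # coefficient reproduces the slope on the original scale
  expect_equal(as.vector(predict(fit, matrix(10))), 20, tolerance = 1e-10)
  # predicting at the column means returns the response mean
  expect_equal(as.vector(predict(fit, matrix(mean(x)))), mean(y))
})

test_that("full-rank NIPALS reproduces ordinary least squares", {
  set.seed(101)
  for (rep in 1:10) {
    n <- sample(10:30, 1)
    p <- sample(3:8, 1)
    x <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    fit <- pls_nipals(x, y, ncomp = p)
    ols <- lm.fit(cbind(1, x), y)
    expect_equal(as.vector(fit$fitted), unname(ols$fitted.values),
                 tolerance = 1e-8)
  }
})

test_that("NIPALS fitted values agree with an independent SIMPLS oracle", {
  set.seed(202)
  for (rep in 1:10) {
    n <- 20; p <- 10
    x <- matrix(rnorm(n * p), n, p)
    y <- x %*% rnorm(p) + rnorm(n)
    for (A in c(1, 3, 5)) {
      fit <- pls_nipals(x, y, ncomp = A)
      oracle <- simpls_fit(x, y, A)
      expect_equal(as.vector(fit$fitted), as.vector(oracle$fitted),
                   tolerance = 1e-6)
    }
  }
})

test_that("scores are orthogonal and explained variance is bounded", {
  set.seed(303)
  x <- scale(matrix(rnorm(200), 20, 10))
  y <- rnorm(20)
  fit <- pls_nipals(x, y, ncomp = 5)
  G <- crossprod(fit$T)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
  expect_lte(sum(fit$ssx_pct), 100 + 1e-8)
  expect_error(pls_nipals(x, y, ncomp = 25), "ncomp")
  expect_error(pls_nipals(x, rep(1, 20), ncomp = 2), "zero-variance")
})

test_that("the sign convention makes refits reproducible", {
  set.seed(99)
  x <- matrix(rnorm(80), 16, 5)
  y <- rnorm(16)
  f1 <- pls_nipals(x, y, 3)
  f2 <- pls_nipals(x, y, 3)
  expect_identical(f1$W, f2$W)
  expect_true(all(apply(f1$W, 2, function(w) w[which.max(abs(w))] > 0)))
})

test_that("VIP normalization and symmetry hold", {
  # single variable: VIP forced to 1
  fit1 <- pls_nipals(matrix(c(1, 2, 3, 5), 4, 1), c(1, 2, 3, 5), 1)
  expect_equal(vip_scores(fit1)$vip, 1)

  # duplicated column: symmetric roles give equal VIPs of 1
  x2 <- cbind(c(1, 2, 4, 8), c(1, 2, 4, 8))
  fit2 <- pls_nipals(x2 + matrix(rnorm(8, sd = 1e-8), 4), c(1, 2, 4, 8), 1)
  v2 <- vip_scores(fit2)$vip
  expect_equal(v2, c(1, 1), tolerance = 1e-3)

  # sum of squared VIPs equals p on random fixtures, and matches a
  # brute-force evaluation of the formula
  set.seed(404)
  x <- matrix(rnorm(160), 20, 8)
  y <- x %*% rnorm(8) + rnorm(20)
  fit <- pls_nipals(x, y, ncomp = 4)
  v <- vip_scores(fit)$vip
  expect_equal(sum(v^2), 8, tolerance = 1e-8)
  ssy <- rowSums(fit$ssy)
  brute <- sapply(seq_len(8), function(j) {
    sqrt(8 * sum(ssy * fit$W[j, ]^2) / sum(ssy))
  })
  expect_equal(v, brute, tolerance = 1e-12)
})

test_that("PLS-DA encoding builds merged one-hot classes", {
  s <- data.frame(sample_id = paste0("s", 1:10),
                  day = rep(c(1L, 4L, 8L, 12L, 16L), each = 2))
  enc <- plsda_encode(s, merges = list(c(8, 12)))
  expect_equal(enc$classes, c("1", "4", "8/12", "16"))
  expect_equal(ncol(enc$Y), 4L)
  expect_true(all(rowSums(enc$Y) == 1))
  expect_equal(sum(enc$Y[, "8/12"]), 4)

  enc5 <- plsda_encode(s)
  expect_equal(ncol(enc5$Y), 5L)

  s_bad <- rbind(s, data.frame(sample_id = "x", day = 3L))
  expect_error(plsda_encode(s_bad, days = c(1, 4, 8, 12, 16)),
               "outside the class design: 3")
})

test_that("class assignment takes the maximum response and logs ties", {
  s <- data.frame(sample_id = paste0("s", 1:8),
                  day = rep(c(1L, 4L, 8L, 16L), each = 2))
  enc <- plsda_encode(s)
  set.seed(7)
  x <- matrix(rnorm(8 * 6), 8, 6) + 3 * enc$Y %*% matrix(rnorm(24), 4, 6)
  fit <- pls_nipals(scale(x), enc$Y, ncomp = 3)
  got <- plsda_assign(fit, scale(x), enc)
  expect_equal(got$class, enc$class_of)

  # explicit tie goes to the first class in encoding order
  fake <- fit
  fake$B[] <- 0
  fake$y_center <- c(0.5, 0.5, 0, 0)
  tied <- plsda_assign(fake, scale(x), enc)
  expect_true(all(tied$class == enc$classes[1]))
  expect_true(all(tied$tie))
})

test_that("well-separated synthetic classes are perfectly re-assigned", {
  sim <- simulate_dataset(sim_config(seed = 17))
  pre <- run_preprocess(sim$feeding)
  xg <- glog(pre$normalized)
  enc <- plsda_encode(xg$samples, merges = list(c(8, 12)))
  fit <- pls_nipals(xg$values, enc$Y, ncomp = 6, scale = TRUE)
  got <- plsda_assign(fit, xg$values, enc)
  expect_equal(mean(got$class == enc$class_of), 1)
})

test_that("SVD PCA satisfies its algebraic identities", {
  # rank-1 matrix: one component carrying all variance
  r1 <- outer(c(1, 2, 3, 4), c(2, 1, 0.5))
  pc <- pca_svd(r1)
  expect_equal(length(pc$variance), 1L)
  expect_equal(pc$variance_pct[1], 100)

  set.seed(55)
  x <- matrix(rnorm(12 * 6), 12, 6)
  pc2 <- pca_svd(x)
  # full reconstruction
  recon <- pc2$scores %*% t(pc2$loadings)
  expect_equal(recon, sweep(x, 2, colMeans(x)), tolerance = 1e-8,
               ignore_attr = TRUE)
  # orthogonal scores; variances sum to the total column variance
  G <- crossprod(pc2$scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
  expect_equal(sum(pc2$variance), sum(apply(x, 2, var)), tolerance = 1e-10)
  # autoscaled input: total variance is p
  xs <- scale(x)
  expect_equal(sum(pca_svd(xs)$variance), 6, tolerance = 1e-10)
})

test_that("Ward clustering merges coincident points first", {
  x <- rbind(c(0, 0), c(0, 0), c(5, 5))
  h <- hca_ward(x)
  expect_equal(h$height[1], 0)
  expect_true(all(diff(h$height) >= 0))

  # two well-separated blobs split at the top
  set.seed(31)
  blob <- rbind(matrix(rnorm(12, 0, 0.1), 6, 2),
                matrix(rnorm(12, 10, 0.1), 6, 2))
  h2 <- hca_ward(blob)
  top <- cutree(h2, k = 2)
  expect_equal(length(unique(top[1:6])), 1L)
  expect_equal(length(unique(top[7:12])), 1L)
  expect_false(top[1] == top[7])
})
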