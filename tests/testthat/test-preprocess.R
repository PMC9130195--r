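make_fm <- function(vals, groups = NULL, days = NULL, rt = NULL) {
  n <- nrow(vals)
  p <- ncol(vals)
  if (is.null(groups)) groups <- rep("B", n)
  if (is.null(days)) days <- ifelse(groups %in% c("B", "F"), 1L, NA_integer_)
  if (is.null(rt)) rt <- seq(12, 30, length.out = p)
  feature_matrix(vals,
                 data.frame(sample_id = paste0("s", seq_len(n)),
                            group = groups, day = days,
                            replicate = seq_len(n)),
                 data.frame(bin_id = seq_len(p), rt_min = rt))
}

test_that("RT trimming keeps the closed 11.5-31 window", {
  fm <- make_fm(matrix(1, 2, 4), rt = c(5, 12, 30, 45))
  out <- trim_rt(fm)
  expect_equal(out$bins$rt_min, c(12, 30))
  expect_equal(out$stage, "trimmed")

  # boundary bin at exactly 11.5 is retained
  fm2 <- make_fm(matrix(1, 2, 2), rt = c(11.5, 31))
  expect_equal(ncol(trim_rt(fm2)$values), 2L)
  # identity when everything is inside
  expect_equal(trim_rt(fm2)$values, fm2$values, ignore_attr = TRUE)
  fm3 <- make_fm(matrix(1, 2, 2), rt = c(2, 40))
  expect_error(trim_rt(fm3), "all bins outside")
})

test_that("total-area normalization is exact and idempotent", {
  fm <- make_fm(matrix(c(2, 3, 5), 1, 3))
  out <- normalize_total_area(fm)
  expect_equal(as.vector(out$values), c(0.2, 0.3, 0.5))
  expect_equal(out$stage, "normalized")
  expect_equal(normalize_total_area(out)$values, out$values)

  # zeros preserved, remainder rescaled
  fm2 <- make_fm(matrix(c(0, 1, 3), 1, 3))
  expect_equal(as.vector(normalize_total_area(fm2)$values),
               c(0, 0.25, 0.75))
  fm3 <- make_fm(matrix(c(0, 0, 1, 1), 2, 2))
  fm3$values[1, ] <- 0
  expect_error(normalize_total_area(fm3), "zero-sum.*s1")
})

test_that("g-log matches its closed form and is strictly increasing", {
  fm <- make_fm(matrix(0, 1, 2))
  out <- glog(fm)
  expect_equal(as.vector(out$values), rep(log(sqrt(0.1)), 2),
               tolerance = 1e-12)
  expect_equal(out$values[1, 1], -1.151293, tolerance = 1e-6)

  # lambda -> 0 limit is ln(2x)
  fm2 <- make_fm(matrix(c(1, 5, 20), 1, 3))
  small <- glog(fm2, preprocess_config(glog_lambda = 1e-12))
  expect_equal(as.vector(small$values), log(2 * c(1, 5, 20)),
               tolerance = 1e-9)

  # monotone on random pairs
  set.seed(1)
  x <- sort(runif(50, 0, 10))
  g <- log(x + sqrt(x^2 + 0.1))
  expect_true(all(diff(g) > 0))
})

test_that("autoscaling yields exact zero mean and unit variance", {
  fm <- make_fm(matrix(c(1, 2, 3, 5, 5, 8), 3, 2))
  out <- autoscale(fm)
  expect_equal(out$values[, 1], c(-1, 0, 1), ignore_attr = TRUE)
  expect_lt(max(abs(colMeans(out$values))), 1e-12)
  expect_lt(max(abs(apply(out$values, 2, sd) - 1)), 1e-12)
  expect_equal(out$stage, "autoscaled")
  fm2 <- make_fm(matrix(c(1, 2, 3, 4, 4, 4), 3, 2))
  expect_error(autoscale(fm2), "zero-variance bin: 2")
})

test_that("g-log and autoscaling commute with sample reordering", {
  set.seed(2)
  fm <- make_fm(matrix(rexp(40) + 0.1, 8, 5))
  perm <- sample(8)
  reord <- feature_matrix(fm$values[perm, ], fm$samples[perm, ], fm$bins)
  a <- autoscale(glog(fm))$values[perm, ]
  b <- autoscale(glog(reord))$values
  expect_equal(a, b, ignore_attr = TRUE)
})

test_that("QC RSD filter removes technically unstable bins", {
  vals <- rbind(c(100, 100, 5), c(100, 150, 5), c(100, 200, 5))
  fm <- make_fm(vals, groups = rep("QC", 3))
  out <- rsd_filter(fm)
  # (100,100,100) -> RSD 0 kept; (100,150,200) -> sd 50 / mean 150 = 33.3%
  expect_equal(out$fm$bins$bin_id, c(1L, 3L))
  expect_equal(out$removed$bin_id, 2L)
  expect_equal(out$removed$rsd_pct, 100 * 50 / 150, tolerance = 1e-12)

  # zero-mean QC bin removed with the degenerate-case reason
  vals0 <- cbind(vals[, 1:2], 0)
  out0 <- rsd_filter(make_fm(vals0, groups = rep("QC", 3)))
  expect_match(out0$removed$reason[out0$removed$bin_id == 3], "undefined")
  expect_error(rsd_filter(make_fm(vals, groups = rep("B", 3))), "QC")
})

test_that("SNR filter uses the strongest group-day mean", {
  vals <- rbind(c(10, 4), c(10, 4))
  fm <- make_fm(vals, groups = c("B", "B"), days = c(1L, 1L))
  out <- snr_filter(fm, noise_level = 1)
  expect_equal(out$fm$bins$bin_id, 1L)   # SNR 10 kept, SNR 4 < 5 removed
  expect_equal(out$removed$bin_id, 2L)
  expect_error(snr_filter(fm, noise_level = 0), "positive")
  expect_error(snr_filter(fm), "OS samples")
})

test_that("occurrence filter requires 75% detection in some cell", {
  # bin 1: 3/3 in one cell; bin 2: 2/3 everywhere
  vals <- cbind(c(10, 10, 10, 10, 10, 10), c(10, 10, 0, 10, 10, 0))
  fm <- make_fm(vals, groups = rep("B", 6),
                days = rep(c(1L, 4L), each = 3))
  out <- occurrence_filter(fm, detection_floor = 1)
  expect_equal(out$fm$bins$bin_id, 1L)
  expect_equal(out$removed$bin_id, 2L)
  expect_error(occurrence_filter(fm, detection_floor = 100), "empty matrix")
})

test_that("blank subtraction drops OS bins and labels CM bins", {
  fm <- make_fm(matrix(1, 2, 3))
  out <- blank_subtraction(fm, os_bins = 2L, cm_bins = 1L)
  expect_equal(out$fm$bins$bin_id, c(1L, 3L))
  expect_equal(out$fm$bins$label[1], "culture_medium")
  expect_error(blank_subtraction(fm, os_bins = 9L), "unknown bin_id")
  ident <- blank_subtraction(fm)
  expect_equal(ident$fm$values, fm$values)
})

test_that("full preprocessing chain runs on the synthetic default", {
  sim <- simulate_dataset(sim_config(seed = 4))
  out <- run_preprocess(sim$feeding)
  expect_equal(out$fm$stage, "autoscaled")
  expect_lte(ncol(out$fm$values), 25L)
  expect_equal(nrow(out$fm$values), 15L)       # QC rows dropped before models
  expect_s3_class(out$log, "tbl_df")

  # extreme RSD threshold: every bin carries QC noise, so nothing survives
  expect_error(run_preprocess(sim$feeding,
                              preprocess_config(rsd_max_pct = 1e-9),
                              keep_normalized = FALSE),
               "empty")
  # an intermediate threshold removes exactly the noisier bins, logged
  qv <- sim$feeding$values[sim$feeding$samples$group == "QC", ]
  rsds <- unname(100 * apply(qv, 2, sd) / colMeans(qv))
  mid <- run_preprocess(sim$feeding,
                        preprocess_config(rsd_max_pct = median(rsds)),
                        keep_normalized = FALSE)
  expect_equal(sort(mid$log$bin_id),
               sort(sim$feeding$bins$bin_id[rsds > median(rsds)]))
  expect_true(all(mid$log$stage == "rsd_filter"))

  # noiseless data loses nothing to the RSD filter
  sim0 <- simulate_dataset(sim_config(seed = 4, replicate_cv = 0))
  out0 <- run_preprocess(sim0$feeding)
  expect_equal(nrow(out0$log[out0$log$stage == "rsd_filter", ]), 0L)
})

test_that("RSD and occurrence filters commute on the default dataset", {
  sim <- simulate_dataset(sim_config(seed = 6))
  fm <- sim$feeding
  a <- occurrence_filter(rsd_filter(fm)$fm, detection_floor = 0)$fm
  b <- rsd_filter(occurrence_filter(fm, detection_floor = 0)$fm)$fm
  expect_identical(a$bins$bin_id, b$bins$bin_id)
  expect_identical(a$values, b$values)
})
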