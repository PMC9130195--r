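test_that("generator respects the configured design", {
  sim <- simulate_dataset(sim_config(seed = 1))
  expect_equal(dim(sim$feeding), c(18L, 25L))   # 5 days x 3 reps + 3 QC
  expect_equal(dim(sim$control), c(18L, 25L))
  expect_equal(sum(sim$truth$kind == "alkaloid"), 2L)
  expect_equal(sum(sim$truth$kind == "early_pulse"), 3L)
  expect_equal(sum(sim$truth$kind == "late_pulse"), 2L)
  expect_equal(sum(sim$truth$plsr_relevant), 15L)
  expect_equal(sum(sim$truth$induced), 5L)
  expect_true(all(sim$feeding$values > 0))
  expect_equal(sort(unique(sim$feeding$samples$day)), c(1L, 4L, 8L, 12L, 16L))
})

test_that("generator is deterministic given the seed", {
  a <- simulate_dataset(sim_config(seed = 7))
  b <- simulate_dataset(sim_config(seed = 7))
  c <- simulate_dataset(sim_config(seed = 8))
  expect_identical(a$feeding$values, b$feeding$values)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$feeding$values, c$feeding$values))
  expect_error(sim_config(), "seed is mandatory")
})

test_that("zero replicate noise collapses replicates to the cell mean", {
  sim <- simulate_dataset(sim_config(seed = 3, replicate_cv = 0))
  v <- sim$feeding$values
  s <- sim$feeding$samples
  for (d in unique(stats::na.omit(s$day))) {
    rows <- which(s$group == "B" & s$day == d)
    expect_equal(v[rows[1], ], v[rows[2], ])
    expect_equal(v[rows[1], ], v[rows[3], ])
  }
})

test_that("planted archetypes carry the intended growth correlation", {
  sim <- simulate_dataset(sim_config(seed = 5, replicate_cv = 0.05))
  g <- log(sim$config$diameters_feeding)
  v <- sim$feeding$values
  s <- sim$feeding$samples
  study <- s$group == "B"
  day_means <- apply(v[study, ], 2, function(col) {
    tapply(col, s$day[study], mean)[as.character(sim$config$days)]
  })
  for (j in which(sim$truth$kind == "growth_linked")) {
    expect_gte(stats::cor(day_means[, j], g), 0.99)
  }
  for (j in which(sim$truth$kind == "media_decay")) {
    expect_lte(stats::cor(day_means[, j], g), -0.99)
  }
  # alkaloids decay below 1% of their initial level by day 12 in B
  for (j in which(sim$truth$kind == "alkaloid")) {
    expect_lt(day_means["12", j], 0.01 * day_means["1", j])
  }
  # pulse bins effectively absent in the control study samples (QC rows are
  # pooled over both groups and legitimately carry pulse signal)
  ctrl_study <- sim$control$samples$group == "F"
  floor_level <- max(sim$control$values[ctrl_study,
                                        sim$truth$kind == "early_pulse"])
  expect_lt(floor_level, 0.01 * max(sim$feeding$values))
})

test_that("config validation rejects inconsistent designs", {
  expect_error(sim_config(seed = 1, diameters_feeding = c(1, 2)), "align")
  expect_error(sim_config(seed = 1, archetype_counts = c(inert = 0L)),
               "sum to 0")
  expect_error(sim_config(seed = 1, replicate_cv = 1.2), "replicate_cv")
})

test_that("rendered chromatograms integrate back to the bin intensities", {
  fm <- feature_matrix(
    matrix(c(100, 40, 250, 10), 2, 2),
    data.frame(sample_id = c("B_D1_R1", "B_D1_R2"), group = "B", day = 1,
               replicate = 1:2),
    data.frame(bin_id = 1:2, rt_min = c(14, 20))
  )
  tr <- render_chromatograms(fm, rt_grid_step = 0.005, peak_width_sd = 0.1,
                             baseline_drift_amplitude = 0)
  # Gaussian area recovery within 1%
  back <- bin_chromatograms(tr, fm$bins, window_half_width = 0.5)
  expect_equal(back$values, fm$values, tolerance = 0.01)
  # peaks sit at their retention times
  expect_equal(tr$rt[which.max(tr$traces[1, tr$rt < 17])], 14,
               tolerance = 0.01)
  i2 <- which(tr$rt > 17)
  expect_equal(tr$rt[i2][which.max(tr$traces[1, i2])], 20, tolerance = 0.01)

  # zero-intensity matrix renders the pure baseline
  fm0 <- feature_matrix(matrix(0, 2, 2), fm$samples, fm$bins)
  tr0 <- render_chromatograms(fm0, rt_grid_step = 0.01, peak_width_sd = 0.1,
                              baseline_drift_amplitude = 5)
  expect_equal(tr0$traces[1, ], tr0$baseline, ignore_attr = TRUE)

  expect_error(bin_chromatograms(tr, fm$bins, window_half_width = 4),
               "overlapping")
  far <- fm$bins
  far$rt_min <- c(5, 20)
  expect_error(bin_chromatograms(tr, far, window_half_width = 0.5),
               "outside")
})

test_that("simulate -> render -> bin round trip preserves the matrix", {
  sim <- simulate_dataset(sim_config(seed = 2, qc_count = 0L))
  fm <- sim$feeding
  tr <- render_chromatograms(fm, rt_grid_step = 0.01, peak_width_sd = 0.08)
  back <- bin_chromatograms(tr, fm$bins, window_half_width = 0.35)
  rel <- abs(back$values - fm$values) / pmax(fm$values, 1)
  expect_lt(max(rel), 0.01)
})
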