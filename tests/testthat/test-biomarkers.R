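# one preprocessed synthetic dataset shared across the file
bm_fixture <- local({
  sim <- simulate_dataset(sim_config(seed = 41))
  preB <- run_preprocess(sim$feeding)
  preF <- run_preprocess(sim$control)
  xgB <- glog(preB$normalized)
  grow <- sim$growth[sim$growth$group == "B", c("day", "diameter_cm")]
  y <- build_y(xgB$samples, grow, "diameter", "log")
  plsr <- pls_nipals(xgB$values, y$values, ncomp = 4, scale = TRUE)
  enc <- plsda_encode(xgB$samples, merges = list(c(8, 12)))
  plsda <- pls_nipals(xgB$values, enc$Y, ncomp = 6, scale = TRUE)
  list(sim = sim, preB = preB, preF = preF, xgB = xgB,
       plsr = plsr, plsda = plsda, enc = enc)
})

test_that("VIP selection is strict at the threshold", {
  expect_equal(select_vip(c(1.2, 0.8, 1.0)), 1L)
  expect_equal(select_vip(c(0.3, 0.9)), integer(0))
  expect_equal(select_vip(tibble::tibble(variable = 5:7,
                                         vip = c(2, 0.5, 1.01))),
               c(5L, 7L))
})

test_that("PLSr VIP recovers the planted growth-monotone bins", {
  f <- bm_fixture
  vip <- vip_scores(f$plsr)$vip
  sel <- vip > 1
  truth <- f$sim$truth$plsr_relevant[match(f$xgB$bins$bin_id,
                                           f$sim$truth$bin_id)]
  expect_gte(mean(sel[truth]), 0.9)
})

test_that("trend classification reproduces the planted archetypes", {
  f <- bm_fixture
  trends <- classify_trend(f$plsr, f$plsda, f$xgB$bins)
  tt <- dplyr::left_join(trends, f$sim$truth, by = "bin_id")
  expect_true(all(tt$trend[tt$kind == "alkaloid"] == "consumed"))
  expect_true(all(tt$trend[tt$kind == "media_decay"] == "consumed"))
  expect_true(all(tt$trend[tt$kind == "growth_linked"] == "produced"))
  expect_true(all(tt$trend[tt$kind == "early_pulse"] == "transient_early"))
  expect_true(all(tt$trend[tt$kind == "late_pulse"] == "transient_late"))
  expect_true(all(tt$trend[tt$kind == "inert"] == "unchanged"))
})

test_that("the induced rule is a strict conjunction of its three criteria", {
  f <- bm_fixture
  shared <- intersect(f$preB$normalized$bins$bin_id,
                      f$preF$normalized$bins$bin_id)
  vipB <- vip_scores(f$plsr)
  vipB$bin_id <- f$xgB$bins$bin_id
  vip_aligned <- vipB$vip[match(shared, vipB$bin_id)]
  vip_da <- vip_scores(f$plsda)
  vip_da$bin_id <- f$xgB$bins$bin_id
  da_aligned <- vip_da[match(shared, vip_da$bin_id),
                       grep("^vip_", names(vip_da))]

  ind <- induced_criterion(f$preB$normalized, f$preF$normalized,
                           vip_aligned, da_aligned)
  truth <- f$sim$truth[match(ind$bin_id, f$sim$truth$bin_id), ]

  # planted feeding-only pulse bins are flagged
  expect_true(all(ind$induced[truth$kind %in% c("early_pulse",
                                                "late_pulse")]))
  # shared growth-linked bins fail the fold criterion
  expect_true(all(!ind$induced[truth$kind == "growth_linked"]))
  expect_true(all(ind$fold_change[truth$kind == "growth_linked"] < 3))

  # killing the VIP evidence un-flags everything (conjunction)
  none <- induced_criterion(f$preB$normalized, f$preF$normalized,
                            rep(0.4, length(shared)), NULL)
  expect_false(any(none$induced))

  # increasing the treatment/control contrast never un-flags a bin
  boosted <- f$preB$normalized
  flagged <- which(ind$induced)[1]
  col <- which(boosted$bins$bin_id == ind$bin_id[flagged])
  boosted$values[, col] <- boosted$values[, col] * 5
  ind2 <- induced_criterion(boosted, f$preF$normalized, vip_aligned,
                            da_aligned)
  expect_true(ind2$induced[flagged])
})

test_that("Spearman correlation map has rank-invariance and unit diagonal", {
  f <- bm_fixture
  cm <- spearman_bin_correlation(f$preB$normalized)
  expect_true(all(diag(cm) == 1))
  expect_true(max(abs(cm - t(cm))) < 1e-12)
  expect_true(all(cm >= -1 & cm <= 1))

  # invariant under the strictly monotone g-log transform
  cm2 <- spearman_bin_correlation(glog(f$preB$normalized))
  expect_equal(unclass(cm), unclass(cm2), tolerance = 1e-12,
               ignore_attr = TRUE)

  # planted opposite trends correlate strongly negatively at low noise
  sim <- simulate_dataset(sim_config(seed = 43, replicate_cv = 0.02))
  fmB <- fm_subset(sim$feeding, samples = group == "B")
  cml <- spearman_bin_correlation(fmB)
  md <- which(sim$truth$kind == "media_decay")[1]
  gl <- which(sim$truth$kind == "growth_linked")[1]
  expect_lte(cml[md, gl], -0.9)

  # a constant bin is reported as zero correlation and flagged
  fmc <- fmB
  fmc$values[, 1] <- 7
  cmc <- spearman_bin_correlation(fmc)
  expect_equal(unname(cmc[1, 2]), 0)
  expect_equal(attr(cmc, "constant_bins"), fmc$bins$bin_id[1])
})
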