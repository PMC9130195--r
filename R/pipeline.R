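#' Run the full growth-informed analysis pipeline
#'
#' Orchestrates the end-to-end chain on a two-group time course:
#' preprocessing of each group's raw matrix (RT trim, occurrence and QC-RSD
#' filters, total-area normalization, g-log), response-model comparison by
#' cross-validated PLS regression (incubation days vs log colony diameter),
#' PLSr per group with VIP selection, PLS-DA on the treated group with the
#' merged day-8/12 class, trend classification, the induced-metabolite
#' rule, and the Spearman bin-correlation map. When planted ground truth is
#' supplied (synthetic data), recovery metrics are attached.
#'
#' All randomness (permutation draws) is governed by `seed`; stage
#' substreams are derived from it so results are reproducible end to end.
#'
#' @param feeding,control Raw [feature_matrix()] objects (QC rows included)
#'   for the treated (`B`) and control (`F`) groups.
#' @param growth Growth tibble with columns `group`, `day`, `diameter_cm`.
#' @param cfg A [preprocess_config()].
#' @param seed Integer seed (mandatory).
#' @param ncomp_max Largest component count for the PLSr comparison.
#' @param ncomp_max_plsda Largest component count for PLS-DA.
#' @param n_perm Permutations for every permutation test.
#' @param merges PLS-DA class merges (default days 8 and 12 into one class).
#' @param vip_threshold,p_max,fold_min Induced-rule cutoffs.
#' @param truth Optional ground-truth tibble from [simulate_dataset()].
#' @return A `run_report` list: `preprocess` (per-group logs),
#'   `y_comparison` (a `model_comparison`), `plsr` (per-group model/cv/vip),
#'   `plsda` (model, encoding, cv, vip, roc), `trends`, `induced`,
#'   `spearman`, `recovery` (when truth given), `config` echo.
#' @export
run_pipeline <- function(feeding, control, growth,
                         cfg = preprocess_config(), seed,
                         ncomp_max = 6L, ncomp_max_plsda = 8L,
                         n_perm = 1000L, merges = list(c(8L, 12L)),
                         vip_threshold = 1.0, p_max = 0.005, fold_min = 3,
                         truth = NULL) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)

  pre <- list(
    B = run_preprocess(feeding, cfg),
    F = run_preprocess(control, cfg)
  )
  glogged <- lapply(pre, function(p) glog(p$normalized, cfg))

  growth <- tibble::as_tibble(growth)
  grow_of <- function(code) growth[growth$group == code, c("day", "diameter_cm")]

  candidates_for <- function(samples, g) {
    list(
      days_raw = build_y(samples, source = "days", treatment = "raw"),
      days_log = build_y(samples, source = "days", treatment = "log"),
      diameter_raw = build_y(samples, g, source = "diameter",
                             treatment = "raw"),
      diameter_log = build_y(samples, g, source = "diameter",
                             treatment = "log")
    )
  }

  y_comparison <- compare_y_models(
    glogged$B, candidates_for(glogged$B$samples, grow_of("B")),
    ncomp_max = ncomp_max, n_perm = n_perm, seed = seed, scale = TRUE
  )
  winner <- y_comparison$winner
  if (is.na(winner)) winner <- "diameter_log"

  fit_group <- function(code) {
    fmx <- glogged[[code]]
    y <- candidates_for(fmx$samples, grow_of(code))[[winner]]
    cv <- loo_cv(fmx$values, y$values,
                 ncomp_max = min(ncomp_max, nrow(fmx$values) - 2L,
                                 ncol(fmx$values)),
                 scale = TRUE)
    model <- pls_nipals(fmx$values, y$values, ncomp = cv$ncomp,
                        center = TRUE, scale = TRUE)
    vip <- vip_scores(model)
    vip$bin_id <- fmx$bins$bin_id
    list(model = model, cv = cv, vip = vip, y = y, fm = fmx)
  }
  plsr <- list(B = fit_group("B"), F = fit_group("F"))

  enc <- plsda_encode(glogged$B$samples, merges = merges)
  cv_da <- loo_cv(glogged$B$values, enc$Y,
                  ncomp_max = min(ncomp_max_plsda, nrow(glogged$B$values) - 2L,
                                  ncol(glogged$B$values)),
                  scale = TRUE)
  model_da <- pls_nipals(glogged$B$values, enc$Y, ncomp = cv_da$ncomp,
                         center = TRUE, scale = TRUE)
  vip_da <- vip_scores(model_da)
  vip_da$bin_id <- glogged$B$bins$bin_id
  perm_da <- permutation_test(glogged$B$values, enc$Y, ncomp = cv_da$ncomp,
                              n_perm = n_perm, seed = seed + 100L,
                              scale = TRUE)
  roc_da <- plsda_roc(model_da, glogged$B$values, enc)
  plsda <- list(model = model_da, encoding = enc, cv = cv_da, vip = vip_da,
                permutation = perm_da, roc = roc_da)

  trends <- classify_trend(plsr$B$model, model_da, glogged$B$bins,
                           vip_threshold = vip_threshold)

  induced <- induced_criterion(
    pre$B$normalized, pre$F$normalized,
    vip_plsr = plsr$B$vip$vip[match(
      intersect(pre$B$normalized$bins$bin_id, pre$F$normalized$bins$bin_id),
      plsr$B$vip$bin_id)],
    vip_plsda = vip_da[match(
      intersect(pre$B$normalized$bins$bin_id, pre$F$normalized$bins$bin_id),
      vip_da$bin_id), grep("^vip_", names(vip_da)), drop = FALSE],
    vip_threshold = vip_threshold, p_max = p_max, fold_min = fold_min
  )

  spearman <- spearman_bin_correlation(pre$B$normalized)

  report <- structure(list(
    preprocess = lapply(pre, function(p) p["log"]),
    glogged = glogged,
    normalized = lapply(pre, function(p) p$normalized),
    y_comparison = y_comparison,
    plsr = plsr,
    plsda = plsda,
    trends = trends,
    induced = induced,
    spearman = spearman,
    seed = seed,
    config = list(cfg = cfg, ncomp_max = ncomp_max, n_perm = n_perm,
                  merges = merges, vip_threshold = vip_threshold,
                  p_max = p_max, fold_min = fold_min)
  ), class = "run_report")
  if (!is.null(truth)) report$recovery <- recovery_metrics(report, truth)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat("  response model winner: ", x$y_comparison$winner, "\n", sep = "")
  cat(sprintf("  PLSr (B): ncomp %d, Q2 %.4f | PLSr (F): ncomp %d, Q2 %.4f\n",
              x$plsr$B$cv$ncomp, x$plsr$B$cv$q2,
              x$plsr$F$cv$ncomp, x$plsr$F$cv$q2))
  cat(sprintf("  PLS-DA: ncomp %d, accuracy %.2f, empirical p %.4g\n",
              x$plsda$cv$ncomp, x$plsda$roc$accuracy,
              x$plsda$permutation$empirical_p))
  cat("  induced bins: ",
      paste(x$induced$bin_id[x$induced$induced], collapse = ", "), "\n",
      sep = "")
  if (!is.null(x$recovery)) {
    cat("  recovery:\n")
    print(x$recovery)
  }
  invisible(x)
}

#' Recovery metrics against planted ground truth
#'
#' Compares a pipeline report with the ground truth of
#' [simulate_dataset()]: whether the response-model comparison picked the
#' log-diameter model, the sensitivity of PLSr VIP selection for planted
#' growth-monotone bins, the accuracy of PLS-DA class attribution for
#' planted pulse bins, and the sensitivity/specificity of the induced rule.
#' Bins removed during preprocessing are excluded from the denominators.
#'
#' @param report A [run_pipeline()] result.
#' @param truth Ground-truth tibble (`bin_id`, `kind`, `plsr_relevant`,
#'   `plsda_class`, `induced`).
#' @return A one-row tibble of the four metrics.
#' @export
recovery_metrics <- function(report, truth) {
  truth <- tibble::as_tibble(truth)
  vipB <- report$plsr$B$vip
  tr <- truth[match(vipB$bin_id, truth$bin_id), ]
  sel <- !is.na(vipB$vip) & vipB$vip > report$config$vip_threshold
  vip_sens <- mean(sel[tr$plsr_relevant])

  tt <- dplyr::left_join(report$trends, truth, by = "bin_id")
  pulses <- tt$kind %in% c("early_pulse", "late_pulse")
  pulse_acc <- if (any(pulses)) {
    mean(tt$plsda_class.x[pulses] == tt$plsda_class.y[pulses] &
           tt$vip_plsda[pulses] > report$config$vip_threshold)
  } else NA_real_

  ind <- dplyr::left_join(report$induced, truth[c("bin_id", "induced")],
                          by = "bin_id", suffix = c("", "_truth"))
  sens <- mean(ind$induced[ind$induced_truth])
  spec <- mean(!ind$induced[!ind$induced_truth])

  tibble::tibble(
    y_winner = report$y_comparison$winner,
    y_winner_correct = identical(report$y_comparison$winner, "diameter_log"),
    vip_sensitivity = vip_sens,
    pulse_class_accuracy = pulse_acc,
    induced_sensitivity = sens,
    induced_specificity = spec
  )
}

#' @export
glance.run_report <- function(x, ...) {
  tibble::tibble(
    y_winner = x$y_comparison$winner,
    q2_plsr_B = x$plsr$B$cv$q2,
    q2_plsr_F = x$plsr$F$cv$q2,
    ncomp_plsda = x$plsda$cv$ncomp,
    plsda_accuracy = x$plsda$roc$accuracy,
    n_induced = sum(x$induced$induced)
  )
}
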