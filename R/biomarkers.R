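#' Select variables by VIP threshold
#'
#' Keeps variables whose VIP score strictly exceeds the threshold
#' (conventionally 1: a VIP of exactly 1.0 is not selected).
#'
#' @param vip Numeric VIP vector, or a [vip_scores()] tibble (its `vip`
#'   column is used).
#' @param threshold Strict lower bound (default 1.0).
#' @param ids Optional identifiers aligned with `vip`; defaults to position.
#' @return Integer (or supplied id) vector of the selected variables.
#' @export
select_vip <- function(vip, threshold = 1.0, ids = NULL) {
  if (is.data.frame(vip)) {
    if (is.null(ids) && "variable" %in% names(vip)) ids <- vip$variable
    vip <- vip$vip
  }
  if (is.null(ids)) ids <- seq_along(vip)
  ids[!is.na(vip) & vip > threshold]
}

#' Classify per-bin temporal trends
#'
#' Combines a PLS regression model (growth-monotone production or
#' consumption) with a PLS-DA model (transient, class-restricted
#' production) into one trend class per bin:
#'
#' * `consumed` / `produced` - PLSr VIP above threshold, with the sign of
#'   the regression coefficient giving the direction;
#' * `transient_early` / `transient_late` - not PLSr-relevant, but the
#'   bin's PLS-DA association points at the early-response class
#'   (`early_class`, default day 4) or the late-response class
#'   (`late_class`, default merged days 8/12) with a per-class VIP above
#'   the threshold. The associated class is the one whose regression
#'   coefficient for the bin is largest - the loading-quadrant reading of
#'   a discriminant model - while the per-class VIP at that class gates
#'   relevance; per-class VIPs alone do not localize a class because
#'   shared components contribute to every class column;
#' * `unchanged` otherwise.
#'
#' When a bin is relevant to both models the regression reading wins and
#' the conflict is recorded in the `conflict` column.
#'
#' @param plsr_model Fitted single-response [pls_nipals()] model.
#' @param plsda_model Fitted multi-response [pls_nipals()] model (or `NULL`
#'   to classify from regression only).
#' @param bins Bin metadata tibble aligned with the model variables.
#' @param vip_threshold Strict VIP cutoff (default 1).
#' @param early_class,late_class PLS-DA class labels of the early and late
#'   transient-response classes.
#' @return A tibble: `bin_id`, `vip_plsr`, `coef_sign`, `plsda_class`
#'   (class of the maximum per-class VIP), `vip_plsda` (that maximum),
#'   `trend`, `conflict`.
#' @export
classify_trend <- function(plsr_model, plsda_model = NULL, bins,
                           vip_threshold = 1.0,
                           early_class = "4", late_class = "8/12") {
  stopifnot(inherits(plsr_model, "pls_model"), !plsr_model$multi_response)
  bins <- tibble::as_tibble(bins)
  vip_r <- vip_scores(plsr_model)$vip
  coef_sign <- sign(plsr_model$B[, 1])
  plsda_class <- rep(NA_character_, length(vip_r))
  vip_da <- rep(NA_real_, length(vip_r))
  if (!is.null(plsda_model)) {
    stopifnot(plsda_model$multi_response)
    vt <- vip_scores(plsda_model)
    per_class <- as.matrix(vt[grep("^vip_", names(vt))])
    cls <- sub("^vip_", "", colnames(per_class))
    best <- apply(plsda_model$B, 1, which.max)
    plsda_class <- cls[best]
    vip_da <- per_class[cbind(seq_len(nrow(per_class)), best)]
  }
  plsr_rel <- vip_r > vip_threshold
  da_rel <- !is.na(vip_da) & vip_da > vip_threshold
  trend <- dplyr::case_when(
    plsr_rel & coef_sign < 0 ~ "consumed",
    plsr_rel ~ "produced",
    da_rel & plsda_class == early_class ~ "transient_early",
    da_rel & plsda_class == late_class ~ "transient_late",
    TRUE ~ "unchanged"
  )
  conflict <- plsr_rel & da_rel &
    plsda_class %in% c(early_class, late_class)
  tibble::tibble(
    bin_id = bins$bin_id,
    vip_plsr = vip_r,
    coef_sign = coef_sign,
    plsda_class = plsda_class,
    vip_plsda = vip_da,
    trend = trend,
    conflict = conflict
  )
}

#' Induced-metabolite decision rule
#'
#' Flags a bin as induced by the treatment when all three criteria hold:
#'
#' 1. multivariate relevance - VIP above `vip_threshold` in the treatment
#'    PLSr or in any PLS-DA class;
#' 2. statistical difference - Welch (unequal-variance) two-sided t-test
#'    between the two groups' per-sample peak areas, `p < p_max`;
#' 3. abundance contrast - mean treatment area at least `fold_min` times
#'    the mean control area (control mean floored at `eps` to keep the
#'    ratio defined).
#'
#' Areas are taken at the normalized (unit total area) stage, before any
#' log transform, since the rule speaks about peak areas. Because many
#' induced metabolites are transient (detectable on a few days only), the
#' t-test is computed on log-areas restricted to the bin's expression
#' window - the days whose treatment-group mean reaches at least
#' `window_frac` of the bin's maximum day mean. Pooling all days would
#' dilute a day-limited signal below any reasonable significance level,
#' while the log scale equalizes the two groups' multiplicative noise.
#'
#' @param fm_treatment,fm_control Normalized-stage [feature_matrix()]
#'   objects for the treated and control groups, sharing bin ids.
#' @param vip_plsr Numeric treatment-PLSr VIP vector aligned to the shared
#'   bins (or a [vip_scores()] tibble).
#' @param vip_plsda Optional matrix/tibble of per-class PLS-DA VIPs aligned
#'   to the shared bins.
#' @param vip_threshold,p_max,fold_min The three cutoffs (defaults 1, 0.005,
#'   3).
#' @param window_frac Fraction of the maximum day mean defining the
#'   expression window (default 0.05).
#' @param eps Floor for the control mean in the fold ratio, as a fraction
#'   of total area (default 1e-12).
#' @return A tibble: `bin_id`, `vip_plsr`, `vip_plsda_max`,
#'   `mean_treatment`, `mean_control`, `fold_change`, `p_value`,
#'   `vip_pass`, `induced`.
#' @export
induced_criterion <- function(fm_treatment, fm_control, vip_plsr,
                              vip_plsda = NULL, vip_threshold = 1.0,
                              p_max = 0.005, fold_min = 3,
                              window_frac = 0.05, eps = 1e-12) {
  validate_feature_matrix(fm_treatment)
  validate_feature_matrix(fm_control)
  shared <- intersect(fm_treatment$bins$bin_id, fm_control$bins$bin_id)
  if (!length(shared)) stop("no shared bins", call. = FALSE)
  ft <- fm_take(fm_treatment, cols = fm_treatment$bins$bin_id %in% shared)
  fc <- fm_take(fm_control, cols = fm_control$bins$bin_id %in% shared)
  fc <- fm_take(fc, cols = match(ft$bins$bin_id, fc$bins$bin_id))
  if (nrow(ft$values) < 2L || nrow(fc$values) < 2L) {
    stop("need at least 2 samples per group", call. = FALSE)
  }
  if (is.data.frame(vip_plsr)) vip_plsr <- vip_plsr$vip
  da_max <- rep(NA_real_, length(shared))
  if (!is.null(vip_plsda)) {
    vm <- if (is.data.frame(vip_plsda)) {
      as.matrix(vip_plsda[grep("^vip_", names(vip_plsda))])
    } else as.matrix(vip_plsda)
    da_max <- apply(vm, 1, max, na.rm = TRUE)
  }

  days_t <- ft$samples$day
  p_val <- numeric(length(shared))
  for (j in seq_along(shared)) {
    mday <- tapply(ft$values[, j], days_t, mean)
    window <- as.numeric(names(mday))[mday >= window_frac * max(mday)]
    sel_t <- days_t %in% window
    sel_c <- fc$samples$day %in% window
    a <- log(ft$values[sel_t, j])
    b <- log(fc$values[sel_c, j])
    p_val[j] <- if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
    } else {
      tryCatch(stats::t.test(a, b, var.equal = FALSE)$p.value,
               error = function(e) 1)
    }
  }
  mean_t <- colMeans(ft$values)
  mean_c <- colMeans(fc$values)
  fold <- mean_t / pmax(mean_c, eps)
  vip_pass <- (!is.na(vip_plsr) & vip_plsr > vip_threshold) |
    (!is.na(da_max) & da_max > vip_threshold)
  tibble::tibble(
    bin_id = ft$bins$bin_id,
    vip_plsr = vip_plsr,
    vip_plsda_max = da_max,
    mean_treatment = mean_t,
    mean_control = mean_c,
    fold_change = fold,
    p_value = p_val,
    vip_pass = vip_pass,
    induced = vip_pass & p_val < p_max & fold >= fold_min
  )
}

#' Spearman rank correlation between bins
#'
#' Symmetric bin-by-bin correlation matrix using Spearman ranks (average
#' tie handling), unit diagonal. Constant bins have undefined correlation;
#' their entries are reported as 0 and the affected bins are listed in the
#' `"constant_bins"` attribute. The matrix is invariant under any strictly
#' monotone transform of the intensities.
#'
#' @param fm A [feature_matrix()] with at least 3 samples.
#' @return A correlation matrix with bin ids as dimnames.
#' @export
spearman_bin_correlation <- function(fm) {
  validate_feature_matrix(fm)
  if (nrow(fm$values) < 3L) stop("need at least 3 samples", call. = FALSE)
  cm <- suppressWarnings(stats::cor(fm$values, method = "spearman"))
  constant <- fm$bins$bin_id[apply(fm$values, 2, function(v) {
    stats::sd(v) == 0
  })]
  cm[is.na(cm)] <- 0
  diag(cm) <- 1
  dimnames(cm) <- list(fm$bins$bin_id, fm$bins$bin_id)
  attr(cm, "constant_bins") <- constant
  cm
}
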