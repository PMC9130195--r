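#' Preprocessing configuration
#'
#' Bundles the tunable parameters of the preprocessing chain. Defaults match
#' the chemometric protocol the package implements: retention-time window
#' 11.5-31 min (closed interval), Whittaker baseline with asymmetry 0.001
#' and lambda 100, generalized-log lambda 0.1, QC relative-standard-deviation
#' cutoff 25%, signal-to-noise minimum 5 and a 75% replicate-occurrence rule.
#'
#' @param rt_lo,rt_hi Retention-time window in minutes.
#' @param whittaker_lambda,whittaker_p Baseline smoothness and asymmetry.
#' @param glog_lambda Generalized-log transform offset.
#' @param rsd_max_pct Maximum QC relative standard deviation, percent.
#' @param snr_min Minimum signal-to-noise ratio.
#' @param occurrence_min_frac Minimum fraction of replicates in which a bin
#'   must be detected in at least one (group, day) cell.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(rt_lo = 11.5, rt_hi = 31,
                              whittaker_lambda = 100, whittaker_p = 0.001,
                              glog_lambda = 0.1, rsd_max_pct = 25,
                              snr_min = 5, occurrence_min_frac = 0.75) {
  stopifnot(rt_lo < rt_hi, whittaker_p > 0, whittaker_p < 1,
            whittaker_lambda > 0, glog_lambda > 0, rsd_max_pct >= 0,
            snr_min > 0, occurrence_min_frac > 0, occurrence_min_frac <= 1)
  structure(list(rt_lo = rt_lo, rt_hi = rt_hi,
                 whittaker_lambda = whittaker_lambda,
                 whittaker_p = whittaker_p, glog_lambda = glog_lambda,
                 rsd_max_pct = rsd_max_pct, snr_min = snr_min,
                 occurrence_min_frac = occurrence_min_frac),
            class = "preprocess_config")
}

#' Trim bins outside the retention-time window
#'
#' Keeps bins with `rt_lo <= rt_min <= rt_hi` (closed interval) and advances
#' the stage tag to `"trimmed"`.
#'
#' @param fm A [feature_matrix()].
#' @param cfg A [preprocess_config()].
#' @return The trimmed `feature_matrix`.
#' @export
trim_rt <- function(fm, cfg = preprocess_config()) {
  validate_feature_matrix(fm)
  keep <- fm$bins$rt_min >= cfg$rt_lo & fm$bins$rt_min <= cfg$rt_hi
  if (!any(keep)) stop("all bins outside the RT window", call. = FALSE)
  out <- fm_take(fm, cols = keep)
  out$stage <- "trimmed"
  out
}

#' Total-area normalization
#'
#' Divides every sample row by its total summed intensity so each row sums
#' to one; idempotent. Stage advances to `"normalized"`.
#'
#' @param fm A [feature_matrix()] with non-negative intensities.
#' @return The normalized `feature_matrix`.
#' @export
normalize_total_area <- function(fm) {
  validate_feature_matrix(fm)
  sums <- rowSums(fm$values)
  bad <- which(sums <= 0)
  if (length(bad)) {
    stop("zero-sum sample row: ",
         paste(fm$samples$sample_id[bad], collapse = ", "), call. = FALSE)
  }
  fm_with_values(fm, fm$values / sums, stage = "normalized")
}

#' Generalized-log transform
#'
#' Applies `g(x) = ln(x + sqrt(x^2 + lambda))` elementwise - logarithmic at
#' high intensity, linear near zero, strictly increasing. The transform is
#' scale-dependent, so `glog_lambda` refers to the scale of the input; in
#' the standard chain the input is total-area-normalized (unit-sum rows).
#' Stage advances to `"glogged"`; outputs can be negative (for example
#' `g(0) = ln(sqrt(lambda))`) - downstream autoscaling absorbs the shift.
#'
#' @param fm A [feature_matrix()] with finite non-negative values.
#' @param cfg A [preprocess_config()] supplying `glog_lambda`.
#' @return The transformed `feature_matrix` (stage `"glogged"`).
#' @export
glog <- function(fm, cfg = preprocess_config()) {
  validate_feature_matrix(fm)
  if (any(fm$values < 0)) {
    stop("glog requires non-negative input (apply baseline clipping first)",
         call. = FALSE)
  }
  x <- fm$values
  fm_with_values(fm, log(x + sqrt(x^2 + cfg$glog_lambda)), stage = "glogged")
}

#' Autoscale (unit-variance scale) every bin
#'
#' Mean-centers each column and divides by its sample standard deviation
#' (n - 1 denominator) so all bins carry the same weight in subsequent
#' multivariate models. Stage advances to `"autoscaled"`.
#'
#' @param fm A [feature_matrix()].
#' @return The autoscaled `feature_matrix`.
#' @export
autoscale <- function(fm) {
  validate_feature_matrix(fm)
  sds <- apply(fm$values, 2, stats::sd)
  zero <- which(sds == 0 | !is.finite(sds))
  if (length(zero)) {
    stop("zero-variance bin: ",
         paste(fm$bins$bin_id[zero], collapse = ", "), call. = FALSE)
  }
  vals <- scale(fm$values, center = TRUE, scale = sds)
  attr(vals, "scaled:center") <- NULL
  attr(vals, "scaled:scale") <- NULL
  fm_with_values(fm, vals[, , drop = FALSE], stage = "autoscaled")
}

#' QC relative-standard-deviation filter
#'
#' Removes bins whose relative standard deviation (100 * sd / mean, n - 1
#' standard deviation) across the pooled-QC samples exceeds
#' `rsd_max_pct` - such bins are technically too variable to interpret.
#' Computed on raw (pre-transform) intensities. Bins with zero QC mean have
#' an undefined RSD and are removed with reason `"undefined RSD"`.
#'
#' @param fm A [feature_matrix()] containing at least 2 QC samples.
#' @param cfg A [preprocess_config()].
#' @return A list: `fm` (filtered matrix) and `removed` (tibble of bin_id,
#'   rsd_pct, reason).
#' @export
rsd_filter <- function(fm, cfg = preprocess_config()) {
  validate_feature_matrix(fm)
  qc <- fm$samples$group == "QC"
  if (sum(qc) < 2L) stop("rsd_filter needs >= 2 QC samples", call. = FALSE)
  qv <- fm$values[qc, , drop = FALSE]
  means <- unname(colMeans(qv))
  sds <- unname(apply(qv, 2, stats::sd))
  rsd <- ifelse(means > 0, 100 * sds / means, NA_real_)
  drop <- is.na(rsd) | rsd > cfg$rsd_max_pct
  removed <- tibble::tibble(
    bin_id = fm$bins$bin_id[drop],
    rsd_pct = rsd[drop],
    reason = ifelse(is.na(rsd[drop]), "undefined RSD",
                    sprintf("QC RSD %.2f%% > %g%%", rsd[drop],
                            cfg$rsd_max_pct))
  )
  fm_out <- if (any(drop)) fm_take(fm, cols = !drop) else fm
  list(fm = fm_out, removed = removed)
}

#' Signal-to-noise filter
#'
#' Removes bins whose strongest (group, day) mean intensity divided by the
#' noise level falls below `snr_min`. When organic-solvent blank (`OS`)
#' samples are present, the noise level defaults to the scaled median
#' absolute deviation (MAD, constant 1.4826) of their intensities; otherwise
#' it must be supplied.
#'
#' @param fm A [feature_matrix()].
#' @param noise_level Positive noise intensity; `NULL` to estimate from OS
#'   samples.
#' @param cfg A [preprocess_config()].
#' @return A list: `fm`, `removed` (tibble of bin_id, snr, reason) and
#'   `noise_level` used.
#' @export
snr_filter <- function(fm, noise_level = NULL, cfg = preprocess_config()) {
  validate_feature_matrix(fm)
  if (is.null(noise_level)) {
    os <- fm$samples$group == "OS"
    if (!any(os)) {
      stop("no OS samples: supply noise_level explicitly", call. = FALSE)
    }
    noise_level <- stats::mad(fm$values[os, , drop = FALSE], constant = 1.4826)
  }
  if (!is.finite(noise_level) || noise_level <= 0) {
    stop("noise_level must be positive", call. = FALSE)
  }
  study <- fm$samples$group %in% c("B", "F")
  cell <- interaction(fm$samples$group[study], fm$samples$day[study],
                      drop = TRUE)
  cell_means <- apply(fm$values[study, , drop = FALSE], 2, function(v) {
    max(tapply(v, cell, mean))
  })
  snr <- cell_means / noise_level
  drop <- snr < cfg$snr_min
  removed <- tibble::tibble(
    bin_id = fm$bins$bin_id[drop],
    snr = snr[drop],
    reason = sprintf("SNR %.2f < %g", snr[drop], cfg$snr_min)
  )
  fm_out <- if (any(drop)) fm_take(fm, cols = !drop) else fm
  list(fm = fm_out, removed = removed, noise_level = noise_level)
}

#' Replicate-occurrence filter
#'
#' Keeps a bin if, in at least one (group, day) cell, the fraction of
#' replicates with intensity above `detection_floor` reaches
#' `occurrence_min_frac`. Bins that never reach consistent detection in any
#' cell are removed.
#'
#' @param fm A [feature_matrix()].
#' @param detection_floor Intensity above which a bin counts as detected.
#' @param cfg A [preprocess_config()].
#' @return A list: `fm` and `removed` (tibble of bin_id, best_frac, reason).
#' @export
occurrence_filter <- function(fm, detection_floor, cfg = preprocess_config()) {
  validate_feature_matrix(fm)
  stopifnot(is.finite(detection_floor))
  study <- fm$samples$group %in% c("B", "F")
  if (!any(study)) stop("no study (B/F) samples", call. = FALSE)
  cell <- interaction(fm$samples$group[study], fm$samples$day[study],
                      drop = TRUE)
  best <- apply(fm$values[study, , drop = FALSE], 2, function(v) {
    max(tapply(v > detection_floor, cell, mean))
  })
  drop <- best < cfg$occurrence_min_frac
  removed <- tibble::tibble(
    bin_id = fm$bins$bin_id[drop],
    best_frac = best[drop],
    reason = sprintf("detected in at most %.0f%% of replicates (< %.0f%%)",
                     100 * best[drop], 100 * cfg$occurrence_min_frac)
  )
  if (all(drop)) stop("empty matrix: all bins below occurrence threshold",
                      call. = FALSE)
  fm_out <- if (any(drop)) fm_take(fm, cols = !drop) else fm
  list(fm = fm_out, removed = removed)
}

#' Blank subtraction and culture-medium annotation
#'
#' Removes bins identified in the organic-solvent blank (contaminants) and
#' flags culture-medium reference bins by appending `"culture_medium"` to
#' their label; medium bins stay in the matrix because they carry real
#' negatively-growth-correlated signal.
#'
#' @param fm A [feature_matrix()].
#' @param os_bins,cm_bins Integer bin ids listed in the organic-solvent
#'   blank and culture-medium reference runs.
#' @return A list: `fm` and `removed` (tibble of bin_id, reason).
#' @export
blank_subtraction <- function(fm, os_bins = integer(), cm_bins = integer()) {
  validate_feature_matrix(fm)
  unknown <- setdiff(c(os_bins, cm_bins), fm$bins$bin_id)
  if (length(unknown)) {
    stop("unknown bin_id in reference list: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  cm_sel <- fm$bins$bin_id %in% cm_bins
  if (any(cm_sel)) {
    lab <- fm$bins$label
    lab[cm_sel] <- ifelse(is.na(lab[cm_sel]) | lab[cm_sel] == "",
                          "culture_medium",
                          paste0(lab[cm_sel], ";culture_medium"))
    fm$bins$label <- lab
  }
  drop <- fm$bins$bin_id %in% os_bins
  removed <- tibble::tibble(bin_id = fm$bins$bin_id[drop],
                            reason = "organic-solvent blank contaminant")
  fm_out <- if (any(drop)) fm_take(fm, cols = !drop) else fm
  list(fm = fm_out, removed = removed)
}

#' Run the full preprocessing chain
#'
#' Applies, in order: RT trimming, signal-to-noise filter, replicate
#' occurrence filter, QC RSD filter, blank subtraction, then drops the
#' QC/OS/CM rows and finishes with total-area normalization,
#' generalized-log transform and autoscaling. Bin filters run on raw
#' intensities before any row scaling; the transforms run on study (B/F)
#' samples only so the scaling used by the models is estimated from the
#' samples they will see. Every removal is logged with a reason code.
#'
#' @param fm A raw [feature_matrix()] (QC rows included when available).
#' @param cfg A [preprocess_config()].
#' @param noise_level Noise intensity for [snr_filter()]; `NULL` estimates
#'   it from OS samples, `NA` skips the SNR filter.
#' @param detection_floor Detection floor for [occurrence_filter()];
#'   defaults to `noise_level` (or 0 when the SNR filter is skipped).
#' @param os_bins,cm_bins Reference bin lists for [blank_subtraction()].
#' @param keep_normalized Also return the normalized-stage matrix (needed by
#'   the induced-metabolite rule, which works on areas rather than
#'   transformed values).
#' @return A list: `fm` (autoscaled study matrix), `normalized` (normalized
#'   study matrix or `NULL`), `log` (tibble of stage, bin_id, reason) and
#'   `noise_level`.
#' @export
run_preprocess <- function(fm, cfg = preprocess_config(), noise_level = NA,
                           detection_floor = NULL,
                           os_bins = integer(), cm_bins = integer(),
                           keep_normalized = TRUE) {
  validate_feature_matrix(fm)
  log <- list()
  note <- function(stage, removed) {
    if (nrow(removed)) {
      tibble::tibble(stage = stage, bin_id = removed$bin_id,
                     reason = removed$reason)
    } else NULL
  }

  fm <- trim_rt(fm, cfg)

  used_noise <- NULL
  if (!(length(noise_level) == 1L && is.na(noise_level))) {
    step <- snr_filter(fm, noise_level = noise_level, cfg = cfg)
    fm <- step$fm
    used_noise <- step$noise_level
    log <- c(log, list(note("snr_filter", step$removed)))
  }

  if (is.null(detection_floor)) {
    detection_floor <- if (!is.null(used_noise)) used_noise else 0
  }
  step <- occurrence_filter(fm, detection_floor = detection_floor, cfg = cfg)
  fm <- step$fm
  log <- c(log, list(note("occurrence_filter", step$removed)))

  if (sum(fm$samples$group == "QC") >= 2L) {
    step <- rsd_filter(fm, cfg)
    fm <- step$fm
    log <- c(log, list(note("rsd_filter", step$removed)))
  }

  step <- blank_subtraction(fm, os_bins = os_bins, cm_bins = cm_bins)
  fm <- step$fm
  log <- c(log, list(note("blank_subtraction", step$removed)))

  fm <- fm_take(fm, rows = fm$samples$group %in% c("B", "F"))
  fm <- normalize_total_area(fm)
  normalized <- if (keep_normalized) fm else NULL
  fm <- autoscale(glog(fm, cfg))

  log_tbl <- dplyr::bind_rows(log)
  if (is.null(log_tbl) || nrow(log_tbl) == 0L) {
    log_tbl <- tibble::tibble(stage = character(), bin_id = integer(),
                              reason = character())
  }
  list(fm = fm, normalized = normalized, log = log_tbl,
       noise_level = used_noise)
}
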