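#' Binned LC-MS feature matrix
#'
#' A `feature_matrix` couples a dense samples-by-bins intensity matrix with
#' sample metadata (group code, incubation day, replicate) and bin metadata
#' (retention time, representative m/z, free-text label), plus a processing
#' stage tag that records where the object sits in the preprocessing chain.
#'
#' Group codes follow the study design convention: `B` (fed cultures), `F`
#' (unfed control), `QC` (pooled quality control), `OS` (organic-solvent
#' blank), `CM` (culture-medium reference). `B`/`F` samples must carry an
#' incubation day; `QC`/`OS`/`CM` samples must not.
#'
#' @param values Numeric matrix, rows = samples, columns = bins.
#' @param samples Data frame with columns `sample_id`, `group`, `day`,
#'   `replicate` (one row per matrix row, in order).
#' @param bins Data frame with columns `bin_id`, `rt_min` and optionally
#'   `mz`, `label` (one row per matrix column, in order).
#' @param stage Processing-stage tag, one of `"raw"`, `"trimmed"`,
#'   `"baselined"`, `"normalized"`, `"glogged"`, `"autoscaled"`.
#'
#' @return An object of class `feature_matrix`.
#' @examples
#' fm <- feature_matrix(
#'   values  = matrix(c(1, 2, 3, 4), 2, 2),
#'   samples = data.frame(sample_id = c("s1", "s2"), group = "B",
#'                        day = c(1, 4), replicate = 1L),
#'   bins    = data.frame(bin_id = 1:2, rt_min = c(12, 15))
#' )
#' fm
#' @export
feature_matrix <- function(values, samples, bins, stage = "raw") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  samples <- tibble::as_tibble(samples)
  bins <- tibble::as_tibble(bins)
  if (!"day" %in% names(samples)) samples$day <- NA_integer_
  if (!"replicate" %in% names(samples)) samples$replicate <- NA_integer_
  if (!"mz" %in% names(bins)) bins$mz <- NA_real_
  if (!"label" %in% names(bins)) bins$label <- NA_character_
  samples$day <- as.integer(samples$day)
  samples$replicate <- as.integer(samples$replicate)
  bins$bin_id <- as.integer(bins$bin_id)
  bins$label <- as.character(bins$label)
  rownames(values) <- samples$sample_id
  colnames(values) <- as.character(bins$bin_id)
  fm <- structure(
    list(values = values, samples = samples, bins = bins, stage = stage),
    class = "feature_matrix"
  )
  validate_feature_matrix(fm)
  fm
}

fm_stages <- c("raw", "trimmed", "baselined", "normalized", "glogged", "autoscaled")
fm_groups <- c("B", "F", "QC", "OS", "CM")

#' Validate a feature matrix
#'
#' Checks the structural invariants of a [feature_matrix()]: dimension
#' agreement between the value matrix and the metadata tables, unique sample
#' and bin identifiers, day rules per group code, positive retention times,
#' and stage-dependent sign constraints (all stages before autoscaling hold
#' finite non-negative intensities; the autoscaled stage holds finite values
#' of either sign).
#'
#' @param fm A `feature_matrix`.
#' @return `fm`, invisibly; errors describe the first violated invariant.
#' @export
validate_feature_matrix <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (!fm$stage %in% fm_stages) {
    stop("unknown stage '", fm$stage, "'", call. = FALSE)
  }
  if (nrow(fm$values) == 0L || ncol(fm$values) == 0L) {
    stop("empty matrix", call. = FALSE)
  }
  if (nrow(fm$values) != nrow(fm$samples)) {
    stop("row count (", nrow(fm$values), ") != number of samples (",
         nrow(fm$samples), ")", call. = FALSE)
  }
  if (ncol(fm$values) != nrow(fm$bins)) {
    stop("column count (", ncol(fm$values), ") != number of bins (",
         nrow(fm$bins), ")", call. = FALSE)
  }
  dup <- fm$samples$sample_id[duplicated(fm$samples$sample_id)]
  if (length(dup)) {
    stop("duplicated sample_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  dup <- fm$bins$bin_id[duplicated(fm$bins$bin_id)]
  if (length(dup)) {
    stop("duplicated bin_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(fm$samples$group), fm_groups)
  if (length(bad)) {
    stop("unknown group code: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  need_day <- fm$samples$group %in% c("B", "F")
  if (any(need_day & is.na(fm$samples$day))) {
    stop("B/F samples must carry an incubation day: ",
         paste(fm$samples$sample_id[need_day & is.na(fm$samples$day)],
               collapse = ", "), call. = FALSE)
  }
  if (any(!need_day & !is.na(fm$samples$day))) {
    stop("QC/OS/CM samples must not carry a day: ",
         paste(fm$samples$sample_id[!need_day & !is.na(fm$samples$day)],
               collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(fm$bins$rt_min)) || any(fm$bins$rt_min <= 0)) {
    stop("rt_min must be strictly positive and finite", call. = FALSE)
  }
  if (any(!is.finite(fm$values))) {
    stop("non-finite intensity values", call. = FALSE)
  }
  if (fm$stage %in% c("raw", "trimmed", "baselined", "normalized") &&
      any(fm$values < 0)) {
    stop("negative intensities at stage '", fm$stage, "'", call. = FALSE)
  }
  invisible(fm)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x$values), " samples x ", ncol(x$values),
      " bins, stage '", x$stage, "'\n", sep = "")
  grp <- table(x$samples$group)
  cat("  groups: ", paste(names(grp), grp, sep = ":", collapse = "  "), "\n",
      sep = "")
  cat("  rt range: ", min(x$bins$rt_min), "-", max(x$bins$rt_min), " min\n",
      sep = "")
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Subset a feature matrix by sample and bin predicates
#'
#' Filters samples and bins with data-masking expressions evaluated against
#' the respective metadata tables, in the style of [dplyr::filter()]. Sample
#' and bin filters commute and the operation is idempotent.
#'
#' @param fm A [feature_matrix()].
#' @param samples,bins Filter expressions on the sample / bin metadata
#'   columns (e.g. `samples = group == "B"`, `bins = rt_min < 20`). `NULL`
#'   keeps everything.
#' @return A `feature_matrix` restricted to the selected rows and columns.
#' @examples
#' fm <- simulate_dataset(sim_config(seed = 1))$feeding
#' fm_subset(fm, samples = group == "B" & day == 4)
#' @export
fm_subset <- function(fm, samples = NULL, bins = NULL) {
  validate_feature_matrix(fm)
  keep_s <- rep(TRUE, nrow(fm$samples))
  keep_b <- rep(TRUE, nrow(fm$bins))
  s_quo <- rlang::enquo(samples)
  b_quo <- rlang::enquo(bins)
  if (!rlang::quo_is_null(s_quo)) {
    keep_s <- rlang::eval_tidy(s_quo, data = fm$samples)
    keep_s[is.na(keep_s)] <- FALSE
  }
  if (!rlang::quo_is_null(b_quo)) {
    keep_b <- rlang::eval_tidy(b_quo, data = fm$bins)
    keep_b[is.na(keep_b)] <- FALSE
  }
  if (!any(keep_s) || !any(keep_b)) stop("empty selection", call. = FALSE)
  feature_matrix(
    values = fm$values[keep_s, keep_b, drop = FALSE],
    samples = fm$samples[keep_s, , drop = FALSE],
    bins = fm$bins[keep_b, , drop = FALSE],
    stage = fm$stage
  )
}

# internal: subset by logical/integer index without tidy-eval
fm_take <- function(fm, rows = NULL, cols = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(fm$values))
  if (is.null(cols)) cols <- seq_len(ncol(fm$values))
  if (length(rows) == 0L || length(cols) == 0L ||
      (is.logical(rows) && !any(rows)) || (is.logical(cols) && !any(cols))) {
    stop("empty selection", call. = FALSE)
  }
  feature_matrix(
    values = fm$values[rows, cols, drop = FALSE],
    samples = fm$samples[rows, , drop = FALSE],
    bins = fm$bins[cols, , drop = FALSE],
    stage = fm$stage
  )
}

# internal: replace values, optionally advancing the stage tag
fm_with_values <- function(fm, values, stage = fm$stage) {
  feature_matrix(values = values, samples = fm$samples, bins = fm$bins,
                 stage = stage)
}

#' Long-format view of a feature matrix
#'
#' @param x A [feature_matrix()].
#' @param ... Unused.
#' @return A tibble with one row per (sample, bin) cell: sample metadata,
#'   bin metadata, `intensity` and the processing `stage`.
#' @export
tidy.feature_matrix <- function(x, ...) {
  validate_feature_matrix(x)
  long <- tibble::tibble(
    sample_id = rep(x$samples$sample_id, times = ncol(x$values)),
    bin_id = rep(x$bins$bin_id, each = nrow(x$values)),
    intensity = as.vector(x$values)
  )
  long <- dplyr::left_join(long, x$samples, by = "sample_id")
  long <- dplyr::left_join(long, x$bins, by = "bin_id")
  long$stage <- x$stage
  long
}

#' One-row summary of a feature matrix
#'
#' @param x A [feature_matrix()].
#' @param ... Unused.
#' @return A one-row tibble: sample/bin counts, stage, per-group tallies,
#'   retention-time span.
#' @export
glance.feature_matrix <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$values),
    n_bins = ncol(x$values),
    stage = x$stage,
    n_study = sum(x$samples$group %in% c("B", "F")),
    n_qc = sum(x$samples$group == "QC"),
    rt_lo = min(x$bins$rt_min),
    rt_hi = max(x$bins$rt_min)
  )
}
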