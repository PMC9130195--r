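#' Read a feature matrix from the three-file delimited dialect
#'
#' The on-disk representation is three UTF-8 CSV files: `features.csv`
#' (header `sample_id,<bin_id>,...`, one row per sample), `samples.csv`
#' (`sample_id,group,day,replicate`; `day` empty for QC/OS/CM rows) and
#' `bins.csv` (`bin_id,rt_min,mz,label`; `mz`/`label` optional). Keeping the
#' metadata in their own typed files avoids overloading the matrix header.
#'
#' File ordering is preserved on read, but no code should rely on it:
#' [write_feature_matrix()] sorts samples by (group, day, replicate).
#'
#' @param matrix_path,sample_meta_path,bin_meta_path Paths to the three files.
#' @param stage Stage tag to attach, default `"raw"`.
#' @return A [feature_matrix()].
#' @seealso [write_feature_matrix()], [read_growth()]
#' @export
read_feature_matrix <- function(matrix_path, sample_meta_path, bin_meta_path,
                                stage = "raw") {
  for (p in c(matrix_path, sample_meta_path, bin_meta_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  feats <- readr::read_csv(matrix_path, show_col_types = FALSE,
                           col_types = readr::cols(sample_id = "c",
                                                   .default = "c"))
  if (names(feats)[1] != "sample_id") {
    stop("features file must start with a 'sample_id' column", call. = FALSE)
  }
  samples <- readr::read_csv(
    sample_meta_path, show_col_types = FALSE,
    col_types = readr::cols(sample_id = "c", group = "c",
                            day = "i", replicate = "i")
  )
  bins <- readr::read_csv(
    bin_meta_path, show_col_types = FALSE,
    col_types = readr::cols(bin_id = "i", rt_min = "d",
                            .default = readr::col_guess())
  )
  if (!"mz" %in% names(bins)) bins$mz <- NA_real_
  if (!"label" %in% names(bins)) bins$label <- NA_character_
  bins$label <- as.character(bins$label)

  dup <- feats$sample_id[duplicated(feats$sample_id)]
  if (length(dup)) {
    stop("duplicated sample_id in matrix file: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  matrix_bins <- names(feats)[-1]
  missing_bins <- setdiff(matrix_bins, as.character(bins$bin_id))
  if (length(missing_bins)) {
    stop("bin_id present in matrix but absent from bin metadata: ",
         paste(missing_bins, collapse = ", "), call. = FALSE)
  }
  missing_samples <- setdiff(feats$sample_id, samples$sample_id)
  if (length(missing_samples)) {
    stop("sample_id present in matrix but absent from sample metadata: ",
         paste(missing_samples, collapse = ", "), call. = FALSE)
  }

  vals <- matrix(NA_real_, nrow(feats), length(matrix_bins))
  for (j in seq_along(matrix_bins)) {
    col <- feats[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col))
    if (length(bad)) {
      stop("non-numeric intensity at row ", bad[1], " (sample '",
           feats$sample_id[bad[1]], "'), column '", matrix_bins[j], "': '",
           col[bad[1]], "'", call. = FALSE)
    }
    vals[, j] <- num
  }

  samples <- samples[match(feats$sample_id, samples$sample_id), , drop = FALSE]
  bins <- bins[match(as.integer(matrix_bins), bins$bin_id), , drop = FALSE]
  feature_matrix(vals, samples, bins, stage = stage)
}

#' Write a feature matrix to the three-file delimited dialect
#'
#' Inverse of [read_feature_matrix()]. Intensities are serialized in full
#' precision (`format(..., digits = 17)`) so that a read/write round trip
#' reproduces values bit-for-bit. Samples are written sorted by
#' (group, day, replicate).
#'
#' @param fm A [feature_matrix()].
#' @param out_dir Output directory, created if absent.
#' @param prefix Optional filename prefix (e.g. a group code).
#' @return Named character vector of the three paths written, invisibly a
#'   tibble is not needed here.
#' @export
write_feature_matrix <- function(fm, out_dir, prefix = "") {
  validate_feature_matrix(fm)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  ord <- order(fm$samples$group, fm$samples$day, fm$samples$replicate)
  vals <- fm$values[ord, , drop = FALSE]
  samples <- fm$samples[ord, , drop = FALSE]

  fmt <- function(x) vapply(x, function(v) format(v, digits = 17), character(1))
  mat_df <- data.frame(sample_id = samples$sample_id,
                       stringsAsFactors = FALSE, check.names = FALSE)
  for (j in seq_len(ncol(vals))) {
    mat_df[[as.character(fm$bins$bin_id[j])]] <- fmt(vals[, j])
  }
  paths <- c(
    features = file.path(out_dir, paste0(prefix, "features.csv")),
    samples = file.path(out_dir, paste0(prefix, "samples.csv")),
    bins = file.path(out_dir, paste0(prefix, "bins.csv")),
    stage = file.path(out_dir, paste0(prefix, "stage.txt"))
  )
  readr::write_csv(mat_df, paths[["features"]])
  readr::write_csv(samples[c("sample_id", "group", "day", "replicate")],
                   paths[["samples"]])
  readr::write_csv(fm$bins[c("bin_id", "rt_min", "mz", "label")],
                   paths[["bins"]])
  writeLines(fm$stage, paths[["stage"]])
  paths
}

#' Read colony-diameter growth records
#'
#' Expects a CSV with header `day,diameter_cm` and optionally a leading
#' `group` column when one file holds several growth series. Diameters must
#' be positive, non-decreasing within a series, and no larger than the
#' 9 cm Petri plate.
#'
#' @param path CSV path.
#' @return A tibble with columns (`group`,) `day`, `diameter_cm`.
#' @export
read_growth <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  g <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("day", "diameter_cm") %in% names(g))) {
    stop("growth file needs columns 'day' and 'diameter_cm'", call. = FALSE)
  }
  g$day <- as.integer(g$day)
  validate_growth(g)
  tibble::as_tibble(g)
}

validate_growth <- function(g, plate_cm = 9) {
  if (any(!is.finite(g$diameter_cm)) || any(g$diameter_cm <= 0)) {
    stop("diameters must be positive", call. = FALSE)
  }
  if (any(g$diameter_cm > plate_cm)) {
    stop("diameter exceeds plate size (", plate_cm, " cm)", call. = FALSE)
  }
  split_by <- if ("group" %in% names(g)) g$group else rep(1L, nrow(g))
  for (piece in split(g, split_by)) {
    piece <- piece[order(piece$day), ]
    if (is.unsorted(piece$diameter_cm)) {
      stop("diameter_cm must be non-decreasing with day", call. = FALSE)
    }
  }
  invisible(g)
}
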