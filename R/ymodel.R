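#' Build a response vector from incubation days or colony diameters
#'
#' Supervised modelling of a microbial time course needs a response (Y)
#' vector per sample. Two sources are supported: the incubation day itself,
#' or the colony diameter measured on that day - the latter encodes the
#' organism's actual growth. Either source can additionally be
#' log-transformed (natural log), reflecting that growth on limited medium
#' follows a logarithmic trajectory; replicates of the same day share a
#' value, and day 1 / a 1 cm colony maps to exactly 0 under the log
#' treatment.
#'
#' @param samples Sample metadata tibble (columns `sample_id`, `day`);
#'   all rows must carry a day.
#' @param growth Growth tibble (`day`, `diameter_cm`) covering every day
#'   present; only needed for `source = "diameter"`.
#' @param source `"days"` or `"diameter"`.
#' @param treatment `"raw"` or `"log"` (natural logarithm).
#' @return A `y_model`: `values` (aligned to `samples`), `source`,
#'   `treatment`, `design` (tibble day / y, the per-class design values).
#' @examples
#' samples <- data.frame(sample_id = paste0("s", 1:5), day = c(1, 4, 8, 12, 16))
#' build_y(samples, source = "days", treatment = "log")$design
#' @export
build_y <- function(samples, growth = NULL,
                    source = c("days", "diameter"),
                    treatment = c("raw", "log")) {
  source <- match.arg(source)
  treatment <- match.arg(treatment)
  samples <- tibble::as_tibble(samples)
  if (any(is.na(samples$day))) {
    stop("all samples must carry an incubation day", call. = FALSE)
  }
  days <- sort(unique(samples$day))
  if (source == "days") {
    design_y <- as.numeric(days)
  } else {
    if (is.null(growth)) stop("growth records required for source = 'diameter'",
                              call. = FALSE)
    growth <- tibble::as_tibble(growth)
    missing_days <- setdiff(days, growth$day)
    if (length(missing_days)) {
      stop("growth records missing day(s): ",
           paste(missing_days, collapse = ", "), call. = FALSE)
    }
    design_y <- growth$diameter_cm[match(days, growth$day)]
  }
  if (treatment == "log") {
    if (any(design_y <= 0)) {
      stop("log treatment requires positive source values", call. = FALSE)
    }
    design_y <- log(design_y)
  }
  design <- tibble::tibble(day = days, y = design_y)
  structure(list(
    values = design$y[match(samples$day, design$day)],
    source = source, treatment = treatment, design = design,
    sample_id = samples$sample_id
  ), class = "y_model")
}

#' @export
print.y_model <- function(x, ...) {
  cat("<y_model> source = ", x$source, ", treatment = ", x$treatment, "\n",
      sep = "")
  print(x$design)
  invisible(x)
}

#' Truncate values toward zero at a fixed number of decimals
#'
#' Reporting convention used for table-style display of design values:
#' truncation toward zero rather than rounding (ln 8 = 2.0794 prints as
#' 2.07, not 2.08).
#'
#' @param x Numeric vector.
#' @param digits Decimals kept (default 2).
#' @return Numeric vector truncated toward zero.
#' @export
truncate_decimals <- function(x, digits = 2L) {
  trunc(x * 10^digits) / 10^digits
}

#' Table-style view of a response model
#'
#' @param x A [build_y()] object.
#' @param ... Unused.
#' @return Tibble with `day`, `y` (full precision) and `y_printed`
#'   (truncated toward zero at two decimals, the table reporting
#'   convention).
#' @export
tidy.y_model <- function(x, ...) {
  dplyr::mutate(x$design, y_printed = truncate_decimals(y, 2L))
}

#' Compare candidate response models by cross-validated PLSr
#'
#' Fits one PLS regression per candidate Y-vector, scores each by
#' leave-one-out Q2 (the cross-validated R2) and a permutation test, and
#' declares a winner: among the candidates whose three permutation
#' p-values (Wilcoxon, sign, t) all fall below `alpha`, the one with the
#' highest Q2; ties break toward fewer latent components, then listed
#' order. Candidates failing validation are recorded and excluded.
#'
#' @param fm A [feature_matrix()] (typically glogged with `scale = TRUE`,
#'   or autoscaled with `scale = FALSE`) restricted to one study group.
#' @param candidates Named list of [build_y()] objects aligned to the
#'   samples of `fm`.
#' @param ncomp_max Largest component count examined per candidate.
#' @param n_perm Permutations per candidate.
#' @param seed Integer seed (one stream per candidate is derived from it).
#' @param scale Passed to [loo_cv()] / [permutation_test()].
#' @param alpha Significance level of the winner rule.
#' @return A `model_comparison`: `results` tibble (candidate, source,
#'   treatment, ncomp, r2, q2, p_wilcoxon, p_sign, p_ttest, empirical_p,
#'   valid), `winner` (candidate name or `NA`), plus the fitted `cv` and
#'   `permutation` objects per candidate.
#' @export
compare_y_models <- function(fm, candidates, ncomp_max = 6L, n_perm = 1000L,
                             seed, scale = TRUE, alpha = 0.05) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  x <- if (inherits(fm, "feature_matrix")) fm$values else as.matrix(fm)
  ncomp_max <- min(ncomp_max, nrow(x) - 2L, ncol(x))
  if (is.null(names(candidates))) {
    names(candidates) <- vapply(candidates, function(cnd) {
      paste(cnd$source, cnd$treatment, sep = "_")
    }, character(1))
  }
  rows <- list()
  cvs <- list()
  perms <- list()
  for (i in seq_along(candidates)) {
    cnd <- candidates[[i]]
    nm <- names(candidates)[i]
    res <- tryCatch({
      cv <- loo_cv(x, cnd$values, ncomp_max = ncomp_max, scale = scale)
      pt <- permutation_test(x, cnd$values, ncomp = cv$ncomp,
                             n_perm = n_perm, seed = seed + i, scale = scale)
      list(cv = cv, pt = pt, ok = TRUE)
    }, error = function(e) list(ok = FALSE, msg = conditionMessage(e)))
    if (res$ok) {
      cvs[[nm]] <- res$cv
      perms[[nm]] <- res$pt
      rows[[i]] <- tibble::tibble(
        candidate = nm, source = cnd$source, treatment = cnd$treatment,
        ncomp = res$cv$ncomp, r2 = res$cv$r2, q2 = res$cv$q2,
        p_wilcoxon = res$pt$p_wilcoxon, p_sign = res$pt$p_sign,
        p_ttest = res$pt$p_ttest, empirical_p = res$pt$empirical_p,
        valid = TRUE, failure = NA_character_
      )
    } else {
      rows[[i]] <- tibble::tibble(
        candidate = nm, source = cnd$source, treatment = cnd$treatment,
        ncomp = NA_integer_, r2 = NA_real_, q2 = NA_real_,
        p_wilcoxon = NA_real_, p_sign = NA_real_, p_ttest = NA_real_,
        empirical_p = NA_real_, valid = FALSE, failure = res$msg
      )
    }
  }
  results <- dplyr::bind_rows(rows)
  eligible <- results$valid &
    results$p_wilcoxon < alpha & results$p_sign < alpha &
    results$p_ttest < alpha
  winner <- NA_character_
  if (any(eligible)) {
    el <- results[eligible, ]
    el <- el[order(-el$q2, el$ncomp, match(el$candidate, results$candidate)), ]
    winner <- el$candidate[1]
  }
  structure(list(results = results, winner = winner, cv = cvs,
                 permutation = perms, alpha = alpha),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison> winner: ", x$winner, "\n", sep = "")
  print(x$results[c("candidate", "ncomp", "q2", "p_wilcoxon", "p_sign",
                    "p_ttest", "valid")])
  invisible(x)
}

#' @export
tidy.model_comparison <- function(x, ...) x$results

#' @export
glance.model_comparison <- function(x, ...) {
  w <- x$results[x$results$candidate %in% x$winner, ]
  tibble::tibble(winner = x$winner,
                 q2 = if (nrow(w)) w$q2 else NA_real_,
                 ncomp = if (nrow(w)) w$ncomp else NA_integer_,
                 n_candidates = nrow(x$results))
}
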