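#' Configuration for the synthetic time-course generator
#'
#' Describes a two-group (fed `B` vs control `F`) solid-culture time course:
#' incubation days, replicate count, per-day colony diameters for each group,
#' replicate noise, pooled-QC rows and the census of bin archetypes. Defaults
#' reproduce the study design the package targets: 5 incubation days
#' (1, 4, 8, 12, 16), triplicates, 25 bins spread over retention times
#' 11.5-31 min, feeding-colony diameters (1, 3.19, 7.54, 8.41, 9) cm and
#' control diameters (1, 4.9, 8, 8.5, 9) cm on a 9 cm plate.
#'
#' The archetype census defaults to 5 `media_decay` (culture-medium
#' components consumed as the colony grows), 8 `growth_linked` (fungal
#' metabolites accumulating with growth), 2 `alkaloid` (fed compounds,
#' consumed in `B`, absent in `F`), 3 `early_pulse` (day-4-only response in
#' `B`), 2 `late_pulse` (days 8-12 only in `B`), 1 `stress_upregulated`
#' (constitutive metabolite up-modulated in `B` during days 8-12) and 4
#' `inert` bins - 25 in total, giving 15 growth-monotone bins in the fed
#' group.
#'
#' @param n_replicates Replicates per (group, day) cell.
#' @param days Integer incubation days.
#' @param archetype_counts Named integer vector over the archetype kinds.
#' @param replicate_cv Fractional coefficient of variation of the
#'   multiplicative lognormal replicate noise, in `[0, 1)`.
#' @param qc_count Pooled-QC rows per group matrix.
#' @param seed Integer seed; mandatory, the generator is deterministic
#'   given it.
#' @param diameters_feeding,diameters_control Colony diameters (cm), one
#'   per day.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_replicates = 3L,
                       days = c(1L, 4L, 8L, 12L, 16L),
                       archetype_counts = c(media_decay = 5L,
                                            growth_linked = 8L,
                                            alkaloid = 2L,
                                            early_pulse = 3L,
                                            late_pulse = 2L,
                                            stress_upregulated = 1L,
                                            inert = 4L),
                       replicate_cv = 0.10,
                       qc_count = 3L,
                       seed = NULL,
                       diameters_feeding = c(1, 3.19, 7.54, 8.41, 9),
                       diameters_control = c(1, 4.9, 8, 8.5, 9)) {
  if (is.null(seed)) stop("seed is mandatory for reproducibility", call. = FALSE)
  kinds <- c("media_decay", "growth_linked", "alkaloid", "early_pulse",
             "late_pulse", "stress_upregulated", "inert")
  if (!all(names(archetype_counts) %in% kinds)) {
    stop("unknown archetype kind: ",
         paste(setdiff(names(archetype_counts), kinds), collapse = ", "),
         call. = FALSE)
  }
  counts <- stats::setNames(integer(length(kinds)), kinds)
  counts[names(archetype_counts)] <- as.integer(archetype_counts)
  if (sum(counts) <= 0L) stop("archetype counts sum to 0", call. = FALSE)
  if (length(diameters_feeding) != length(days) ||
      length(diameters_control) != length(days)) {
    stop("diameter lists must align with days", call. = FALSE)
  }
  if (replicate_cv < 0 || replicate_cv >= 1) {
    stop("replicate_cv must be in [0, 1)", call. = FALSE)
  }
  validate_growth(tibble::tibble(day = days, diameter_cm = diameters_feeding))
  validate_growth(tibble::tibble(day = days, diameter_cm = diameters_control))
  structure(list(
    n_replicates = as.integer(n_replicates),
    days = as.integer(days),
    archetype_counts = counts,
    replicate_cv = replicate_cv,
    qc_count = as.integer(qc_count),
    seed = as.integer(seed),
    diameters_feeding = diameters_feeding,
    diameters_control = diameters_control
  ), class = "sim_config")
}

# noiseless group-mean trajectory of one archetype bin over the days.
# g = log colony diameter is the growth signal tying intensities to the
# growth-informed response model; s = g scaled to [0, 1].
archetype_trajectory <- function(kind, base, group, g, pulse_days, days) {
  s <- g / max(g)
  switch(kind,
    media_decay = base * (1 - s),
    growth_linked = base * s,
    alkaloid = if (group == "B") base * exp(-2.5 * g) else rep(0, length(g)),
    early_pulse = ,
    late_pulse = if (group == "B") base * as.numeric(days %in% pulse_days)
                 else rep(0, length(g)),
    stress_upregulated = base * (0.3 + 0.7 * s) *
      (if (group == "B") ifelse(days %in% c(8L, 12L), 4, 1) else 1),
    inert = rep(base, length(g)),
    stop("unknown kind ", kind)
  )
}

#' Simulate a two-group LC-MS feature-matrix time course
#'
#' Generates one [feature_matrix()] per group (fed `B` and control `F`), a
#' growth table, and a planted ground-truth table for recovery studies. Bin
#' mean trajectories follow the archetypes of [sim_config()]: the growth
#' signal is `g(day) = ln(diameter)`, media components decay as
#' `1 - g/g_max`, growth-linked metabolites rise as `g/g_max`, fed alkaloids
#' decay as `exp(-2.5 g)` in `B` (below 1% of their initial level by day 12)
#' and stay at the noise floor in `F`, pulse bins are nonzero only on their
#' pulse days and only in `B`. Replicates receive multiplicative lognormal
#' noise with the configured CV after addition of a small constant floor
#' (0.1% of the median base intensity) so no intensity is exactly zero.
#' QC rows are the pooled mean over all study samples of both groups, with
#' the same noise model.
#'
#' Ground truth: bins with growth-monotone means (`media_decay`,
#' `growth_linked`, `alkaloid`) are marked PLSr-relevant; pulse bins carry
#' their PLS-DA class (`"4"` or `"8/12"`); `early_pulse`/`late_pulse` bins
#' (feeding-only, produced) are marked induced.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `feeding`, `control` (feature matrices),
#'   `growth` (tibble: group, day, diameter_cm), `truth` (tibble: bin_id,
#'   kind, plsr_relevant, plsda_class, induced) and `config`.
#' @examples
#' sim <- simulate_dataset(sim_config(seed = 1))
#' sim$feeding
#' dplyr::count(sim$truth, kind)
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  counts <- cfg$archetype_counts
  p <- sum(counts)
  kinds <- rep(names(counts), counts)
  # interleave kinds over the RT axis so archetypes are not RT-contiguous
  kinds <- sample(kinds)
  rt <- seq(11.5, 31, length.out = p + 2L)[-c(1L, p + 2L)]
  base <- stats::runif(p, min = 500, max = 5000)
  floor_add <- 0.001 * stats::median(base)
  pulse_days <- lapply(kinds, function(k) {
    switch(k, early_pulse = 4L, late_pulse = c(8L, 12L), integer(0))
  })

  g_B <- log(cfg$diameters_feeding)
  g_F <- log(cfg$diameters_control)
  sdlog <- sqrt(log(1 + cfg$replicate_cv^2))
  noise <- function(n) {
    if (cfg$replicate_cv == 0) rep(1, n)
    else stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }

  group_means <- function(group, g) {
    m <- matrix(0, length(cfg$days), p)
    for (j in seq_len(p)) {
      m[, j] <- archetype_trajectory(kinds[j], base[j], group, g,
                                     pulse_days[[j]], cfg$days)
    }
    m + floor_add
  }
  mean_B <- group_means("B", g_B)
  mean_F <- group_means("F", g_F)

  make_group <- function(group, means, pooled) {
    n_study <- length(cfg$days) * cfg$n_replicates
    vals <- matrix(0, n_study + cfg$qc_count, p)
    ids <- character(n_study + cfg$qc_count)
    day_col <- rep(NA_integer_, n_study + cfg$qc_count)
    rep_col <- rep(NA_integer_, n_study + cfg$qc_count)
    grp_col <- rep(group, n_study + cfg$qc_count)
    i <- 0L
    for (d in seq_along(cfg$days)) {
      for (r in seq_len(cfg$n_replicates)) {
        i <- i + 1L
        vals[i, ] <- means[d, ] * noise(p)
        ids[i] <- sprintf("%s_D%d_R%d", group, cfg$days[d], r)
        day_col[i] <- cfg$days[d]
        rep_col[i] <- r
      }
    }
    for (q in seq_len(cfg$qc_count)) {
      i <- i + 1L
      vals[i, ] <- pooled * noise(p)
      ids[i] <- sprintf("QC_%s_%d", group, q)
      grp_col[i] <- "QC"
    }
    feature_matrix(
      vals,
      samples = tibble::tibble(sample_id = ids, group = grp_col,
                               day = day_col, replicate = rep_col),
      bins = tibble::tibble(bin_id = seq_len(p), rt_min = rt, mz = NA_real_,
                            label = kinds),
      stage = "raw"
    )
  }

  pooled <- (colMeans(mean_B[rep(seq_along(cfg$days), each = cfg$n_replicates), ,
                             drop = FALSE]) +
             colMeans(mean_F[rep(seq_along(cfg$days), each = cfg$n_replicates), ,
                             drop = FALSE])) / 2
  fm_B <- make_group("B", mean_B, pooled)
  fm_F <- make_group("F", mean_F, pooled)

  truth <- tibble::tibble(
    bin_id = seq_len(p),
    kind = kinds,
    plsr_relevant = kinds %in% c("media_decay", "growth_linked", "alkaloid"),
    plsda_class = dplyr::case_when(
      kinds == "early_pulse" ~ "4",
      kinds %in% c("late_pulse", "stress_upregulated") ~ "8/12",
      kinds %in% c("media_decay", "alkaloid") ~ "1",
      kinds == "growth_linked" ~ "16",
      TRUE ~ NA_character_
    ),
    induced = kinds %in% c("early_pulse", "late_pulse")
  )
  growth <- dplyr::bind_rows(
    tibble::tibble(group = "B", day = cfg$days,
                   diameter_cm = cfg$diameters_feeding),
    tibble::tibble(group = "F", day = cfg$days,
                   diameter_cm = cfg$diameters_control)
  )
  list(feeding = fm_B, control = fm_F, growth = growth, truth = truth,
       config = cfg)
}

#' Render per-sample chromatogram traces from a feature matrix
#'
#' Produces point-by-point traces in which each bin becomes a Gaussian peak
#' centered at its retention time with area equal to the bin intensity, on
#' top of an optional smooth low-frequency baseline (a raised sinusoid of
#' the stated amplitude spanning the RT range). Used to exercise baseline
#' correction and re-binning; integrating a drift-free trace over a bin
#' window recovers the bin intensity to within numerical quadrature error.
#'
#' @param fm A [feature_matrix()] whose bins carry `rt_min`.
#' @param rt_grid_step Grid spacing in minutes.
#' @param peak_width_sd Gaussian peak SD in minutes.
#' @param baseline_drift_amplitude Baseline amplitude in intensity units.
#' @param pad Extra RT span rendered beyond the extreme bin centers
#'   (minutes); defaults to four peak SDs plus half a minute so integration
#'   windows around edge bins stay inside the trace.
#' @return A list with `rt` (grid vector), `traces` (samples x grid matrix),
#'   `baseline` (the drift added to every trace) and the echoing parameters.
#' @export
render_chromatograms <- function(fm, rt_grid_step = 0.02,
                                 peak_width_sd = 0.08,
                                 baseline_drift_amplitude = 0,
                                 pad = 4 * peak_width_sd + 0.5) {
  validate_feature_matrix(fm)
  stopifnot(rt_grid_step > 0, peak_width_sd > 0, pad >= 0)
  gaps <- diff(sort(fm$bins$rt_min))
  if (length(gaps) && any(gaps < 2 * peak_width_sd)) {
    warning("bins closer than 2 peak-width SDs: convolution expected",
            call. = FALSE)
  }
  rt <- seq(min(fm$bins$rt_min) - pad, max(fm$bins$rt_min) + pad,
            by = rt_grid_step)
  span <- diff(range(rt))
  baseline <- baseline_drift_amplitude *
    (0.5 + 0.5 * sin(2 * pi * (rt - rt[1]) / span))
  n <- nrow(fm$values)
  traces <- matrix(rep(baseline, each = n), n, length(rt))
  for (j in seq_len(ncol(fm$values))) {
    peak <- stats::dnorm(rt, mean = fm$bins$rt_min[j], sd = peak_width_sd)
    traces <- traces + fm$values[, j, drop = FALSE] %*% rbind(peak)
  }
  rownames(traces) <- fm$samples$sample_id
  list(rt = rt, traces = traces, baseline = baseline,
       samples = fm$samples, bins = fm$bins,
       peak_width_sd = peak_width_sd, rt_grid_step = rt_grid_step)
}

#' Integrate chromatogram traces back into a feature matrix
#'
#' Bin intensity is the trapezoidal integral of each trace inside the
#' closed window `rt_min +/- window_half_width`. Windows must not overlap
#' after clipping and must lie inside the rendered RT span.
#'
#' @param traces Output of [render_chromatograms()].
#' @param bins Bin metadata tibble (`bin_id`, `rt_min`, ...).
#' @param window_half_width Half-width of the integration window (minutes).
#' @return A [feature_matrix()] at stage `"raw"`.
#' @export
bin_chromatograms <- function(traces, bins, window_half_width) {
  stopifnot(window_half_width > 0)
  bins <- tibble::as_tibble(bins)
  o <- order(bins$rt_min)
  if (any(diff(bins$rt_min[o]) < 2 * window_half_width)) {
    stop("overlapping integration windows", call. = FALSE)
  }
  rt <- traces$rt
  vals <- matrix(0, nrow(traces$traces), nrow(bins))
  for (j in seq_len(nrow(bins))) {
    lo <- bins$rt_min[j] - window_half_width
    hi <- bins$rt_min[j] + window_half_width
    if (lo < min(rt) || hi > max(rt)) {
      stop("window for bin ", bins$bin_id[j], " outside trace RT span",
           call. = FALSE)
    }
    sel <- which(rt >= lo & rt <= hi)
    if (length(sel) < 2L) {
      vals[, j] <- 0
    } else {
      y <- traces$traces[, sel, drop = FALSE]
      dx <- diff(rt[sel])
      vals[, j] <- as.vector((y[, -1, drop = FALSE] +
                              y[, -length(sel), drop = FALSE]) %*% dx) / 2
    }
  }
  feature_matrix(vals, samples = traces$samples, bins = bins, stage = "raw")
}
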