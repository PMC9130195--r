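#' Plot mean bin trajectories over the time course
#'
#' One panel per bin: mean intensity against incubation day per group, the
#' standard exploratory view of a binned time course.
#'
#' @param fm A [feature_matrix()].
#' @param bins Optional bin ids to show (default all).
#' @return A ggplot object.
#' @export
plot_trajectories <- function(fm, bins = NULL) {
  long <- tidy(fm)
  long <- long[long$group %in% c("B", "F"), ]
  if (!is.null(bins)) long <- long[long$bin_id %in% bins, ]
  agg <- dplyr::summarise(
    dplyr::group_by(long, .data$bin_id, .data$group, .data$day),
    intensity = mean(.data$intensity), .groups = "drop"
  )
  ggplot2::ggplot(agg, ggplot2::aes(.data$day, .data$intensity,
                                    colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~bin_id, scales = "free_y") +
    ggplot2::labs(x = "incubation day", y = "mean intensity",
                  colour = "group") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_trajectories Score plot of the first two PLS components,
#'   coloured by response value or class.
#' @param object A fitted [pls_nipals()] model.
#' @param ... Unused.
#' @export
autoplot.pls_model <- function(object, ...) {
  d <- tibble::tibble(t1 = object$T[, 1],
                      t2 = if (object$ncomp >= 2) object$T[, 2] else 0)
  if (object$multi_response) {
    cls <- object$response_names[apply(object$y, 1, which.max)]
    d$colour <- cls
    lab <- "class"
  } else {
    d$colour <- object$y[, 1]
    lab <- "y"
  }
  ggplot2::ggplot(d, ggplot2::aes(.data$t1, .data$t2,
                                  colour = .data$colour)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = sprintf("LV1 (%.1f%% X-var)", object$ssx_pct[1]),
                  y = if (object$ncomp >= 2) {
                    sprintf("LV2 (%.1f%% X-var)", object$ssx_pct[2])
                  } else "",
                  colour = lab) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_trajectories RMSEC/RMSECV against component count,
#'   with the chosen count marked.
#' @export
autoplot.cv_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object$components, c("rmsec", "rmsecv"),
                              names_to = "metric", values_to = "rmse")
  ggplot2::ggplot(long, ggplot2::aes(.data$ncomp, .data$rmse,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$ncomp, linetype = 2) +
    ggplot2::labs(x = "components", y = "RMSE") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_trajectories Null Q2 distribution of a permutation test
#'   with the true model's Q2 marked.
#' @export
autoplot.permutation_result <- function(object, ...) {
  ggplot2::ggplot(object$permutations, ggplot2::aes(.data$q2)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$q2_true, colour = "red") +
    ggplot2::labs(x = expression(Q^2), y = "permutations",
                  subtitle = sprintf("empirical p = %.4g", object$empirical_p)) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_trajectories ROC curve with the Youden-optimal point.
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::annotate("point",
                      x = 1 - object$youden$specificity,
                      y = object$youden$sensitivity, colour = "red") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  subtitle = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Heatmap of the Spearman bin-correlation matrix
#'
#' @param cm Output of [spearman_bin_correlation()].
#' @return A ggplot object.
#' @export
plot_spearman_heatmap <- function(cm) {
  d <- tibble::as_tibble(as.table(cm), .name_repair = "minimal")
  names(d) <- c("bin_a", "bin_b", "rho")
  d$bin_a <- factor(d$bin_a, levels = rownames(cm))
  d$bin_b <- factor(d$bin_b, levels = colnames(cm))
  ggplot2::ggplot(d, ggplot2::aes(.data$bin_a, .data$bin_b,
                                  fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' VIP score bar chart with the selection threshold
#'
#' @param vip A [vip_scores()] tibble (optionally with a `bin_id` column).
#' @param threshold Strict selection cutoff drawn as a dashed line.
#' @return A ggplot object.
#' @export
plot_vip <- function(vip, threshold = 1.0) {
  vip <- tibble::as_tibble(vip)
  vip$id <- if ("bin_id" %in% names(vip)) vip$bin_id else vip$variable
  vip$selected <- vip$vip > threshold
  ggplot2::ggplot(vip, ggplot2::aes(factor(.data$id), .data$vip,
                                    fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "grey60")) +
    ggplot2::labs(x = "bin", y = "VIP") +
    ggplot2::theme_minimal()
}
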