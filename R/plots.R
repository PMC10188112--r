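#' Group activity time course
#'
#' Mean delta-pixel activity per group over Zeitgeber time, binned, with a
#' ribbon of +/- SEM across wells and shaded night epochs — the standard
#' locomotor summary plot of a tracking experiment.
#'
#' @param x A [tracking_data()] object.
#' @param bin_minutes Bin width in minutes (default 10).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_activity <- function(x, bin_minutes = 10, ...) {
  stopifnot(inherits(x, "tracking_data"))
  frames_per_bin <- max(1, round_half_up(bin_minutes * 60 * x$fps))
  n_frames <- nrow(x$values)
  bin <- (seq_len(n_frames) - 1) %/% frames_per_bin
  binned <- apply(x$values, 2, function(v) {
    as.vector(tapply(v, bin, mean))
  })
  df <- as_tibble(binned) %>%
    mutate(zt = x$start_zt + (unique(bin) + 0.5) * frames_per_bin /
             (3600 * x$fps)) %>%
    pivot_longer(-"zt", names_to = "well_id", values_to = "activity") %>%
    mutate(group = x$groups[.data$well_id]) %>%
    group_by(.data$zt, .data$group) %>%
    summarise(mean = mean(.data$activity),
              sem = sd(.data$activity) / sqrt(n()), .groups = "drop")

  nights <- segment_epochs(x, use = "all") %>%
    filter(.data$label == "night") %>%
    mutate(zt_start = x$start_zt + .data$start_frame / (3600 * x$fps),
           zt_end = x$start_zt + .data$end_frame / (3600 * x$fps))

  ggplot2::ggplot(df, ggplot2::aes(.data$zt, .data$mean,
                                   color = .data$group,
                                   fill = .data$group)) +
    ggplot2::geom_rect(
      data = nights, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$zt_start, xmax = .data$zt_end,
                   ymin = -Inf, ymax = Inf),
      fill = "grey85", alpha = 0.5
    ) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.3, color = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Zeitgeber time (h)",
                  y = expression(Delta * " pixels (mean " %+-% " SEM)"),
                  color = "Group", fill = "Group") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.tracking_data <- function(object, ...) plot_activity(object, ...)

#' Fingerprint profile plot
#'
#' Mean +/- SEM Z-score per behavioral measure for one or more group
#' fingerprints, in canonical measure order with the zero line marking the
#' wild-type sibling reference.
#'
#' @param gfp One or more [group_fingerprint()] tibbles (row-bound).
#' @return A ggplot object.
#' @export
plot_fingerprint <- function(gfp) {
  ggplot2::ggplot(gfp, ggplot2::aes(.data$measure, .data$mean_z,
                                    color = .data$group,
                                    group = .data$group)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_z - .data$sem_z,
      ymax = .data$mean_z + .data$sem_z)) +
    ggplot2::labs(x = NULL, y = "Z-score (mean ± SEM)",
                  color = "Group") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Ranked drug matches plot
#'
#' Pearson correlation of the top library conditions with the query
#' fingerprint.
#'
#' @param matches A [rank_library()] result.
#' @param top_n Number of top conditions to show (default 20).
#' @return A ggplot object.
#' @export
plot_ranked_matches <- function(matches, top_n = 20) {
  df <- head(matches, top_n) %>%
    mutate(condition = factor(.data$condition, levels = rev(.data$condition)))
  ggplot2::ggplot(df, ggplot2::aes(.data$r, .data$condition)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Pearson r with query fingerprint", y = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn permutation_null Histogram of the null significant-peak
#'   counts with the observed count marked.
#' @param object A `perm_null` object.
#' @export
autoplot.perm_null <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$n_significant)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey60") +
    ggplot2::geom_vline(xintercept = object$observed, color = "red") +
    ggplot2::labs(
      x = "Significant peaks per shuffle",
      y = "Shuffles",
      title = sprintf("Observed %d, empirical p = %.3g",
                      object$observed, object$p_empirical)
    ) +
    ggplot2::theme_minimal()
}
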