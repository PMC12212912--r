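# ggplot2 displays for the main result types.

#' Plot adjusted severity-level BD means with comparison intervals
#'
#' The multiple-comparison display: one point per severity level at its
#' model-adjusted mean BD, with intervals drawn so that two levels whose
#' intervals do not overlap differ significantly under the Tukey HSD
#' criterion.
#'
#' @param object A `bd_tukey` object from [tukey_hsd()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bd_tukey
#' @export
autoplot.bd_tukey <- function(object, ...) {
  m <- object$means
  m$severity <- factor(m$severity, levels = unique(m$severity))
  ggplot2::ggplot(m, ggplot2::aes(x = .data$severity, y = .data$emmean)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$comparison_low, ymax = .data$comparison_high),
      width = 0.2, colour = "grey40"
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "Reported attack severity (0-10)",
      y = "Adjusted mean Bhattacharyya distance",
      title = "Colour change by reported severity",
      subtitle = "Non-overlapping intervals: significantly different (Tukey HSD)"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-image mean BD over time, coloured by episode
#'
#' @param object An `rp_analysis` from [analyze_folder()].
#' @param patient Optional patient id to restrict to.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rp_analysis
#' @export
autoplot.rp_analysis <- function(object, patient = NULL, ...) {
  grouped <- if (object$config$episode_mode == "window") {
    group_by_window(object$images, object$config$window_minutes)
  } else {
    object$images
  }
  if (!"episode_id" %in% names(grouped)) grouped$episode_id <- NA_character_
  if (!is.null(patient)) grouped <- grouped[grouped$patient_id == patient, ]
  ggplot2::ggplot(
    grouped,
    ggplot2::aes(x = .data$timestamp, y = .data$mean_bd,
                 colour = .data$episode_id, group = .data$episode_id)
  ) +
    ggplot2::geom_line(alpha = 0.5, na.rm = TRUE) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::facet_wrap(~patient_id, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "Image mean BD", colour = "Episode") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Scatter of episode mean BD against reported severity
#'
#' The raw (unadjusted) view of the BD-severity relationship.
#'
#' @param episodes Episode table with `mean_bd` and `severity`.
#' @return A ggplot.
#' @export
plot_bd_severity <- function(episodes) {
  dat <- episodes[!is.na(episodes$severity), , drop = FALSE]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$severity, y = .data$mean_bd)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.6) +
    ggplot2::labs(x = "Reported attack severity (0-10)",
                  y = "Episode mean Bhattacharyya distance") +
    ggplot2::theme_minimal()
}
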