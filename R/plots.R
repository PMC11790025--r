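#' Plot ROI fluorescence traces
#'
#' Line plot of selected ROI traces over time, optionally annotating
#' detected event onsets and the detection threshold.
#'
#' @param traces A `ca_traces` tibble.
#' @param rois ROIs to show (default: the 6 most active by variance).
#' @param events Optional `ca_events` tibble; onsets are marked.
#' @param baseline Optional baseline tibble; F0 and the 10-SD threshold are
#'   drawn as horizontal lines.
#' @param threshold_k Threshold multiple used for the threshold line.
#' @return A ggplot object.
#' @export
plot_traces <- function(traces, rois = NULL, events = NULL,
                        baseline = NULL, threshold_k = 10) {
  if (is.null(rois)) {
    v <- dplyr::summarise(dplyr::group_by(traces, .data$roi),
                          v = stats::var(.data$f), .groups = "drop")
    rois <- v$roi[order(-v$v)][seq_len(min(6, nrow(v)))]
  }
  d <- traces[traces$roi %in% rois, ]
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$time_s, .data$f)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~roi, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time (s)", y = "mean ROI fluorescence (AU)") +
    ggplot2::theme_minimal()
  if (!is.null(baseline)) {
    b <- baseline[baseline$roi %in% rois, ]
    b$thr <- b$f0 + threshold_k * b$sigma
    p <- p +
      ggplot2::geom_hline(data = b, ggplot2::aes(yintercept = .data$f0),
                          linetype = 2, colour = "grey50") +
      ggplot2::geom_hline(data = b, ggplot2::aes(yintercept = .data$thr),
                          linetype = 3, colour = "red")
  }
  if (!is.null(events)) {
    e <- events[events$roi %in% rois, ]
    p <- p + ggplot2::geom_vline(
      data = e, ggplot2::aes(xintercept = .data$onset_s),
      colour = "steelblue", alpha = 0.5
    )
  }
  p
}

#' @export
autoplot.ca_traces <- function(object, ...) plot_traces(object, ...)

#' Plot the lag-distance relation of detected waves
#'
#' Scatter of member onset lag against distance from the wave origin, with
#' the origin-constrained fit line whose inverse slope is the wave speed.
#'
#' @param waves A `ca_waves` tibble from [cluster_waves()].
#' @param wave_ids Waves to show (default: up to 9).
#' @return A ggplot object.
#' @export
plot_wave_fit <- function(waves, wave_ids = NULL) {
  if (is.null(wave_ids)) {
    wave_ids <- waves$wave_id[seq_len(min(9, nrow(waves)))]
  }
  w <- waves[waves$wave_id %in% wave_ids, ]
  mem <- dplyr::bind_rows(lapply(seq_len(nrow(w)), function(i) {
    m <- w$members[[i]]
    m$wave_id <- w$wave_id[i]
    m$speed <- w$speed_um_s[i]
    m
  }))
  ggplot2::ggplot(mem, ggplot2::aes(.data$distance_um, .data$lag_s)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      data = w[w$speed_defined, ],
      ggplot2::aes(intercept = 0, slope = 1 / .data$speed_um_s),
      colour = "red"
    ) +
    ggplot2::facet_wrap(~wave_id, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "distance from origin (um)", y = "onset lag (s)") +
    ggplot2::theme_minimal()
}

#' Plot normalized expression folds by group
#'
#' Per-gene jittered points with group mean and SEM bars, on the
#' fold-vs-control scale (control averages 1).
#'
#' @param folds Output of [fold_vs_control()].
#' @return A ggplot object.
#' @export
plot_expression <- function(folds) {
  summ <- dplyr::summarise(
    dplyr::group_by(folds, .data$gene, .data$group),
    mean = mean(.data$fold),
    sem = stats::sd(.data$fold) / sqrt(dplyr::n()), .groups = "drop"
  )
  ggplot2::ggplot(folds, ggplot2::aes(.data$group, .data$fold)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    ggplot2::geom_pointrange(
      data = summ,
      ggplot2::aes(y = .data$mean, ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      colour = "red", linewidth = 0.6
    ) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::facet_wrap(~gene, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "fold vs control (2^-dCt)") +
    ggplot2::theme_minimal()
}
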