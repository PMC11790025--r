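#' Steady-state fluorescence over a fixed window
#'
#' The steady-state cytosolic Ca2+ level of a recording is summarised as the
#' arithmetic mean of the raw trace over a fixed window (300 s by default),
#' per ROI.
#'
#' @param traces A `ca_traces` tibble.
#' @param window_start Window start time in seconds (default 0).
#' @param params A [detection_params()]; `steady_state_window` sets the
#'   window length in seconds.
#' @return A tibble with `roi`, `steady_state_f`, `window_start`,
#'   `window_s`.
#' @export
steady_state <- function(traces, window_start = 0,
                         params = detection_params()) {
  dt <- trace_dt(traces)
  w <- params$steady_state_window
  if (w < dt) stop("steady-state window shorter than one frame", call. = FALSE)
  t_end <- max(traces$time_s) + dt
  if (window_start < 0 || window_start + w > t_end + 1e-9) {
    stop("steady-state window does not fit in the recording", call. = FALSE)
  }
  sel <- traces$time_s >= window_start & traces$time_s < window_start + w
  out <- dplyr::summarise(
    dplyr::group_by(traces[sel, ], .data$roi),
    steady_state_f = mean(.data$f), .groups = "drop"
  )
  out$window_start <- window_start
  out$window_s <- w
  out
}

#' Event rate per second, overall or by region
#'
#' Peak activity of a recording is reported as events per second over the
#' recording duration. When a region map is supplied (e.g. inner sulcus /
#' hair-cell region / outer sulcus), rates are reported per region; rates
#' over disjoint regions sum to the all-field rate.
#'
#' @param events A `ca_events` tibble (or any tibble with `roi`, `onset_s`).
#' @param duration Recording duration in seconds; defaults to the events'
#'   `duration` attribute.
#' @param regions Optional tibble mapping `roi` to a `region` label; events
#'   in unmapped ROIs are labelled `"all"`.
#' @return A tibble with `region`, `n_events`, `duration_s`, `peaks_per_s`.
#' @export
peak_rate <- function(events, duration = NULL, regions = NULL) {
  duration <- duration %||% attr(events, "duration")
  if (is.null(duration) || duration <= 0) {
    stop("`duration` must be a positive number of seconds", call. = FALSE)
  }
  if (is.null(regions)) {
    return(tibble::tibble(
      region = "all", n_events = nrow(events), duration_s = duration,
      peaks_per_s = nrow(events) / duration
    ))
  }
  lab <- regions$region[match(events$roi, regions$roi)]
  lab[is.na(lab)] <- "all"
  counts <- table(factor(lab, levels = unique(regions$region)))
  tibble::tibble(
    region = names(counts), n_events = as.integer(counts),
    duration_s = duration,
    peaks_per_s = as.integer(counts) / duration
  )
}

#' Wave rate per second
#'
#' @param waves A wave table from [cluster_waves()] (or any tibble with one
#'   row per wave and a `start_s` column).
#' @param duration Recording duration in seconds.
#' @return A tibble with `n_waves`, `duration_s`, `waves_per_s`.
#' @export
wave_rate <- function(waves, duration) {
  assert_scalar_num(duration, "duration", min = 0, strict = TRUE)
  n <- sum(waves$start_s >= 0 & waves$start_s <= duration)
  tibble::tibble(n_waves = n, duration_s = duration,
                 waves_per_s = n / duration)
}
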