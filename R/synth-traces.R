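# Event waveform shared by trace- and movie-level generation: linear rise
# from 0 to `amplitude` over `rise`, then exponential decay exp(-t/tau).
event_waveform <- function(t_rel, amplitude, rise, tau) {
  out <- numeric(length(t_rel))
  if (rise > 0) {
    up <- t_rel >= 0 & t_rel < rise
    out[up] <- amplitude * t_rel[up] / rise
  }
  dn <- t_rel >= rise
  out[dn] <- amplitude * exp(-(t_rel[dn] - rise) / tau)
  out
}

# amplitude unit: noise_sd when positive, otherwise 1 intensity unit so that
# noiseless configs still carry visible events
amp_unit <- function(config) if (config$noise_sd > 0) config$noise_sd else 1

# Resolve the cell table against the implied grid: ids, ROI assignment and
# per-cell overrides.
resolve_cells <- function(config, grid) {
  cells <- config$cells
  if (is.null(cells) || nrow(cells) == 0) {
    return(tibble::tibble(
      cell_id = integer(), x_um = numeric(), y_um = numeric(),
      class = character(), roi = integer(), rate = numeric(),
      n_events = integer(), slow = logical()
    ))
  }
  cells$cell_id <- seq_len(nrow(cells))
  cells$roi <- roi_at(grid, cells$x_um, cells$y_um)
  if (anyNA(cells$roi)) {
    stop("every cell must fall inside an ROI of the implied grid",
         call. = FALSE)
  }
  if (!"rate" %in% names(cells)) cells$rate <- config$transient_rate
  cells$rate[is.na(cells$rate)] <- config$transient_rate
  if (!"n_events" %in% names(cells)) cells$n_events <- NA_integer_
  if (!"slow" %in% names(cells)) cells$slow <- NA
  cells
}

# Draw the ground-truth event and wave tables for a config. Substream ids:
# ROI noise = roi, spontaneous events = 1e7 + cell, slow selection = 2e7,
# slow onsets = 2e7 + cell, wave site times = 3e7 + site, movie pixel noise
# = 4e7 + frame.
synth_truth <- function(config, grid, cells) {
  amp <- config$transient_amplitude * amp_unit(config)
  ev <- list()

  # spontaneous fast transients, one substream per cell; an explicit
  # per-cell `event_times` list overrides the Poisson draw entirely
  has_times <- "event_times" %in% names(cells)
  for (i in seq_len(nrow(cells))) {
    cl <- cells[i, ]
    fixed <- if (has_times) cells$event_times[[i]] else NULL
    n <- if (!is.null(fixed)) {
      as.numeric(fixed)
    } else {
      with_substream(config$seed, 1e7 + cl$cell_id, {
        k <- if (!is.na(cl$n_events)) cl$n_events else
          stats::rpois(1, cl$rate * config$duration)
        if (k > 0) stats::runif(k, 0, config$duration) else numeric()
      })
    }
    if (length(n)) {
      ev[[length(ev) + 1L]] <- tibble::tibble(
        cell_id = cl$cell_id, roi = cl$roi, class = cl$class,
        type = "spont", onset_s = sort(n), amplitude = amp,
        rise_duration = config$rise_duration, decay_tau = config$decay_tau,
        wave_id = NA_integer_
      )
    }
  }

  # slow transients: explicit per-cell flag, else a slow_fraction draw
  # among OHCs (rounded count, sampled under a dedicated substream)
  slow_ids <- cells$cell_id[which(cells$slow)]
  if (all(is.na(cells$slow)) && config$slow_fraction > 0) {
    ohc <- cells$cell_id[cells$class == "OHC"]
    k <- round(config$slow_fraction * length(ohc))
    if (k > 0) {
      slow_ids <- with_substream(config$seed, 2e7,
        sort(sample(ohc, k)))
    }
  }
  for (cid in slow_ids) {
    cl <- cells[cells$cell_id == cid, ]
    onset <- with_substream(config$seed, 2e7 + cid,
      stats::runif(1, 0.1, 0.4) * config$duration)
    ev[[length(ev) + 1L]] <- tibble::tibble(
      cell_id = cid, roi = cl$roi, class = cl$class, type = "slow",
      onset_s = onset, amplitude = amp,
      rise_duration = config$slow_rise_duration,
      decay_tau = config$slow_tau, wave_id = NA_integer_
    )
  }

  # intercellular waves: Poisson initiations per site; members are all
  # cells within wave_radius, activated at start + distance/speed
  waves <- tibble::tibble(
    wave_id = integer(), site = integer(), origin_x_um = numeric(),
    origin_y_um = numeric(), start_s = numeric(), speed_um_s = numeric(),
    radius_um = numeric(), members = list()
  )
  sites <- config$wave_sites
  if (!is.null(sites) && nrow(sites) > 0 && config$wave_site_rate > 0 &&
        nrow(cells) > 0) {
    wid <- 0L
    wrows <- list()
    for (s in seq_len(nrow(sites))) {
      starts <- with_substream(config$seed, 3e7 + s, {
        k <- stats::rpois(1, config$wave_site_rate * config$duration)
        if (k > 0) sort(stats::runif(k, 0, config$duration)) else numeric()
      })
      if (!length(starts)) next
      d <- sqrt((cells$x_um - sites$x_um[s])^2 +
                  (cells$y_um - sites$y_um[s])^2)
      in_range <- which(d <= config$wave_radius)
      if (!length(in_range)) next
      for (t0 in starts) {
        wid <- wid + 1L
        act <- t0 + d[in_range] / config$wave_speed
        keep <- act <= config$duration
        members <- tibble::tibble(
          cell_id = cells$cell_id[in_range][keep],
          roi = cells$roi[in_range][keep],
          distance_um = d[in_range][keep],
          activation_s = act[keep]
        )
        wrows[[wid]] <- tibble::tibble(
          wave_id = wid, site = s, origin_x_um = sites$x_um[s],
          origin_y_um = sites$y_um[s], start_s = t0,
          speed_um_s = config$wave_speed, radius_um = config$wave_radius,
          members = list(members)
        )
        if (nrow(members)) {
          ev[[length(ev) + 1L]] <- tibble::tibble(
            cell_id = members$cell_id, roi = members$roi,
            class = cells$class[match(members$cell_id, cells$cell_id)],
            type = "wave", onset_s = members$activation_s, amplitude = amp,
            rise_duration = config$rise_duration,
            decay_tau = config$decay_tau, wave_id = wid
          )
        }
      }
    }
    if (length(wrows)) waves <- dplyr::bind_rows(wrows)
  }

  events <- if (length(ev)) dplyr::bind_rows(ev) else tibble::tibble(
    cell_id = integer(), roi = integer(), class = character(),
    type = character(), onset_s = numeric(), amplitude = numeric(),
    rise_duration = numeric(), decay_tau = numeric(), wave_id = integer()
  )
  events <- dplyr::arrange(events, .data$onset_s, .data$cell_id)
  list(events = events, waves = waves)
}

#' Generate a synthetic ROI trace table with exact ground truth
#'
#' Simulates the ROI-by-frame fluorescence table of a recording directly
#' (without rendering pixels): each trace is `baseline_level` plus i.i.d.
#' Gaussian noise plus the waveforms of the cell's events. Wave members are
#' activated exactly at `start + distance(origin, cell) / speed`, which
#' makes the table an oracle for detector and wave-clustering validation.
#'
#' @param config A [synth_config()].
#' @return A list of class `synth_recording` with elements `traces` (a
#'   `ca_traces` tibble covering every ROI of the implied grid), `events`
#'   and `waves` (ground-truth tibbles; `waves$members` is a list-column of
#'   member activations), `grid`, and `config`.
#' @export
#' @examples
#' cfg <- synth_config(168, 56, duration = 60,
#'                     cells = cell_grid(168, 56), transient_rate = 0.05)
#' rec <- generate_traces(cfg)
#' head(rec$events)
generate_traces <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  grid <- roi_grid(config$field_width_px, config$field_height_px,
                   config$roi_size_px, config$pixel_size)
  cells <- resolve_cells(config, grid)
  truth <- synth_truth(config, grid, cells)

  n_frames <- floor(config$duration / config$frame_interval)
  tt <- (seq_len(n_frames) - 1) * config$frame_interval
  m <- matrix(config$baseline_level, nrow(grid), n_frames)
  if (config$noise_sd > 0) {
    for (r in seq_len(nrow(grid))) {
      m[r, ] <- m[r, ] +
        with_substream(config$seed, r,
                       stats::rnorm(n_frames, 0, config$noise_sd))
    }
  }
  ev <- truth$events
  for (i in seq_len(nrow(ev))) {
    m[ev$roi[i], ] <- m[ev$roi[i], ] + event_waveform(
      tt - ev$onset_s[i], ev$amplitude[i], ev$rise_duration[i],
      ev$decay_tau[i]
    )
  }
  structure(
    list(traces = traces_from_matrix(m, config$frame_interval, grid),
         events = truth$events, waves = truth$waves,
         grid = grid, config = config),
    class = "synth_recording"
  )
}

#' @export
print.synth_recording <- function(x, ...) {
  n_frames <- if (!is.null(x$traces)) attr(x$traces, "n_frames") else
    dim(x$movie$frames)[1]
  cat(sprintf(
    "<synth_recording> %d ROIs x %d frames, %d ground-truth events, %d waves\n",
    nrow(x$grid), n_frames, nrow(x$events), nrow(x$waves)
  ))
  invisible(x)
}
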