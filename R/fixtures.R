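#' Canonical validation fixtures
#'
#' These constructors encode the package's standard validation scenarios as
#' code, so tests, scripts and examples exercise identical study
#' conditions: noiseless wave chains for exact speed recovery, Poisson wave
#' and transient fields for rate recovery, long-decay traces for kinetics
#' recovery, and the 80-hair-cell field with known fast/slow composition
#' for the classifier.
#'
#' @name fixtures
NULL

#' Noiseless wave chains with exact lag-distance structure
#'
#' Builds `n_waves` chains of events on a single-row ROI grid: each chain
#' activates `n_members` adjacent ROIs at the grid pitch (11 um by default)
#' with a fixed onset lag per step, so the generating speed is
#' `pitch / lag_s` exactly. Successive chains are separated in time so they
#' cluster independently.
#'
#' @param n_waves Number of chains.
#' @param n_members ROIs per chain.
#' @param lag_s Onset lag per 11-um step, seconds.
#' @param spacing_s Time between chain starts (default 100 s, far beyond
#'   any linking window).
#' @param roi_size_px,pixel_size Grid geometry (defaults 56 px, 11/56
#'   um/px).
#' @return A list with `events` (tibble `roi`, `onset_s`) and `grid`.
#' @export
sim_wave_chains <- function(n_waves, n_members, lag_s, spacing_s = 100,
                            roi_size_px = 56, pixel_size = 11 / 56) {
  grid <- roi_grid(n_members * roi_size_px, roi_size_px, roi_size_px,
                   pixel_size)
  ev <- dplyr::bind_rows(lapply(seq_len(n_waves), function(w) {
    tibble::tibble(
      roi = seq_len(n_members),
      onset_s = (w - 1) * spacing_s + (seq_len(n_members) - 1) * lag_s
    )
  }))
  list(events = ev, grid = grid)
}

#' Poisson wave-field configuration
#'
#' Initiation sites on a 110-um lattice (10 ROI pitches apart, so waves of
#' up to 44-um radius from neighbouring sites can never link), a confluent
#' supporting-cell sheet on the ROI lattice, and Poisson initiations per
#' site. The organ-level expected wave rate is `n_sites x site_rate`.
#'
#' @param n_sites Number of initiation sites.
#' @param site_rate Per-site Poisson initiation rate, events/s.
#' @param duration Recording length, s.
#' @param wave_speed Propagation speed, um/s.
#' @param wave_radius Wave extent, um (default 44).
#' @param seed RNG seed.
#' @return A [synth_config()].
#' @export
sim_wave_field_config <- function(n_sites, site_rate, duration, wave_speed,
                                  wave_radius = 44, seed = 1L) {
  ns_x <- ceiling(sqrt(n_sites))
  ns_y <- ceiling(n_sites / ns_x)
  width_px <- ns_x * 10L * 56L
  height_px <- ns_y * 10L * 56L
  grid <- roi_grid(width_px, height_px)
  nx <- ns_x * 10L
  bx <- rep(seq_len(ns_x) - 1L, times = ns_y)[seq_len(n_sites)]
  by <- rep(seq_len(ns_y) - 1L, each = ns_x)[seq_len(n_sites)]
  site_roi <- (by * 10L + 5L) * nx + bx * 10L + 6L
  sites <- tibble::tibble(
    x_um = grid$cx_um[site_roi], y_um = grid$cy_um[site_roi]
  )
  synth_config(
    width_px, height_px, duration = duration,
    cells = cell_grid(width_px, height_px),
    wave_sites = sites, wave_site_rate = site_rate,
    wave_speed = wave_speed, wave_radius = wave_radius, seed = seed
  )
}

#' Spontaneously active transient-field configuration
#'
#' `n_active` cells on the ROI lattice of a near-square field, each firing
#' spontaneous transients as an independent Poisson process. The field-level
#' expected peak rate is `n_active x rate`.
#'
#' @param n_active Number of active cells.
#' @param rate Per-cell transient rate, events/s.
#' @param duration Recording length, s.
#' @param decay_tau Transient decay constant, s (default 2).
#' @param transient_amplitude Amplitude in baseline-SD multiples
#'   (default 20).
#' @param seed RNG seed.
#' @return A [synth_config()].
#' @export
sim_active_field_config <- function(n_active, rate, duration,
                                    decay_tau = 2, transient_amplitude = 20,
                                    seed = 1L) {
  n_side <- ceiling(sqrt(n_active))
  width_px <- n_side * 56L
  cells <- cell_grid(width_px, width_px)[seq_len(n_active), ]
  synth_config(
    width_px, width_px, duration = duration, cells = cells,
    transient_rate = rate, transient_amplitude = transient_amplitude,
    decay_tau = decay_tau, seed = seed
  )
}

#' Long-record traces each carrying one planted transient
#'
#' One ROI trace per row: Gaussian baseline noise plus a single transient
#' (linear 1-s rise to `amplitude` baseline SDs, exponential decay) planted
#' at `onset`. Records are kept long relative to the decay so the robust
#' baseline is essentially uncontaminated by the decay tail.
#'
#' @param n_traces Number of traces.
#' @param decay_tau Decay constant, s.
#' @param duration Record length, s.
#' @param onset Transient onset, s.
#' @param frame_interval Sampling interval, s (default 0.1).
#' @param amplitude Amplitude in noise-SD multiples (default 100).
#' @param noise_sd Baseline noise SD (default 1).
#' @param rise_duration Rise time, s (default 1).
#' @param seed RNG seed.
#' @return A list with `traces` (a `ca_traces` tibble, one ROI per planted
#'   transient) and `truth` (tibble `roi`, `onset_s`).
#' @export
sim_decay_traces <- function(n_traces, decay_tau, duration, onset,
                             frame_interval = 0.1, amplitude = 100,
                             noise_sd = 1, rise_duration = 1, seed = 1L) {
  n_frames <- floor(duration / frame_interval)
  tt <- (seq_len(n_frames) - 1) * frame_interval
  wf <- event_waveform(tt - onset, amplitude * noise_sd, rise_duration,
                       decay_tau)
  m <- matrix(NA_real_, n_traces, n_frames)
  for (i in seq_len(n_traces)) {
    m[i, ] <- 100 + wf +
      with_substream(seed, 5e7 + i, stats::rnorm(n_frames, 0, noise_sd))
  }
  list(
    traces = traces_from_matrix(m, frame_interval),
    truth = tibble::tibble(roi = seq_len(n_traces), onset_s = onset)
  )
}

#' The 80-hair-cell classification field
#'
#' An OHC field with a known fast/slow composition: `n_fast` cells carry a
#' single fast transient (no morphological change), `n_slow` cells carry a
#' slow transient with swelling and fragmentation, and the remaining cells
#' are silent. With the defaults (7 fast, 13 slow, 80 cells) the expected
#' prevalences are 8.8% and 16.3%.
#'
#' @param n_fast,n_slow,n_cells Composition (defaults 7, 13, 80).
#' @param duration Recording length, s (default 400; long enough that the
#'   slow transient decays within the record).
#' @param fast_onset Onset of the fast transients, s.
#' @param seed RNG seed.
#' @return A [synth_config()] for [generate_movie()].
#' @export
sim_hair_cell_field_config <- function(n_fast = 7, n_slow = 13,
                                       n_cells = 80, duration = 400,
                                       fast_onset = 150, seed = 42L) {
  stopifnot(n_fast + n_slow <= n_cells)
  nx <- ceiling(n_cells / 5) # 16 x 5 ROI layout for the default 80 cells
  cells <- cell_grid(nx * 56L, 5L * 56L, class = "OHC")[seq_len(n_cells), ]
  cells$n_events <- 0L
  cells$event_times <- vector("list", n_cells)
  cells$slow <- FALSE
  for (i in seq_len(n_fast)) cells$event_times[[i]] <- fast_onset
  if (n_slow > 0) cells$slow[n_fast + seq_len(n_slow)] <- TRUE
  synth_config(nx * 56L, 5L * 56L, duration = duration, cells = cells,
               seed = seed)
}
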