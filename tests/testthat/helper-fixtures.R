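# shared helpers for building tiny traces and movies in tests

# a ca_traces table from a single numeric vector
one_trace <- function(f, dt = 1) {
  traces_from_matrix_test(matrix(f, nrow = 1), dt)
}

# thin wrapper so tests do not depend on the internal name
traces_from_matrix_test <- function(m, dt) {
  n_rois <- nrow(m); n_frames <- ncol(m)
  frame <- rep(seq_len(n_frames) - 1L, times = n_rois)
  tr <- tibble::tibble(
    roi = rep(seq_len(n_rois), each = n_frames),
    frame = frame, time_s = frame * dt, f = as.vector(t(m))
  )
  structure(tr, frame_interval = dt, n_frames = n_frames, grid = NULL,
            class = c("ca_traces", class(tr)))
}

# known baseline for noiseless detection tests
flat_baseline <- function(rois, f0 = 100, sigma = 1) {
  tibble::tibble(roi = as.integer(rois), f0 = f0, sigma = sigma,
                 n_baseline = 100L, fallback = FALSE)
}

# a trace carrying one transient: linear rise + exponential decay on a
# constant baseline (no noise unless noise_sd > 0)
planted_trace <- function(amp, rise = 2, tau = 4, onset = 40, dur = 120,
                          dt = 2, f0 = 100, noise_sd = 0, seed = NULL) {
  tt <- seq(0, dur - dt, by = dt)
  f <- rep(f0, length(tt))
  up <- tt >= onset & tt < onset + rise
  f[up] <- f0 + amp * (tt[up] - onset) / rise
  dn <- tt >= onset + rise
  f[dn] <- f0 + amp * exp(-(tt[dn] - onset - rise) / tau)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    f <- f + rnorm(length(f), 0, noise_sd)
  }
  one_trace(f, dt)
}

# independent waveform oracle: linear rise then exponential decay
event_waveform_test <- function(t_rel, amp, rise, tau) {
  out <- numeric(length(t_rel))
  up <- t_rel >= 0 & t_rel < rise
  out[up] <- amp * t_rel[up] / rise
  dn <- t_rel >= rise
  out[dn] <- amp * exp(-(t_rel[dn] - rise) / tau)
  out
}

# small movie with one centered disk cell
one_cell_movie_config <- function(duration = 100, slow = FALSE,
                                  swell_factor = 1.5, seed = 3L) {
  cells <- tibble::tibble(x_um = 5.5, y_um = 5.5, class = "OHC",
                          n_events = 0L, slow = slow)
  if (!slow) {
    cells$event_times <- list(40)
  }
  synth_config(56, 56, duration = duration, cells = cells,
               swell_factor = swell_factor, seed = seed)
}
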