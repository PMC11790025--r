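# Upward/downward threshold crossing times around a supra-threshold run.
# `s`/`e` are the first/last above-threshold sample indices (1-based),
# `tt` the frame times.
cross_up <- function(f, tt, s, thr, dt, interp) {
  if (s == 1L) return(tt[1])
  if (!interp) return(tt[s])
  tt[s - 1] + dt * (thr - f[s - 1]) / (f[s] - f[s - 1])
}
cross_down <- function(f, tt, e, thr, dt, interp) {
  if (e == length(f)) return(NA_real_)
  if (!interp) return(tt[e + 1])
  tt[e] + dt * (f[e] - thr) / (f[e] - f[e + 1])
}

# Detect events on one trace. Returns a data.frame of merged supra-threshold
# excursions with interpolated onset and decay-crossing times.
detect_one <- function(f, dt, f0, sigma, params) {
  n <- length(f)
  tt <- (seq_len(n) - 1) * dt
  thr <- f0 + params$threshold_k * sigma
  if (sigma == 0) {
    if (length(unique(f)) > 1L) {
      stop("degenerate baseline: sigma = 0 on a non-constant trace",
           call. = FALSE)
    }
    return(NULL)
  }
  above <- f > thr
  if (!any(above)) return(NULL)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  s_idx <- starts[r$values]
  e_idx <- ends[r$values]
  interp <- params$interpolate_crossings
  min_sep <- resolve_min_separation(params, dt)
  on_t <- vapply(s_idx, function(s) cross_up(f, tt, s, thr, dt, interp), 0)
  off_t <- vapply(e_idx, function(e) cross_down(f, tt, e, thr, dt, interp), 0)

  # merge excursions whose onsets are closer than min_separation
  # (chained over consecutive excursions)
  grp <- if (length(on_t) > 1) {
    cumsum(c(1L, as.integer(diff(on_t) >= min_sep)))
  } else 1L
  out <- lapply(split(seq_along(s_idx), grp), function(ii) {
    s <- s_idx[ii[1]]
    e <- e_idx[ii[length(ii)]]
    pk <- s - 1L + which.max(f[s:e])
    data.frame(
      onset_s = on_t[ii[1]], peak_s = tt[pk],
      amplitude = f[pk] - f0, amp_ratio = (f[pk] - f0) / sigma,
      complete = !is.na(off_t[ii[length(ii)]]),
      end_s = if (is.na(off_t[ii[length(ii)]])) tt[n] else
        off_t[ii[length(ii)]],
      onset_idx = s, peak_idx = pk, end_idx = e
    )
  })
  do.call(rbind, out)
}

#' Detect Ca2+ transients as supra-threshold excursions
#'
#' A Ca2+ peak is a maximal contiguous excursion of the trace above
#' `F0 + threshold_k x sigma` (default 10 baseline SDs). Excursions whose
#' onsets are closer than `min_separation` merge into one event, so a noise
#' dip at the threshold boundary does not double-count a transient.
#' Onset and decay-crossing times are linearly interpolated between the
#' bracketing frames. Events still above threshold at the end of the
#' recording are kept with `complete = FALSE`.
#'
#' @param traces A `ca_traces` tibble.
#' @param baseline Per-ROI baseline statistics from [estimate_baseline()];
#'   computed on the fly when `NULL`.
#' @param params A [detection_params()].
#' @return A tibble of class `ca_events`, one row per detected event:
#'   `roi`, `onset_s`, `peak_s`, `amplitude` (F_max - F0), `amp_ratio`
#'   (amplitude / sigma), `complete`, `end_s` (decay crossing, or last frame
#'   time if incomplete) plus frame indices `onset_idx`, `peak_idx`,
#'   `end_idx`. Attributes: `duration`, `frame_interval`, `params`.
#' @seealso [peak_kinetics()] to add rise/decay times, [detect_events()] for
#'   the combined call.
#' @export
detect_peaks <- function(traces, baseline = NULL,
                         params = detection_params()) {
  m <- trace_matrix(traces)
  dt <- trace_dt(traces)
  if (is.null(baseline)) baseline <- estimate_baseline(traces, params)
  rois <- as.integer(rownames(m))
  bl <- baseline[match(rois, baseline$roi), ]
  out <- vector("list", length(rois))
  for (i in seq_along(rois)) {
    thr <- bl$f0[i] + params$threshold_k * bl$sigma[i]
    if (bl$sigma[i] > 0 && !any(m[i, ] > thr)) next
    ev <- detect_one(m[i, ], dt, bl$f0[i], bl$sigma[i], params)
    if (!is.null(ev) && nrow(ev)) {
      ev$roi <- rois[i]
      out[[i]] <- ev
    }
  }
  ev <- dplyr::bind_rows(out)
  if (!nrow(ev)) {
    ev <- tibble::tibble(
      roi = integer(), onset_s = numeric(), peak_s = numeric(),
      amplitude = numeric(), amp_ratio = numeric(), complete = logical(),
      end_s = numeric(), onset_idx = integer(), peak_idx = integer(),
      end_idx = integer()
    )
  } else {
    ev <- tibble::as_tibble(ev[, c(
      "roi", "onset_s", "peak_s", "amplitude", "amp_ratio", "complete",
      "end_s", "onset_idx", "peak_idx", "end_idx"
    )])
    ev <- dplyr::arrange(ev, .data$onset_s, .data$roi)
  }
  structure(ev,
    duration = trace_duration(traces), frame_interval = dt, params = params,
    class = c("ca_events", class(ev))
  )
}

#' Rise and decay kinetics of detected events
#'
#' Rise time is the onset-side time from baseline to half-maximum: the
#' interval between the last interpolated upward crossing of `F0` before the
#' peak and the interpolated crossing of `F0 + amplitude / 2` on the rising
#' limb. Decay time is the interval from the peak to the event's decay
#' crossing, i.e. the interpolated downward crossing of the detection
#' threshold `F0 + threshold_k x sigma` that ends the event (dip-merged per
#' `min_separation`); using the detection threshold as the return-to-baseline
#' criterion keeps onset and offset symmetric and closed-form testable.
#' Events that never return below threshold get a censored decay time (time
#' to the end of the recording, `decay_censored = TRUE`); censored decays
#' should be excluded from mean-decay summaries.
#'
#' @param traces A `ca_traces` tibble.
#' @param events Events from [detect_peaks()].
#' @param baseline Baseline statistics (recomputed when `NULL`).
#' @param params A [detection_params()].
#' @return `events` with columns `rise_s`, `decay_s`, `decay_censored`
#'   added.
#' @export
peak_kinetics <- function(traces, events, baseline = NULL,
                          params = detection_params()) {
  m <- trace_matrix(traces)
  dt <- trace_dt(traces)
  if (is.null(baseline)) baseline <- estimate_baseline(traces, params)
  rois <- as.integer(rownames(m))
  interp <- params$interpolate_crossings
  rise <- decay <- rep(NA_real_, nrow(events))
  cens <- rep(FALSE, nrow(events))
  for (i in seq_len(nrow(events))) {
    ri <- match(events$roi[i], rois)
    f <- m[ri, ]
    n <- length(f)
    tt <- (seq_len(n) - 1) * dt
    f0 <- baseline$f0[baseline$roi == events$roi[i]][1]
    pk <- events$peak_idx[i]
    half <- f0 + events$amplitude[i] / 2

    # last upward crossing of F0 on the rising limb
    below <- which(f[seq_len(pk)] <= f0)
    if (length(below)) {
      j <- max(below)
      t_f0 <- if (j == pk) tt[j] else if (interp) {
        tt[j] + dt * (f0 - f[j]) / (f[j + 1] - f[j])
      } else tt[j + 1]
      start_j <- j
    } else {
      t_f0 <- tt[1]
      start_j <- 1L
    }
    # first crossing of half-maximum between there and the peak
    seg <- start_j:pk
    ab <- seg[f[seg] >= half]
    if (length(ab)) {
      j <- ab[1]
      t_half <- if (j == start_j || j == 1L) tt[j] else if (interp) {
        tt[j - 1] + dt * (half - f[j - 1]) / (f[j] - f[j - 1])
      } else tt[j]
    } else {
      t_half <- tt[pk]
    }
    rise[i] <- t_half - t_f0

    decay[i] <- events$end_s[i] - events$peak_s[i]
    cens[i] <- !events$complete[i]
  }
  events$rise_s <- rise
  events$decay_s <- decay
  events$decay_censored <- cens
  events
}

#' Detect events and measure their kinetics in one call
#'
#' @inheritParams peak_kinetics
#' @return A `ca_events` tibble with detection and kinetics columns.
#' @export
detect_events <- function(traces, baseline = NULL,
                          params = detection_params()) {
  if (is.null(baseline)) baseline <- estimate_baseline(traces, params)
  ev <- detect_peaks(traces, baseline, params)
  at <- attributes(ev)
  ev <- peak_kinetics(traces, ev, baseline, params)
  attr(ev, "duration") <- at$duration
  attr(ev, "frame_interval") <- at$frame_interval
  attr(ev, "params") <- at$params
  ev
}

#' Match detected events against ground truth
#'
#' Greedy one-to-one matching within each ROI: a detected event matches the
#' nearest unmatched ground-truth event whose onset differs by at most
#' `tol_s`. Used to score detector recall and precision on synthetic
#' recordings.
#'
#' @param detected Events from [detect_peaks()] / [detect_events()].
#' @param truth Ground-truth events (a tibble with `roi`, `onset_s`).
#' @param tol_s Onset tolerance in seconds.
#' @return A list with `recall`, `precision`, and the `matches` tibble
#'   (`truth_idx`, `det_idx`, `dt_onset`).
#' @export
match_events <- function(detected, truth, tol_s) {
  matches <- list()
  used <- rep(FALSE, nrow(detected))
  for (i in seq_len(nrow(truth))) {
    cand <- which(!used & detected$roi == truth$roi[i] &
                    abs(detected$onset_s - truth$onset_s[i]) <= tol_s)
    if (length(cand)) {
      j <- cand[which.min(abs(detected$onset_s[cand] - truth$onset_s[i]))]
      used[j] <- TRUE
      matches[[length(matches) + 1L]] <- tibble::tibble(
        truth_idx = i, det_idx = j,
        dt_onset = detected$onset_s[j] - truth$onset_s[i]
      )
    }
  }
  matches <- if (length(matches)) dplyr::bind_rows(matches) else
    tibble::tibble(truth_idx = integer(), det_idx = integer(),
                   dt_onset = numeric())
  list(
    recall = if (nrow(truth)) nrow(matches) / nrow(truth) else NA_real_,
    precision = if (nrow(detected)) nrow(matches) / nrow(detected) else
      NA_real_,
    matches = matches
  )
}
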