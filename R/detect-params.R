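#' Peak-detection parameters
#'
#' Collects the tunable constants of the transient detector. The detection
#' threshold is `threshold_k` baseline standard deviations above baseline
#' (default 10, the conventional cutoff for GCaMP ROI traces); the baseline
#' and its SD are estimated robustly per ROI (see [estimate_baseline()]).
#'
#' @param threshold_k Detection threshold as a multiple of the baseline SD.
#' @param baseline_min_fraction Minimum fraction of frames that must survive
#'   baseline exclusion; below it the ROI falls back to a global
#'   median/MAD estimate and is flagged.
#' @param baseline_exclude_k Frames more than this many robust SDs above the
#'   running median are excluded from the baseline (default 5).
#' @param baseline_iterations Number of exclusion/re-estimation passes
#'   (default 2).
#' @param min_separation Minimum separation in seconds between distinct
#'   peak onsets in one ROI: supra-threshold excursions whose (interpolated)
#'   onsets are closer than this merge into a single event, which limits
#'   double counting when noise dips the trace just below threshold.
#'   `NULL` (default) resolves to 2 frame intervals at detection time.
#' @param steady_state_window Window length in seconds for
#'   [steady_state()] (default 300).
#' @param interpolate_crossings Linearly interpolate threshold crossings
#'   between bracketing samples (default `TRUE`); when `FALSE`, crossing
#'   times snap to the first frame beyond the crossing.
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(threshold_k = 10, baseline_min_fraction = 0.2,
                             baseline_exclude_k = 5, baseline_iterations = 2,
                             min_separation = NULL,
                             steady_state_window = 300,
                             interpolate_crossings = TRUE) {
  assert_scalar_num(threshold_k, "threshold_k", min = 0, strict = TRUE)
  assert_scalar_num(baseline_min_fraction, "baseline_min_fraction", min = 0)
  assert_scalar_num(baseline_exclude_k, "baseline_exclude_k", min = 0,
                    strict = TRUE)
  assert_scalar_num(steady_state_window, "steady_state_window", min = 0,
                    strict = TRUE)
  if (!is.null(min_separation)) {
    assert_scalar_num(min_separation, "min_separation", min = 0)
  }
  structure(
    list(threshold_k = threshold_k,
         baseline_min_fraction = baseline_min_fraction,
         baseline_exclude_k = baseline_exclude_k,
         baseline_iterations = baseline_iterations,
         min_separation = min_separation,
         steady_state_window = steady_state_window,
         interpolate_crossings = isTRUE(interpolate_crossings)),
    class = "detection_params"
  )
}

resolve_min_separation <- function(params, frame_interval) {
  params$min_separation %||% (2 * frame_interval)
}
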