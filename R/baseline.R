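# robust location/scale of one trace: median and 1.4826 x MAD over frames
# surviving iterative exclusion of frames > exclude_k robust SDs above the
# running median
baseline_one <- function(f, params) {
  n <- length(f)
  keep <- rep(TRUE, n)
  for (it in seq_len(params$baseline_iterations)) {
    med <- stats::median(f[keep])
    sig <- stats::mad(f[keep]) # 1.4826 * MAD
    if (sig == 0) break
    keep <- f <= med + params$baseline_exclude_k * sig
  }
  fallback <- sum(keep) < params$baseline_min_fraction * n
  if (fallback) keep <- rep(TRUE, n)
  c(f0 = stats::median(f[keep]), sigma = stats::mad(f[keep]),
    n_baseline = sum(keep), fallback = as.numeric(fallback))
}

#' Robust per-ROI baseline fluorescence and baseline SD
#'
#' The detection threshold is defined relative to the baseline fluorescence
#' `F0` and the SD of the baseline, which must be estimated without
#' contamination by the very transients being detected. Per ROI this uses a
#' robust location/scale estimate: `F0` is the median and `sigma` is
#' 1.4826 x the median absolute deviation, computed over frames that survive
#' an iterative exclusion of supra-baseline frames (frames more than
#' `baseline_exclude_k` robust SDs above the median are dropped and the
#' estimate recomputed, `baseline_iterations` times). For a Gaussian
#' baseline, `sigma` is a consistent estimate of the noise SD even when a
#' sizeable minority of frames lies inside events. ROIs where fewer than
#' `baseline_min_fraction` of frames survive exclusion fall back to the
#' global median/MAD and are flagged.
#'
#' @param traces A `ca_traces` tibble (see [extract_traces()]), >= 10 frames.
#' @param params A [detection_params()].
#' @return A tibble with one row per ROI: `roi`, `f0`, `sigma`,
#'   `n_baseline` (frames used), `fallback` (logical).
#' @export
estimate_baseline <- function(traces, params = detection_params()) {
  m <- trace_matrix(traces)
  if (ncol(m) < 10) stop("traces must have at least 10 frames", call. = FALSE)
  stats <- t(apply(m, 1, baseline_one, params = params))
  tibble::tibble(
    roi = as.integer(rownames(m)),
    f0 = stats[, "f0"],
    sigma = stats[, "sigma"],
    n_baseline = as.integer(stats[, "n_baseline"]),
    fallback = stats[, "fallback"] > 0
  )
}
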