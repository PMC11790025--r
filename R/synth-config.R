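#' Configuration for the synthetic cochlear recording generator
#'
#' Describes a simulated field of GCaMP-labelled cells: a static cell layout
#' with baseline fluorescence and Gaussian noise, spontaneous cell-level
#' transients (linear rise, exponential decay), radially propagating
#' intercellular Ca2+ waves initiated at point sites, and rare "slow"
#' hair-cell transients accompanied by swelling and fragmentation. Defaults
#' mirror the recording conditions the package targets: 56-px (11-um) ROIs,
#' 2-s frame interval, wave speeds of order 15-30 um/s.
#'
#' @param field_width_px,field_height_px Field size in pixels.
#' @param pixel_size um per pixel (default 11/56 = 0.1964).
#' @param frame_interval Seconds between frames (default 2).
#' @param duration Recording length in seconds (default 600, a 10-min
#'   session).
#' @param baseline_level Resting fluorescence of a cell (arbitrary units).
#' @param background_level Fluorescence of unlabelled background pixels
#'   (movies only); kept well below `baseline_level` so cells are
#'   segmentable.
#' @param noise_sd SD of the additive Gaussian noise, in intensity units.
#'   At trace level it is applied per ROI sample; at movie level per pixel.
#' @param cells Tibble of cell positions with columns `x_um`, `y_um`,
#'   `class` (`"IHC"`, `"OHC"` or `"supporting"`). Optional per-cell
#'   override columns: `rate` (events/s), `n_events` (exact spontaneous
#'   event count, overriding the Poisson draw), `event_times` (list-column
#'   of exact onset times, for deterministic fixtures), `slow` (logical,
#'   force a slow transient). Each cell must fall inside exactly one ROI.
#' @param transient_rate Per-cell Poisson rate of spontaneous transients
#'   (events/s).
#' @param transient_amplitude Event amplitude as a multiple of `noise_sd`
#'   (default 20, i.e. twice the 10x-SD detection threshold).
#' @param rise_duration Linear rise time to peak, seconds.
#' @param decay_tau Exponential decay constant of fast transients, seconds.
#' @param wave_sites Tibble of wave initiation points (`x_um`, `y_um`).
#' @param wave_site_rate Per-site Poisson initiation rate (events/s).
#' @param wave_speed Radial propagation speed, um/s (> 0 when sites given).
#' @param wave_radius Hard cutoff of wave spatial extent, um.
#' @param slow_fraction Fraction of OHCs assigned a slow transient (ignored
#'   for cells with an explicit `slow` column).
#' @param slow_tau Decay constant of slow transients, seconds.
#' @param slow_rise_duration Rise time of slow transients, seconds; cell
#'   swelling develops over this rise.
#' @param swell_factor Linear radius multiplier at the slow-transient peak
#'   (>= 1); segmented area scales with its square.
#' @param cell_radius_um Rendered cell radius in movies, um.
#' @param roi_size_px ROI side used for the implied grid (default 56).
#' @param seed Master RNG seed; all draws derive from per-cell / per-site /
#'   per-frame substreams so that adding a cell never perturbs the others.
#' @return A validated list of class `synth_config`.
#' @export
#' @examples
#' cfg <- synth_config(
#'   field_width_px = 280, field_height_px = 280, duration = 120,
#'   cells = cell_grid(280, 280), transient_rate = 0.02
#' )
synth_config <- function(field_width_px, field_height_px,
                         pixel_size = 11 / 56, frame_interval = 2,
                         duration = 600, baseline_level = 100,
                         background_level = 20, noise_sd = 5,
                         cells = NULL,
                         transient_rate = 0, transient_amplitude = 20,
                         rise_duration = 2, decay_tau = 2,
                         wave_sites = NULL, wave_site_rate = 0,
                         wave_speed = 15.5, wave_radius = 44,
                         slow_fraction = 0, slow_tau = 60,
                         slow_rise_duration = 10, swell_factor = 1.5,
                         cell_radius_um = 2.5, roi_size_px = 56,
                         seed = 1L) {
  assert_scalar_num(field_width_px, "field_width_px", min = 1)
  assert_scalar_num(field_height_px, "field_height_px", min = 1)
  assert_scalar_num(pixel_size, "pixel_size", min = 0, strict = TRUE)
  assert_scalar_num(frame_interval, "frame_interval", min = 0, strict = TRUE)
  assert_scalar_num(duration, "duration", min = 0, strict = TRUE)
  if (duration < frame_interval) {
    stop("`duration` must be at least one frame interval", call. = FALSE)
  }
  assert_scalar_num(noise_sd, "noise_sd", min = 0)
  assert_scalar_num(transient_rate, "transient_rate", min = 0)
  assert_scalar_num(transient_amplitude, "transient_amplitude", min = 0)
  assert_scalar_num(rise_duration, "rise_duration", min = 0)
  assert_scalar_num(decay_tau, "decay_tau", min = 0, strict = TRUE)
  assert_scalar_num(wave_site_rate, "wave_site_rate", min = 0)
  assert_scalar_num(wave_radius, "wave_radius", min = 0)
  assert_scalar_num(slow_fraction, "slow_fraction", min = 0)
  if (slow_fraction > 1) stop("`slow_fraction` must be <= 1", call. = FALSE)
  assert_scalar_num(slow_tau, "slow_tau", min = 0, strict = TRUE)
  assert_scalar_num(slow_rise_duration, "slow_rise_duration", min = 0)
  assert_scalar_num(swell_factor, "swell_factor", min = 1)
  assert_scalar_num(cell_radius_um, "cell_radius_um", min = 0, strict = TRUE)

  if (!is.null(wave_sites) && nrow(wave_sites) > 0) {
    assert_scalar_num(wave_speed, "wave_speed", min = 0, strict = TRUE)
    stopifnot(all(c("x_um", "y_um") %in% names(wave_sites)))
  }
  if (!is.null(cells) && nrow(cells) > 0) {
    stopifnot(all(c("x_um", "y_um") %in% names(cells)))
    if (!"class" %in% names(cells)) cells$class <- "supporting"
    w_um <- field_width_px * pixel_size
    h_um <- field_height_px * pixel_size
    if (any(cells$x_um < 0 | cells$x_um > w_um |
              cells$y_um < 0 | cells$y_um > h_um)) {
      stop("cell centers must lie inside the field", call. = FALSE)
    }
  }

  cfg <- list(
    field_width_px = field_width_px, field_height_px = field_height_px,
    pixel_size = pixel_size, frame_interval = frame_interval,
    duration = duration, baseline_level = baseline_level,
    background_level = background_level, noise_sd = noise_sd,
    cells = if (is.null(cells)) NULL else tibble::as_tibble(cells),
    transient_rate = transient_rate,
    transient_amplitude = transient_amplitude,
    rise_duration = rise_duration, decay_tau = decay_tau,
    wave_sites = if (is.null(wave_sites)) NULL else
      tibble::as_tibble(wave_sites),
    wave_site_rate = wave_site_rate, wave_speed = wave_speed,
    wave_radius = wave_radius, slow_fraction = slow_fraction,
    slow_tau = slow_tau, slow_rise_duration = slow_rise_duration,
    swell_factor = swell_factor, cell_radius_um = cell_radius_um,
    roi_size_px = roi_size_px, seed = as.integer(seed)
  )
  class(cfg) <- "synth_config"
  cfg
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(
    "<synth_config> %g x %g px, %g s at dt = %g s, %d cells, %d wave sites, seed %d\n",
    x$field_width_px, x$field_height_px, x$duration, x$frame_interval,
    if (is.null(x$cells)) 0L else nrow(x$cells),
    if (is.null(x$wave_sites)) 0L else nrow(x$wave_sites), x$seed
  ))
  invisible(x)
}

#' Lay cells on the ROI lattice of a field
#'
#' Convenience builder: one cell at the center of every ROI of the implied
#' grid, mimicking a confluent supporting-cell sheet.
#'
#' @param field_width_px,field_height_px Field size in pixels.
#' @param roi_size_px,pixel_size Grid geometry (defaults as in [roi_grid()]).
#' @param class Cell class label for all cells.
#' @return Tibble with `x_um`, `y_um`, `class`.
#' @export
cell_grid <- function(field_width_px, field_height_px, roi_size_px = 56,
                      pixel_size = 11 / 56, class = "supporting") {
  g <- roi_grid(field_width_px, field_height_px, roi_size_px, pixel_size)
  tibble::tibble(x_um = g$cx_um, y_um = g$cy_um, class = class)
}

#' Read a generator configuration from a YAML or JSON document
#'
#' The document's keys mirror the arguments of [synth_config()]; `cells` and
#' `wave_sites` are given as lists of records.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return A `synth_config`.
#' @export
read_synth_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required to read YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  for (fld in c("cells", "wave_sites")) {
    if (!is.null(obj[[fld]])) {
      obj[[fld]] <- tibble::as_tibble(as.data.frame(obj[[fld]]))
    }
  }
  do.call(synth_config, obj)
}
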