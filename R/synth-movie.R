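# linear pixel indices (into an h x w matrix) of a disk, given pixel-center
# coordinates in um
disk_indices <- function(cx, cy, r, w_px, h_px, pixel_size) {
  x0 <- max(1L, floor((cx - r) / pixel_size))
  x1 <- min(w_px, ceiling((cx + r) / pixel_size) + 1L)
  y0 <- max(1L, floor((cy - r) / pixel_size))
  y1 <- min(h_px, ceiling((cy + r) / pixel_size) + 1L)
  if (x0 > x1 || y0 > y1) return(integer())
  xs <- (x0:x1 - 0.5) * pixel_size
  ys <- (y0:y1 - 0.5) * pixel_size
  dx2 <- outer(ys - cy, xs - cx, function(a, b) a^2 + b^2) # rows = y
  sel <- which(dx2 <= r^2, arr.ind = TRUE)
  if (!nrow(sel)) return(integer())
  (x0 + sel[, 2] - 2L) * h_px + (y0 + sel[, 1] - 1L)
}

#' Generate a synthetic movie with exact ground truth
#'
#' Renders the field described by a [synth_config()] as a pixel movie: each
#' cell is a disk of radius `cell_radius_um` whose interior intensity follows
#' the same trace model as [generate_traces()] (baseline plus event
#' waveforms); non-cell pixels sit at `background_level`; i.i.d. Gaussian
#' pixel noise of SD `noise_sd` is added everywhere. Cells carrying a slow
#' transient swell linearly to `swell_factor` times their radius over the
#' transient rise and then fragment into two disjoint half-area blobs after
#' the peak, emulating the swelling/fragmentation that accompanies
#' Ca2+-associated hair-cell death.
#'
#' Overlapping cell disks are permitted but reported with a warning.
#'
#' @param config A [synth_config()].
#' @return A list of class `synth_recording` with elements `movie` (a
#'   [ca_movie()]), `events`, `waves`, `grid`, `config`.
#' @export
generate_movie <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  grid <- roi_grid(config$field_width_px, config$field_height_px,
                   config$roi_size_px, config$pixel_size)
  cells <- resolve_cells(config, grid)
  truth <- synth_truth(config, grid, cells)

  w <- config$field_width_px
  h <- config$field_height_px
  ps <- config$pixel_size
  n_frames <- floor(config$duration / config$frame_interval)
  tt <- (seq_len(n_frames) - 1) * config$frame_interval
  r0 <- config$cell_radius_um

  if (nrow(cells) > 1) {
    dmin <- min(stats::dist(cells[, c("x_um", "y_um")]))
    if (dmin < 2 * r0) {
      warning("overlapping cell disks in rendered movie (min center ",
              "distance ", signif(dmin, 3), " um < 2 x radius)")
    }
  }

  # static masks; slow cells get time-varying geometry
  masks <- lapply(seq_len(nrow(cells)), function(i) {
    disk_indices(cells$x_um[i], cells$y_um[i], r0, w, h, ps)
  })
  slow_ev <- truth$events[truth$events$type == "slow", ]
  # per-cell deterministic intensity time course
  cell_val <- matrix(config$baseline_level, nrow(cells), n_frames)
  for (i in seq_len(nrow(truth$events))) {
    e <- truth$events[i, ]
    ci <- match(e$cell_id, cells$cell_id)
    cell_val[ci, ] <- cell_val[ci, ] + event_waveform(
      tt - e$onset_s, e$amplitude, e$rise_duration, e$decay_tau)
  }

  frames <- array(config$background_level, dim = c(n_frames, h, w))
  for (f in seq_len(n_frames)) {
    img <- matrix(config$background_level, h, w)
    for (ci in seq_len(nrow(cells))) {
      idx <- masks[[ci]]
      se <- slow_ev[slow_ev$cell_id == cells$cell_id[ci], ]
      if (nrow(se)) {
        onset <- se$onset_s[1]
        rise <- se$rise_duration[1]
        t_rel <- tt[f] - onset
        if (t_rel >= 0 && t_rel <= rise) {
          frac <- if (rise > 0) t_rel / rise else 1
          r_t <- r0 * (1 + (config$swell_factor - 1) * frac)
          idx <- disk_indices(cells$x_um[ci], cells$y_um[ci], r_t, w, h, ps)
        } else if (t_rel > rise) {
          # fragmentation: the original blob splits into two disjoint
          # half-area blobs
          r_fr <- r0 / sqrt(2)
          off <- 0.9 * r0 # keeps the blobs cleanly disjoint after rasterization
          idx <- c(
            disk_indices(cells$x_um[ci] - off, cells$y_um[ci], r_fr, w, h, ps),
            disk_indices(cells$x_um[ci] + off, cells$y_um[ci], r_fr, w, h, ps)
          )
        }
      }
      img[idx] <- cell_val[ci, f]
    }
    if (config$noise_sd > 0) {
      img <- img + with_substream(config$seed, 4e7 + f,
        matrix(stats::rnorm(h * w, 0, config$noise_sd), h, w))
    }
    frames[f, , ] <- img
  }

  structure(
    list(movie = ca_movie(frames, ps, config$frame_interval),
         events = truth$events, waves = truth$waves,
         grid = grid, config = config),
    class = "synth_recording"
  )
}
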