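#' Construct a calcium movie object
#'
#' A movie is a stack of single-channel frames with a physical pixel size and
#' a fixed frame interval. Frame 0 is at t = 0 s.
#'
#' @param frames Numeric array with dim `c(n_frames, height, width)`,
#'   non-negative intensities.
#' @param pixel_size Pixel size in um/px.
#' @param frame_interval Time between frames in seconds.
#' @return An object of class `ca_movie`.
#' @export
ca_movie <- function(frames, pixel_size, frame_interval) {
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop("`frames` must be a 3D array (frames x height x width)", call. = FALSE)
  }
  if (dim(frames)[1] < 2L) stop("a movie needs at least 2 frames", call. = FALSE)
  assert_scalar_num(pixel_size, "pixel_size", min = 0, strict = TRUE)
  assert_scalar_num(frame_interval, "frame_interval", min = 0, strict = TRUE)
  structure(
    list(frames = frames, pixel_size = pixel_size,
         frame_interval = frame_interval),
    class = "ca_movie"
  )
}

#' @export
print.ca_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<ca_movie> %d frames, %d x %d px (%.4g um/px), dt = %g s, %.4g s total\n",
    d[1], d[3], d[2], x$pixel_size, x$frame_interval,
    (d[1] - 1) * x$frame_interval
  ))
  invisible(x)
}

#' @export
dim.ca_movie <- function(x) dim(x$frames)

#' Read / write a movie as a multi-page TIFF
#'
#' Thin wrappers around the tiff package. Intensities are stored 16-bit
#' (scaled to the stack maximum on write and rescaled back on read via the
#' `intensity_max` argument).
#'
#' @param path TIFF file path.
#' @param pixel_size,frame_interval Physical calibration (not stored in the
#'   TIFF; must be supplied on read).
#' @param movie A [ca_movie()].
#' @param intensity_max Full-scale intensity mapped to 16-bit 1.0. On write,
#'   defaults to the stack maximum; pass the same value to `read_movie_tiff()`
#'   to recover the original scale.
#' @return `read_movie_tiff()` returns a `ca_movie`; `write_movie_tiff()`
#'   returns `intensity_max` invisibly.
#' @export
read_movie_tiff <- function(path, pixel_size, frame_interval,
                            intensity_max = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  arr <- array(0, dim = c(length(pages), h, w))
  for (i in seq_along(pages)) {
    pg <- pages[[i]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1] # single channel expected
    arr[i, , ] <- pg * intensity_max
  }
  ca_movie(arr, pixel_size, frame_interval)
}

#' @rdname read_movie_tiff
#' @export
write_movie_tiff <- function(movie, path, intensity_max = NULL) {
  stopifnot(inherits(movie, "ca_movie"))
  mx <- intensity_max %||% max(movie$frames)
  if (mx <= 0) mx <- 1
  pages <- lapply(seq_len(dim(movie$frames)[1]), function(i) {
    pmin(pmax(movie$frames[i, , ] / mx, 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(mx)
}

#' Extract the ROI-by-frame mean-fluorescence table from a movie
#'
#' For every ROI of the grid and every frame, the arithmetic mean intensity
#' of the ROI's pixels is recorded; this is the standard reduction of a
#' cochlear GCaMP movie to a trace table on which peak detection operates.
#'
#' @param movie A [ca_movie()].
#' @param grid A [roi_grid()] that fits inside the movie frame.
#' @return A tibble of class `ca_traces` in long format with columns `roi`,
#'   `frame` (0-based), `time_s`, `f`, carrying the grid and frame interval
#'   as attributes (`grid`, `frame_interval`, `n_frames`).
#' @export
extract_traces <- function(movie, grid) {
  stopifnot(inherits(movie, "ca_movie"), inherits(grid, "roi_grid"))
  d <- dim(movie$frames)
  size <- attr(grid, "roi_size_px")
  if (max(grid$x0) + size > d[3] || max(grid$y0) + size > d[2]) {
    stop("grid does not fit inside the movie frame", call. = FALSE)
  }
  n_frames <- d[1]
  n_rois <- nrow(grid)
  m <- matrix(NA_real_, n_rois, n_frames)
  for (i in seq_len(n_rois)) {
    ys <- grid$y0[i] + seq_len(size)
    xs <- grid$x0[i] + seq_len(size)
    block <- movie$frames[, ys, xs, drop = FALSE]
    m[i, ] <- rowMeans(matrix(block, nrow = n_frames))
  }
  traces_from_matrix(m, movie$frame_interval, grid)
}

# Build a long ca_traces tibble from an ROI x frame matrix.
traces_from_matrix <- function(m, frame_interval, grid = NULL) {
  n_rois <- nrow(m); n_frames <- ncol(m)
  frame <- rep(seq_len(n_frames) - 1L, times = n_rois)
  tr <- tibble::tibble(
    roi = rep(seq_len(n_rois), each = n_frames),
    frame = frame,
    time_s = frame * frame_interval,
    f = as.vector(t(m))
  )
  structure(tr,
    frame_interval = frame_interval, n_frames = n_frames, grid = grid,
    class = c("ca_traces", class(tr))
  )
}

#' Convert a long trace table to an ROI-by-frame matrix
#'
#' @param traces A `ca_traces` tibble (or any data frame with `roi`, `frame`,
#'   `f` columns).
#' @return Numeric matrix with one row per ROI (rownames = ROI ids) and one
#'   column per frame.
#' @export
trace_matrix <- function(traces) {
  rois <- sort(unique(traces$roi))
  frames <- sort(unique(traces$frame))
  ord <- order(match(traces$roi, rois), traces$frame)
  m <- matrix(traces$f[ord], nrow = length(rois), ncol = length(frames),
              byrow = TRUE)
  rownames(m) <- rois
  m
}

#' Read / write trace tables as CSV
#'
#' Long format with columns `roi, frame, time_s, f`.
#'
#' @param traces A `ca_traces` tibble.
#' @param path CSV path.
#' @param frame_interval Frame interval in seconds (on read; inferred from
#'   the `time_s` column when omitted).
#' @return `read_traces_csv()` returns a `ca_traces` tibble.
#' @export
write_traces_csv <- function(traces, path) {
  utils::write.csv(
    as.data.frame(traces)[, c("roi", "frame", "time_s", "f")],
    path, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path, frame_interval = NULL) {
  df <- utils::read.csv(path)
  if (is.null(frame_interval)) {
    ts <- sort(unique(df$time_s))
    frame_interval <- if (length(ts) > 1) min(diff(ts)) else 1
  }
  m <- trace_matrix(df)
  traces_from_matrix(m, frame_interval)
}

# frame interval of a trace table, tolerating attribute loss through dplyr
trace_dt <- function(traces) {
  dt <- attr(traces, "frame_interval")
  if (!is.null(dt)) return(dt)
  ts <- sort(unique(traces$time_s))
  if (length(ts) > 1) min(diff(ts)) else 1
}

trace_duration <- function(traces) {
  dt <- trace_dt(traces)
  (max(traces$frame) + 1L) * dt
}
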