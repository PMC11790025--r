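#' Tile a field of view into a grid of square ROIs
#'
#' Reproduces the ROI-grid convention used for cochlear GCaMP recordings:
#' square regions of interest slightly larger than one cell (56 x 56 px =
#' 11 x 11 um) tiled from the top-left corner, with partial tiles at the
#' right/bottom edges dropped. A 1400 x 728 px frame yields the canonical
#' 325-ROI (25 x 13) grid.
#'
#' Pixel indices are 0-based and each box is the half-open square
#' `[x0, x0 + roi_size_px) x [y0, y0 + roi_size_px)`. Physical ROI centers
#' (in um) are `(x0 + size/2) * pixel_size`, likewise for y, so that
#' inter-ROI distances used for wave-speed estimation are unambiguous.
#'
#' @param width_px,height_px Frame dimensions in pixels.
#' @param roi_size_px Side of each square ROI in pixels (default 56).
#' @param pixel_size Physical pixel size in um/px (default 11/56, i.e. a
#'   56-px ROI spans 11 um).
#' @return A tibble of class `roi_grid` with one row per ROI in row-major
#'   order: `roi` (1-based id), `x0`, `y0` (0-based top-left pixel),
#'   `cx_um`, `cy_um` (center in um). Grid geometry is carried in
#'   attributes `roi_size_px`, `pixel_size`, `width_px`, `height_px`.
#' @export
#' @examples
#' g <- roi_grid(1400, 728)
#' nrow(g) # 325
roi_grid <- function(width_px, height_px, roi_size_px = 56,
                     pixel_size = 11 / 56) {
  assert_scalar_num(width_px, "width_px", min = 1)
  assert_scalar_num(height_px, "height_px", min = 1)
  assert_scalar_num(roi_size_px, "roi_size_px", min = 0, strict = TRUE)
  assert_scalar_num(pixel_size, "pixel_size", min = 0, strict = TRUE)
  if (roi_size_px > min(width_px, height_px)) {
    stop("`roi_size_px` exceeds the frame dimensions", call. = FALSE)
  }
  nx <- floor(width_px / roi_size_px)
  ny <- floor(height_px / roi_size_px)
  ix <- rep(seq_len(nx) - 1L, times = ny)
  iy <- rep(seq_len(ny) - 1L, each = nx)
  g <- tibble::tibble(
    roi = seq_len(nx * ny),
    x0 = ix * roi_size_px,
    y0 = iy * roi_size_px,
    cx_um = (ix * roi_size_px + roi_size_px / 2) * pixel_size,
    cy_um = (iy * roi_size_px + roi_size_px / 2) * pixel_size
  )
  structure(g,
    roi_size_px = roi_size_px, pixel_size = pixel_size,
    width_px = width_px, height_px = height_px,
    class = c("roi_grid", class(g))
  )
}

#' Locate the ROI containing a physical point
#'
#' @param grid A [roi_grid()].
#' @param x_um,y_um Point coordinates in um (vectorised).
#' @return Integer ROI ids (`NA` for points outside every ROI).
#' @export
roi_at <- function(grid, x_um, y_um) {
  size <- attr(grid, "roi_size_px")
  ps <- attr(grid, "pixel_size")
  nx <- length(unique(grid$x0))
  ny <- length(unique(grid$y0))
  ix <- floor(x_um / ps / size)
  iy <- floor(y_um / ps / size)
  ok <- ix >= 0 & ix < nx & iy >= 0 & iy < ny &
    x_um >= 0 & y_um >= 0
  out <- rep(NA_integer_, length(x_um))
  out[ok] <- as.integer(iy[ok] * nx + ix[ok] + 1L)
  out
}

#' Write / read a grid sidecar as JSON
#'
#' @param grid A [roi_grid()].
#' @param path File path for the JSON sidecar.
#' @return `write_roi_grid()` returns `path` invisibly; `read_roi_grid()`
#'   returns the reconstructed `roi_grid`.
#' @export
write_roi_grid <- function(grid, path) {
  obj <- list(
    roi_size_px = attr(grid, "roi_size_px"),
    pixel_size = attr(grid, "pixel_size"),
    width_px = attr(grid, "width_px"),
    height_px = attr(grid, "height_px")
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi_grid
#' @export
read_roi_grid <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  roi_grid(obj$width_px, obj$height_px, obj$roi_size_px, obj$pixel_size)
}
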