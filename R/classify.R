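#' Classification parameters for fast/slow hair-cell transients
#'
#' @param seg_threshold_k Segmentation threshold: pixels brighter than
#'   background + `seg_threshold_k` x background SD belong to the cell
#'   (default 5; background statistics come from the ROI border ring).
#' @param ring_width_px Width of the ROI border ring used for the local
#'   background estimate (default 2 px).
#' @param min_blob_px Connected components smaller than this many pixels are
#'   ignored as speckle (default 5).
#' @param area_cut Slow-transient boundary on the maximum area ratio
#'   (default 1.2): a cell whose segmented area exceeds `area_cut` x its
#'   baseline area, or that fragments, is labelled `slow`.
#' @return A list of class `classify_params`.
#' @export
classify_params <- function(seg_threshold_k = 5, ring_width_px = 2,
                            min_blob_px = 5, area_cut = 1.2) {
  assert_scalar_num(seg_threshold_k, "seg_threshold_k", min = 0)
  assert_scalar_num(area_cut, "area_cut", min = 0, strict = TRUE)
  structure(list(seg_threshold_k = seg_threshold_k,
                 ring_width_px = ring_width_px,
                 min_blob_px = min_blob_px, area_cut = area_cut),
            class = "classify_params")
}

#' Track a cell's segmented area through a movie
#'
#' Per frame, the ROI cutout is segmented against a local background
#' (median and SD of the ROI border ring): pixels above
#' `background + seg_threshold_k x SD` are foreground. The cell's area is
#' the pixel count of the connected component overlapping the baseline
#' centroid; the cell is flagged as fragmented on frames where segmentation
#' yields two or more components after a single component at baseline. The
#' headline quantity is `max_area_ratio`, the maximum area relative to the
#' baseline (median over baseline frames) area — for a disk that swells by a
#' linear factor s, this ratio is s^2.
#'
#' @param movie A [ca_movie()].
#' @param box One row of a [roi_grid()] (or a list with `x0`, `y0`) giving
#'   the cell's ROI; the ROI side is taken from `size_px`.
#' @param baseline_frames Integer frame indices (1-based) known to precede
#'   any transient; at least 5 are required.
#' @param params A [classify_params()].
#' @param size_px ROI side in pixels (default 56).
#' @return A list of class `cell_track`: `area_px` (per-frame area),
#'   `n_components` (per-frame component count), `baseline_area_px`,
#'   `max_area_ratio`, `fragmented`, `area_um2` conversion factor fields.
#' @export
track_cell_area <- function(movie, box, baseline_frames,
                            params = classify_params(), size_px = 56) {
  stopifnot(inherits(movie, "ca_movie"))
  if (length(baseline_frames) < 5) {
    stop("at least 5 baseline frames are required", call. = FALSE)
  }
  d <- dim(movie$frames)
  ys <- box$y0 + seq_len(size_px)
  xs <- box$x0 + seq_len(size_px)
  if (max(ys) > d[2] || max(xs) > d[3]) {
    stop("cell ROI does not fit inside the movie frame", call. = FALSE)
  }
  rw <- params$ring_width_px
  ring <- matrix(FALSE, size_px, size_px)
  ring[c(seq_len(rw), size_px - seq_len(rw) + 1L), ] <- TRUE
  ring[, c(seq_len(rw), size_px - seq_len(rw) + 1L)] <- TRUE

  n_frames <- d[1]
  area <- integer(n_frames)
  ncomp <- integer(n_frames)
  centroid <- NULL

  seg_frame <- function(f) {
    cut <- movie$frames[f, ys, xs]
    bg <- stats::median(cut[ring])
    bg_sd <- stats::sd(cut[ring])
    mask <- cut > bg + params$seg_threshold_k * bg_sd
    lab <- EBImage::bwlabel(mask)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= params$min_blob_px)
    list(lab = lab, keep = keep, sizes = sizes)
  }

  # baseline geometry: single component expected; its centroid anchors the
  # tracked component in later frames
  base_area <- numeric(length(baseline_frames))
  for (k in seq_along(baseline_frames)) {
    s <- seg_frame(baseline_frames[k])
    if (!length(s$keep)) {
      stop("empty segmentation at baseline; cell rejected", call. = FALSE)
    }
    main <- s$keep[which.max(s$sizes[s$keep])]
    base_area[k] <- s$sizes[main]
    if (is.null(centroid)) {
      w <- which(s$lab == main, arr.ind = TRUE)
      centroid <- round(colMeans(w))
    }
  }
  baseline_area <- stats::median(base_area)

  for (f in seq_len(n_frames)) {
    s <- seg_frame(f)
    ncomp[f] <- length(s$keep)
    if (!length(s$keep)) {
      area[f] <- 0L
      next
    }
    at_centroid <- s$lab[centroid[1], centroid[2]]
    comp <- if (at_centroid > 0 && at_centroid %in% s$keep) at_centroid else {
      # nearest surviving component to the baseline centroid
      dmin <- Inf; comp <- s$keep[1]
      for (kk in s$keep) {
        w <- which(s$lab == kk, arr.ind = TRUE)
        dk <- min((w[, 1] - centroid[1])^2 + (w[, 2] - centroid[2])^2)
        if (dk < dmin) { dmin <- dk; comp <- kk }
      }
      comp
    }
    area[f] <- s$sizes[comp]
  }

  structure(list(
    area_px = area,
    n_components = ncomp,
    baseline_area_px = baseline_area,
    max_area_ratio = max(area) / baseline_area,
    fragmented = any(ncomp >= 2),
    pixel_size = movie$pixel_size,
    area_um2 = area * movie$pixel_size^2,
    baseline_area_um2 = baseline_area * movie$pixel_size^2
  ), class = "cell_track")
}

#' Label transients as fast or slow from cell-area dynamics
#'
#' The two populations of noise-evoked hair-cell transients are separated by
#' whether the cell changes shape: a transient is `slow` iff its cell's
#' maximum area ratio reaches `area_cut` (default 1.2) or the cell
#' fragments; otherwise it is `fast`. The rule is total and deterministic.
#' Rows with a missing area track get label `NA` (undetermined) and are
#' excluded from prevalence.
#'
#' @param cell_features A tibble with one row per event (or per cell) and
#'   columns `max_area_ratio` and `fragmented`.
#' @param params A [classify_params()] (uses `area_cut`).
#' @return `cell_features` with a `label` column (`"fast"`/`"slow"`/`NA`).
#' @export
classify_transients <- function(cell_features, params = classify_params()) {
  ratio <- cell_features$max_area_ratio
  frag <- cell_features$fragmented
  # NA ratio with fragmented TRUE still resolves to slow; NA with unknown
  # fragmentation stays undetermined
  lab <- ifelse(ratio >= params$area_cut | frag, "slow", "fast")
  cell_features$label <- lab
  cell_features
}

#' Per-label prevalence among all cells of a field
#'
#' A cell counts once per label when it has at least one event of that
#' label; the denominator is the total number of cells in the analysed
#' field, including silent ones. Percentages are rounded half-up to one
#' decimal, the convention for reporting prevalences like 7/80 = 8.8%.
#'
#' @param classes A tibble with `cell_id` and `label` columns (one row per
#'   classified event or cell).
#' @param n_cells Total number of cells in the field (> 0).
#' @return A tibble with `label`, `n_cells`, `total_cells`,
#'   `prevalence_pct`.
#' @export
transient_prevalence <- function(classes, n_cells) {
  assert_scalar_num(n_cells, "n_cells", min = 0, strict = TRUE)
  cl <- classes[!is.na(classes$label), , drop = FALSE]
  out <- dplyr::summarise(
    dplyr::group_by(cl, .data$label),
    n_cells = dplyr::n_distinct(.data$cell_id), .groups = "drop"
  )
  out$total_cells <- n_cells
  out$prevalence_pct <- round_half_up(100 * out$n_cells / n_cells, 1)
  out
}

#' Classify the transient-bearing cells of a movie
#'
#' Pipeline convenience: for every cell whose ROI carries at least one
#' detected event, track the cell area through the movie
#' ([track_cell_area()], with baseline frames taken before the cell's first
#' event onset) and apply the fast/slow rule ([classify_transients()]).
#'
#' @param movie A [ca_movie()].
#' @param grid The [roi_grid()] of the recording.
#' @param events Detected events ([detect_events()]).
#' @param cells Tibble mapping `cell_id` to `roi` (e.g. the `cells` table
#'   of a [synth_config()] after [generate_movie()], or one row per ROI).
#' @param params A [classify_params()].
#' @param min_baseline_frames Minimum leading frames used as area baseline.
#' @return A tibble with one row per event-bearing cell: `cell_id`, `roi`,
#'   `n_events`, `max_area_ratio`, `fragmented`, `label`.
#' @export
classify_cells <- function(movie, grid, events, cells,
                           params = classify_params(),
                           min_baseline_frames = 5) {
  dt <- movie$frame_interval
  size <- attr(grid, "roi_size_px")
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    ev <- events[events$roi == cells$roi[i], , drop = FALSE]
    if (!nrow(ev)) next
    first_onset <- min(ev$onset_s)
    n_base <- floor(first_onset / dt)
    if (n_base < min_baseline_frames) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        cell_id = cells$cell_id[i], roi = cells$roi[i], n_events = nrow(ev),
        max_area_ratio = NA_real_, fragmented = NA
      )
      next
    }
    box <- grid[grid$roi == cells$roi[i], ]
    tr <- track_cell_area(movie, box, seq_len(n_base), params,
                          size_px = size)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      cell_id = cells$cell_id[i], roi = cells$roi[i], n_events = nrow(ev),
      max_area_ratio = tr$max_area_ratio, fragmented = tr$fragmented
    )
  }
  feats <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble(
    cell_id = integer(), roi = integer(), n_events = integer(),
    max_area_ratio = numeric(), fragmented = logical()
  )
  classify_transients(feats, params)
}
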