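#' Wave-clustering parameters
#'
#' Events are linked into intercellular Ca2+ signaling (ICS) waves when they
#' are close in both space and onset time. Defaults: `d_max` = 1.5 x the
#' 11-um ROI pitch (16.5 um), `dt_max` = `d_max` divided by a 5 um/s minimum
#' propagation speed (3.3 s), and at least 3 member ROIs per wave.
#'
#' @param d_max Maximum center-to-center distance (um) for linking.
#' @param dt_max Maximum onset-time gap (s) for linking.
#' @param min_members Minimum number of member events per wave (>= 2).
#' @return A list of class `wave_params`.
#' @export
wave_params <- function(d_max = 16.5, dt_max = d_max / 5, min_members = 3) {
  assert_scalar_num(d_max, "d_max", min = 0, strict = TRUE)
  assert_scalar_num(dt_max, "dt_max", min = 0, strict = TRUE)
  assert_scalar_num(min_members, "min_members", min = 2)
  structure(list(d_max = d_max, dt_max = dt_max,
                 min_members = as.integer(min_members)),
            class = "wave_params")
}

#' Group events into intercellular Ca2+ waves
#'
#' Single-linkage spatiotemporal clustering: two events are linked iff their
#' ROI centers are within `d_max` um *and* their onsets within `dt_max` s;
#' connected components of this relation with at least `min_members` events
#' become waves. Smaller components remain isolated peaks (they still count
#' in [peak_rate()]). For each wave the origin is the center of the
#' earliest-onset member (ties broken by lowest ROI index), the propagation
#' distance is the maximum member distance from the origin, and the speed is
#' estimated by [wave_speed()] from the origin-constrained regression of
#' onset lag on distance.
#'
#' The clustering is invariant to the order of the input events, and every
#' event belongs to at most one wave.
#'
#' @param events A `ca_events` tibble (needs `roi`, `onset_s`).
#' @param grid The [roi_grid()] providing ROI centers (defaults to the
#'   events' grid when they carry one).
#' @param params A [wave_params()].
#' @return A tibble of class `ca_waves`, one row per wave: `wave_id`,
#'   `start_s`, `origin_x_um`, `origin_y_um`, `n_members`, `speed_um_s`,
#'   `speed_defined`, `distance_um`, and a `members` list-column holding
#'   each wave's member events with `distance_um` and `lag_s`.
#' @export
cluster_waves <- function(events, grid, params = wave_params()) {
  if (nrow(events) == 0) {
    return(empty_waves())
  }
  cx <- grid$cx_um[match(events$roi, grid$roi)]
  cy <- grid$cy_um[match(events$roi, grid$roi)]
  if (anyNA(cx)) stop("events reference ROIs absent from the grid",
                      call. = FALSE)
  n <- nrow(events)
  # candidate pairs within dt_max found on the onset-sorted order, then
  # filtered by distance
  ord <- order(events$onset_s)
  ot <- events$onset_s[ord]
  hi <- findInterval(ot + params$dt_max + 1e-12, ot)
  edges <- vector("list", n)
  for (a in seq_len(n - 1)) {
    if (hi[a] <= a) next
    jj <- ord[(a + 1L):hi[a]]
    i <- ord[a]
    near <- (cx[i] - cx[jj])^2 + (cy[i] - cy[jj])^2 <= params$d_max^2
    if (any(near)) {
      edges[[a]] <- rbind(i, jj[near])
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  ee <- unlist(edges)
  if (length(ee)) {
    g <- igraph::add_edges(g, ee)
  }
  comp <- igraph::components(g)$membership

  rows <- list()
  wid <- 0L
  for (cc in unique(comp)) {
    idx <- which(comp == cc)
    if (length(idx) < params$min_members) next
    mem <- events[idx, , drop = FALSE]
    mem$cx_um <- cx[idx]
    mem$cy_um <- cy[idx]
    # origin: earliest onset, ties -> lowest ROI index
    o <- order(mem$onset_s, mem$roi)
    mem <- mem[o, , drop = FALSE]
    ox <- mem$cx_um[1]; oy <- mem$cy_um[1]
    start <- mem$onset_s[1]
    mem$distance_um <- sqrt((mem$cx_um - ox)^2 + (mem$cy_um - oy)^2)
    mem$lag_s <- mem$onset_s - start
    v <- wave_speed(mem$distance_um, mem$lag_s)
    wid <- wid + 1L
    rows[[wid]] <- tibble::tibble(
      wave_id = wid, start_s = start, origin_x_um = ox, origin_y_um = oy,
      n_members = nrow(mem), speed_um_s = v,
      speed_defined = is.finite(v), distance_um = wave_distance(mem),
      members = list(mem)
    )
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else empty_waves()
  out <- dplyr::arrange(out, .data$start_s)
  out$wave_id <- seq_len(nrow(out))
  class(out) <- c("ca_waves", class(tibble::tibble()))
  out
}

empty_waves <- function() {
  out <- tibble::tibble(
    wave_id = integer(), start_s = numeric(), origin_x_um = numeric(),
    origin_y_um = numeric(), n_members = integer(), speed_um_s = numeric(),
    speed_defined = logical(), distance_um = numeric(), members = list()
  )
  class(out) <- c("ca_waves", class(tibble::tibble()))
  out
}

#' Wave propagation speed from the lag-distance relation
#'
#' For a radially propagating wave, member onset lags satisfy
#' `lag = distance / v`. The speed is estimated as `1 / b` where `b` is the
#' least-squares slope of lag on distance constrained through the origin
#' (`b = sum(d * lag) / sum(d^2)`). Using all members makes the estimate
#' robust to a single straggler, and it is exact on noiseless radial waves.
#' The speed is undefined (`NA`) when `b <= 0` (e.g. all members
#' simultaneous) or all distances are zero; undefined speeds are flagged and
#' should be excluded from mean-speed summaries.
#'
#' @param distance_um Member distances from the wave origin, um. A wave
#'   member tibble (with `distance_um` and `lag_s` columns) may be given
#'   instead.
#' @param lag_s Member onset lags relative to the wave start, s.
#' @return Speed in um/s, or `NA_real_` when undefined.
#' @export
wave_speed <- function(distance_um, lag_s = NULL) {
  if (is.data.frame(distance_um)) {
    lag_s <- distance_um$lag_s
    distance_um <- distance_um$distance_um
  }
  ss <- sum(distance_um^2)
  if (ss == 0) return(NA_real_)
  b <- sum(distance_um * lag_s) / ss
  if (b <= 0) return(NA_real_)
  1 / b
}

#' Wave propagation distance
#'
#' Maximum Euclidean distance of any member from the wave origin.
#'
#' @param members A wave member tibble with a `distance_um` column (as in
#'   the `members` list-column of [cluster_waves()]), or a numeric vector of
#'   distances.
#' @return Distance in um.
#' @export
wave_distance <- function(members) {
  d <- if (is.data.frame(members)) members$distance_um else members
  if (!length(d)) return(NA_real_)
  max(d)
}
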