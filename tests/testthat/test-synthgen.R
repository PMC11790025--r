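test_that("an event-free config produces pure baseline noise and empty truth", {
  cfg <- synth_config(168, 112, duration = 300, noise_sd = 5,
                      cells = cell_grid(168, 112), transient_rate = 0,
                      seed = 9)
  rec <- generate_traces(cfg)
  expect_equal(nrow(rec$events), 0L)
  expect_equal(nrow(rec$waves), 0L)
  m <- trace_matrix(rec$traces)
  n <- ncol(m)
  expect_true(all(abs(rowMeans(m) - 100) < 4 * 5 / sqrt(n)))
})

test_that("wave-member activation lags are exactly distance / speed", {
  cells <- tibble::tibble(
    x_um = c(5.5, 16.5, 27.5, 38.5), y_um = 5.5, class = "supporting"
  )
  cfg <- synth_config(224, 56, duration = 60,
                      cells = cells,
                      wave_sites = tibble::tibble(x_um = 5.5, y_um = 5.5),
                      wave_site_rate = 0.1, wave_speed = 27.9,
                      wave_radius = 44, seed = 21)
  rec <- generate_traces(cfg)
  expect_gt(nrow(rec$waves), 0)
  mem <- rec$waves$members[[1]]
  start <- rec$waves$start_s[1]
  # machine-precision start + d / v, including the lags at 11/22/33 um
  expect_identical(mem$activation_s, start + mem$distance_um / 27.9)
  lags <- (mem$activation_s - start)[match(c(11, 22, 33), mem$distance_um)]
  expect_equal(lags, c(0.394, 0.789, 1.183), tolerance = 1e-3)
})

test_that("generation is bit-identical for a fixed seed", {
  cfg <- synth_config(112, 112, duration = 200,
                      cells = cell_grid(112, 112), transient_rate = 0.05,
                      slow_fraction = 0, seed = 31)
  r1 <- generate_traces(cfg)
  r2 <- generate_traces(cfg)
  expect_identical(r1$traces$f, r2$traces$f)
  expect_identical(r1$events, r2$events)
})

test_that("adding a cell does not perturb the other cells' traces or events", {
  base_cells <- cell_grid(168, 56)[1:2, ]
  cfg2 <- synth_config(168, 56, duration = 300, cells = base_cells,
                       transient_rate = 0.05, seed = 17)
  cfg3 <- synth_config(168, 56, duration = 300,
                       cells = cell_grid(168, 56)[1:3, ],
                       transient_rate = 0.05, seed = 17)
  r2 <- generate_traces(cfg2)
  r3 <- generate_traces(cfg3)
  m2 <- trace_matrix(r2$traces)
  m3 <- trace_matrix(r3$traces)
  expect_identical(m2[1:2, ], m3[1:2, ])
  expect_identical(r2$events[r2$events$cell_id <= 2, ],
                   r3$events[r3$events$cell_id <= 2, ])
})

test_that("ground-truth event counts are Poisson across seeds", {
  rate <- 0.05; dur <- 200; n_rep <- 30
  counts <- vapply(seq_len(n_rep), function(s) {
    cfg <- synth_config(56, 56, duration = dur,
                        cells = cell_grid(56, 56),
                        transient_rate = rate, seed = 100 + s)
    nrow(generate_traces(cfg)$events)
  }, 0)
  expected <- rate * dur
  tol <- 3 * sqrt(expected * n_rep) / n_rep
  expect_lt(abs(mean(counts) - expected), tol)
})

test_that("movie pixels carry the configured noise and match the trace model", {
  cfg <- synth_config(112, 56, duration = 40, noise_sd = 4,
                      cells = cell_grid(112, 56), seed = 5)
  rec <- generate_movie(cfg)
  # per-pixel temporal SD close to noise_sd (sampled pixels)
  sds <- apply(rec$movie$frames[, seq(1, 56, by = 7), seq(1, 112, by = 7)],
               c(2, 3), sd)
  expect_true(all(abs(sds - 4) / 4 < 0.5))
  expect_lt(abs(median(sds) - 4) / 4, 0.2)

  # noiseless movie -> extracted traces correlate > 0.99 with trace model
  cells <- cell_grid(112, 56)
  cells$event_times <- list(10, 20)
  cells$n_events <- NA_integer_
  cfg0 <- synth_config(112, 56, duration = 40, noise_sd = 0,
                       cells = cells, seed = 5)
  tr_direct <- trace_matrix(generate_traces(cfg0)$traces)
  rec0 <- generate_movie(cfg0)
  tr_movie <- trace_matrix(extract_traces(rec0$movie, rec0$grid))
  for (r in 1:2) {
    expect_gt(cor(tr_direct[r, ], tr_movie[r, ]), 0.99)
  }
})

test_that("swelling scales segmented area by swell_factor squared", {
  cfg <- one_cell_movie_config(duration = 200, slow = TRUE,
                               swell_factor = 1.5)
  rec <- generate_movie(cfg)
  onset <- rec$events$onset_s[1]
  n_base <- floor(onset / 2)
  trk <- track_cell_area(rec$movie, rec$grid[1, ], seq_len(n_base))
  expect_equal(trk$max_area_ratio, 2.25, tolerance = 0.1)
  expect_true(trk$fragmented)
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(56, 56, duration = 1, frame_interval = 2),
               "frame interval")
  expect_error(
    synth_config(56, 56, cells = tibble::tibble(x_um = 50, y_um = 5,
                                                class = "OHC")),
    "inside the field"
  )
  expect_error(synth_config(56, 56, swell_factor = 0.5), "swell_factor")
  bad <- synth_config(56, 56,
                      cells = tibble::tibble(x_um = 5, y_um = 5,
                                             class = "supporting"))
  bad$cells$x_um <- 1e6 # corrupt after validation
  expect_error(generate_traces(bad), "inside an ROI")
})

test_that("overlapping rendered cells trigger a warning", {
  cells <- tibble::tibble(x_um = c(5, 7), y_um = 5.5,
                          class = "supporting")
  cfg <- synth_config(56, 56, duration = 10, cells = cells, seed = 1)
  expect_warning(generate_movie(cfg), "overlapping")
})
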