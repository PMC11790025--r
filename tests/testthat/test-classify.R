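test_that("the fast/slow rule is total, deterministic, and area-driven", {
  feats <- tibble::tibble(
    cell_id = 1:4,
    max_area_ratio = c(1.0, 2.0, 1.0, NA),
    fragmented = c(FALSE, FALSE, TRUE, NA)
  )
  out <- classify_transients(feats)
  expect_equal(out$label, c("fast", "slow", "slow", NA))
  # boundary: ratio exactly at the cut is slow
  expect_equal(
    classify_transients(tibble::tibble(cell_id = 1, max_area_ratio = 1.2,
                                       fragmented = FALSE))$label, "slow")
})

test_that("prevalences use half-up rounding over all cells", {
  classes <- tibble::tibble(
    cell_id = c(1:7, 8:20),
    label = c(rep("fast", 7), rep("slow", 13))
  )
  prev <- transient_prevalence(classes, 80)
  expect_equal(prev$prevalence_pct[prev$label == "fast"], 8.8)  # 8.75 up
  expect_equal(prev$prevalence_pct[prev$label == "slow"], 16.3) # 16.25 up
  expect_error(transient_prevalence(classes, 0), "n_cells")
  # a cell with events of both labels counts once in each
  both <- tibble::tibble(cell_id = c(1, 1), label = c("fast", "slow"))
  pb <- transient_prevalence(both, 10)
  expect_equal(pb$n_cells, c(1L, 1L))
})

test_that("round_half_up rounds halves away from zero", {
  expect_equal(round_half_up(c(8.75, 16.25, 1.05), 1), c(8.8, 16.3, 1.1))
  expect_equal(round_half_up(-8.75, 1), -8.8)
  expect_equal(round(16.25, 1), 16.2) # the base-R behaviour it replaces
})

test_that("a static rendered cell keeps unit area ratio", {
  cells <- tibble::tibble(x_um = 5.5, y_um = 5.5, class = "OHC",
                          n_events = 0L)
  cfg <- synth_config(56, 56, duration = 60, cells = cells, seed = 6)
  rec <- generate_movie(cfg)
  trk <- track_cell_area(rec$movie, rec$grid[1, ], 1:10)
  expect_equal(trk$max_area_ratio, 1.0, tolerance = 0.1)
  expect_false(trk$fragmented)
})

test_that("segmentation failures and bad inputs are rejected", {
  # a cell at background brightness cannot be segmented at baseline
  arr <- array(20, dim = c(20, 56, 56))
  mov <- ca_movie(arr + rnorm(length(arr)), 11 / 56, 2)
  g <- roi_grid(56, 56)
  expect_error(track_cell_area(mov, g[1, ], 1:10), "baseline")
  expect_error(track_cell_area(mov, g[1, ], 1:3), "baseline frames")
})

test_that("the 80-cell field classifies 7 fast and 13 slow cells exactly", {
  cfg <- sim_hair_cell_field_config(seed = 42)
  rec <- generate_movie(cfg)
  tr <- extract_traces(rec$movie, rec$grid)
  ev <- detect_events(tr)
  cells <- tibble::tibble(
    cell_id = seq_len(nrow(cfg$cells)),
    roi = roi_at(rec$grid, cfg$cells$x_um, cfg$cells$y_um)
  )
  cls <- classify_cells(rec$movie, rec$grid, ev, cells)
  expect_equal(sum(cls$label == "fast"), 7L)
  expect_equal(sum(cls$label == "slow"), 13L)
  prev <- transient_prevalence(cls, 80)
  expect_equal(prev$prevalence_pct[prev$label == "fast"], 8.8)
  expect_equal(prev$prevalence_pct[prev$label == "slow"], 16.3)
})
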