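test_that("an isolated event never forms a wave", {
  sim <- sim_wave_chains(1, 1, 0.4)
  expect_equal(nrow(cluster_waves(sim$events, sim$grid)), 0L)
})

test_that("a 5-ROI chain clusters into one wave with exact speed and span", {
  sim <- sim_wave_chains(1, 5, 11 / 27.9)
  wv <- cluster_waves(sim$events, sim$grid)
  expect_equal(nrow(wv), 1L)
  expect_equal(wv$n_members, 5L)
  expect_equal(wv$speed_um_s, 27.9, tolerance = 1e-9)
  expect_equal(wv$distance_um, 44, tolerance = 1e-9) # 4 x 11-um pitch
})

test_that("chains 200 um apart form two separate waves", {
  g <- roi_grid(56 * 25, 56) # one row of 25 ROIs
  ev <- tibble::tibble(
    roi = c(1:5, 21:25), # centers 220 um apart
    onset_s = c((0:4) * 0.4, (0:4) * 0.4)
  )
  wv <- cluster_waves(ev, g)
  expect_equal(nrow(wv), 2L)
  expect_equal(sort(wv$n_members), c(5L, 5L))
})

test_that("simultaneous members give an undefined, flagged speed", {
  sim <- sim_wave_chains(1, 4, 0)
  wv <- cluster_waves(sim$events, sim$grid)
  expect_equal(nrow(wv), 1L)
  expect_false(wv$speed_defined)
  expect_true(is.na(wv$speed_um_s))
  expect_identical(wave_speed(c(0, 11, 22), c(0, 0, 0)), NA_real_)
  expect_identical(wave_speed(c(0, 0, 0), c(0, 1, 2)), NA_real_)
})

test_that("jittered 15.5-um/s waves are recovered without bias", {
  set.seed(303)
  speeds <- vapply(seq_len(100), function(i) {
    d <- (0:9) * 11
    lag <- d / 15.5 + rnorm(10, 0, 0.05)
    wave_speed(d, lag)
  }, 0)
  expect_equal(mean(speeds), 15.5, tolerance = 0.5 / 15.5)
})

test_that("clustering is invariant to event order and partitions events", {
  sim <- sim_wave_chains(3, 6, 0.5)
  ev <- sim$events
  wv1 <- cluster_waves(ev, sim$grid)
  set.seed(8)
  wv2 <- cluster_waves(ev[sample(nrow(ev)), ], sim$grid)
  key <- function(w) {
    lapply(seq_len(nrow(w)), function(i) {
      m <- w$members[[i]]
      sort(paste(m$roi, round(m$onset_s, 9)))
    })
  }
  expect_setequal(key(wv1), key(wv2))
  # every event belongs to at most one wave
  all_members <- dplyr::bind_rows(wv1$members)
  expect_lte(nrow(all_members), nrow(ev))
  expect_equal(anyDuplicated(all_members[, c("roi", "onset_s")]), 0L)
})

test_that("loosening the linking thresholds can only merge components", {
  set.seed(12)
  g <- roi_grid(56 * 20, 56 * 4)
  ev <- tibble::tibble(roi = sample(nrow(g), 60, replace = TRUE),
                       onset_s = runif(60, 0, 60))
  n_comp <- function(d_max, dt_max) {
    w <- cluster_waves(ev, g, wave_params(d_max, dt_max, min_members = 2))
    # count all components: clustered events as components plus the
    # remaining singletons
    n_in_waves <- sum(w$n_members)
    nrow(w) + (nrow(ev) - n_in_waves)
  }
  for (d in c(12, 17, 23, 34)) {
    expect_gte(n_comp(d, 3), n_comp(d * 1.5, 3))
    expect_gte(n_comp(d, 3), n_comp(d, 4.5))
  }
})
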