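test_that("the 10-SD threshold separates 9-SD from 12-SD transients", {
  bl <- flat_baseline(1, f0 = 100, sigma = 1)
  ev9 <- detect_peaks(planted_trace(9, f0 = 100), bl)
  expect_equal(nrow(ev9), 0L)
  ev12 <- detect_peaks(planted_trace(12, f0 = 100), bl)
  expect_equal(nrow(ev12), 1L)
  expect_gte(ev12$amp_ratio, 10)
})

test_that("flat traces yield no events; degenerate baselines are rejected", {
  expect_equal(nrow(detect_peaks(one_trace(rep(5, 30)))), 0L)
  bad_bl <- flat_baseline(1, f0 = 100, sigma = 0)
  expect_error(detect_peaks(planted_trace(12), bad_bl), "degenerate")
})

test_that("well-separated transients are found near their planted onsets", {
  set.seed(77)
  tt <- seq(0, 598, by = 2)
  f <- 100 + rnorm(length(tt), 0, 5)
  onsets <- c(100, 150)
  for (o in onsets) {
    f <- f + event_waveform_test(tt - o, 100, 2, 4)
  }
  ev <- detect_events(one_trace(f, 2))
  expect_equal(nrow(ev), 2L)
  expect_true(all(abs(sort(ev$onset_s) - onsets) <= 2))
})

test_that("raising the threshold never increases the event count", {
  set.seed(88)
  for (rep in 1:5) {
    tt <- seq(0, 398, by = 2)
    f <- 100 + rnorm(length(tt), 0, 5)
    for (o in runif(4, 20, 380)) {
      f <- f + event_waveform_test(tt - o, runif(1, 40, 120), 2, 4)
    }
    tr <- one_trace(f, 2)
    bl <- estimate_baseline(tr)
    counts <- vapply(c(4, 6, 8, 10, 12), function(k) {
      nrow(detect_peaks(tr, bl, detection_params(threshold_k = k)))
    }, 0L)
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("detection is time-shift and amplitude-scale equivariant", {
  bl <- flat_baseline(1, f0 = 100, sigma = 1)
  tr <- planted_trace(50, onset = 40, dur = 120, f0 = 100)
  ev <- detect_events(tr, bl)

  # delay by m frames: all times shift by exactly m * dt
  m <- 7L
  f2 <- c(rep(100, m), trace_matrix(tr)[1, ])
  ev2 <- detect_events(one_trace(f2[seq_len(60)], 2), bl)
  expect_equal(ev2$onset_s, ev$onset_s + m * 2)
  expect_equal(ev2$peak_s, ev$peak_s + m * 2)

  # scale trace and baseline by c > 0: times and kinetics unchanged
  c0 <- 3.7
  tr3 <- one_trace(trace_matrix(tr)[1, ] * c0, 2)
  bl3 <- flat_baseline(1, f0 = 100 * c0, sigma = 1 * c0)
  ev3 <- detect_events(tr3, bl3)
  expect_equal(ev3$onset_s, ev$onset_s)
  expect_equal(ev3$rise_s, ev$rise_s)
  expect_equal(ev3$decay_s, ev$decay_s)
  expect_equal(ev3$amplitude, ev$amplitude * c0)
})

test_that("events straddling the recording end are kept and censored", {
  bl <- flat_baseline(1, f0 = 100, sigma = 1)
  ev <- detect_events(planted_trace(100, onset = 100, tau = 50, dur = 120),
                      bl)
  expect_equal(nrow(ev), 1L)
  expect_false(ev$complete)
  expect_true(ev$decay_censored)
  expect_equal(ev$end_s, 118) # last frame time
})

test_that("detector recall and precision reach 0.9 at 15x baseline SD", {
  recalls <- precisions <- numeric(3)
  for (s in 1:3) {
    cfg <- synth_config(392, 392, duration = 600,
                        cells = cell_grid(392, 392),
                        transient_rate = 0.004,
                        transient_amplitude = 15, decay_tau = 6,
                        seed = 500 + s)
    rec <- generate_traces(cfg)
    ev <- detect_peaks(rec$traces)
    m <- match_events(ev, rec$events, tol_s = 4)
    recalls[s] <- m$recall
    precisions[s] <- m$precision
  }
  expect_gte(mean(recalls), 0.9)
  expect_gte(mean(precisions), 0.9)
})
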