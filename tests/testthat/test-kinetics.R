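test_that("rise time is the baseline-to-half-maximum interval of the ramp", {
  # noiseless 4-s linear ramp to 100 SD: half-max is reached 2.0 s after
  # the trace leaves baseline
  bl <- flat_baseline(1, f0 = 100, sigma = 1)
  tr <- planted_trace(100, rise = 4, tau = 10, onset = 40, dur = 200,
                      dt = 0.1, f0 = 100)
  ev <- detect_events(tr, bl)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$rise_s, 2.0, tolerance = 1e-6)
})

test_that("decay time matches tau * ln(amplitude ratio / threshold)", {
  # 100-SD peak decaying with tau = 11.81 s crosses the 10-SD threshold
  # 11.81 * ln(10) = 27.19 s after the peak
  bl <- flat_baseline(1, f0 = 100, sigma = 1)
  tr <- planted_trace(100, rise = 1, tau = 11.81, onset = 100, dur = 400,
                      dt = 0.1, f0 = 100)
  ev <- detect_events(tr, bl)
  expect_equal(ev$decay_s, 11.81 * log(10), tolerance = 0.05)
  expect_false(ev$decay_censored)
})

test_that("a single-sample spike decays within one frame interval", {
  bl <- flat_baseline(1, f0 = 0, sigma = 1)
  f <- rep(0, 50); f[25] <- 50
  ev <- detect_events(one_trace(f, 2), bl)
  expect_equal(nrow(ev), 1L)
  expect_lte(ev$decay_s, 2)
})

test_that("steady state is the plain window mean and is order-invariant", {
  expect_equal(steady_state(one_trace(rep(7, 200), 2))$steady_state_f, 7)

  # baseline 100 plus one event of area A inside the window -> 100 + A/n
  f <- rep(100, 200)
  f[50:59] <- f[50:59] + 30 # area A = 300 over n = 150 window frames
  st <- steady_state(one_trace(f, 2), window_start = 0)
  expect_equal(st$steady_state_f, 100 + 300 / 150)

  f_perm <- f
  f_perm[1:150] <- sample(f[1:150]) # permute frames within the window
  expect_equal(steady_state(one_trace(f_perm, 2))$steady_state_f,
               st$steady_state_f)

  expect_error(steady_state(one_trace(rep(1, 100), 2), window_start = 100),
               "window")
})

test_that("rates are counts over duration and add across regions", {
  ev <- tibble::tibble(roi = rep(1:3, c(200, 150, 100)),
                       onset_s = runif(450, 0, 600))
  expect_equal(peak_rate(ev, 600)$peaks_per_s, 0.75)
  expect_equal(peak_rate(ev[0, ], 600)$peaks_per_s, 0)

  regions <- tibble::tibble(roi = 1:3, region = c("IS", "IS", "OS"))
  by_region <- peak_rate(ev, 600, regions)
  expect_equal(sum(by_region$peaks_per_s), 0.75)
  expect_equal(by_region$peaks_per_s[by_region$region == "OS"], 100 / 600)

  waves <- tibble::tibble(start_s = runif(120, 0, 600))
  expect_equal(wave_rate(waves, 600)$waves_per_s, 0.2)
  expect_equal(wave_rate(waves[0, ], 600)$waves_per_s, 0)
})
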