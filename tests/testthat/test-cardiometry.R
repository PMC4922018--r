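test_that("roi_mean_trace averages pixels inside the half-open rectangle", {
  # uniform frames give a constant trace
  st <- constant_stack(c(3, 3, 3))
  expect_equal(roi_mean_trace(st, roi(0, 0, 8, 10))$values, c(3, 3, 3))
  # 2x2 ROI over pixels {0, 0, 10, 10} -> 5
  fr <- array(0, c(4, 4, 1)); fr[1, 2, 1] <- 10; fr[2, 2, 1] <- 10
  st2 <- frame_stack(fr, 300)
  expect_equal(roi_mean_trace(st2, roi(0, 0, 2, 2))$values, 5)
  # horizontal gradient: column index (0-based) as value, cols [10, 20) -> 14.5
  grad <- array(rep(0:29, each = 5), c(5, 30, 1))
  st3 <- frame_stack(grad, 300)
  expect_equal(roi_mean_trace(st3, roi(0, 10, 5, 20))$values, 14.5)
  expect_error(roi_mean_trace(st2, roi(0, 0, 9, 2)), "bounds")
})

test_that("reference subtraction cancels common-mode signal exactly", {
  n <- 500; fps <- 300
  a <- sin(seq_len(n) / 10)
  h <- lapply(c(10, 20, 30), function(k) intensity_trace(rep(k, n), fps))
  ref <- intensity_trace(rep(5, n), fps)
  expect_equal(cardiac_signal(h, ref)$values, rep(15, n))
  # adding any common-mode artifact to all four traces changes nothing
  v <- 3 * cos(seq_len(n) / 7)
  h2 <- lapply(h, function(tr) intensity_trace(tr$values + v, fps))
  ref2 <- intensity_trace(ref$values + v, fps)
  expect_equal(cardiac_signal(h2, ref2)$values,
               cardiac_signal(h, ref)$values, tolerance = 1e-12)
  # heart traces equal to a(t) with zero reference pass through
  ha <- lapply(1:3, function(i) intensity_trace(a, fps))
  expect_equal(cardiac_signal(ha, intensity_trace(rep(0, n), fps))$values, a)
  expect_error(cardiac_signal(h[1:2], ref), "3 traces")
  expect_error(
    cardiac_signal(h, intensity_trace(rep(0, n - 1), fps)), "length")
})

test_that("moving average keeps length, mass and linear ramps", {
  fps <- 300
  expect_equal(smooth_trace(intensity_trace(rep(7, 100), fps))$values,
               rep(7, 100))
  # unit impulse spreads into 21 values of 1/21
  imp <- rep(0, 101); imp[51] <- 1
  sm <- smooth_trace(intensity_trace(imp, fps), 21)$values
  expect_equal(sm[41:61], rep(1 / 21, 21))
  expect_equal(sum(sm[sm > 0]), 1)
  # linear ramp unchanged in the interior (centred mean of a linear sequence)
  ramp <- seq(0, 10, length.out = 200)
  smr <- smooth_trace(intensity_trace(ramp, fps), 21)$values
  expect_equal(smr[11:190], ramp[11:190])
  # truncated-edge convention: length preserved, constants exact at edges
  expect_length(smr, 200)
  # mean preservation on random traces (truncated windows reweight edges
  # only slightly; interior mass is conserved)
  set.seed(3)
  x <- rnorm(5000)
  expect_equal(mean(smooth_trace(intensity_trace(x, fps), 21)$values),
               mean(x), tolerance = 1e-2)
  expect_error(smooth_trace(intensity_trace(x, fps), 20), "odd")
  expect_error(smooth_trace(intensity_trace(rnorm(5), fps), 7), "length")
})

test_that("diastole minima of a clean cosine fall at the analytic positions", {
  tr <- cosine_trace(n = 1000, period = 100)
  m <- detect_diastole_minima(tr, min_separation = 60, min_prominence = 0.5)
  expect_identical(m, as.integer(seq(50, 950, by = 100)) + 1L)
  # constant trace: no minima, not an error
  expect_identical(
    detect_diastole_minima(intensity_trace(rep(1, 100), 300)),
    integer(0))
  expect_error(
    detect_diastole_minima(intensity_trace(c(1, 2), 300)), "short")
})

test_that("minima detection survives noise within a small frame tolerance", {
  tr <- cosine_trace(n = 1000, period = 100, noise_sd = 0.01, seed = 7)
  m <- detect_diastole_minima(tr, min_separation = 60, min_prominence = 0.5)
  expect_length(m, 10L)
  # brute-force oracle: scan each analytic trough's neighbourhood
  truth <- sapply(seq(50, 950, by = 100) + 1, function(c0) {
    win <- max(1, c0 - 10):min(1000, c0 + 10)
    win[which.min(tr$values[win])]
  })
  expect_true(all(abs(m - truth) == 0))
  expect_true(all(abs(m - (seq(50, 950, by = 100) + 1)) <= 2))
})

test_that("minima detection is invariant to affine intensity changes", {
  tr <- cosine_trace(n = 1000, period = 100, noise_sd = 0.02, seed = 9)
  m0 <- detect_diastole_minima(tr, min_separation = 60, min_prominence = 0.5)
  shifted <- intensity_trace(tr$values + 42, tr$fps)
  expect_identical(
    detect_diastole_minima(shifted, 60, 0.5), m0)
  scaled <- intensity_trace(tr$values * 3, tr$fps)
  expect_identical(
    detect_diastole_minima(scaled, 60, 1.5), m0)
})

test_that("interbeat intervals and beat-by-beat rates follow their formulas", {
  expect_equal(interbeat_intervals(c(50, 150, 250)), c(100, 100))
  expect_equal(interbeat_intervals(c(0, 106, 212, 318)), c(106, 106, 106))
  expect_error(interbeat_intervals(100), "2 minima")
  expect_equal(beat_by_beat_hr(300, 300), 60)
  expect_equal(beat_by_beat_hr(100, 300), 180)
  expect_equal(beat_by_beat_hr(105.88, 300), 170.0, tolerance = 0.01 / 170)
  expect_error(beat_by_beat_hr(0, 300), "> 0")
})

test_that("steady-state averaging uses only beats wholly inside the window", {
  fps <- 300
  # constant 170 bpm: minima every 105.88.. frames
  minima <- round(seq(1, by = fps * 60 / 170, length.out = 200))
  b <- beat_series(minima, fps)
  s <- steady_state_hr(b, window_seconds = 60)
  expect_equal(s$mean_bpm, 170, tolerance = 5e-3)
  # alternating 160/180 bpm gives mean 170
  ib <- rep(c(fps * 60 / 160, fps * 60 / 180), 60)
  minima2 <- cumsum(c(1, ib))
  b2 <- beat_series(minima2, fps)
  s2 <- steady_state_hr(b2, window_seconds = 50)  # covers all 120 beats
  expect_equal(s2$mean_bpm, 170)
  # a beat straddling the window end is excluded
  b3 <- beat_series(c(1, 200, 400, 700), 100)  # times 0, ~2, ~4, ~7 s
  s3 <- steady_state_hr(b3, window_seconds = 5)
  expect_identical(s3$n_beats, 2L)
  expect_error(steady_state_hr(b3, window_seconds = 2.5), "window")
})

test_that("full pipeline recovers the generator's rate from traces", {
  p <- heart_sim_params(true_hr_bpm = 165, duration_s = 120, seed = 21)
  tr <- gen_heart_trace(p)
  res <- run_heartrate_traces(tr$heart_traces, tr$reference_trace, fps = 300,
                              window_seconds = 120)
  expect_s3_class(res$summary, "heart_rate_summary")
  expect_equal(res$summary$mean_bpm, 165, tolerance = 1 / 165)
  # number of beats in the window is near rate * window / 60
  expect_equal(res$summary$n_beats, 165 * 120 / 60, tolerance = 0.03)
})

test_that("pipeline reports absence of beats instead of crashing", {
  # ventilation-only traces: reference subtraction leaves pure noise
  p <- heart_sim_params(true_hr_bpm = 170, duration_s = 20, seed = 3,
                        cardiac_amplitude = 1e-9, noise_sd = 0.05,
                        ventilation_amplitude = 5)
  tr <- gen_heart_trace(p)
  res <- run_heartrate_traces(tr$heart_traces, tr$reference_trace, fps = 300,
                              window_seconds = 20,
                              min_prominence = 1)
  expect_null(res$summary)
  expect_identical(res$n_minima, 0L)
})

test_that("reference subtraction matters exactly when ventilation is present", {
  run_hr <- function(vent, subtract) {
    p <- heart_sim_params(true_hr_bpm = 170, duration_s = 60, seed = 12,
                          ventilation_amplitude = vent)
    tr <- gen_heart_trace(p)
    res <- run_heartrate_traces(tr$heart_traces, tr$reference_trace,
                                fps = 300, window_seconds = 60,
                                subtract_reference = subtract)
    if (is.null(res$summary)) NA_real_ else res$summary$mean_bpm
  }
  # strong ventilation: disabling the subtraction moves the estimate more
  # than it does with no ventilation at all
  d_high <- abs(run_hr(20, TRUE) - run_hr(20, FALSE))
  d_zero <- abs(run_hr(0, TRUE) - run_hr(0, FALSE))
  expect_true(is.na(d_high) || d_high > d_zero)
  expect_lt(d_zero, 0.5)
})

test_that("recovered rate stays within 1 bpm across the physiological sweep", {
  rates <- c(120, 150, 165, 170, 174, 200)
  n_rep <- 20
  ok <- 0L; total <- 0L
  for (r in rates) {
    for (s in seq_len(n_rep)) {
      p <- heart_sim_params(true_hr_bpm = r, duration_s = 120,
                            seed = 1000 * r + s)
      tr <- gen_heart_trace(p)
      res <- run_heartrate_traces(tr$heart_traces, tr$reference_trace,
                                  fps = 300, window_seconds = 120)
      total <- total + 1L
      if (!is.null(res$summary) &&
          abs(res$summary$mean_bpm - r) <= 1) ok <- ok + 1L
    }
  }
  expect_gte(ok / total, 0.95)
})

test_that("trace and beat CSV export round-trips the pipeline output", {
  p <- heart_sim_params(true_hr_bpm = 150, duration_s = 30, seed = 5)
  tr <- gen_heart_trace(p)
  res <- run_heartrate_traces(tr$heart_traces, tr$reference_trace, fps = 300,
                              window_seconds = 30)
  stem <- file.path(withr::local_tempdir(), "hr")
  paths <- write_heartrate_csv(res, stem)
  expect_true(all(file.exists(paths)))
  beats <- read.csv(paths[2])
  expect_equal(beats$hr_bpm, res$beats$hr_bpm)
  expect_equal(nrow(read.csv(paths[1])), 30 * 300)
})
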