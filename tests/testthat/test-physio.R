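test_that("an 80 s belt at 8 s period yields exactly 10 cycles of 200 points", {
  p <- signal_params(duration_s = 80, resp_freq_hz = 0.125)
  ph <- generate_physio(p, 64, 5, 50)
  cyc <- segment_cycles(ph$belt)
  expect_equal(nrow(cyc$cycles), 10)
  expect_equal(ncol(cyc$normalized), 200)
  expect_equal(cyc$valley_times, seq(0, 80, by = 8), tolerance = 0.05)
  expect_false(anyNA(cyc$normalized))
})

test_that("cycle segmentation rejects degenerate belts", {
  ramp <- tibble::tibble(time_s = seq(0, 60, by = 0.02),
                         value = seq(0, 1, length.out = 3001))
  expect_error(segment_cycles(ramp), "cycle")
  flat <- tibble::tibble(time_s = seq(0, 60, by = 0.02), value = 1)
  expect_error(segment_cycles(flat), "Flat")
})

test_that("respiratory features report timing on constructed cycles", {
  # triangular cycles: inhale 3 s, exhale 2 s
  one <- c(seq(0, 1, length.out = 151)[-151], seq(1, 0, length.out = 101)[-101])
  belt <- tibble::tibble(time_s = seq_len(5 * 250 + 1) * 0.02 - 0.02,
                         value = c(rep(one, 5), 0))
  cyc <- segment_cycles(belt)
  rf <- respiratory_features(belt, cyc)
  sc <- glance(rf)
  expect_equal(sc$cycle_length, 5, tolerance = 1e-6)
  expect_equal(sc$respiratory_rate, 12, tolerance = 1e-6)
  expect_equal(sc$inhale_length, 3, tolerance = 0.05)
  expect_equal(sc$ie_ratio, 1.5, tolerance = 0.05)
  # the sum rule holds exactly per cycle
  expect_equal(rf$inhale_length + rf$exhale_length, rf$cycle_length,
               tolerance = 1e-9)
})

test_that("generator inhale fraction propagates to the I:E ratio", {
  p <- signal_params(duration_s = 140, resp_freq_hz = 0.125,
                     inhale_frac = 0.6)
  ph <- generate_physio(p, 64, 5, 50)
  cyc <- segment_cycles(ph$belt)
  sc <- glance(respiratory_features(ph$belt, cyc))
  expect_equal(sc$ie_ratio, 1.5, tolerance = 0.05)
  expect_equal(sc$respiratory_rate, 60 / mean(cyc$cycles$end_s - cyc$cycles$onset_s),
               tolerance = 1e-9)
  # symmetric breathing gives unit ratio
  p2 <- signal_params(duration_s = 140, resp_freq_hz = 0.125,
                      inhale_frac = 0.5)
  ph2 <- generate_physio(p2, 64, 5, 50)
  sc2 <- glance(respiratory_features(ph2$belt, segment_cycles(ph2$belt)))
  expect_equal(sc2$ie_ratio, 1, tolerance = 0.02)
})

test_that("PPG-to-HR recovers constant and modulated rates", {
  p <- signal_params(duration_s = 140, resp_freq_hz = 0.1)
  ph <- generate_physio(p, 64, 0, 100)
  hr <- ppg_to_hr(ph$ppg)
  expect_equal(mean(hr$hr_bpm), 64, tolerance = 0.05)
  expect_lt(diff(range(hr$hr_bpm)), 0.2)
  # RSA modulation: the HR series swings rsa/2 about the baseline
  ph2 <- generate_physio(p, 64, 5, 100)
  hr2 <- ppg_to_hr(ph2$ppg)
  mid <- hr2$time_s > 20 & hr2$time_s < 120
  expect_equal(max(hr2$hr_bpm[mid]), 66.5, tolerance = 0.2)
  expect_equal(min(hr2$hr_bpm[mid]), 61.5, tolerance = 0.2)
  expect_error(ppg_to_hr(tibble::tibble(time_s = 1:10 / 10, value = 0)),
               "Flat|beats")
})

test_that("missing beats are flagged as gaps, not interpolated as one beat", {
  p <- signal_params(duration_s = 80, resp_freq_hz = 0.125)
  ph <- generate_physio(p, 60, 0, 100)
  # blank out three seconds of signal (three beats at 60 bpm)
  ppg <- ph$ppg
  ppg$value[ppg$time_s > 40 & ppg$time_s < 43] <- 0
  hr <- ppg_to_hr(ppg)
  expect_gte(attr(hr, "qc")$n_gaps, 1)
  # the gap is excluded from support, so HR nearby stays near 60
  expect_equal(median(hr$hr_bpm), 60, tolerance = 0.5)
})

test_that("HR displacement matches the RSA closed form", {
  p <- signal_params(duration_s = 140, resp_freq_hz = 0.1)
  for (rsa in c(1, 2.5, 5)) {
    ph <- generate_physio(p, 64, rsa, 100)
    cyc <- segment_cycles(ph$belt)
    hr <- ppg_to_hr(ph$ppg, grid = ph$belt$time_s)
    hd <- hr_displacement(hr, cyc)
    expect_equal(hd$hr_displacement_bpm, rsa, tolerance = 0.02 * rsa)
  }
  # constant HR gives zero displacement
  ph0 <- generate_physio(p, 64, 0, 100)
  hd0 <- hr_displacement(ppg_to_hr(ph0$ppg, grid = ph0$belt$time_s),
                         segment_cycles(ph0$belt))
  expect_lt(hd0$hr_displacement_bpm, 0.1)
})

test_that("subject-wise bandpass separates respiratory and cardiac content", {
  dt <- 0.19
  tt <- seq(0, 140 - dt, by = dt)
  v <- sin(2 * pi * 0.125 * tt) + sin(2 * pi * 1.2 * tt)
  tc <- csfflow:::new_flow_timecourse(
    tibble::tibble(time_s = tt, velocity_raw = v, velocity = v),
    grid_geometry(), 52L, dt)
  amp_of <- function(x, f) {
    fit <- lm(x ~ sin(2 * pi * f * tt) + cos(2 * pi * f * tt))
    sqrt(sum(coef(fit)[2:3]^2))
  }
  resp <- bandpass_subjectwise(tc, 0.125, "respiratory")
  expect_gt(amp_of(resp$velocity, 0.125), 0.95)       # in-band within 5%
  expect_lt(amp_of(resp$velocity, 1.2), 0.1)          # >= 20 dB down
  card <- bandpass_subjectwise(tc, 1.2, "cardiac")
  expect_gt(amp_of(card$velocity, 1.2), 0.95)
  expect_lt(amp_of(card$velocity, 0.125), 0.1)
  expect_error(bandpass_subjectwise(tc, 2.0, "cardiac", half_width = 1),
               "Nyquist")
  expect_error(bandpass_subjectwise(tc, 0.7, "respiratory"), "outside")
})

test_that("venous features isolate respiratory and cardiac components", {
  p <- validation_params(resp_amp = 0.4, cardiac_amp = 0.02, seed = 41)
  gen <- generate_velocity_series(p, grid_geometry(), default_roi_spec())
  ph <- generate_physio(p, 72, 3, 50)
  cyc <- segment_cycles(ph$belt)
  stc <- detrend_linear(extract_mean_velocity(gen$series, gen$truth$roi_mask))
  vf <- venous_features(stc, cyc, resp_freq = p$resp_freq_hz,
                        cardiac_freq = 1.2)
  expect_equal(vf$sss_displacement_resp, vf$sss_displacement,
               tolerance = 0.02 * vf$sss_displacement)
  expect_lt(vf$sss_displacement_cardio, 0.05 * vf$sss_displacement)
  # zero signal gives all-zero features
  gen0 <- gen
  gen0$series$data[] <- 0
  stc0 <- extract_mean_velocity(gen0$series, gen$truth$roi_mask)
  stc0$velocity <- stc0$velocity # flat; detrend would fit exactly
  vf0 <- venous_features(stc0, cyc, p$resp_freq_hz, 1.2)
  expect_lt(max(abs(unlist(vf0))), 1e-9)
})
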