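test_that("fixed seed gives bit-identical velocity series", {
  p <- signal_params(noise_sd_cm_s = 0.2, seed = 9L)
  g1 <- generate_velocity_series(p, grid_geometry(), default_roi_spec())
  g2 <- generate_velocity_series(p, grid_geometry(), default_roi_spec())
  expect_identical(g1$series$data, g2$series$data)
})

test_that("noiseless oracle quantities match closed forms", {
  # pure cardiac sinusoid: mean speed = 2A/pi
  p <- signal_params(cardiac_amp_cm_s = 1, resp_amp_cm_s = 0,
                     drift_cm_s_per_s = 0, noise_sd_cm_s = 0)
  g <- generate_velocity_series(p, grid_geometry(), default_roi_spec())
  expect_equal(g$truth$mean_speed_cm_s, 2 / pi, tolerance = 1e-3)
  # doubling the amplitude doubles the oracle mean speed (linearity)
  p2 <- signal_params(cardiac_amp_cm_s = 2, resp_amp_cm_s = 0,
                      noise_sd_cm_s = 0)
  g2 <- generate_velocity_series(p2, grid_geometry(), default_roi_spec())
  expect_equal(g2$truth$mean_speed_cm_s / g$truth$mean_speed_cm_s, 2,
               tolerance = 1e-9)
})

test_that("zero-amplitude parameters give an all-zero ROI series", {
  p <- signal_params(cardiac_amp_cm_s = 0, resp_amp_cm_s = 0,
                     offset_cm_s = 0, noise_sd_cm_s = 0)
  g <- generate_velocity_series(p, grid_geometry(), default_roi_spec())
  expect_equal(max(abs(g$series$data)), 0)
  expect_equal(max(g$truth$per_cycle_displacement_ml), 0, tolerance = 1e-12)
  expect_equal(max(g$truth$per_cycle_net_flow_ul), 0, tolerance = 1e-9)
})

test_that("injected net volume appears in the oracle per-cycle integral", {
  p <- validation_params(net_ul = 50)
  g <- generate_velocity_series(p, grid_geometry(), default_roi_spec())
  expect_true(all(abs(g$truth$per_cycle_raw_integral_ul - 50) < 0.1))
  expect_equal(mean(g$truth$per_cycle_net_flow_ul), 50, tolerance = 0.01)
})

test_that("infeasible net volume errors with the feasible bound", {
  p <- signal_params(resp_amp_cm_s = 0.05, net_volume_per_cycle_ul = 500)
  expect_error(generate_velocity_series(p, grid_geometry(), default_roi_spec()),
               "feasible bound")
  # zero respiratory amplitude cannot carry any net volume
  p0 <- signal_params(resp_amp_cm_s = 0, net_volume_per_cycle_ul = 10)
  expect_error(generate_velocity_series(p0, grid_geometry(), default_roi_spec()),
               "feasible bound")
})

test_that("an ROI outside the grid is rejected", {
  p <- signal_params()
  expect_error(
    generate_velocity_series(p, grid_geometry(8L, 8L),
                             cbind(row = c(1, 9), col = c(1, 1))),
    "outside the grid")
})

test_that("parameter validation enforces the stated bounds", {
  expect_error(signal_params(inhale_frac = 1.2))
  expect_error(signal_params(cardiac_freq_hz = 2.5))
  expect_error(signal_params(duration_s = 10, resp_freq_hz = 0.1))
})

test_that("physio generator is phase-locked with known RSA ground truth", {
  p <- signal_params(duration_s = 80, resp_freq_hz = 0.125)
  ph <- generate_physio(p, hr0_bpm = 64, rsa_amp_bpm = 5, fs_hz = 50)
  expect_equal(ph$truth$hr_displacement_bpm, 5)
  # belt valleys at 8 s spacing starting at the record onset
  expect_equal(ph$truth$valley_times_s, seq(0, 80, by = 8))
  v <- ph$belt$value[match(seq(0, 80, by = 8), ph$belt$time_s)]
  expect_true(all(v <= min(ph$belt$value) + 1e-9))
  # constant rate when RSA is zero: uniform inter-beat intervals
  ph0 <- generate_physio(p, hr0_bpm = 64, rsa_amp_bpm = 0, fs_hz = 50)
  ibi <- diff(ph0$truth$beat_times_s)
  expect_lt(diff(range(ibi)), 1e-6)
  expect_equal(mean(ibi), 60 / 64, tolerance = 1e-6)
})

test_that("excessive RSA amplitude is rejected", {
  p <- signal_params()
  expect_error(generate_physio(p, hr0_bpm = 40, rsa_amp_bpm = 90),
               "nonpositive")
})

test_that("landmark generator produces a breathing square with known area", {
  p <- signal_params(duration_s = 80, resp_freq_hz = 0.125)
  lt <- generate_landmark_tracks(p, side_px = 10, amp_px = 2)
  mm <- compute_motion_metrics(lt$track)
  expect_equal(min(mm$lung_area), 100, tolerance = 1e-6)
  expect_equal(max(mm$lung_area), 144, tolerance = 0.1)
  # zero amplitude freezes every metric
  lt0 <- generate_landmark_tracks(p, side_px = 10, amp_px = 0)
  mm0 <- compute_motion_metrics(lt0$track)
  expect_equal(diff(range(mm0$lung_area)), 0)
  expect_equal(diff(range(mm0$diaphragm_3)), 0)
})

test_that("degenerate landmark contours are rejected", {
  p <- signal_params()
  expect_error(generate_landmark_tracks(p, side_px = 5, amp_px = -6),
               "degenerate")
})

test_that("phantom sessions carry the imposed amplitude and frequency", {
  ph <- generate_phantom_session("cardiac_2", "forward", noise_sd_cm_s = 0)
  tube <- which(ph$truth$tube_mask)
  v <- apply(ph$series$data, 3, function(fr) mean(fr[tube]))
  expect_equal(max(abs(v)), 2, tolerance = 0.01)
  # dominant spectral peak of the 8 s condition at 0.125 Hz
  ph2 <- generate_phantom_session("resp_3", "forward", noise_sd_cm_s = 0)
  spec <- compute_power_spectrum(ph2$series, c(0.01, 0.5))
  tube_freqs <- spec$peak_freq[ph2$truth$tube_mask]
  expect_lt(abs(median(tube_freqs) - 0.125), spec$delta_f_hz)
  expect_error(generate_phantom_session("bogus"), "cardiac_1")
})

test_that("forward and reverse phantom flows are sign-mirrored", {
  f <- generate_phantom_session("resp_2", "forward", noise_sd_cm_s = 0)
  r <- generate_phantom_session("resp_2", "reverse", noise_sd_cm_s = 0)
  expect_equal(f$series$data, -r$series$data)
})
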