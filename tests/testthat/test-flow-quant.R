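test_that("ROI-mean extraction averages the masked voxels", {
  arr <- array(0, dim = c(2, 2, 10))
  arr[1, 1, ] <- 1
  arr[2, 1, ] <- 3
  s <- velocity_series(arr, dt_s = 0.19)
  m <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  tc <- extract_mean_velocity(s, m)
  expect_equal(unique(tc$velocity), 2)
  expect_equal(attr(tc, "roi_size"), 2L)
  expect_error(extract_mean_velocity(s, matrix(FALSE, 2, 2)), "Empty")
})

test_that("averaging reduces frame noise by sqrt(roi size)", {
  p <- signal_params(cardiac_amp_cm_s = 0, resp_amp_cm_s = 0,
                     offset_cm_s = 0, noise_sd_cm_s = 0.1, seed = 21)
  gen <- generate_velocity_series(p, grid_geometry(), default_roi_spec())
  tc <- extract_mean_velocity(gen$series, gen$truth$roi_mask)
  expect_equal(stats::sd(tc$velocity), 0.1 / sqrt(52), tolerance = 0.1)
})

test_that("linear detrend removes lines and is idempotent", {
  tc <- sinusoid_timecourse(0, duration = 50)
  tc$velocity <- 0.5 + 0.02 * tc$time_s
  out <- detrend_linear(tc)
  expect_lt(max(abs(out$velocity)), 1e-12)
  # sinusoid plus drift: the oscillation survives
  tc2 <- sinusoid_timecourse(1, freq = 1, duration = 140)
  tc2$velocity <- tc2$velocity + 0.02 * tc2$time_s + 0.3
  out2 <- detrend_linear(tc2)
  expect_equal(out2$velocity, sin(2 * pi * out2$time_s), tolerance = 0.02)
  # idempotence
  out3 <- detrend_linear(out2)
  expect_equal(out2$velocity, out3$velocity, tolerance = 1e-10)
})

test_that("peak detection recovers sinusoid extrema with refinement", {
  tc <- sinusoid_timecourse(1, freq = 1, duration = 140)
  pk <- detect_peaks_valleys(tc, cardiac_freq = 1)
  qc <- attr(pk, "qc")
  expect_true(abs(qc$n_peaks - 140) <= 1)
  expect_equal(mean(pk$value[pk$type == "peak"]), 1, tolerance = 0.02)
  expect_equal(mean(pk$value[pk$type == "valley"]), -1, tolerance = 0.02)
  # alternation
  expect_true(all(rle(pk$type)$lengths == 1))
  # flat input errors
  tcf <- sinusoid_timecourse(0, duration = 50)
  expect_error(detect_peaks_valleys(tcf, 1), "Flat")
})

test_that("velocity summary reproduces closed-form sinusoid features", {
  tc <- sinusoid_timecourse(1, freq = 1.2, duration = 140)
  pk <- detect_peaks_valleys(tc, 1.2)
  vs <- velocity_summary(tc, pk)
  expect_equal(vs$mean_speed, 2 / pi, tolerance = 0.01)
  expect_equal(vs$mean_peak_to_peak, 2, tolerance = 0.02 * 2)
  expect_lt(abs(vs$mean_pv), 0.02)
  expect_equal(vs$mean_peak_to_peak, vs$mean_peak - vs$mean_valley)
  expect_gte(vs$mean_peak, vs$mean_valley)
  # the alternative mean-PV definition
  vs2 <- velocity_summary(tc, pk, pv_definition = "difference")
  expect_equal(vs2$mean_pv, vs2$mean_peak_to_peak)
})

test_that("flow-rate conversion follows the unit chain", {
  tc <- sinusoid_timecourse(0, duration = 10)
  tc$velocity <- rep(1, nrow(tc))
  g <- grid_geometry(pixel_area_mm2 = 1.6128)
  out <- velocity_to_flowrate(tc, g, roi_size = 20)
  expect_equal(unique(out$flow_rate), 0.32256)
  # doubling the ROI doubles the flow rate
  out2 <- velocity_to_flowrate(tc, g, roi_size = 40)
  expect_equal(unique(out2$flow_rate), 2 * 0.32256)
  # zero velocity gives zero flow
  tc$velocity <- rep(0, nrow(tc))
  expect_equal(unique(velocity_to_flowrate(tc, g, 20)$flow_rate), 0)
  # the literal formula adds the slice-thickness factor (3 mm / 10)
  tc$velocity <- rep(1, nrow(tc))
  lit <- velocity_to_flowrate(tc, g, 20, formula = "literal")
  expect_equal(unique(lit$flow_rate), 0.32256 * 0.3)
})

test_that("volume integration is exact for constants and closes sine loops", {
  tc <- sinusoid_timecourse(0, duration = 10.07, dt = 0.19)
  tc$flow_rate <- rep(1, nrow(tc))
  out <- integrate_volume(tc)
  expect_equal(out$volume[1], 0)
  expect_equal(out$volume, out$time_s, tolerance = 1e-12)
  # a full-period sine returns to ~0
  tc2 <- sinusoid_timecourse(1, freq = 0.5, duration = 140)
  tc2$flow_rate <- sin(2 * pi * 0.5 * tc2$time_s)
  out2 <- integrate_volume(tc2)
  ends <- out2$volume[abs((out2$time_s %% 2)) < 1e-9]
  expect_lt(max(abs(ends)), 1e-3)
})

test_that("per-cycle features recover displacement and net flow arithmetic", {
  # volume excursion +0.15 / -0.05 ml within each 8 s cycle: two half-sine
  # lobes with unequal amplitudes
  dt <- 0.19
  tt <- seq(0, 18 * 7.98 + dt - 1e-9, by = dt)
  u <- 2 * pi * tt / 7.98
  vol <- ifelse(sin(u) >= 0, 0.15, 0.05) * sin(u)
  q <- c(diff(vol) / dt, 0)
  tc <- csfflow:::new_flow_timecourse(
    tibble::tibble(time_s = tt, velocity_raw = q, velocity = q,
                   flow_rate = q, volume = vol),
    grid_geometry(), 52L, dt)
  p <- validation_params()
  ph <- generate_physio(p, 72, 0, 50)
  cyc <- segment_cycles(ph$belt)
  cf <- cycle_flow_features(tc, cyc)
  sc <- glance(cf)
  expect_equal(sc$displacement, 0.20, tolerance = 0.01)
  expect_equal(sc$net_flow, 100, tolerance = 2)
  expect_true(all(cf$net_flow <= 1000 * cf$displacement + 1e-9))
})

test_that("generator net volume is recovered through the full chain", {
  p <- validation_params(net_ul = 50)
  gen <- generate_velocity_series(p, grid_geometry(), default_roi_spec())
  ph <- generate_physio(p, 72, 0, 50)
  res <- quantify_session(gen, ph$belt)
  expect_equal(res$scan$net_flow, mean(gen$truth$per_cycle_net_flow_ul),
               tolerance = 0.05 * 50)
  expect_equal(res$scan$displacement,
               mean(gen$truth$per_cycle_displacement_ml), tolerance = 0.01)
})

test_that("the pipeline is sign-symmetric in the velocity", {
  p <- validation_params(net_ul = 40, cardiac_amp = 1, noise_sd = 0.1,
                         seed = 31)
  gen <- generate_velocity_series(p, grid_geometry(), default_roi_spec())
  ph <- generate_physio(p, 72, 0, 50)
  res <- quantify_session(gen, ph$belt)
  gen_neg <- gen
  gen_neg$series$data <- -gen$series$data
  res_neg <- quantify_session(gen_neg, ph$belt)
  for (f in c("displacement", "net_flow")) {
    expect_equal(res_neg$scan[[f]], res$scan[[f]], tolerance = 1e-9)
  }
  tc <- detrend_linear(extract_mean_velocity(gen$series, gen$truth$roi_mask))
  tcn <- detrend_linear(extract_mean_velocity(gen_neg$series,
                                              gen$truth$roi_mask))
  expect_equal(mean(abs(tcn$velocity)), mean(abs(tc$velocity)),
               tolerance = 1e-12)
})
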