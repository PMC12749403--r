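# Build a small grid where chosen voxels carry pure sinusoids and the rest
# carry white noise.
toy_series <- function(freqs, noise_sd = 0.1, n_rows = 8, n_cols = 8,
                       duration = 140, dt = 0.19, seed = 1) {
  set.seed(seed)
  tt <- (seq_len(ceiling(duration / dt - 1e-6)) - 1) * dt
  arr <- array(rnorm(n_rows * n_cols * length(tt), sd = noise_sd),
               dim = c(n_rows, n_cols, length(tt)))
  for (nm in names(freqs)) {
    ij <- as.integer(strsplit(nm, ",")[[1]])
    arr[ij[1], ij[2], ] <- arr[ij[1], ij[2], ] + sin(2 * pi * freqs[[nm]] * tt)
  }
  velocity_series(arr, dt_s = dt)
}

test_that("per-voxel spectra localize a pure tone and report delta-f", {
  s <- toy_series(list(`3,4` = 1.2), noise_sd = 0)
  spec <- compute_power_spectrum(s, c(0.8, 2))
  expect_equal(spec$delta_f_hz, 1 / (737 * 0.19), tolerance = 1e-12)
  expect_equal(spec$delta_f_hz, 1 / 140, tolerance = 1e-3)
  expect_equal(spec$peak_freq[3, 4], 1.2, tolerance = spec$delta_f_hz)
  # constant series: essentially no in-band power
  s0 <- velocity_series(array(2, dim = c(4, 4, 737)), dt_s = 0.19)
  sp0 <- compute_power_spectrum(s0, c(0.8, 2))
  in_band <- sp0$freq_hz >= 0.8 & sp0$freq_hz <= 2
  expect_lt(max(sp0$power[, in_band]), 1e-12)
})

test_that("bands beyond Nyquist are rejected", {
  s <- toy_series(list(), noise_sd = 0.1)
  expect_error(compute_power_spectrum(s, c(0.8, 3)), "Nyquist")
})

test_that("relative spectral intensity separates tones from noise", {
  s <- toy_series(list(`2,2` = 1.2), noise_sd = 0.1, seed = 2)
  spec <- compute_power_spectrum(s, c(0.8, 2))
  ipi <- relative_spectral_intensity(spec)
  expect_true(all(ipi$values >= 0 & ipi$values <= 1))
  expect_gt(ipi$values[2, 2], 0.9)
  noise_vals <- ipi$values[-c(2 + (2 - 1) * 8)]
  expect_lt(stats::quantile(noise_vals, 0.99), 0.2)
  # flat voxels take the zero-denominator convention
  s0 <- velocity_series(array(1, dim = c(4, 4, 737)), dt_s = 0.19)
  sp0 <- compute_power_spectrum(s0, c(0.8, 2))
  expect_equal(max(relative_spectral_intensity(sp0)$values), 0)
})

test_that("center-frequency estimation prefers the PPG and reads the belt", {
  p <- signal_params(duration_s = 80, resp_freq_hz = 0.125)
  ph <- generate_physio(p, hr0_bpm = 64, rsa_amp_bpm = 0, fs_hz = 100)
  expect_equal(estimate_center_frequency("cardiac", ppg = ph$ppg),
               64 / 60, tolerance = 0.005)
  expect_equal(estimate_center_frequency("respiratory", belt = ph$belt),
               0.125, tolerance = 0.02)
  # PPG precedence over a conflicting spectrum
  s <- toy_series(list(`2,2` = 1.6), noise_sd = 0)
  spec <- compute_power_spectrum(s, c(0.8, 2))
  expect_equal(estimate_center_frequency("cardiac", ppg = ph$ppg, spec = spec),
               64 / 60, tolerance = 0.005)
  expect_equal(estimate_center_frequency("cardiac", spec = spec),
               1.6, tolerance = 0.01)
  expect_error(estimate_center_frequency("cardiac"), "ppg|spec")
})

test_that("ROI selection recovers the generator mask without false positives", {
  p <- signal_params(cardiac_freq_hz = 1.2, cardiac_amp_cm_s = 1,
                     resp_amp_cm_s = 0.15, noise_sd_cm_s = 0.1, seed = 11)
  gen <- generate_velocity_series(p, grid_geometry(), default_roi_spec())
  spec <- compute_power_spectrum(gen$series, c(0.8, 2))
  ipi <- relative_spectral_intensity(spec)
  mask <- build_roi_mask(ipi, spec, center_freq = 1.2, tolerance = 0.2,
                         percentile = 95)
  truth <- gen$truth$roi_mask
  expect_gte(sum(mask$mask & truth) / sum(truth), 0.95)
  expect_equal(sum(mask$mask & !truth), 0)
  expect_equal(mask$qc$n_voxels, sum(mask$mask))
  expect_gte(mask$qc$largest_component_fraction, 0.99)
})

test_that("out-of-tolerance distractor voxels are excluded", {
  s <- toy_series(list(`2,2` = 1.2, `2,3` = 1.2, `5,5` = 1.6, `5,6` = 1.6),
                  noise_sd = 0.05, seed = 3)
  spec <- compute_power_spectrum(s, c(0.8, 2))
  ipi <- relative_spectral_intensity(spec)
  mask <- build_roi_mask(ipi, spec, center_freq = 1.2, tolerance = 0.2,
                         percentile = 90, denoise = FALSE)
  expect_true(mask$mask[2, 2] && mask$mask[2, 3])
  expect_false(mask$mask[5, 5] || mask$mask[5, 6])
})

test_that("the mask is invariant to global velocity scaling", {
  p <- signal_params(noise_sd_cm_s = 0.1, seed = 4)
  gen <- generate_velocity_series(p, grid_geometry(), default_roi_spec())
  masks <- lapply(c(1, 7.5), function(k) {
    s <- gen$series
    s$data <- s$data * k
    spec <- compute_power_spectrum(s, c(0.8, 2))
    build_roi_mask(relative_spectral_intensity(spec), spec, 1.2, 0.2, 95)$mask
  })
  expect_identical(masks[[1]], masks[[2]])
})

test_that("raising the percentile never grows the mask", {
  p <- signal_params(noise_sd_cm_s = 0.1, seed = 5)
  gen <- generate_velocity_series(p, grid_geometry(), default_roi_spec())
  spec <- compute_power_spectrum(gen$series, c(0.8, 2))
  ipi <- relative_spectral_intensity(spec)
  sizes <- suppressWarnings(vapply(c(80, 90, 95, 99), function(pc) {
    sum(build_roi_mask(ipi, spec, 1.2, 0.2, pc, denoise = FALSE)$mask)
  }, numeric(1)))
  expect_true(all(diff(sizes) <= 0))
  # percentile 100 keeps at most the single maximum voxel
  m100 <- build_roi_mask(ipi, spec, 1.2, 0.2, 100, denoise = FALSE)
  expect_lte(sum(m100$mask), 1)
})

test_that("an empty mask raises an error carrying QC diagnostics", {
  s <- toy_series(list(`2,2` = 1.6), noise_sd = 0.05, seed = 6)
  spec <- compute_power_spectrum(s, c(0.8, 2))
  ipi <- relative_spectral_intensity(spec)
  # tolerance excludes the only strong voxel; threshold excludes the rest
  expect_error(build_roi_mask(ipi, spec, center_freq = 0.9, tolerance = 0.01,
                              percentile = 99.9),
               "Empty ROI mask")
})
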