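# Shared fixtures: validation sessions whose respiratory period (7.98 s) is
# commensurate with the 0.19 s frame grid and whose record spans 18 complete
# cycles plus the closing frame, so quadrature and detrending are exercised
# on a cleanly bounded record.

VAL_PERIOD <- 42 * 0.19 # 7.98 s
VAL_DURATION <- 18 * VAL_PERIOD + 0.19

validation_params <- function(net_ul = 0, inhale_frac = 0.6,
                              cardiac_amp = 0, resp_amp = 0.3,
                              noise_sd = 0, seed = 1L, ...) {
  signal_params(
    duration_s = VAL_DURATION, dt_s = 0.19,
    cardiac_freq_hz = 1.2, cardiac_amp_cm_s = cardiac_amp,
    resp_freq_hz = 1 / VAL_PERIOD, inhale_frac = inhale_frac,
    resp_amp_cm_s = resp_amp, net_volume_per_cycle_ul = net_ul,
    noise_sd_cm_s = noise_sd, seed = seed, ...
  )
}

# Run the flow-quantification chain on a generated session; returns the
# per-cycle features plus the intermediate objects.
quantify_session <- function(gen, belt, formula = "cross-section") {
  cycles <- segment_cycles(belt)
  tc <- extract_mean_velocity(gen$series, gen$truth$roi_mask)
  tc <- detrend_linear(tc)
  tc <- velocity_to_flowrate(tc, formula = formula)
  tc <- integrate_volume(tc)
  cf <- cycle_flow_features(tc, cycles)
  list(tc = tc, cycles = cycles, per_cycle = cf, scan = glance(cf))
}

# A pure-sinusoid single-ROI time course at the native sampling.
sinusoid_timecourse <- function(amp = 1, freq = 1.2, duration = 140,
                                dt = 0.19) {
  tt <- (seq_len(ceiling(duration / dt - 1e-6)) - 1) * dt
  v <- amp * sin(2 * pi * freq * tt)
  csfflow:::new_flow_timecourse(
    tibble::tibble(time_s = tt, velocity_raw = v, velocity = v),
    geometry = grid_geometry(), roi_size = 52L, dt_s = dt
  )
}
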