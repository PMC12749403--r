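#' Generate belt and PPG recordings phase-locked to the velocity generator
#'
#' The belt is `-cos(2*pi*phase(t))` with the same warped respiratory phase as
#' [generate_velocity_series()], so its valleys fall exactly at cycle onsets
#' and its peak at end-inhale. The PPG is a train of Gaussian pulses whose
#' beat times come from integrating the instantaneous heart rate
#' `hr0 + (rsa_amp/2) * sin(2*pi*resp_freq*t)`; the ground-truth heart-rate
#' displacement (max minus min of that rate) is therefore exactly `rsa_amp`.
#'
#' @param params A [signal_params()] object (supplies duration, respiratory
#'   frequency and inhale fraction).
#' @param hr0_bpm Baseline heart rate (beats per minute).
#' @param rsa_amp_bpm Peak-to-peak respiratory sinus arrhythmia (delta BPM).
#' @param fs_hz Sampling rate of both recordings (Hz, >= 20).
#' @param noise_sd Additive Gaussian noise SD on both traces (signal units).
#' @return List with `belt` and `ppg` tibbles (`time_s`, `value`) and `truth`
#'   (`hr_displacement_bpm`, `beat_times_s`, `valley_times_s`).
#' @export
generate_physio <- function(params, hr0_bpm = 64, rsa_amp_bpm = 5,
                            fs_hz = 50, noise_sd = 0) {
  stopifnot(inherits(params, "signal_params"), fs_hz >= 20, rsa_amp_bpm >= 0)
  if (hr0_bpm - rsa_amp_bpm / 2 <= 0) {
    abort("`rsa_amp_bpm` would make the instantaneous heart rate nonpositive.")
  }
  tt <- seq(0, params$duration_s, by = 1 / fs_hz)
  ph <- resp_phase(tt, params$resp_freq_hz, params$inhale_frac)
  belt_v <- -cos(2 * pi * ph$phase)

  # beat times: invert the cumulative beat count (trapezoid on a fine grid)
  dtf <- 1 / (fs_hz * 10)
  tf <- seq(0, params$duration_s, by = dtf)
  rate <- (hr0_bpm + rsa_amp_bpm / 2 *
             sin(2 * pi * params$resp_freq_hz * tf)) / 60 # beats/s
  beats_cum <- cumsum(c(0, (rate[-1] + rate[-length(rate)]) / 2 * dtf))
  n_beats <- floor(max(beats_cum))
  beat_times <- stats::approx(beats_cum, tf, xout = seq_len(n_beats))$y

  sigma <- 0.05 # s, Gaussian pulse width
  ppg_v <- numeric(length(tt))
  for (b in beat_times) {
    sel <- which(abs(tt - b) < 6 * sigma)
    ppg_v[sel] <- ppg_v[sel] + exp(-(tt[sel] - b)^2 / (2 * sigma^2))
  }
  if (noise_sd > 0) {
    set.seed(params$seed + 1L)
    belt_v <- belt_v + rnorm(length(tt), sd = noise_sd)
    ppg_v <- ppg_v + rnorm(length(tt), sd = noise_sd)
  }
  T_c <- 1 / params$resp_freq_hz
  valleys <- seq(0, params$duration_s + 1e-9, by = T_c)
  valleys <- valleys[valleys <= max(tt) + 1e-9]
  list(
    belt = tibble(time_s = tt, value = belt_v),
    ppg = tibble(time_s = tt, value = ppg_v),
    truth = list(hr_displacement_bpm = rsa_amp_bpm,
                 beat_times_s = beat_times,
                 valley_times_s = valleys)
  )
}

#' Generate diaphragm/chest landmark tracks with known motion amplitudes
#'
#' Eight landmarks trace a breathing rectangular lung contour: corners plus
#' edge midpoints, scaled about the centroid by
#' `1 + (amp/side) * (1 - cos(2*pi*phase))/2`, so the contour is at its exhale
#' baseline (side `side_px`) at every respiratory valley and maximally
#' expanded at end-inhale. All pairwise distances scale with the contour, and
#' the lung area is the squared side, giving closed-form ground truth for
#' every motion metric.
#'
#' @param params A [signal_params()] object (respiratory timing).
#' @param frame_dt_s Frame spacing of the track (s); default 0.857.
#' @param side_px Exhale-baseline side length of the square contour (pixels).
#' @param amp_px Peak increase of the side length over a cycle (pixels). May
#'   be a single number or a named per-landmark vector of radial scaling
#'   shares (all equal keeps the contour similar; zero freezes a landmark).
#' @param noise_sd_px Coordinate jitter SD (pixels).
#' @return List with `track` (tibble: `frame`, `landmark`, `x`, `y`,
#'   `likelihood`) and `truth` (baseline side, area range, scale range).
#' @export
generate_landmark_tracks <- function(params, frame_dt_s = 0.857,
                                     side_px = 20, amp_px = 4,
                                     noise_sd_px = 0) {
  stopifnot(inherits(params, "signal_params"), frame_dt_s > 0, side_px > 0)
  if (side_px + min(amp_px) <= 0) {
    abort("Contour would degenerate: `side_px + amp_px` must stay positive.")
  }
  tt <- seq(0, params$duration_s, by = frame_dt_s)
  ph <- resp_phase(tt, params$resp_freq_hz, params$inhale_frac)
  # unit square contour: corners and edge midpoints, counter-clockwise
  ux <- c(-1, 0, 1, 1, 1, 0, -1, -1) / 2
  uy <- c(-1, -1, -1, 0, 1, 1, 1, 0) / 2
  lm_names <- landmark_names()
  amp <- rep_len(amp_px, 8)
  names(amp) <- lm_names
  scale_t <- (1 - cos(2 * pi * ph$phase)) / 2 # 0 at valleys, 1 at end-inhale
  center <- c(x = 100, y = 100)
  rows <- vector("list", length(tt))
  if (noise_sd_px > 0) set.seed(params$seed + 2L)
  for (f in seq_along(tt)) {
    side_f <- side_px + amp * scale_t[f] # per-landmark radial side
    x <- center["x"] + ux * side_f
    y <- center["y"] + uy * side_f
    if (noise_sd_px > 0) {
      x <- x + rnorm(8, sd = noise_sd_px)
      y <- y + rnorm(8, sd = noise_sd_px)
    }
    rows[[f]] <- tibble(frame = f - 1L, landmark = lm_names,
                        x = unname(x), y = unname(y), likelihood = 1)
  }
  track <- dplyr::bind_rows(rows)
  attr(track, "frame_dt_s") <- frame_dt_s
  list(
    track = track,
    truth = list(
      baseline_side_px = side_px,
      area_range_px2 = c(side_px^2, (side_px + max(amp))^2),
      scale_range = c(1, 1 + max(amp) / side_px),
      frame_dt_s = frame_dt_s
    )
  )
}

#' Canonical landmark names and default role map
#'
#' @return `landmark_names()` gives the eight landmark labels in contour
#'   order; `default_landmark_map()` assigns the contour order and the five
#'   distance pairs (upper/lower chest, diaphragm 1--3).
#' @export
landmark_names <- function() {
  c("chest_upper_ant", "chest_upper_mid", "chest_upper_post",
    "chest_lateral", "diaphragm_post", "diaphragm_mid", "diaphragm_ant",
    "back_wall")
}

#' @rdname landmark_names
#' @export
default_landmark_map <- function() {
  list(
    contour = landmark_names(),
    upper_chest = c("chest_upper_ant", "chest_upper_post"),
    lower_chest = c("chest_lateral", "back_wall"),
    diaphragm_1 = c("diaphragm_ant", "chest_upper_ant"),
    diaphragm_2 = c("diaphragm_mid", "chest_upper_mid"),
    diaphragm_3 = c("diaphragm_post", "chest_upper_post")
  )
}

# The six imposed flow-phantom conditions: sinusoidal velocity amplitude
# (cm/s) and cycle length (s).
phantom_conditions <- function() {
  tibble(
    id = c("cardiac_1", "cardiac_2", "cardiac_3",
           "resp_1", "resp_2", "resp_3"),
    amp_cm_s = c(1, 2, 3, 1.5, 2, 2.5),
    period_s = c(1, 1, 1, 8, 8, 8)
  )
}

#' Generate a flow-phantom session
#'
#' A straight-tube phantom: a disc of voxels carries a pure sinusoidal
#' velocity at one of the six imposed conditions (amplitudes 1, 2, 3 cm/s at
#' a 1 s cycle; 1.5, 2, 2.5 cm/s at an 8 s cycle); surrounding voxels carry
#' noise only. Reverse direction negates the velocity sign.
#'
#' @param condition One of `"cardiac_1"`, `"cardiac_2"`, `"cardiac_3"`,
#'   `"resp_1"`, `"resp_2"`, `"resp_3"`.
#' @param direction `"forward"` or `"reverse"`.
#' @param duration_s,dt_s Acquisition timing.
#' @param noise_sd_cm_s Background noise SD.
#' @param seed Integer seed.
#' @return A list with `series` (a `velocity_series`), `truth` (imposed
#'   amplitude, frequency and tube mask).
#' @export
generate_phantom_session <- function(condition, direction = c("forward", "reverse"),
                                     duration_s = 140, dt_s = 0.19,
                                     noise_sd_cm_s = 0.05, seed = 1L) {
  direction <- match.arg(direction)
  cond <- phantom_conditions()
  if (!condition %in% cond$id) {
    abort(sprintf("Unknown phantom condition '%s'. Valid ids: %s.",
                  condition, paste(cond$id, collapse = ", ")))
  }
  row <- cond[cond$id == condition, ]
  geom <- grid_geometry(32L, 32L)
  # tube lumen: disc of radius 4 voxels at the grid centre
  cc <- expand.grid(row = 0:31, col = 0:31)
  inside <- (cc$row - 15.5)^2 + (cc$col - 15.5)^2 <= 16
  mask <- matrix(inside, 32, 32)
  n <- ceiling(duration_s / dt_s - 1e-6)
  tt <- (seq_len(n) - 1L) * dt_s
  sgn <- if (direction == "forward") 1 else -1
  v <- sgn * row$amp_cm_s * sin(2 * pi * tt / row$period_s)
  set.seed(as.integer(seed))
  arr <- array(rnorm(32 * 32 * length(tt), sd = noise_sd_cm_s),
               dim = c(32, 32, length(tt)))
  idx <- which(mask)
  for (f in seq_along(tt)) {
    frame <- arr[, , f]
    frame[idx] <- frame[idx] + v[f]
    arr[, , f] <- frame
  }
  list(
    series = velocity_series(arr, dt_s = dt_s, geometry = geom),
    truth = list(amp_cm_s = row$amp_cm_s, freq_hz = 1 / row$period_s,
                 direction = direction, tube_mask = mask,
                 mean_speed_cm_s = row$amp_cm_s * 2 / pi)
  )
}
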