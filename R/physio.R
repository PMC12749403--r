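#' Segment a respiratory-belt signal into cycles
#'
#' Valleys (local minima with prominence at least `prominence_frac` times the
#' signal range) mark cycle onsets; cycles are half-open intervals from one
#' valley to the next. A record edge counts as a valley when the signal rises
#' from it by at least the prominence threshold before any interior extremum,
#' so a recording that starts or ends exactly at a cycle onset contributes
#' its boundary cycles. Each cycle is temporally normalized to 0--100% phase
#' and resampled to 200 points.
#'
#' @param belt Tibble with `time_s`, `value`.
#' @param prominence_frac Valley prominence threshold as a fraction of the
#'   signal range (default 0.25).
#' @return A `resp_cycles` object: list with `valley_times` (s), `cycles`
#'   (tibble `cycle`, `onset_s`, `end_s`), and `normalized` (cycles x 200
#'   matrix of resampled belt values on the percent-phase grid `phase_pct`).
#' @export
segment_cycles <- function(belt, prominence_frac = 0.25) {
  stopifnot(is.data.frame(belt), all(c("time_s", "value") %in% names(belt)))
  y <- belt$value
  tt <- belt$time_s
  rng <- diff(range(y))
  if (rng == 0) abort("Flat belt signal: no respiratory cycles detectable.")
  prom <- prominence_frac * rng
  vl <- find_peaks(-y, min_prominence = prom, min_distance = 2L)
  # boundary valleys: edge sample below its neighbourhood with a rise of at
  # least the prominence threshold before the first/last interior extremum
  first_ext <- c(find_peaks(y, prom, 2L), vl)
  first_ext <- if (length(first_ext)) min(first_ext) else length(y)
  if (!1L %in% vl && max(y[seq_len(first_ext)]) - y[1] >= prom &&
      y[1] <= min(y[seq_len(first_ext)])) {
    vl <- c(1L, vl)
  }
  last_ext <- c(find_peaks(y, prom, 2L), vl)
  last_ext <- if (length(last_ext)) max(last_ext) else 1L
  n <- length(y)
  if (!n %in% vl && max(y[last_ext:n]) - y[n] >= prom &&
      y[n] <= min(y[last_ext:n])) {
    vl <- c(vl, n)
  }
  vl <- sort(unique(vl))
  if (length(vl) < 2) abort("Fewer than one complete respiratory cycle.")
  valley_times <- tt[vl]
  n_cyc <- length(vl) - 1L
  norm <- matrix(NA_real_, n_cyc, 200L)
  for (i in seq_len(n_cyc)) {
    seg <- vl[i]:vl[i + 1L]
    grid <- seq(tt[vl[i]], tt[vl[i + 1L]], length.out = 200L)
    norm[i, ] <- stats::approx(tt[seg], y[seg], xout = grid)$y
  }
  structure(list(
    valley_times = valley_times,
    cycles = tibble(cycle = seq_len(n_cyc),
                    onset_s = valley_times[-length(valley_times)],
                    end_s = valley_times[-1]),
    normalized = norm,
    phase_pct = seq(0, 100, length.out = 200L)
  ), class = "resp_cycles")
}

#' @export
print.resp_cycles <- function(x, ...) {
  cat(sprintf("<resp_cycles> %d complete cycles, mean length %.2f s\n",
              nrow(x$cycles), mean(x$cycles$end_s - x$cycles$onset_s)))
  invisible(x)
}

#' Respiratory timing features
#'
#' Per cycle, the inhale runs from the onset valley to the intra-cycle
#' maximum of the belt and the exhale from that maximum to the next valley,
#' so inhale + exhale equals the cycle length exactly. The scan respiratory
#' rate is 60 over the mean cycle length.
#'
#' @param belt Tibble with `time_s`, `value`.
#' @param cycles A `resp_cycles` segmentation of the same belt.
#' @return A tibble (one row per cycle: `cycle`, `inhale_length`,
#'   `exhale_length`, `cycle_length`, `ie_ratio`) with attribute `scan`
#'   (scan means plus `respiratory_rate` in breaths/min).
#' @export
respiratory_features <- function(belt, cycles) {
  stopifnot(inherits(cycles, "resp_cycles"))
  rows <- purrr::pmap(cycles$cycles, function(cycle, onset_s, end_s) {
    sel <- belt$time_s >= onset_s & belt$time_s <= end_s
    seg_t <- belt$time_s[sel]
    seg_y <- belt$value[sel]
    imax <- which.max(seg_y)
    if (imax == 1L || imax == length(seg_y)) {
      warn(sprintf("Cycle %d has no interior maximum; skipped.", cycle))
      return(NULL)
    }
    # refine the peak time with a parabola when the grid allows
    tpk <- seg_t[imax]
    if (imax > 1L && imax < length(seg_y)) {
      off <- parabolic_refine(seg_y, imax)[1]
      tpk <- tpk + off * median(diff(seg_t))
    }
    inh <- tpk - onset_s
    exh <- end_s - tpk
    tibble(cycle = cycle, inhale_length = inh, exhale_length = exh,
           cycle_length = end_s - onset_s, ie_ratio = inh / exh)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) abort("No usable respiratory cycles.")
  scan <- out %>% dplyr::summarise(
    inhale_length = mean(.data$inhale_length),
    exhale_length = mean(.data$exhale_length),
    cycle_length = mean(.data$cycle_length),
    ie_ratio = mean(.data$ie_ratio),
    respiratory_rate = 60 / mean(.data$cycle_length)
  )
  structure(out, class = c("resp_features", class(tibble())), scan = scan)
}

#' @export
glance.resp_features <- function(object, ...) attr(object, "scan")

#' Heart-rate series from a PPG recording
#'
#' Detects pulse peaks (prominence-gated, parabolically refined below the
#' sample grid), forms inter-beat intervals, converts them to beats per
#' minute, assigns each value to the beat-interval midpoint and interpolates
#' (cubic spline) onto `grid` (default: the PPG time grid). Gaps longer than
#' twice the median inter-beat interval are flagged in the QC attribute and
#' excluded from interpolation support.
#'
#' @param ppg Tibble with `time_s`, `value`.
#' @param grid Optional time grid (s) for the output series.
#' @return Tibble `time_s`, `hr_bpm` with attributes `beat_times` and `qc`
#'   (`n_beats`, `n_gaps`).
#' @export
ppg_to_hr <- function(ppg, grid = NULL) {
  stopifnot(is.data.frame(ppg), all(c("time_s", "value") %in% names(ppg)))
  y <- ppg$value
  tt <- ppg$time_s
  dt <- median(diff(tt))
  if (stats::sd(y) == 0) abort("Flat PPG signal.")
  prom <- 0.5 * diff(range(y))
  pk <- find_peaks(y, min_prominence = prom,
                   min_distance = max(1L, round(0.25 / dt)))
  if (length(pk) < 3) abort("Fewer than three PPG beats detected.")
  beat_times <- vapply(pk, function(i) tt[i] + parabolic_refine(y, i)[1] * dt,
                       numeric(1))
  ibi <- diff(beat_times)
  gap <- ibi > 2 * median(ibi)
  hr <- 60 / ibi[!gap]
  mid <- (beat_times[-1] + beat_times[-length(beat_times)])[!gap] / 2
  if (is.null(grid)) grid <- tt
  hr_s <- stats::spline(mid, hr, xout = grid, method = "natural")$y
  # constant extrapolation outside the supported range
  hr_s[grid < min(mid)] <- hr[1]
  hr_s[grid > max(mid)] <- hr[length(hr)]
  structure(tibble(time_s = grid, hr_bpm = hr_s),
            class = c("hr_series", class(tibble())),
            beat_times = beat_times,
            qc = list(n_beats = length(beat_times), n_gaps = sum(gap)))
}

#' Heart-rate displacement (respiratory sinus arrhythmia)
#'
#' Within each respiratory cycle, the difference between the maximum and
#' minimum heart rate; the scan value is the mean over cycles. Cycles
#' covered by fewer than two heart-rate samples are skipped.
#'
#' @param hr A tibble `time_s`, `hr_bpm` (see [ppg_to_hr()]).
#' @param cycles A `resp_cycles` segmentation.
#' @return List with `per_cycle` (tibble `cycle`, `hr_max`, `hr_min`,
#'   `hr_range_bpm`) and `hr_displacement_bpm` (scan mean).
#' @export
hr_displacement <- function(hr, cycles) {
  stopifnot(is.data.frame(hr), inherits(cycles, "resp_cycles"))
  rows <- purrr::pmap(cycles$cycles, function(cycle, onset_s, end_s) {
    sel <- hr$time_s >= onset_s & hr$time_s < end_s
    if (sum(sel) < 2) return(NULL)
    tibble(cycle = cycle, hr_max = max(hr$hr_bpm[sel]),
           hr_min = min(hr$hr_bpm[sel]),
           hr_range_bpm = max(hr$hr_bpm[sel]) - min(hr$hr_bpm[sel]))
  })
  per_cycle <- dplyr::bind_rows(rows)
  if (nrow(per_cycle) == 0) abort("No cycle is covered by the HR series.")
  list(per_cycle = per_cycle,
       hr_displacement_bpm = mean(per_cycle$hr_range_bpm))
}

#' Subject-specific zero-phase band-pass filter
#'
#' Fourth-order Butterworth band-pass applied forward and backward
#' (zero-phase), with the pass band centred on the subject-specific cardiac
#' or respiratory frequency. Default half-widths: +/- 0.2 Hz (cardiac),
#' +/- 0.05 Hz (respiratory).
#'
#' @param tc A `flow_timecourse` (filters the `velocity` column).
#' @param center Centre frequency (Hz), inside the kind's physiological band.
#' @param kind `"cardiac"` or `"respiratory"`.
#' @param half_width Pass-band half-width (Hz); defaults by kind.
#' @return The time course with `velocity` band-limited.
#' @export
bandpass_subjectwise <- function(tc, center, kind = c("cardiac", "respiratory"),
                                 half_width = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(tc, "flow_timecourse"))
  band_lim <- if (kind == "cardiac") CARDIAC_BAND else RESP_BAND
  if (center < band_lim[1] || center > band_lim[2]) {
    abort(sprintf("Centre %.3g Hz outside the %s band (%g-%g Hz).",
                  center, kind, band_lim[1], band_lim[2]))
  }
  if (is.null(half_width)) half_width <- if (kind == "cardiac") 0.2 else 0.05
  fs <- 1 / attr(tc, "dt_s")
  lo <- max(center - half_width, 1e-3)
  hi <- center + half_width
  if (hi >= fs / 2) abort("Pass band extends beyond the Nyquist frequency.")
  bf <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  tc$velocity <- as.numeric(signal::filtfilt(bf, tc$velocity))
  tc
}

#' Venous flow features at the superior sagittal sinus
#'
#' Applies the CSF cycle machinery to a venous (SSS) time course and adds
#' band-limited variants: maximum flow rate and displacement from the
#' unfiltered series, plus displacement (and max flow rate) after
#' respiratory- and cardiac-band zero-phase filtering centred on the
#' subject-specific frequencies.
#'
#' @param sss_tc A detrended `flow_timecourse` for the SSS ROI.
#' @param cycles A `resp_cycles` segmentation.
#' @param resp_freq,cardiac_freq Subject-specific centre frequencies (Hz).
#' @param half_widths Named list with `respiratory` and `cardiac` half-widths
#'   (Hz); defaults 0.05 and 0.2.
#' @return One-row tibble: `sss_max_flow_rate`, `sss_max_flow_rate_resp`,
#'   `sss_displacement`, `sss_displacement_resp`, `sss_displacement_cardio`.
#' @export
venous_features <- function(sss_tc, cycles, resp_freq, cardiac_freq,
                            half_widths = list(respiratory = 0.05,
                                               cardiac = 0.2)) {
  stopifnot(inherits(sss_tc, "flow_timecourse"))
  quantify <- function(tc) {
    tc <- velocity_to_flowrate(tc)
    tc <- integrate_volume(tc)
    glance(cycle_flow_features(tc, cycles))
  }
  base <- quantify(sss_tc)
  resp_tc <- bandpass_subjectwise(sss_tc, resp_freq, "respiratory",
                                  half_widths$respiratory)
  resp <- quantify(resp_tc)
  card_tc <- bandpass_subjectwise(sss_tc, cardiac_freq, "cardiac",
                                  half_widths$cardiac)
  card <- quantify(card_tc)
  tibble(
    sss_max_flow_rate = base$max_flow_rate,
    sss_max_flow_rate_resp = resp$max_flow_rate,
    sss_displacement = base$displacement,
    sss_displacement_resp = resp$displacement,
    sss_displacement_cardio = card$displacement
  )
}
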