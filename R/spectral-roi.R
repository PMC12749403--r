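#' Voxel-wise power spectrum of a velocity series
#'
#' One-sided periodogram per voxel (rectangular window, no zero padding), so
#' the frequency resolution is exactly `1 / (n_frames * dt)` -- one over the
#' total acquisition time. The per-voxel peak frequency is the argmax of the
#' spectrum inside the analysis band.
#'
#' @param series A `velocity_series`.
#' @param band Length-2 numeric, analysis band in Hz (e.g. `c(0.8, 2)` for
#'   cardiac-driven CSF pulsation, `c(0.01, 0.5)` for respiration).
#' @return A `spectrum_map`: list with `power` (voxels x frequencies matrix),
#'   `freq_hz`, `delta_f_hz`, `peak_freq` (matrix of in-band argmax per
#'   voxel), `band`, and the grid dimensions.
#' @export
compute_power_spectrum <- function(series, band) {
  stopifnot(inherits(series, "velocity_series"), length(band) == 2,
            band[1] < band[2])
  d <- dim(series$data)
  n <- d[3]
  nyq <- 1 / (2 * series$dt_s)
  if (band[2] > nyq + 1e-12) {
    abort(sprintf("Band upper edge %.3g Hz exceeds Nyquist %.3g Hz.",
                  band[2], nyq))
  }
  # low frequencies with fewer than two cycles in the record are not
  # resolvable: clip the band's low edge to 2 / record length
  band_requested <- band
  band[1] <- max(band[1], 2 / (n * series$dt_s))
  if (band[1] >= band[2]) {
    abort("Record too short to resolve any frequency inside the band.")
  }
  x <- matrix(series$data, nrow = d[1] * d[2], ncol = n) # voxels x frames
  X <- mvfft(t(x))                                      # frames x voxels
  n_keep <- floor(n / 2) + 1L
  pow <- t(Mod(X[seq_len(n_keep), , drop = FALSE])^2)   # voxels x freqs
  freq <- (seq_len(n_keep) - 1L) / (n * series$dt_s)
  delta_f <- 1 / (n * series$dt_s)
  in_band <- which(freq >= band[1] - 1e-12 & freq <= band[2] + 1e-12)
  pk <- freq[in_band[max.col(pow[, in_band, drop = FALSE], ties.method = "first")]]
  structure(list(
    power = pow, freq_hz = freq, delta_f_hz = delta_f,
    peak_freq = matrix(pk, d[1], d[2]), band = band,
    band_requested = band_requested,
    n_rows = d[1], n_cols = d[2]
  ), class = "spectrum_map")
}

#' Relative spectral intensity map
#'
#' Per voxel, the ratio of spectral power within `peak_freq +/- delta_f` to
#' the total power over the analysis band (discrete sums over frequency
#' bins, numerator clipped at the band edges). Values lie in `[0, 1]`; a
#' voxel with zero band power is assigned 0.
#'
#' @param spec A `spectrum_map` from [compute_power_spectrum()].
#' @param band Analysis band; must match the spectrum's band.
#' @return An `ipi_map`: list with `values` (matrix), `band`.
#' @export
relative_spectral_intensity <- function(spec, band = spec$band) {
  stopifnot(inherits(spec, "spectrum_map"))
  if (!isTRUE(all.equal(band, spec$band)) &&
      !isTRUE(all.equal(band, spec$band_requested))) {
    abort("`band` must match the band used for the spectrum.")
  }
  band <- spec$band
  in_band <- spec$freq_hz >= band[1] - 1e-12 & spec$freq_hz <= band[2] + 1e-12
  fb <- spec$freq_hz[in_band]
  pb <- spec$power[, in_band, drop = FALSE]
  denom <- rowSums(pb)
  pk <- as.vector(spec$peak_freq)
  tol <- spec$delta_f_hz * (1 + 1e-9)
  num <- vapply(seq_len(nrow(pb)), function(i) {
    sum(pb[i, abs(fb - pk[i]) <= tol])
  }, numeric(1))
  # a voxel whose in-band power is only floating-point residue (relative to
  # its total spectrum) is treated as flat
  tot <- rowSums(spec$power)
  flat <- denom <= 1e-12 * pmax(tot, .Machine$double.xmin)
  vals <- ifelse(flat, 0, num / denom)
  structure(list(values = matrix(vals, spec$n_rows, spec$n_cols), band = band),
            class = "ipi_map")
}

#' Subject-specific centre frequency (cardiac or respiratory)
#'
#' Cardiac: mean beat rate from the PPG when available, otherwise the modal
#' in-band spectral peak of the velocity series. Respiratory: modal spectral
#' peak of the belt signal (or of the velocity series). PPG takes precedence
#' over the spectrum when both are supplied.
#'
#' @param kind `"cardiac"` or `"respiratory"`.
#' @param ppg Optional PPG tibble (`time_s`, `value`).
#' @param belt Optional belt tibble (`time_s`, `value`).
#' @param spec Optional `spectrum_map` of the velocity series.
#' @return Centre frequency in Hz.
#' @export
estimate_center_frequency <- function(kind = c("cardiac", "respiratory"),
                                      ppg = NULL, belt = NULL, spec = NULL) {
  kind <- match.arg(kind)
  if (kind == "cardiac") {
    if (!is.null(ppg)) {
      hr <- ppg_to_hr(ppg)
      return(mean(hr$hr_bpm) / 60)
    }
    if (!is.null(spec)) return(spectrum_mode(spec, CARDIAC_BAND))
    abort("Need `ppg` or `spec` to estimate the cardiac frequency.")
  }
  src <- if (!is.null(belt)) belt else NULL
  if (!is.null(src)) {
    dt <- median(diff(src$time_s))
    n <- nrow(src)
    pow <- Mod(fft(src$value - mean(src$value)))^2
    freq <- (seq_len(n) - 1) / (n * dt)
    sel <- freq >= RESP_BAND[1] & freq <= min(RESP_BAND[2], 1 / (2 * dt))
    return(freq[sel][which.max(pow[sel])])
  }
  if (!is.null(spec)) return(spectrum_mode(spec, RESP_BAND))
  abort("Need `belt` or `spec` to estimate the respiratory frequency.")
}

# Modal in-band peak frequency across voxels, weighted by in-band power.
spectrum_mode <- function(spec, band) {
  in_band <- spec$freq_hz >= band[1] & spec$freq_hz <= band[2]
  w <- rowSums(spec$power[, in_band, drop = FALSE])
  pk <- as.vector(spec$peak_freq)
  # power-weighted mode: the peak frequency carrying the most total power
  agg <- tapply(w, pk, sum)
  as.numeric(names(agg)[which.max(agg)])
}

#' Build the analysis ROI mask from a relative-intensity map
#'
#' Voxels whose in-band peak frequency lies outside
#' `center_freq +/- tolerance` are zeroed first; the map is then thresholded
#' at the given percentile of the nonzero relative-intensity values of the
#' whole map, and (optionally) denoised by removing isolated single-voxel
#' components. QC reports the mask size and the fraction of the mask in its
#' largest 8-connected component (a warning is raised below 0.5).
#'
#' @param ipi An `ipi_map`.
#' @param spec The matching `spectrum_map`.
#' @param center_freq Subject-specific centre frequency (Hz).
#' @param tolerance Retention half-width around `center_freq` (Hz): 0.2 for
#'   cardiac-band CSF, 0.025 for the respiratory-band venous variant.
#' @param percentile Threshold percentile in (0, 100]; default 95.
#' @param denoise Remove isolated single-voxel components (default TRUE).
#' @return A `roi_mask`: list with `mask` (logical matrix), `threshold_value`,
#'   `center_freq_hz`, `tolerance_hz`, and `qc` (`n_voxels`,
#'   `largest_component_fraction`, `n_removed_isolated`).
#' @export
build_roi_mask <- function(ipi, spec, center_freq, tolerance,
                           percentile = 95, denoise = TRUE) {
  stopifnot(inherits(ipi, "ipi_map"), inherits(spec, "spectrum_map"),
            percentile > 0, percentile <= 100, tolerance > 0)
  vals <- ipi$values
  in_tol <- abs(spec$peak_freq - center_freq) <= tolerance + 1e-12
  nz <- vals[vals > 0]
  if (!length(nz)) abort("All relative-intensity values are zero.")
  thr <- as.numeric(quantile(nz, percentile / 100, type = 7))
  mask <- vals >= thr & in_tol
  if (percentile == 100) mask <- vals >= max(nz) & in_tol
  n_removed <- 0L
  if (denoise && any(mask)) {
    lab <- label_components(mask)
    sizes <- tabulate(lab[lab > 0])
    iso <- which(sizes == 1L)
    if (length(iso)) {
      mask[lab %in% iso] <- FALSE
      n_removed <- length(iso)
    }
  }
  if (!any(mask)) {
    abort(sprintf(paste0(
      "Empty ROI mask (threshold %.4f at percentile %g, tolerance %.3g Hz ",
      "around %.3g Hz; %d voxels in tolerance)."),
      thr, percentile, tolerance, center_freq, sum(in_tol)))
  }
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0])
  lcf <- max(sizes) / sum(mask)
  if (lcf < 0.5) {
    warn(sprintf("Largest connected component holds only %.0f%% of the mask.",
                 100 * lcf))
  }
  structure(list(
    mask = mask, threshold_value = thr, center_freq_hz = center_freq,
    tolerance_hz = tolerance,
    qc = list(n_voxels = sum(mask), largest_component_fraction = lcf,
              n_removed_isolated = n_removed)
  ), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf(paste0("<roi_mask> %d voxels (threshold %.3f, centre %.3g Hz ",
                     "+/- %.3g Hz, largest component %.0f%%)\n"),
              x$qc$n_voxels, x$threshold_value, x$center_freq_hz,
              x$tolerance_hz, 100 * x$qc$largest_component_fraction))
  invisible(x)
}
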