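#' Pipeline configuration
#'
#' All tunable parameters of the end-to-end pipeline with their defaults.
#' Region presets: FM and LV select on the cardiac band (0.8--2.0 Hz, +/-0.2
#' Hz tolerance); SSS selects on the respiratory band (0.01--0.5 Hz,
#' +/-0.025 Hz tolerance).
#'
#' @param region `"FM"`, `"LV"` or `"SSS"`.
#' @param velocity_path,belt_path,ppg_path Input files (NIfTI / CSV).
#' @param sss_path Optional SSS velocity NIfTI for venous features.
#' @param landmarks_path,rb_landmarks_path Optional landmark CSVs (the RB
#'   track supplies the exhale baseline).
#' @param out_dir Output directory.
#' @param percentile ROI threshold percentile.
#' @param tolerance_hz Frequency tolerance; `NULL` uses the region preset.
#' @param flowrate_formula `"cross-section"` or `"literal"`.
#' @param cardiac_half_width_hz,resp_half_width_hz Band-pass half-widths.
#' @param pv_definition Mean-PV definition, `"average"` or `"difference"`.
#' @param denoise_roi Remove isolated mask voxels.
#' @param participant,condition Labels copied into the feature row.
#' @param seed Integer seed for any stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(region = "FM", velocity_path = NULL,
                            belt_path = NULL, ppg_path = NULL,
                            sss_path = NULL, landmarks_path = NULL,
                            rb_landmarks_path = NULL, out_dir = NULL,
                            percentile = 95, tolerance_hz = NULL,
                            flowrate_formula = "cross-section",
                            cardiac_half_width_hz = 0.2,
                            resp_half_width_hz = 0.05,
                            pv_definition = "average", denoise_roi = TRUE,
                            participant = "P01", condition = "RB",
                            seed = 1L) {
  stopifnot(region %in% c("FM", "LV", "SSS"))
  if (is.null(tolerance_hz)) {
    tolerance_hz <- if (region == "SSS") 0.025 else 0.2
  }
  structure(list(
    region = region, velocity_path = velocity_path, belt_path = belt_path,
    ppg_path = ppg_path, sss_path = sss_path,
    landmarks_path = landmarks_path, rb_landmarks_path = rb_landmarks_path,
    out_dir = out_dir, percentile = percentile, tolerance_hz = tolerance_hz,
    flowrate_formula = flowrate_formula,
    cardiac_half_width_hz = cardiac_half_width_hz,
    resp_half_width_hz = resp_half_width_hz,
    pv_definition = pv_definition, denoise_roi = denoise_roi,
    participant = participant, condition = condition, seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Read and write velocity series as NIfTI
#'
#' The series is stored as an `(x, y, t)` NIfTI volume in cm/s with the frame
#' spacing in the fourth pixdim slot; voxel in-plane spacing carries the
#' pixel area and the third spacing the slice thickness. `units = "mm/s"` on
#' write/read converts and logs the conversion.
#'
#' @param series A `velocity_series`.
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @param units Stored velocity units, `"cm/s"` (default) or `"mm/s"`.
#' @return `read_velocity_series()` returns a `velocity_series`.
#' @export
write_velocity_series <- function(series, path, units = "cm/s") {
  stopifnot(inherits(series, "velocity_series"))
  g <- series$geometry
  px <- sqrt(g$pixel_area_mm2)
  arr <- series$data
  if (units == "mm/s") {
    arr <- arr * 10
  } else if (units != "cm/s") {
    abort(sprintf("Unsupported velocity unit '%s'.", units))
  }
  d <- dim(arr)
  arr4 <- array(arr, dim = c(d[1], d[2], 1L, d[3])) # (x, y, z, t)
  img <- RNifti::asNifti(arr4)
  RNifti::pixdim(img) <- c(px, px, g$slice_thickness_mm, series$dt_s)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_velocity_series
#' @export
read_velocity_series <- function(path, units = "cm/s") {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4 || d[3] != 1) {
    abort("Expected a 4D (x, y, 1, t) NIfTI volume.")
  }
  pd <- RNifti::pixdim(img)
  dt <- pd[4]
  if (is.na(dt) || dt <= 0) {
    abort("NIfTI header carries no temporal spacing (pixdim time slot).")
  }
  px <- pd[1:2]
  slice <- pd[3]
  if (is.na(slice) || slice <= 0) slice <- 3
  arr <- array(as.numeric(img), dim = c(d[1], d[2], d[4]))
  if (units == "mm/s") {
    arr <- arr / 10
    message("Converted stored mm/s to cm/s.")
  } else if (units != "cm/s") {
    abort(sprintf("Unsupported velocity unit '%s'.", units))
  }
  geom <- grid_geometry(d[1], d[2], pixel_area_mm2 = prod(px),
                        slice_thickness_mm = slice)
  velocity_series(arr, dt_s = dt, geometry = geom)
}

#' Write a full synthetic session to disk
#'
#' Velocity NIfTI, belt and PPG CSVs, landmark-track CSV and the analytic
#' ground truth as JSON -- everything [run_pipeline()] consumes.
#'
#' @param dir Output directory (created if needed).
#' @param params A [signal_params()].
#' @param geom A [grid_geometry()].
#' @param roi ROI specification (see [generate_velocity_series()]).
#' @param hr0_bpm,rsa_amp_bpm,fs_hz PPG/belt parameters; `hr0_bpm` defaults
#'   to the session's cardiac frequency in beats per minute.
#' @param sss_params Optional `signal_params` for a companion SSS series.
#' @return Invisible named list of the written paths.
#' @export
simulate_session <- function(dir, params = signal_params(),
                             geom = grid_geometry(), roi = NULL,
                             hr0_bpm = NULL, rsa_amp_bpm = 5, fs_hz = 50,
                             sss_params = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(hr0_bpm)) hr0_bpm <- params$cardiac_freq_hz * 60
  gen <- generate_velocity_series(params, geom, roi)
  phys <- generate_physio(params, hr0_bpm, rsa_amp_bpm, fs_hz)
  lmk <- generate_landmark_tracks(params)
  paths <- list(
    velocity = file.path(dir, "velocity.nii.gz"),
    belt = file.path(dir, "belt.csv"),
    ppg = file.path(dir, "ppg.csv"),
    landmarks = file.path(dir, "landmarks.csv"),
    truth = file.path(dir, "truth.json")
  )
  write_velocity_series(gen$series, paths$velocity)
  readr::write_csv(phys$belt, paths$belt)
  readr::write_csv(phys$ppg, paths$ppg)
  write_landmarks(lmk$track, paths$landmarks)
  truth <- c(gen$truth[c("per_cycle_displacement_ml", "per_cycle_net_flow_ul",
                         "mean_speed_cm_s", "cycle_boundaries_s", "n_roi")],
             phys$truth["hr_displacement_bpm"], lmk$truth)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  if (!is.null(sss_params)) {
    sss <- generate_velocity_series(sss_params, geom, roi)
    paths$sss <- file.path(dir, "sss.nii.gz")
    write_velocity_series(sss$series, paths$sss)
  }
  invisible(paths)
}

#' Run the full analysis pipeline
#'
#' Stages in order: load inputs, estimate subject frequencies, spectral ROI
#' selection, velocity extraction + detrend, peak features, flow-rate
#' conversion, Boole volume integration, respiratory segmentation, per-cycle
#' flow features, heart-rate displacement, optional venous (SSS) and
#' diaphragm stages, and the assembled feature row. A stage error is
#' recorded in the run record and downstream stages are skipped.
#'
#' @param config A [pipeline_config()] with input paths set.
#' @return A `run_record`: list with `config`, `checksums`, `qc`, `features`
#'   (one-row tibble), `per_cycle`, `errors`, `outputs` (written files).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  rec <- list(config = config, qc = list(), errors = list(),
              outputs = character(0))
  inputs <- c(config$velocity_path, config$belt_path, config$ppg_path,
              config$sss_path, config$landmarks_path,
              config$rb_landmarks_path)
  rec$checksums <- tools::md5sum(inputs[!vapply(inputs, is.null, logical(1))])
  feats <- tibble(participant = config$participant,
                  condition = config$condition, region = config$region)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rec$errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  series <- stage("load", read_velocity_series(config$velocity_path))
  belt <- stage("load", readr::read_csv(config$belt_path,
                                        show_col_types = FALSE))
  ppg <- if (!is.null(config$ppg_path)) {
    stage("load", readr::read_csv(config$ppg_path, show_col_types = FALSE))
  }
  if (is.null(series) || is.null(belt)) {
    rec$features <- feats
    return(structure(rec, class = "run_record"))
  }

  cycles <- stage("segment", segment_cycles(belt))
  resp_freq <- stage("center_freq",
                     estimate_center_frequency("respiratory", belt = belt))
  band <- if (config$region == "SSS") RESP_BAND else CARDIAC_BAND
  spec <- stage("spectrum", compute_power_spectrum(series, band))
  cardiac_freq <- stage("center_freq", if (!is.null(ppg)) {
    estimate_center_frequency("cardiac", ppg = ppg)
  } else {
    estimate_center_frequency("cardiac", spec = spec)
  })
  center <- if (config$region == "SSS") resp_freq else cardiac_freq
  mask <- NULL
  if (!is.null(spec) && !is.null(center)) {
    ipi <- relative_spectral_intensity(spec)
    mask <- stage("roi", build_roi_mask(ipi, spec, center,
                                        tolerance = config$tolerance_hz,
                                        percentile = config$percentile,
                                        denoise = config$denoise_roi))
  }
  if (!is.null(mask)) rec$qc$roi <- mask$qc

  tc <- NULL
  if (!is.null(mask)) {
    tc <- stage("quantify", {
      tc <- extract_mean_velocity(series, mask)
      tc <- detrend_linear(tc)
      tc <- velocity_to_flowrate(tc, formula = config$flowrate_formula)
      integrate_volume(tc)
    })
  }
  if (!is.null(tc) && !is.null(cardiac_freq) && config$region != "SSS") {
    pk <- stage("peaks", detect_peaks_valleys(tc, cardiac_freq))
    if (!is.null(pk)) {
      rec$qc$peaks <- attr(pk, "qc")
      vs <- velocity_summary(tc, pk, pv_definition = config$pv_definition)
      feats$MeanPV <- vs$mean_pv
      feats$mean_speed <- vs$mean_speed
      feats$mean_peak <- vs$mean_peak
      feats$mean_valley <- vs$mean_valley
      feats$mean_peak_to_peak <- vs$mean_peak_to_peak
    }
  }
  per_cycle <- NULL
  if (!is.null(tc) && !is.null(cycles)) {
    cf <- stage("cycles", cycle_flow_features(tc, cycles))
    if (!is.null(cf)) {
      per_cycle <- cf
      sc <- glance(cf)
      feats$MaxFlow <- sc$max_flow_rate
      feats$Dis <- sc$displacement
      feats$NET <- sc$net_flow
      rec$qc$cycles <- list(n_cycles = sc$n_cycles)
    }
  }
  if (!is.null(cycles)) {
    rf <- stage("resp_features", respiratory_features(belt, cycles))
    if (!is.null(rf)) {
      sc <- glance(rf)
      feats$Inhale <- sc$inhale_length
      feats$RR <- sc$respiratory_rate
      feats$ie_ratio <- sc$ie_ratio
    }
  }
  if (!is.null(ppg) && !is.null(cycles)) {
    hrd <- stage("hr", {
      hr <- ppg_to_hr(ppg, grid = belt$time_s)
      hr_displacement(hr, cycles)
    })
    if (!is.null(hrd)) feats$HR <- hrd$hr_displacement_bpm
  }
  if (!is.null(config$sss_path) && !is.null(cycles) &&
      !is.null(resp_freq) && !is.null(cardiac_freq)) {
    sssf <- stage("sss", {
      sss_series <- read_velocity_series(config$sss_path)
      sspec <- compute_power_spectrum(sss_series, RESP_BAND)
      sipi <- relative_spectral_intensity(sspec)
      smask <- build_roi_mask(sipi, sspec, resp_freq, tolerance = 0.025,
                              percentile = config$percentile,
                              denoise = config$denoise_roi)
      stc <- detrend_linear(extract_mean_velocity(sss_series, smask))
      venous_features(stc, cycles, resp_freq, cardiac_freq,
                      half_widths = list(respiratory = config$resp_half_width_hz,
                                         cardiac = config$cardiac_half_width_hz))
    })
    if (!is.null(sssf)) feats$SSS <- sssf$sss_displacement
    if (!is.null(sssf)) feats <- dplyr::bind_cols(feats, sssf)
  }
  if (!is.null(config$landmarks_path)) {
    dia <- stage("diaphragm", {
      trk <- read_landmarks(config$landmarks_path)
      mm <- compute_motion_metrics(trk)
      rb_mm <- if (!is.null(config$rb_landmarks_path)) {
        compute_motion_metrics(read_landmarks(config$rb_landmarks_path))
      } else mm
      diaphragm_summary(normalize_to_baseline(mm, rb_mm))
    })
    if (!is.null(dia)) {
      feats$Lung <- dia$lung_area_displacement
      feats$Chest <- dia$chest_displacement
      feats$Dia <- dia$diaphragm_displacement
    }
  }
  rec$features <- feats
  rec$per_cycle <- per_cycle
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    fpath <- file.path(config$out_dir, "features.csv")
    readr::write_csv(feats, fpath)
    rec$outputs <- fpath
    if (!is.null(per_cycle)) {
      cpath <- file.path(config$out_dir, "per_cycle.csv")
      readr::write_csv(as_tibble(per_cycle), cpath)
      rec$outputs <- c(rec$outputs, cpath)
    }
    qpath <- file.path(config$out_dir, "qc.json")
    jsonlite::write_json(rec$qc, qpath, auto_unbox = TRUE, digits = NA)
    rec$outputs <- c(rec$outputs, qpath)
  }
  structure(rec, class = "run_record")
}

#' @export
print.run_record <- function(x, ...) {
  cat(sprintf("<run_record> region %s, %d stage error(s)\n",
              x$config$region, length(x$errors)))
  if (length(x$errors)) {
    for (nm in names(x$errors)) cat("  !", nm, ":", x$errors[[nm]], "\n")
  }
  invisible(x)
}

#' Markdown QC report for a pipeline run
#'
#' Summarizes per-stage QC metrics and errors: ROI size and connectivity,
#' peak-detection ratio against the expected beat count, cycle counts, and
#' the assembled feature row. Flags are raised for an empty or fragmented
#' mask, peak detection far from the expected beat count, and missing PPG.
#'
#' @param record A `run_record`.
#' @param path Optional file to write the markdown to.
#' @return The report as a character vector of lines (invisibly when
#'   written to `path`).
#' @export
qc_report <- function(record, path = NULL) {
  stopifnot(inherits(record, "run_record"))
  flags <- character(0)
  L <- c("# Pipeline QC report", "",
         sprintf("Region: %s | participant: %s | condition: %s",
                 record$config$region, record$config$participant,
                 record$config$condition), "")
  if (!is.null(record$qc$roi)) {
    q <- record$qc$roi
    L <- c(L, "## ROI", "",
           sprintf("- voxels: %d", q$n_voxels),
           sprintf("- largest component fraction: %.2f",
                   q$largest_component_fraction),
           sprintf("- isolated voxels removed: %d", q$n_removed_isolated), "")
    if (q$largest_component_fraction < 0.5) {
      flags <- c(flags, "ROI fragmented (largest component < 50%)")
    }
  } else {
    flags <- c(flags, "ROI stage did not complete")
  }
  if (!is.null(record$qc$peaks)) {
    q <- record$qc$peaks
    L <- c(L, "## Peak detection", "",
           sprintf("- peaks detected: %d (expected ~%.0f, ratio %.2f)",
                   q$n_peaks, q$n_expected, q$detection_ratio), "")
    if (q$detection_ratio < 0.8 || q$detection_ratio > 1.2) {
      flags <- c(flags, "peak count far from the expected beat count")
    }
  } else if (is.null(record$config$ppg_path)) {
    L <- c(L, "## Peak detection", "", "- PPG unavailable: beat-count QC skipped", "")
  }
  if (!is.null(record$qc$cycles)) {
    L <- c(L, "## Respiratory cycles", "",
           sprintf("- complete cycles: %d", record$qc$cycles$n_cycles), "")
  }
  if (length(record$errors)) {
    L <- c(L, "## Stage errors", "",
           paste0("- ", names(record$errors), ": ",
                  unlist(record$errors)), "")
    flags <- c(flags, paste("stage error:", names(record$errors)))
  }
  L <- c(L, "## Flags", "",
         if (length(flags)) paste0("- ", flags) else "- none", "")
  if (!is.null(path)) {
    writeLines(L, path)
    return(invisible(L))
  }
  L
}
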