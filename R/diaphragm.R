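#' Read (and write) pose-estimation landmark tracks
#'
#' Long-format pose-estimation CSV dialect: one row per frame per landmark
#' with columns `frame`, `landmark`, `x`, `y`, `likelihood`. Exactly eight
#' landmarks are required. Points below the likelihood threshold are linearly
#' interpolated from neighbouring frames and counted in the QC attribute.
#'
#' @param path CSV file path.
#' @param frame_dt_s Frame spacing (s); default 0.857.
#' @param likelihood_min Interpolation threshold (default 0.6).
#' @return A `landmark_track` tibble (`frame`, `landmark`, `x`, `y`,
#'   `likelihood`) with attributes `frame_dt_s` and `qc`
#'   (`n_interpolated`).
#' @export
read_landmarks <- function(path, frame_dt_s = 0.857, likelihood_min = 0.6) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("frame", "landmark", "x", "y", "likelihood")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort(paste0("Landmark CSV is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  as_landmark_track(df, frame_dt_s = frame_dt_s,
                    likelihood_min = likelihood_min)
}

#' @rdname read_landmarks
#' @param track A landmark track tibble.
#' @export
write_landmarks <- function(track, path) {
  readr::write_csv(track[, c("frame", "landmark", "x", "y", "likelihood")],
                   path)
  invisible(path)
}

#' @rdname read_landmarks
#' @param df A data frame in the landmark dialect.
#' @export
as_landmark_track <- function(df, frame_dt_s = 0.857, likelihood_min = 0.6) {
  lms <- unique(df$landmark)
  if (length(lms) != 8) {
    abort(sprintf("Expected 8 landmarks, found %d (%s).", length(lms),
                  paste(head(lms, 10), collapse = ", ")))
  }
  df <- dplyr::arrange(df, .data$landmark, .data$frame)
  n_interp <- 0L
  out <- df %>%
    dplyr::group_by(.data$landmark) %>%
    dplyr::group_modify(function(g, key) {
      low <- g$likelihood < likelihood_min
      if (any(low)) {
        if (all(low)) abort(paste0("Landmark '", key$landmark,
                                   "' has no usable frames."))
        g$x[low] <- stats::approx(g$frame[!low], g$x[!low],
                                  xout = g$frame[low], rule = 2)$y
        g$y[low] <- stats::approx(g$frame[!low], g$y[!low],
                                  xout = g$frame[low], rule = 2)$y
        n_interp <<- n_interp + sum(low)
      }
      g$interpolated <- low
      g
    }) %>%
    dplyr::ungroup()
  structure(out, class = c("landmark_track", class(tibble())),
            frame_dt_s = frame_dt_s, qc = list(n_interpolated = n_interp))
}

#' Six diaphragm/chest motion metrics from a landmark track
#'
#' Lung area is the shoelace (polygon) area of the eight landmarks in the
#' contour order given by `landmark_map$contour`; upper/lower chest and
#' diaphragm 1--3 are Euclidean distances between the mapped landmark pairs.
#' A warning is raised (and the absolute signed area used) if the contour
#' orientation flips between frames, which indicates self-intersection.
#'
#' @param track A `landmark_track` (or tibble in the same dialect).
#' @param landmark_map List assigning `contour` (8 names in order) and the
#'   pairs `upper_chest`, `lower_chest`, `diaphragm_1..3`; see
#'   [default_landmark_map()].
#' @return A `motion_metrics` tibble (`frame`, `time_s`, `lung_area`,
#'   `upper_chest`, `lower_chest`, `diaphragm_1`, `diaphragm_2`,
#'   `diaphragm_3`) with attributes `frame_dt_s`, `normalized = FALSE`.
#' @export
compute_motion_metrics <- function(track, landmark_map = default_landmark_map()) {
  stopifnot(is.data.frame(track))
  frame_dt <- attr(track, "frame_dt_s") %||% 0.857
  wide_x <- tidyr::pivot_wider(track[, c("frame", "landmark", "x")],
                               names_from = "landmark", values_from = "x")
  wide_y <- tidyr::pivot_wider(track[, c("frame", "landmark", "y")],
                               names_from = "landmark", values_from = "y")
  contour <- landmark_map$contour
  if (!all(contour %in% names(wide_x))) {
    abort("`landmark_map$contour` names absent from the track.")
  }
  X <- as.matrix(wide_x[, contour])
  Y <- as.matrix(wide_y[, contour])
  nxt <- c(2:8, 1)
  signed <- rowSums(X * Y[, nxt] - X[, nxt] * Y) / 2
  if (length(unique(sign(signed[signed != 0]))) > 1) {
    warn("Contour orientation flips between frames (self-intersection?); using absolute areas.")
  }
  dist_pair <- function(pair) {
    sqrt((wide_x[[pair[1]]] - wide_x[[pair[2]]])^2 +
           (wide_y[[pair[1]]] - wide_y[[pair[2]]])^2)
  }
  out <- tibble(
    frame = wide_x$frame,
    time_s = wide_x$frame * frame_dt,
    lung_area = abs(signed),
    upper_chest = dist_pair(landmark_map$upper_chest),
    lower_chest = dist_pair(landmark_map$lower_chest),
    diaphragm_1 = dist_pair(landmark_map$diaphragm_1),
    diaphragm_2 = dist_pair(landmark_map$diaphragm_2),
    diaphragm_3 = dist_pair(landmark_map$diaphragm_3)
  )
  structure(out, class = c("motion_metrics", class(tibble())),
            frame_dt_s = frame_dt, normalized = FALSE, baseline = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize motion metrics to the exhale baseline
#'
#' The baseline is the square root of the mean lung area at the respiratory
#' valleys of the regular-breathing reference (`rb_metrics`, detected with
#' the belt valley detector on the lung-area series). Distances are divided
#' by the baseline and the area by its square; the same reference baseline
#' normalizes deep-breathing metrics.
#'
#' @param metrics A `motion_metrics` tibble to normalize.
#' @param rb_metrics The regular-breathing `motion_metrics` supplying the
#'   baseline (defaults to `metrics` itself).
#' @param prominence_frac Valley prominence threshold (fraction of range).
#' @return The normalized `motion_metrics` (attribute `normalized = TRUE`,
#'   `baseline` in pixels).
#' @export
normalize_to_baseline <- function(metrics, rb_metrics = metrics,
                                  prominence_frac = 0.25) {
  stopifnot(inherits(metrics, "motion_metrics"),
            inherits(rb_metrics, "motion_metrics"))
  area <- rb_metrics$lung_area
  if (diff(range(area)) == 0) {
    abort("Constant lung area: exhale valleys are undefined.")
  }
  vl <- find_peaks(-area, min_prominence = prominence_frac * diff(range(area)),
                   min_distance = 2L)
  # a record starting/ending at exhale counts as a valley
  if (length(vl) < 2) {
    lev <- min(area) + 0.05 * diff(range(area))
    vl <- sort(unique(c(vl, which(area <= lev))))
  }
  if (length(vl) < 2) abort("Fewer than two exhale valleys in the reference.")
  baseline <- sqrt(mean(area[vl]))
  for (col in c("upper_chest", "lower_chest",
                "diaphragm_1", "diaphragm_2", "diaphragm_3")) {
    metrics[[col]] <- metrics[[col]] / baseline
  }
  metrics$lung_area <- metrics$lung_area / baseline^2
  attr(metrics, "normalized") <- TRUE
  attr(metrics, "baseline") <- baseline
  metrics
}

#' Envelope displacement of an oscillatory signal
#'
#' Upper and lower envelopes are linear interpolations through the local
#' maxima and minima (constant-extended at the record edges); the
#' displacement is the mean difference between them, i.e. the mean total
#' oscillation amplitude. With `method = "upper-minus-mean"` the result is
#' twice the mean difference between the upper envelope and the signal mean.
#'
#' @param x Numeric signal (a normalized motion metric).
#' @param method `"upper-minus-lower"` (default) or `"upper-minus-mean"`.
#' @return Envelope displacement (same units as `x`); 0 with a warning when
#'   the signal has no interior extrema.
#' @export
envelope_displacement <- function(x, method = c("upper-minus-lower",
                                                "upper-minus-mean")) {
  method <- match.arg(method)
  pk <- local_maxima(x)
  vl <- local_maxima(-x)
  if (!length(pk) || !length(vl)) {
    warn("No oscillation extrema found; envelope displacement set to 0.")
    return(0)
  }
  idx <- seq_along(x)
  # refine extremum heights below the frame grid (three-point parabola)
  pk_h <- vapply(pk, function(i) parabolic_refine(x, i)[2], numeric(1))
  vl_h <- -vapply(vl, function(i) parabolic_refine(-x, i)[2], numeric(1))
  upper <- stats::approx(pk, pk_h, xout = idx, rule = 2)$y
  lower <- stats::approx(vl, vl_h, xout = idx, rule = 2)$y
  # restrict to the span covered by both envelopes without edge extension
  lo <- max(min(pk), min(vl))
  hi <- min(max(pk), max(vl))
  sel <- idx >= lo & idx <= hi
  if (!any(sel)) sel <- rep(TRUE, length(idx))
  if (method == "upper-minus-lower") {
    mean(upper[sel] - lower[sel])
  } else {
    2 * mean(upper[sel] - mean(x))
  }
}

#' Diaphragm-motion summary parameters
#'
#' The three summary displacements: lung-area displacement (envelope
#' displacement of the normalized lung-area signal), chest displacement
#' (upper-chest distance by default) and diaphragm displacement (posterior
#' landmark pair, diaphragm 3).
#'
#' @param metrics A normalized `motion_metrics` tibble.
#' @param chest `"upper_chest"` (default) or `"lower_chest"`.
#' @param method Envelope method, see [envelope_displacement()].
#' @return One-row tibble: `lung_area_displacement`, `chest_displacement`,
#'   `diaphragm_displacement` (A.U.).
#' @export
diaphragm_summary <- function(metrics, chest = c("upper_chest", "lower_chest"),
                              method = "upper-minus-lower") {
  chest <- match.arg(chest)
  if (!isTRUE(attr(metrics, "normalized"))) {
    warn("Metrics are not baseline-normalized; summaries are in pixel units.")
  }
  tibble(
    lung_area_displacement = envelope_displacement(metrics$lung_area, method),
    chest_displacement = envelope_displacement(metrics[[chest]], method),
    diaphragm_displacement = envelope_displacement(metrics$diaphragm_3, method)
  )
}
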