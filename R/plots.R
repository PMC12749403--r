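#' Plot methods
#'
#' `autoplot()` methods for the main result types: relative-intensity maps,
#' ROI masks, flow time courses (velocity / flow rate / volume panels),
#' respiratory segmentations overlaid on the belt, and the retained-path
#' diagram of a fitted path model.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-csfflow
NULL

grid_df <- function(m, value = "value") {
  df <- expand.grid(row = seq_len(nrow(m)) - 1L, col = seq_len(ncol(m)) - 1L)
  df[[value]] <- as.vector(m)
  as_tibble(df)
}

#' @rdname autoplot-csfflow
#' @export
autoplot.ipi_map <- function(object, ...) {
  ggplot2::ggplot(grid_df(object$values),
                  ggplot2::aes(x = .data$col, y = .data$row,
                               fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "relative\nintensity",
                                  limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column", y = "row",
                  title = sprintf("Relative spectral intensity (%.3g-%.3g Hz)",
                                  object$band[1], object$band[2]))
}

#' @rdname autoplot-csfflow
#' @export
autoplot.roi_mask <- function(object, ...) {
  ggplot2::ggplot(grid_df(object$mask),
                  ggplot2::aes(x = .data$col, y = .data$row,
                               fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey90",
                                          `TRUE` = "firebrick"),
                               name = "in ROI") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column", y = "row",
                  title = sprintf("ROI mask: %d voxels", object$qc$n_voxels))
}

#' @rdname autoplot-csfflow
#' @param peaks Optional `peak_set` to overlay on the velocity panel.
#' @export
autoplot.flow_timecourse <- function(object, peaks = NULL, ...) {
  cols <- intersect(c("velocity", "flow_rate", "volume"), names(object))
  long <- tidyr::pivot_longer(as_tibble(object)[, c("time_s", cols)],
                              dplyr::all_of(cols),
                              names_to = "series", values_to = "value")
  long$series <- factor(long$series, levels = cols,
                        labels = c("velocity (cm/s)", "flow rate (ml/s)",
                                   "volume (ml)")[seq_along(cols)])
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s,
                                          y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~series, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL)
  if (!is.null(peaks)) {
    p <- p + ggplot2::geom_point(
      data = dplyr::mutate(as_tibble(peaks), series = "velocity (cm/s)"),
      ggplot2::aes(colour = .data$type), size = 0.8)
  }
  p
}

#' @rdname autoplot-csfflow
#' @param belt Belt tibble used for the segmentation.
#' @export
autoplot.resp_cycles <- function(object, belt = NULL, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(belt)) {
    p <- p + ggplot2::geom_line(data = belt,
                                ggplot2::aes(x = .data$time_s,
                                             y = .data$value),
                                linewidth = 0.3)
  }
  p + ggplot2::geom_vline(xintercept = object$valley_times,
                          colour = "steelblue", linetype = 2) +
    ggplot2::labs(x = "time (s)", y = "belt signal",
                  title = sprintf("%d complete respiratory cycles",
                                  nrow(object$cycles)))
}

#' @rdname autoplot-csfflow
#' @export
autoplot.path_model_fit <- function(object, ...) {
  df <- object$paths
  df$path <- paste(df$term, "→", df$response)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$beta, y = .data$path,
                                   fill = .data$retained)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2) +
    ggplot2::facet_wrap(~region) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "grey70"),
                               name = sprintf("p < %.2g", object$alpha)) +
    ggplot2::labs(x = "standardized β", y = NULL,
                  title = "Hierarchical path model")
}
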