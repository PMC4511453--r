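leg_colors <- c(LF = "#E6C419", LH = "#2B5FD9", RF = "#E87E1B", RH = "#3DA93D")

#' Footprint-pattern plot
#'
#' Heat map of the per-pixel maximum footprint brightness accumulated
#' over the trial, with the body-centre path overlaid; falls back to
#' per-frame footprint centroids when the track was reloaded from CSV and
#' carries no heat map. Axes are in centimetres via the calibration.
#'
#' @param track A `gait_track`.
#' @return A ggplot object.
#' @export
plot_footprint_pattern <- function(track) {
  px <- track$config$px_per_cm
  p <- ggplot2::ggplot()
  if (!is.null(track$heatmap) && any(track$heatmap > 0)) {
    hm <- track$heatmap
    idx <- which(hm > 0, arr.ind = TRUE)
    df <- tibble::tibble(x = (idx[, 2] - 1) / px, y = (idx[, 1] - 1) / px,
                         intensity = hm[idx])
    p <- p + ggplot2::geom_tile(
      data = df, ggplot2::aes(x = .data$x, y = .data$y,
                              fill = .data$intensity),
      width = 1 / px, height = 1 / px) +
      ggplot2::scale_fill_viridis_c(option = "inferno")
  } else {
    fp <- footprints_table(track$events)
    p <- p + ggplot2::geom_point(
      data = fp, ggplot2::aes(x = .data$x / px, y = .data$y / px,
                              size = .data$area_px, colour = .data$leg),
      alpha = 0.6) +
      ggplot2::scale_colour_manual(values = leg_colors, na.value = "grey60")
  }
  path <- track$body_path
  p +
    ggplot2::geom_path(data = path,
                       ggplot2::aes(x = .data$center_x / px,
                                    y = .data$center_y / px),
                       colour = "white", linewidth = 0.3) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (cm)", y = "y (cm)", fill = "fTIR intensity",
                  title = "Footprint pattern") +
    ggplot2::theme_minimal()
}

#' Colour-coded footprint pattern by leg
#'
#' Replaces pixel intensity with a leg-specific colour code so footprints
#' from each leg are unambiguous even where hind placements overlap
#' previous fore placements.
#'
#' @param track A `gait_track`.
#' @return A ggplot object.
#' @export
plot_footprint_pattern_legs <- function(track) {
  px <- track$config$px_per_cm
  fp <- footprints_table(track$events)
  ggplot2::ggplot(fp, ggplot2::aes(x = .data$x / px, y = .data$y / px,
                                   colour = .data$leg)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$area_px), alpha = 0.5) +
    ggplot2::scale_colour_manual(values = leg_colors, na.value = "grey60") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::guides(size = "none") +
    ggplot2::labs(x = "x (cm)", y = "y (cm)", colour = "leg",
                  title = "Footprints by leg") +
    ggplot2::theme_minimal()
}

#' Gait diagram with instantaneous speed
#'
#' Stance intervals of the four legs as horizontal bars over time, with
#' the smoothed instantaneous speed trace above.
#'
#' @param analysis A `gait_analysis`.
#' @param events The labelled event tibble of the same trial.
#' @return A ggplot object.
#' @export
plot_gait_diagram <- function(analysis, events) {
  fps <- analysis$config$frame_rate_hz
  ev <- events[!is.na(events$leg), , drop = FALSE]
  bars <- tibble::tibble(leg = factor(ev$leg, levels = rev(leg_ids)),
                         t0 = ev$onset / fps, t1 = (ev$offset + 1) / fps)
  sp <- tibble::as_tibble(analysis$speed)
  smax <- max(sp$speed_cm_s, 1)
  sp$y <- 4.6 + 1.6 * sp$speed_cm_s / smax
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = bars,
                          ggplot2::aes(x = .data$t0, xend = .data$t1,
                                       y = as.integer(.data$leg),
                                       yend = as.integer(.data$leg),
                                       colour = .data$leg),
                          linewidth = 4) +
    ggplot2::geom_line(data = sp, ggplot2::aes(x = .data$time, y = .data$y),
                       colour = "grey30") +
    ggplot2::scale_colour_manual(values = leg_colors) +
    ggplot2::scale_y_continuous(
      breaks = 1:4, labels = rev(leg_ids),
      sec.axis = ggplot2::sec_axis(~ (. - 4.6) / 1.6 * smax,
                                   name = "speed (cm/s)")) +
    ggplot2::labs(x = "time (s)", y = NULL, title = "Gait diagram") +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}

#' Stance traces in the body frame
#'
#' All stance traces of a trial, from AEP (touchdown) to PEP (liftoff),
#' in body-length units relative to the body centre at (0, 0).
#'
#' @param analysis A `gait_analysis`.
#' @return A ggplot object.
#' @export
plot_stance_traces <- function(analysis) {
  df <- purrr::imap_dfr(analysis$traces, function(t, k) {
    dplyr::mutate(tibble::as_tibble(t), trace = k)
  })
  ends <- analysis$aep_pep
  ggplot2::ggplot(df, ggplot2::aes(x = .data$longitudinal, y = .data$lateral,
                                   group = .data$trace,
                                   colour = .data$leg)) +
    ggplot2::geom_path(alpha = 0.7) +
    ggplot2::geom_point(data = ends,
                        ggplot2::aes(x = .data$aep_long, y = .data$aep_lat,
                                     colour = .data$leg),
                        inherit.aes = FALSE, shape = 16) +
    ggplot2::geom_point(data = ends,
                        ggplot2::aes(x = .data$pep_long, y = .data$pep_lat,
                                     colour = .data$leg),
                        inherit.aes = FALSE, shape = 1) +
    ggplot2::annotate("point", x = 0, y = 0, shape = 3, size = 3) +
    ggplot2::scale_colour_manual(values = leg_colors) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "longitudinal (body lengths)",
                  y = "lateral (body lengths)",
                  title = "Stance traces (filled = AEP, open = PEP)") +
    ggplot2::theme_minimal()
}

#' Per-stance pressure strip
#'
#' Footprint intensity of each stance event over normalised stance time,
#' one row per event grouped by leg — the rise, plateau and rostral
#' transfer of loading are visible as the brightness profile.
#'
#' @param analysis A `gait_analysis`.
#' @return A ggplot object.
#' @export
plot_stance_strip <- function(analysis) {
  pr <- analysis$pressures
  pr <- pr[!is.na(pr$pressure), , drop = FALSE]
  pr <- pr |>
    dplyr::group_by(.data$event_id) |>
    dplyr::mutate(u = (dplyr::row_number() - 1) /
                    pmax(1, dplyr::n() - 1)) |>
    dplyr::ungroup()
  ggplot2::ggplot(pr, ggplot2::aes(x = .data$u, y = factor(.data$event_id),
                                   fill = .data$intensity)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$leg), scales = "free_y",
                        space = "free_y") +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::labs(x = "normalised stance time", y = "stance event",
                  fill = "intensity", title = "Stance-phase loading") +
    ggplot2::theme_minimal()
}

#' Autoplot a speed series
#'
#' @param object A `speed_series`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.speed_series <- function(object, ...) {
  avg <- attr(object, "average_cm_s")
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$time, y = .data$speed_cm_s)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_hline(yintercept = avg, linetype = 2, colour = "red") +
    ggplot2::labs(x = "time (s)", y = "speed (cm/s)",
                  title = sprintf("Instantaneous speed (average %.1f cm/s)",
                                  avg)) +
    ggplot2::theme_minimal()
}

#' Autoplot a duty-factor regression
#'
#' @param object A `duty_regression` with an underlying model.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.duty_regression <- function(object, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(object$model)) {
    d <- object$model$model
    names(d) <- c("duty_factor", "speed_cm_s")
    p <- p + ggplot2::geom_point(data = d,
                                 ggplot2::aes(x = .data$speed_cm_s,
                                              y = .data$duty_factor))
  }
  p +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "blue") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "red") +
    {if (!object$flagged)
      ggplot2::geom_vline(xintercept = object$crossing_speed_cm_s,
                          linetype = 2, colour = "red")} +
    ggplot2::labs(x = "speed (cm/s)", y = "duty factor",
                  title = "Duty factor vs speed") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

write_report_images <- function(analysis, track, out_dir) {
  save_plot <- function(p, name, w = 7, h = 4) {
    grDevices::png(file.path(out_dir, name), width = w * 120, height = h * 120,
                   res = 120)
    print(p)
    grDevices::dev.off()
  }
  save_plot(plot_footprint_pattern(track), "footprint_pattern.png", 8, 3)
  save_plot(plot_footprint_pattern_legs(track),
            "footprint_pattern_legs.png", 8, 3)
  save_plot(plot_gait_diagram(analysis, track$events), "gait_diagram.png")
  save_plot(plot_stance_traces(analysis), "stance_traces.png", 6, 4)
  save_plot(plot_stance_strip(analysis), "stance_strip.png", 6, 5)
  save_plot(autoplot.speed_series(analysis$speed), "speed.png")
  invisible(out_dir)
}
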