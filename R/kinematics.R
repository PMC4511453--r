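#' Instantaneous and average body speed
#'
#' Central-difference velocity magnitude of the body centre, converted to
#' cm/s and smoothed by a centred moving average (window shrunk
#' symmetrically at the ends). The average speed is the net displacement
#' of the body centre over the elapsed time of the valid range, matching
#' analysis of runs in which the animal moves continuously along the
#' walkway. Untracked gaps of up to 10 frames are bridged by linear
#' interpolation of the centre; longer interior gaps are an error.
#'
#' @param poses Per-frame pose tibble.
#' @param cfg A [gait_config()] list (`frame_rate_hz`, `px_per_cm`,
#'   `speed_smooth_win`).
#' @return A tibble of class `speed_series` (`frame`, `time`, `speed_cm_s`)
#'   with attributes `average_cm_s` and `valid_range`.
#' @export
instantaneous_speed <- function(poses, cfg) {
  tr <- poses[poses$tracked, , drop = FALSE]
  if (nrow(tr) < 3) stop("need at least 3 tracked poses", call. = FALSE)
  f0 <- min(tr$frame); f1 <- max(tr$frame)
  gaps <- diff(tr$frame) - 1
  if (any(gaps > 10)) stop("untracked gap longer than 10 frames inside valid range",
                           call. = FALSE)
  full <- seq(f0, f1)
  cx <- stats::approx(tr$frame, tr$center_x, xout = full)$y
  cy <- stats::approx(tr$frame, tr$center_y, xout = full)$y
  n <- length(full)
  fps <- cfg$frame_rate_hz
  vx <- c(cx[2] - cx[1], (cx[3:n] - cx[1:(n - 2)]) / 2, cx[n] - cx[n - 1]) * fps
  vy <- c(cy[2] - cy[1], (cy[3:n] - cy[1:(n - 2)]) / 2, cy[n] - cy[n - 1]) * fps
  sp <- sqrt(vx^2 + vy^2) / cfg$px_per_cm
  sp <- moving_average(sp, cfg$speed_smooth_win)
  avg <- sqrt((cx[n] - cx[1])^2 + (cy[n] - cy[1])^2) / cfg$px_per_cm /
    ((f1 - f0) / fps)
  out <- tibble::tibble(frame = full, time = full / fps, speed_cm_s = sp)
  structure(out, average_cm_s = avg, valid_range = c(f0, f1),
            class = c("speed_series", class(out)))
}

# centred moving average, window shrunk symmetrically at the ends
moving_average <- function(x, win) {
  n <- length(x)
  h <- (win - 1) %/% 2
  if (h < 1 || n < 2) return(x)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  hh <- pmin(h, i - 1L, n - i)
  (cs[i + hh + 1L] - cs[i - hh]) / (2 * hh + 1)
}

#' Duty factor of a step cycle
#'
#' Stance duration divided by period. Cycles with no detected swing give a
#' duty factor of exactly 1 and should carry the `degenerate` flag from
#' [build_step_cycles()].
#'
#' @param stance_time,period Stance duration and cycle period in seconds
#'   (vectorised).
#' @return Duty factor in (0, 1].
#' @export
duty_factor <- function(stance_time, period) {
  if (any(period <= 0)) stop("period must be > 0", call. = FALSE)
  stance_time / period
}

#' Swing speed of a step cycle
#'
#' Step length divided by swing time, in m/s. Cycles with zero swing time
#' are undefined (`NA`) and must be excluded from averages.
#'
#' @param step_length_mm Step length in millimetres (vectorised).
#' @param swing_time Swing duration in seconds.
#' @return Swing speed in m/s, `NA` where `swing_time` is zero.
#' @export
swing_speed <- function(step_length_mm, swing_time) {
  ifelse(swing_time > 0, (step_length_mm / 1000) / swing_time, NA_real_)
}

#' Classify a trial as walk or run from its mean duty factor
#'
#' Duty factors of 0.5 and above are walks; values below 0.5 are runs.
#'
#' @param mean_duty Mean duty factor in [0, 1] (vectorised).
#' @return Character vector, `"walk"` or `"run"`.
#' @export
classify_gait_regime <- function(mean_duty) {
  stopifnot(all(mean_duty >= 0 & mean_duty <= 1))
  ifelse(mean_duty >= 0.5, "walk", "run")
}

#' Linear regression of duty factor on speed
#'
#' Ordinary least squares of per-trial mean duty factor on per-trial
#' average speed. The walk-to-run crossing speed is where the fitted line
#' reaches a duty factor of 0.5; it is undefined (flagged) when the slope
#' is not negative.
#'
#' @param trials Data frame with columns `speed_cm_s` and `duty_factor`,
#'   one row per trial.
#' @return An object of class `duty_regression`: list with `slope`,
#'   `intercept`, `crossing_speed_cm_s` (`NA` when flagged), `flagged`,
#'   `model` (the underlying `lm`), `n`.
#' @export
fit_duty_speed_regression <- function(trials) {
  stopifnot(all(c("speed_cm_s", "duty_factor") %in% names(trials)))
  if (nrow(trials) < 3) stop("need at least 3 trials", call. = FALSE)
  if (diff(range(trials$speed_cm_s)) <= 10) {
    stop("trials must span more than 10 cm/s", call. = FALSE)
  }
  m <- stats::lm(duty_factor ~ speed_cm_s, data = trials)
  slope <- unname(stats::coef(m)[2])
  intercept <- unname(stats::coef(m)[1])
  duty_regression(slope, intercept, model = m, n = nrow(trials))
}

#' Build a duty-factor regression object from known coefficients
#'
#' Useful for evaluating a published duty-versus-speed line: the crossing
#' speed where duty factor = 0.5 is `(0.5 - intercept) / slope` for a
#' negative slope.
#'
#' @param slope Slope in units of 1/(cm/s).
#' @param intercept Dimensionless intercept.
#' @param model Optional underlying `lm` fit.
#' @param n Optional number of trials behind the coefficients.
#' @return A `duty_regression` object.
#' @export
duty_regression <- function(slope, intercept, model = NULL, n = NA_integer_) {
  flagged <- slope >= 0
  structure(list(
    slope = slope, intercept = intercept,
    crossing_speed_cm_s = if (flagged) NA_real_ else (0.5 - intercept) / slope,
    flagged = flagged, model = model, n = n
  ), class = "duty_regression")
}

#' @export
print.duty_regression <- function(x, ...) {
  cat("Duty factor ~ speed (OLS)\n")
  cat(sprintf("  slope     %+.6f per cm/s\n", x$slope))
  cat(sprintf("  intercept % .6f\n", x$intercept))
  if (x$flagged) {
    cat("  crossing speed undefined (slope not negative)\n")
  } else {
    cat(sprintf("  walk-to-run crossing %.1f cm/s\n", x$crossing_speed_cm_s))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a duty-factor regression
#'
#' @param x A `duty_regression` object.
#' @param ... Unused.
#' @return One-row tibble with `slope`, `intercept`,
#'   `crossing_speed_cm_s`, `flagged`.
#' @export
tidy.duty_regression <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 crossing_speed_cm_s = x$crossing_speed_cm_s,
                 flagged = x$flagged)
}

#' Glance at a duty-factor regression
#'
#' @param x A `duty_regression` object.
#' @param ... Unused.
#' @return One-row tibble with `n`, `r.squared` (`NA` without a model) and
#'   `sigma`.
#' @export
glance.duty_regression <- function(x, ...) {
  if (is.null(x$model)) {
    return(tibble::tibble(n = x$n, r.squared = NA_real_, sigma = NA_real_))
  }
  s <- summary(x$model)
  tibble::tibble(n = x$n, r.squared = s$r.squared, sigma = s$sigma)
}

#' Exponential fit of stance time against speed
#'
#' Optional descriptive fit of the form `a * exp(-b * speed) + c` for the
#' shortening of stance duration with speed. Coefficients are reported,
#' not asserted.
#'
#' @param trials Data frame with `speed_cm_s` and `stance_time` columns.
#' @return Named coefficient vector `c(a, b, c)`, or `NULL` when the fit
#'   fails to converge.
#' @export
fit_stance_time_curve <- function(trials) {
  stopifnot(all(c("speed_cm_s", "stance_time") %in% names(trials)))
  st <- trials$stance_time; v <- trials$speed_cm_s
  start <- list(a = max(st) - min(st), b = 1 / max(1, diff(range(v))),
                c = min(st))
  fit <- tryCatch(
    minpack.lm::nlsLM(stance_time ~ a * exp(-b * speed_cm_s) + c,
                      data = trials, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  stats::coef(fit)
}
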