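#' Cohort report over multiple trial summaries
#'
#' Collects per-trial summary tables into one wide table and fits the
#' step-parameter-versus-speed relationships: step length (linear), stance
#' time (exponential `a*exp(-b*v)+c`, coefficients reported only), swing
#' time (linear), duty factor (linear, with the walk-to-run crossing
#' speed) and swing speed (linear). Zero-slope or inestimable fits are
#' flagged rather than dropped.
#'
#' @param summaries List of trial summary tibbles (from [run_analyze()]
#'   `$summary`), optionally named by trial.
#' @param out_dir Optional directory for `report_trials.csv` and
#'   `report_fits.csv`.
#' @return A list of class `gait_report`: `trials` (wide per-trial
#'   tibble), `fits` (tibble of fit coefficients), `duty_regression`
#'   (a `duty_regression` object or `NULL`).
#' @export
run_report <- function(summaries, out_dir = NULL) {
  if (length(summaries) < 2) stop("need at least 2 trials", call. = FALSE)
  if (is.null(names(summaries)) || any(!nzchar(names(summaries)))) {
    names(summaries) <- paste0("trial_", seq_along(summaries))
  }
  trials <- purrr::imap_dfr(summaries, function(s, nm) {
    wide <- rlang::set_names(as.list(s$value), s$parameter)
    tibble::as_tibble(wide[canonical_parameters]) |>
      dplyr::mutate(trial = nm, .before = 1)
  })

  lin_fit <- function(yname) {
    d <- trials[!is.na(trials[[yname]]) &
                  !is.na(trials$average_speed_cm_s), , drop = FALSE]
    if (nrow(d) < 2) {
      return(tibble::tibble(response = yname, form = "linear",
                            a = NA_real_, b = NA_real_, c = NA_real_,
                            flagged = TRUE))
    }
    m <- stats::lm(d[[yname]] ~ d$average_speed_cm_s)
    co <- stats::coef(m)
    tibble::tibble(response = yname, form = "linear",
                   a = unname(co[2]), b = unname(co[1]), c = NA_real_,
                   flagged = is.na(co[2]) || abs(co[2]) < 1e-12)
  }
  fits <- dplyr::bind_rows(
    lin_fit("step_length_mm"),
    lin_fit("swing_time_s"),
    lin_fit("swing_speed_m_s")
  )
  st <- trials[!is.na(trials$stance_time_s), , drop = FALSE]
  exp_co <- if (nrow(st) >= 4) {
    fit_stance_time_curve(tibble::tibble(speed_cm_s = st$average_speed_cm_s,
                                         stance_time = st$stance_time_s))
  } else NULL
  if (is.null(exp_co)) exp_co <- c(a = NA_real_, b = NA_real_, c = NA_real_)
  fits <- dplyr::bind_rows(fits, tibble::tibble(
    response = "stance_time_s", form = "a*exp(-b*v)+c",
    a = exp_co[["a"]], b = exp_co[["b"]], c = exp_co[["c"]],
    flagged = anyNA(exp_co)))

  dd <- trials[!is.na(trials$duty_factor), , drop = FALSE]
  dreg <- tryCatch(
    fit_duty_speed_regression(tibble::tibble(
      speed_cm_s = dd$average_speed_cm_s, duty_factor = dd$duty_factor)),
    error = function(e) NULL)
  fits <- dplyr::bind_rows(fits, tibble::tibble(
    response = "duty_factor", form = "linear",
    a = if (is.null(dreg)) NA_real_ else dreg$slope,
    b = if (is.null(dreg)) NA_real_ else dreg$intercept,
    c = if (is.null(dreg)) NA_real_ else dreg$crossing_speed_cm_s,
    flagged = is.null(dreg) || dreg$flagged))

  report <- structure(list(trials = trials, fits = fits,
                           duty_regression = dreg),
                      class = "gait_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table(trials, file.path(out_dir, "report_trials.csv"))
    write_table(fits, file.path(out_dir, "report_fits.csv"))
  }
  report
}

#' @export
print.gait_report <- function(x, ...) {
  cat("Gait report:", nrow(x$trials), "trials\n")
  if (!is.null(x$duty_regression)) print(x$duty_regression)
  invisible(x)
}
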