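#' Exercise trial time series
#'
#' Container for one exercise repetition: uniformly sampled time, ankle
#' angle, net ankle plantarflexion moment, and optionally knee flexion.
#' Angles are stored in radians internally; file interfaces use degrees
#' (see [read_trial()] / [write_trial()]).
#'
#' @param time_s Strictly increasing, uniformly sampled time (s).
#' @param theta_rad Ankle angle (rad, dorsiflexion positive).
#' @param moment_Nm Net ankle plantarflexion moment (N·m, plantarflexion
#'   positive).
#' @param knee_rad Knee flexion angle (rad); scalar or per-frame, default 0
#'   (straight).
#' @param exercise Label: `"heel_drop"`, `"heel_rise"` or `"walk"`.
#' @param events Numeric length-2 vector, start and end event times (s) of
#'   the exercise cycle; defaults to the trial span.
#' @param meta Optional list of provenance metadata (generator spec, seed).
#' @return An object of class `ts_trial` (a data frame with attributes).
#' @export
ts_trial <- function(time_s, theta_rad, moment_Nm, knee_rad = 0,
                     exercise = c("heel_drop", "heel_rise", "walk"),
                     events = NULL, meta = list()) {
  exercise <- match.arg(exercise)
  n <- length(time_s)
  stopifnot(n >= 2, length(theta_rad) == n, length(moment_Nm) == n)
  if (length(knee_rad) == 1L) knee_rad <- rep(knee_rad, n)
  stopifnot(length(knee_rad) == n)
  if (any(!is.finite(time_s)) || any(!is.finite(theta_rad)) ||
      any(!is.finite(moment_Nm)) || any(!is.finite(knee_rad)))
    stop("trial series must be finite")
  dt <- diff(time_s)
  if (any(dt <= 0)) stop("time must be strictly increasing")
  if (diff(range(dt)) > 1e-6 * mean(dt))
    stop("time must be uniformly sampled")
  if (is.null(events)) events <- c(time_s[1], time_s[n])
  stopifnot(length(events) == 2)
  if (events[2] <= events[1]) stop("events must be increasing")
  if (events[1] < time_s[1] - 1e-9 || events[2] > time_s[n] + 1e-9)
    stop("event times must lie within the trial span")
  structure(
    data.frame(time_s = time_s, theta_rad = theta_rad,
               moment_Nm = moment_Nm, knee_rad = knee_rad),
    exercise = exercise, events = events, meta = meta,
    class = c("ts_trial", "data.frame"))
}

#' @export
print.ts_trial <- function(x, ...) {
  cat(sprintf(
    "<ts_trial> %s: %d frames over %.2f s; ankle %.1f..%.1f deg, moment %.1f..%.1f N.m\n",
    attr(x, "exercise"), nrow(x), diff(range(x$time_s)),
    min(x$theta_rad) * 180 / pi, max(x$theta_rad) * 180 / pi,
    min(x$moment_Nm), max(x$moment_Nm)))
  invisible(x)
}
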