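#' Exercise specification for the synthetic trial generator
#'
#' Defines the kinematic/kinetic conditions of one exercise repetition.  The
#' defaults encode the study conditions emulated by the generator: bilateral
#' heel drop and heel rise on a 15-cm box, 3 s per repetition paced by a
#' 1-Hz metronome, for an 85-kg participant; self-paced walking stance.
#'
#' @param exercise `"heel_drop"`, `"heel_rise"` or `"walk"`.
#' @param duration Repetition (or stance) duration (s).
#' @param range_deg Ankle-angle range (deg, dorsiflexion positive):
#'   for the heel exercises the plantarflexed and dorsiflexed end postures,
#'   for walking the extreme stance angles.
#' @param body_mass Participant mass (kg).
#' @param lever Forefoot lever arm of the ground reaction force about the
#'   ankle (m), used by the quasi-static heel-exercise moment model.
#' @param moment_scale Walking peak plantarflexion moment per body mass
#'   (N·m/kg).
#' @param sample_rate Sampling rate (Hz).
#' @param noise_sd_deg,noise_sd_Nm Gaussian measurement-noise standard
#'   deviations for angle (deg) and moment (N·m).
#' @param seed Integer seed for the trial's random-number stream.
#' @return An object of class `exercise_spec`.
#' @export
exercise_spec <- function(exercise = c("heel_drop", "heel_rise", "walk"),
                          duration = NULL, range_deg = NULL, body_mass = 85,
                          lever = 0.12, moment_scale = 1.4,
                          sample_rate = 100, noise_sd_deg = 0,
                          noise_sd_Nm = 0, seed = 0L) {
  exercise <- match.arg(exercise)
  if (is.null(duration)) duration <- if (exercise == "walk") 0.7 else 3.0
  if (is.null(range_deg))
    range_deg <- if (exercise == "walk") c(-15, 12) else c(-20, 15)
  stopifnot(duration > 0, sample_rate > 0, body_mass > 0, lever > 0,
            moment_scale > 0, noise_sd_deg >= 0, noise_sd_Nm >= 0,
            length(range_deg) == 2)
  structure(
    list(exercise = exercise, duration = duration, range_deg = range_deg,
         body_mass = body_mass, lever = lever, moment_scale = moment_scale,
         sample_rate = sample_rate, noise_sd_deg = noise_sd_deg,
         noise_sd_Nm = noise_sd_Nm, seed = as.integer(seed),
         cadence_hz = if (exercise == "walk") NA_real_ else 1.0),
    class = "exercise_spec")
}

## Minimum-jerk (quintic) interpolant on s in [0, 1]: C^2, zero end
## velocities and accelerations.
.min_jerk <- function(s) 10 * s^3 - 15 * s^4 + 6 * s^5

.gen_heel <- function(spec, seed, reverse) {
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  set.seed(spec$seed)
  n <- round(spec$duration * spec$sample_rate) + 1L
  t <- seq(0, spec$duration, length.out = n)
  s <- t / spec$duration
  from <- spec$range_deg[1]; to <- spec$range_deg[2]
  if (reverse) { tmp <- from; from <- to; to <- tmp }
  theta_deg <- from + (to - from) * .min_jerk(s)
  # quasi-static forefoot lever under half body weight (bilateral stance)
  g <- 9.80665
  moment <- 0.5 * spec$body_mass * g * spec$lever *
    cos(theta_deg * pi / 180)
  theta_deg <- theta_deg + stats::rnorm(n, 0, spec$noise_sd_deg)
  moment <- moment + stats::rnorm(n, 0, spec$noise_sd_Nm)
  ts_trial(t, theta_deg * pi / 180, moment,
           exercise = if (reverse) "heel_rise" else "heel_drop",
           events = c(0, spec$duration),
           meta = list(spec = unclass(spec), seed = spec$seed,
                       cadence_hz = spec$cadence_hz))
}

#' Generate synthetic exercise trials
#'
#' `gen_heel_drop()` produces an eccentric bilateral heel drop: a
#' minimum-jerk ankle sweep from the plantarflexed to the dorsiflexed end
#' posture (lengthening the plantarflexor muscle-tendon units) under the
#' quasi-static forefoot-lever moment `0.5 * body_mass * g * lever *
#' cos(theta)`.  `gen_heel_rise()` is the exact time-reverse (concentric).
#' `gen_walk()` produces a stance-phase profile: brief loading
#' plantarflexion, a dorsiflexion ramp, then push-off plantarflexion, with
#' the plantarflexion moment rising to a single push-off peak of
#' `moment_scale * body_mass` N·m.  All profiles are smooth and reproducible
#' given the seed; event times (cycle start/end) are attached to the trial.
#'
#' @param spec An [exercise_spec()]; a default one is built when omitted.
#' @param seed Optional integer overriding the spec's seed.
#' @return A [ts_trial()].
#' @export
#' @examples
#' tr <- gen_heel_drop()
#' range(tr$theta_rad) * 180 / pi
gen_heel_drop <- function(spec = exercise_spec("heel_drop"), seed = NULL) {
  stopifnot(inherits(spec, "exercise_spec"))
  .gen_heel(spec, seed, reverse = FALSE)
}

#' @rdname gen_heel_drop
#' @export
gen_heel_rise <- function(spec = exercise_spec("heel_rise"), seed = NULL) {
  stopifnot(inherits(spec, "exercise_spec"))
  .gen_heel(spec, seed, reverse = TRUE)
}

#' @rdname gen_heel_drop
#' @export
gen_walk <- function(spec = exercise_spec("walk"), seed = NULL) {
  stopifnot(inherits(spec, "exercise_spec"))
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  set.seed(spec$seed)
  n <- round(spec$duration * spec$sample_rate) + 1L
  t <- seq(0, spec$duration, length.out = n)
  s <- t / spec$duration
  lo <- spec$range_deg[1]; hi <- spec$range_deg[2]
  ## piecewise minimum-jerk knots: initial contact slightly plantarflexed,
  ## loading response to the plantarflexed extreme, dorsiflexion ramp to the
  ## dorsiflexed extreme at 70% stance, push-off back to plantarflexion
  knots_s <- c(0, 0.15, 0.70, 1)
  knots_th <- c(lo / 3, lo, hi, lo)
  theta_deg <- numeric(n)
  for (k in seq_len(length(knots_s) - 1)) {
    idx <- s >= knots_s[k] & s <= knots_s[k + 1]
    u <- (s[idx] - knots_s[k]) / (knots_s[k + 1] - knots_s[k])
    theta_deg[idx] <- knots_th[k] + (knots_th[k + 1] - knots_th[k]) *
      .min_jerk(u)
  }
  ## single push-off peak, maximum at 75% stance
  m_peak <- spec$moment_scale * spec$body_mass
  shape <- s^3 * (1 - s)
  moment <- m_peak * shape / max(shape)
  theta_deg <- theta_deg + stats::rnorm(n, 0, spec$noise_sd_deg)
  moment <- moment + stats::rnorm(n, 0, spec$noise_sd_Nm)
  ts_trial(t, theta_deg * pi / 180, moment, exercise = "walk",
           events = c(0, spec$duration),
           meta = list(spec = unclass(spec), seed = spec$seed))
}

#' Generate a trial by exercise label
#'
#' Dispatch helper used by the grid runner and the command-line interface.
#'
#' @param exercise Exercise label.
#' @param seed Integer seed.
#' @param ... Passed to [exercise_spec()].
#' @return A [ts_trial()].
#' @export
gen_trial <- function(exercise, seed = 0L, ...) {
  spec <- exercise_spec(exercise, seed = seed, ...)
  switch(spec$exercise,
         heel_drop = gen_heel_drop(spec),
         heel_rise = gen_heel_rise(spec),
         walk = gen_walk(spec))
}
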