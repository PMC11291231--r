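#' Derive the tendon compliance model set
#'
#' Constructs the four normalized tendon stiffness values used by the
#' compliance analysis from the generic (healthy control) value: the mean
#' tendinopathic model is the generic value reduced by `at_reduction`
#' (tendinopathic tendons are more compliant), the compliant model subtracts
#' two tendinopathic standard deviations from the mean model, and the stiff
#' model adds two control-group standard deviations to the generic value.
#' With the defaults this yields stiffness 21 (compliant), 28 (mean),
#' 35 (generic) and 47 (stiff).
#'
#' @param generic_k Generic normalized tendon stiffness (default 35).
#' @param at_reduction Fractional stiffness reduction of the tendinopathic
#'   group mean (default 0.20).
#' @param sd_at Tendinopathic-group standard deviation of normalized
#'   stiffness (default 3.5).
#' @param sd_ctrl Control-group standard deviation (default 6.0).
#' @return An object of class `compliance_set`: list with numeric fields
#'   `compliant < mean < generic < stiff` (each rounded to the nearest
#'   integer for reporting, as the values are quoted) and the exact
#'   unrounded values in `exact`.
#' @export
#' @examples
#' derive_compliance_models()  # 21, 28, 35, 47
derive_compliance_models <- function(generic_k = 35, at_reduction = 0.20,
                                     sd_at = 3.5, sd_ctrl = 6.0) {
  stopifnot(is.numeric(generic_k), generic_k > 0,
            is.numeric(at_reduction), at_reduction >= 0, at_reduction < 1,
            sd_at >= 0, sd_ctrl >= 0)
  m <- generic_k * (1 - at_reduction)
  compliant <- m - 2 * sd_at
  stiff <- generic_k + 2 * sd_ctrl
  if (compliant <= 0)
    stop("derived compliant stiffness is not positive (", compliant, ")")
  structure(
    list(compliant = round(compliant), mean = round(m),
         generic = round(generic_k), stiff = round(stiff),
         exact = c(compliant = compliant, mean = m, generic = generic_k,
                   stiff = stiff)),
    class = "compliance_set")
}

#' @export
print.compliance_set <- function(x, ...) {
  cat(sprintf("<compliance_set> compliant=%g mean=%g generic=%g stiff=%g\n",
              x$compliant, x$mean, x$generic, x$stiff))
  invisible(x)
}

#' Frame of peak total triceps surae force
#'
#' Index of the first maximum of the summed muscle forces in a solved
#' trajectory.
#'
#' @param traj A `force_trajectory` (see [solve_trial()]).
#' @return Integer frame index.
#' @export
peak_index <- function(traj) {
  stopifnot(inherits(traj, "force_trajectory"))
  tot <- rowSums(traj$force)
  if (length(tot) == 0) stop("empty trajectory")
  if (all(tot <= 0)) stop("no peak defined: total muscle force is never positive")
  which.max(tot)  # first occurrence on exact ties
}

#' Muscle contributions at peak total force
#'
#' Percentage contribution of each muscle to the total triceps surae force
#' at the frame of peak total force: individual force divided by the sum of
#' the three muscle forces, times 100.
#'
#' @param traj A `force_trajectory`.
#' @return Named numeric vector of percentages summing to 100.
#' @export
contributions_at_peak <- function(traj) {
  i <- peak_index(traj)
  f <- traj$force[i, ]
  tot <- sum(f)
  if (tot <= 0) stop("zero total force at peak")
  100 * f / tot
}

#' Normalize a trial to the exercise cycle
#'
#' Resamples a trial onto 101 points spanning 0-100% of the exercise cycle
#' defined by two event times (cycle start and end), by linear
#' interpolation.
#'
#' @param trial A [ts_trial()].
#' @param events Numeric length-2 event times (s); defaults to the trial's
#'   stored events.
#' @return A data frame with columns `pct` (0..100), `theta_rad`,
#'   `moment_Nm`, `knee_rad`.
#' @export
normalize_time <- function(trial, events = attr(trial, "events")) {
  stopifnot(inherits(trial, "ts_trial"), length(events) == 2)
  if (events[2] <= events[1]) stop("events must be increasing")
  if (events[1] < trial$time_s[1] - 1e-9 ||
      events[2] > trial$time_s[nrow(trial)] + 1e-9)
    stop("event times must lie within the trial span")
  tt <- seq(events[1], events[2], length.out = 101L)
  data.frame(
    pct = seq(0, 100, length.out = 101L),
    theta_rad = stats::approx(trial$time_s, trial$theta_rad, tt)$y,
    moment_Nm = stats::approx(trial$time_s, trial$moment_Nm, tt)$y,
    knee_rad = stats::approx(trial$time_s, trial$knee_rad, tt)$y)
}

#' Run the twist x compliance x exercise grid
#'
#' Solves every combination of exercise, twist class and tendon compliance
#' and tabulates the per-muscle percentage contributions at peak total
#' triceps surae force, together with difference tables (percentage points)
#' against the generic no-twist, generic-compliance reference row of each
#' exercise.
#'
#' @param exercises Character vector of exercise labels.
#' @param twists Character vector of twist classes.
#' @param k_ts Numeric vector of normalized tendon stiffness values.
#' @param scale Insertion enlargement factor applied to all twisted models.
#' @param config Model configuration passed to [ts_model()].
#' @param seed Integer seed forwarded to the trial generator.
#' @param generic_k Stiffness of the reference row (default 35).
#' @param sample_rate Trial sampling rate (Hz) forwarded to the generator.
#' @return An object of class `sharing_table`: list with `sharing` (data
#'   frame: exercise, twist, k_t, SOL, GM, GL), `diffs` (same layout, in
#'   percentage points relative to the reference row), and `stats` (list
#'   with `max_abs_change_twist` over twisted rows at the reference
#'   stiffness and `max_abs_change_compliance` over no-twist rows across
#'   stiffness values).
#' @export
#' @examples
#' \donttest{
#' gr <- grid_run(exercises = "heel_drop", twists = "none", k_ts = 35)
#' gr$sharing
#' }
grid_run <- function(exercises = c("heel_drop", "heel_rise", "walk"),
                     twists = c("none", "low", "medium", "high"),
                     k_ts = c(21, 28, 35, 47), scale = 1.0, config = NULL,
                     seed = 0L, generic_k = 35, sample_rate = 100) {
  stopifnot(length(exercises) >= 1, length(twists) >= 1, length(k_ts) >= 1)
  rows <- list()
  for (ex in exercises) {
    trial <- gen_trial(ex, seed = seed, sample_rate = sample_rate)
    for (tw in twists) {
      for (kt in k_ts) {
        model <- ts_model(config, k_t = kt, twist = tw, scale = scale)
        traj <- solve_trial(trial, model)
        ct <- contributions_at_peak(traj)
        rows[[length(rows) + 1L]] <- data.frame(
          exercise = ex, twist = tw, k_t = kt,
          SOL = ct[["SOL"]], GM = ct[["GM"]], GL = ct[["GL"]],
          peak_frame = peak_index(traj),
          peak_force_N = max(rowSums(traj$force)),
          flagged = any(traj$flagged))
      }
    }
  }
  sharing <- do.call(rbind, rows)
  rownames(sharing) <- NULL

  ## reference: generic compliance, no-twist row per exercise
  diffs <- sharing
  for (ex in unique(sharing$exercise)) {
    ref <- sharing[sharing$exercise == ex & sharing$twist == "none" &
                   sharing$k_t == generic_k, c("SOL", "GM", "GL")]
    sel <- diffs$exercise == ex
    if (nrow(ref) == 1) {
      diffs[sel, c("SOL", "GM", "GL")] <-
        sweep(as.matrix(sharing[sel, c("SOL", "GM", "GL")]), 2,
              as.numeric(ref[1, ]), "-")
    } else {
      diffs[sel, c("SOL", "GM", "GL")] <- NA_real_
    }
  }
  diffs$peak_frame <- diffs$peak_force_N <- diffs$flagged <- NULL

  tw_sel <- diffs$k_t == generic_k & diffs$twist != "none"
  co_sel <- diffs$twist == "none"
  stats <- list(
    max_abs_change_twist =
      if (any(tw_sel)) max(abs(as.matrix(diffs[tw_sel, c("SOL", "GM", "GL")])))
      else NA_real_,
    max_abs_change_compliance =
      if (any(co_sel)) max(abs(as.matrix(diffs[co_sel, c("SOL", "GM", "GL")])),
                           na.rm = TRUE)
      else NA_real_)

  structure(list(sharing = sharing, diffs = diffs, stats = stats,
                 seed = seed, generic_k = generic_k),
            class = "sharing_table")
}

#' @export
print.sharing_table <- function(x, ...) {
  cat("<sharing_table> contributions at peak total triceps surae force (%)\n")
  df <- x$sharing
  df$SOL <- round(df$SOL, 2); df$GM <- round(df$GM, 2); df$GL <- round(df$GL, 2)
  print(df[, c("exercise", "twist", "k_t", "SOL", "GM", "GL")],
        row.names = FALSE)
  if (is.finite(x$stats$max_abs_change_twist))
    cat(sprintf("max |change| vs no-twist at k_t=%g: %.2f pp\n",
                x$generic_k, x$stats$max_abs_change_twist))
  invisible(x)
}

#' Fiber operating-point report
#'
#' Summarizes where each muscle operated on its force-length and
#' force-velocity curves over a solved trajectory: minimum, mean and maximum
#' normalized fiber length and velocity, and the limb of the force-length
#' curve occupied by the mean operating length (ascending < 0.95, plateau
#' 0.95-1.05, descending > 1.05).
#'
#' @param traj A `force_trajectory`.
#' @return Data frame, one row per muscle.
#' @export
operating_point_report <- function(traj) {
  stopifnot(inherits(traj, "force_trajectory"))
  mus <- colnames(traj$lm_norm)
  do.call(rbind, lapply(mus, function(m) {
    l <- traj$lm_norm[, m]; v <- traj$vm_norm[, m]
    mean_l <- mean(l)
    limb <- if (mean_l < 0.95) "ascending"
            else if (mean_l <= 1.05) "plateau" else "descending"
    data.frame(muscle = m, lm_min = min(l), lm_mean = mean_l,
               lm_max = max(l), vm_min = min(v), vm_mean = mean(v),
               vm_max = max(v), limb = limb)
  }))
}
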