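## Muscle redundancy solver: minimize the sum of squared activations plus a
## heavily penalized residual torque, subject to elastic-tendon muscle
## mechanics and exact moment equilibrium.
##
## The problem  min_a  sum(a^2) + w (res/s)^2,  res = M - sum(r_m f_m(a_m)),
## 0 <= a <= 1, has the exact gradient  2 a_m - 2 (w/s^2) res r_m f_m'(a_m)
## with f_m'(a) from implicit differentiation of the fiber-tendon
## equilibrium, and a Gauss-Newton Hessian  2 I + 2 (w/s^2) q q^T  with
## q_m = r_m f_m'(a_m): diagonal plus rank one, so the Newton step has a
## closed form (Sherman-Morrison).  A projected Newton iteration with
## backtracking line search and bound freezing solves each frame to KKT
## stationarity; the strict convexity of the cost makes the solution unique.



#' Solve one frame of the muscle redundancy problem
#'
#' Distributes a net ankle plantarflexion moment over the model's muscles by
#' minimizing the sum of squared activations plus a heavily penalized
#' residual torque, subject to elastic-tendon Hill-type muscle mechanics and
#' tendon-excursion moment arms.  Moment equilibrium
#' `sum(r_m f_m) + residual = moment` holds exactly by construction; the
#' residual actuator absorbs what the muscles cannot (or should not, at
#' quadratic cost) produce and is flagged when it exceeds its bound.
#'
#' @param model A [ts_model()].
#' @param theta Ankle angle (rad, dorsiflexion positive).
#' @param moment Net plantarflexion moment (N·m).
#' @param vm_norm Named numeric vector of normalized fiber velocities held
#'   fixed during the solve (default all zero, i.e. isometric fibers).
#' @param knee Knee flexion angle (rad).
#' @param warm Optional warm start: the `warm` element of a previous result.
#' @return List with named vectors `a`, `force` (N), `r` (moment arms, m),
#'   per-muscle `states`, the `residual` (N·m), the shadow price `lambda`,
#'   logical `flagged` (residual bound exceeded), `kkt` (maximal projected
#'   KKT violation) and `warm` (warm-start data for the next frame).
#' @export
#' @examples
#' m <- ts_model()
#' fr <- solve_frame(m, theta = 0.1, moment = 40)
#' fr$force
solve_frame <- function(model, theta, moment, vm_norm = NULL, knee = 0,
                        warm = NULL) {
  stopifnot(inherits(model, "ts_model"))
  if (!is.finite(theta) || !is.finite(moment))
    stop("theta and moment must be finite")
  mus <- names(model$muscles)
  if (is.null(vm_norm)) vm_norm <- stats::setNames(rep(0, length(mus)), mus)
  stopifnot(all(mus %in% names(vm_norm)))

  l_mt <- vapply(mus, function(m) mtu_length(theta, model$paths[[m]], knee),
                 numeric(1))
  r <- vapply(mus, function(m) moment_arm(theta, model$paths[[m]], knee),
              numeric(1))
  w_res <- model$residual$weight
  s_res <- model$residual$scale
  ctx <- sprintf("theta=%.4f rad", theta)

  a_ws <- if (!is.null(warm)) warm$a else stats::setNames(rep(0.05, length(mus)), mus)
  w_ws <- if (!is.null(warm)) warm$w else stats::setNames(rep(NA_real_, length(mus)), mus)

  wt <- w_res / s_res^2
  nm <- length(mus)

  fv_vals <- vapply(mus, function(m) force_velocity(vm_norm[[m]]), numeric(1))

  ## Solve all muscle equilibria at an activation vector, warm-starting the
  ## fiber-extent root from the previous evaluation.
  eval_a <- function(a) {
    sols <- vector("list", nm)
    f <- numeric(nm)
    for (j in seq_len(nm)) {
      m <- mus[j]
      sols[[j]] <- .eq_core(a[j], l_mt[[m]], fv_vals[[m]],
                            model$muscles[[m]], model$curve,
                            w0 = w_ws[[m]], context = ctx)
      w_ws[[m]] <<- sols[[j]]$w
      f[j] <- sols[[j]]$f
    }
    res <- moment - sum(r * f)
    list(sols = sols, f = f, res = res, g = sum(a^2) + wt * res^2)
  }

  snap <- function(a) {
    a[a < 1e-9] <- 0
    a[a > 1 - 1e-9] <- 1
    a
  }
  tol_pg <- 1e-8

  run_solve <- function(a_init) {
  a <- snap(pmin(pmax(a_init, 0), 1))
  ev <- eval_a(a)

  ## Phase 1: projected Gauss-Newton descent on the penalized objective
  ## (globally convergent; conditioning of the penalty limits how tightly
  ## it can resolve the multiplier, hence the polish phase below).
  for (it in seq_len(150)) {
    q <- r * vapply(ev$sols, function(s) s$df, numeric(1))
    grad <- 2 * a - 2 * wt * ev$res * q
    frozen <- (a <= 0 & grad > 0) | (a >= 1 & grad < 0)
    pg <- grad
    pg[frozen] <- 0
    if (max(abs(pg)) < tol_pg) break
    qf <- q
    qf[frozen] <- 0
    cc <- 2 * wt
    qn2 <- sum(qf^2)
    if (qn2 > 0) {
      qh <- qf / sqrt(qn2)
      par <- sum(pg * qh)
      d <- -(pg - par * qh) / 2 - (par / (2 + cc * qn2)) * qh
    } else {
      d <- -pg / 2
    }
    d[frozen] <- 0
    alpha <- 1
    improved <- FALSE
    dec <- sum(pg * d)
    for (ls in seq_len(40)) {
      a_new <- snap(pmin(pmax(a + alpha * d, 0), 1))
      if (all(a_new == a)) { alpha <- alpha / 2; next }
      ev_new <- eval_a(a_new)
      if (ev_new$g <= ev$g + 1e-4 * alpha * dec ||
          ev_new$g < ev$g - 1e-14 * max(1, abs(ev$g))) {
        a <- a_new; ev <- ev_new; improved <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!improved) break
  }

  ## Phase 2: primal-dual Newton polish of the KKT system.
  lambda <- 2 * wt * ev$res
  ## Scaled KKT residual: stationarity F_a = 2a - lambda q on the free set
  ## and multiplier consistency F_l = lambda - 2 wt res, the latter scaled
  ## into stationarity units so the merit balances both blocks.
  kkt_res <- function(a, lambda, ev) {
    q <- r * vapply(ev$sols, function(s) s$df, numeric(1))
    F_a <- 2 * a - lambda * q
    frozen <- (a <= 0 & F_a > 0) | (a >= 1 & F_a < 0)
    F_a[frozen] <- 0
    list(q = q, F_a = F_a, frozen = frozen,
         F_l = lambda - 2 * wt * ev$res)
  }
  kr <- kkt_res(a, lambda, ev)
  l_scale <- max(abs(kr$q), 1e-8)  # converts multiplier units to gradient units
  merit <- function(kr) sum(kr$F_a^2) + (kr$F_l * l_scale)^2
  for (it in seq_len(50)) {
    if (max(abs(kr$F_a)) < tol_pg && abs(kr$F_l) * l_scale < tol_pg) break
    ## primal-dual Newton step on the free set:
    ##   J da - q dl = -F_a,   2 wt q^T da + dl = -F_l
    ## with the true diagonal J_mm = 2 - lambda dq_m/da_m (the curvature of
    ## the muscle force in activation matters at short fiber lengths)
    qf <- kr$q
    qf[kr$frozen] <- 0
    h <- 1e-4
    Jd <- vapply(seq_len(nm), function(j) {
      if (kr$frozen[j] || qf[j] == 0) return(2)
      m <- mus[j]
      ap <- min(1, a[j] + h); am <- max(0, a[j] - h)
      dq <- r[[j]] *
        (.eq_core(ap, l_mt[[m]], fv_vals[[m]], model$muscles[[m]],
                  model$curve, w0 = w_ws[[m]])$df -
         .eq_core(am, l_mt[[m]], fv_vals[[m]], model$muscles[[m]],
                  model$curve, w0 = w_ws[[m]])$df) / (ap - am)
      max(0.5, 2 - lambda * dq)
    }, numeric(1))
    Jinv <- ifelse(kr$frozen, 0, 1 / Jd)
    dl <- (-kr$F_l + 2 * wt * sum(qf * Jinv * kr$F_a)) /
      (1 + 2 * wt * sum(qf^2 * Jinv))
    da <- Jinv * (-kr$F_a + qf * dl)
    da[kr$frozen] <- 0
    phi <- merit(kr)
    alpha <- 1
    improved <- FALSE
    for (ls in seq_len(30)) {
      a_new <- snap(pmin(pmax(a + alpha * da, 0), 1))
      l_new <- lambda + alpha * dl
      if (all(a_new == a) && l_new == lambda) { alpha <- alpha / 2; next }
      ev_new <- eval_a(a_new)
      kr_new <- kkt_res(a_new, l_new, ev_new)
      if (merit(kr_new) < phi * (1 - 1e-4 * alpha)) {
        a <- a_new; lambda <- l_new; ev <- ev_new; kr <- kr_new
        improved <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!improved) break  # numerically converged
  }

  ## projected stationarity against the penalty-implied multiplier
  lam_star <- 2 * wt * ev$res
  dfv <- vapply(ev$sols, function(s) s$df, numeric(1))
  kkt <- max(vapply(seq_len(nm), function(j) {
    g <- 2 * a[[j]] - lam_star * r[[j]] * dfv[j]
    if (a[[j]] <= 0) max(0, -g) else if (a[[j]] >= 1) max(0, g) else abs(g)
  }, numeric(1)))
  list(a = a, ev = ev, kkt = kkt)
  }

  sol <- run_solve(as.numeric(a_ws[mus]))
  if (sol$kkt > 1e-6) {
    ## rare warm-start-dependent stall: retry once from a fixed cold start
    alt <- run_solve(rep(0.25, nm))
    if (alt$kkt < sol$kkt) sol <- alt
  }
  a <- sol$a
  ev <- sol$ev
  kkt <- sol$kkt

  f <- ev$f
  states <- lapply(seq_len(nm), function(j) {
    s <- ev$sols[[j]]
    structure(list(a = a[j], l_m_norm = s$lmn, v_m_norm = vm_norm[[mus[j]]],
                   f_t = s$f, f_t_norm = s$ftn, l_t_norm = s$ltn,
                   cos_alpha = s$cosa, residual = s$res, w = s$w),
              class = "mtu_state")
  })
  names(states) <- mus
  names(a) <- names(f) <- mus
  residual <- ev$res
  lambda <- 2 * wt * residual

  list(a = a, force = f, r = r, states = states, residual = residual,
       lambda = lambda, flagged = abs(residual) > model$residual$bound,
       kkt = kkt,
       warm = list(a = a, w = vapply(states, function(s) s$w, numeric(1)),
                   lambda = lambda))
}

#' Solve a full trial
#'
#' Frame-wise redundancy solutions over a trial: a first pass with isometric
#' fibers yields equilibrium fiber lengths, fiber velocities are then formed
#' by finite differences of those lengths, and a single fixed-point pass
#' re-solves every frame with the velocities held fixed.  Deterministic
#' given inputs; warm starts are defined by the previous frame.
#'
#' @param trial A [ts_trial()].
#' @param model A [ts_model()].
#' @return An object of class `force_trajectory`: list with the `trial`,
#'   per-muscle matrices `a`, `force` (N), `lm_norm`, `vm_norm` (frames x
#'   muscles), vectors `residual` (N·m) and `flagged`, `kkt`, and the model
#'   metadata (`k_t`, `twist`, `scale`).
#' @export
#' @examples
#' tr <- gen_heel_drop()
#' traj <- solve_trial(tr, ts_model())
#' contributions_at_peak(traj)
solve_trial <- function(trial, model) {
  stopifnot(inherits(trial, "ts_trial"), inherits(model, "ts_model"))
  mus <- names(model$muscles)
  n <- nrow(trial)
  run_pass <- function(vm, warms = NULL) {
    a <- force <- lm <- vmn <- matrix(NA_real_, n, length(mus),
                                      dimnames = list(NULL, mus))
    residual <- kkt <- numeric(n)
    flagged <- logical(n)
    warm_out <- vector("list", n)
    warm <- NULL
    for (i in seq_len(n)) {
      fr <- solve_frame(model, trial$theta_rad[i], trial$moment_Nm[i],
                        vm_norm = vm[i, ], knee = trial$knee_rad[i],
                        warm = if (!is.null(warms)) warms[[i]] else warm)
      warm <- fr$warm
      warm_out[[i]] <- fr$warm
      a[i, ] <- fr$a[mus]
      force[i, ] <- fr$force[mus]
      lm[i, ] <- vapply(fr$states[mus], function(s) s$l_m_norm, numeric(1))
      vmn[i, ] <- vm[i, mus]
      residual[i] <- fr$residual
      flagged[i] <- fr$flagged
      kkt[i] <- fr$kkt
    }
    list(a = a, force = force, lm = lm, vm = vmn, residual = residual,
         flagged = flagged, kkt = kkt, warms = warm_out)
  }

  vm0 <- matrix(0, n, length(mus), dimnames = list(NULL, mus))
  p1 <- run_pass(vm0)

  ## finite-difference fiber velocities from pass-1 equilibrium lengths
  vm <- vm0
  dt <- diff(trial$time_s)
  for (m in mus) {
    l_m <- p1$lm[, m] * model$muscles[[m]]$l_m_opt
    v <- c(
      (l_m[2] - l_m[1]) / dt[1],
      (l_m[-(1:2)] - l_m[-c(n - 1, n)]) / (trial$time_s[-(1:2)] -
                                            trial$time_s[-c(n - 1, n)]),
      (l_m[n] - l_m[n - 1]) / dt[n - 1])
    vm[, m] <- v / (model$muscles[[m]]$l_m_opt * model$muscles[[m]]$v_m_max)
  }
  p2 <- run_pass(vm, warms = p1$warms)

  structure(
    list(trial = trial, a = p2$a, force = p2$force, lm_norm = p2$lm,
         vm_norm = p2$vm, residual = p2$residual, flagged = p2$flagged,
         kkt = p2$kkt, k_t = model$curve$k_t,
         twist = model$insertions$twist_class,
         scale = model$insertions$scale),
    class = "force_trajectory")
}

#' @export
print.force_trajectory <- function(x, ...) {
  tot <- rowSums(x$force)
  cat(sprintf(
    "<force_trajectory> %s, k_t=%g, twist=%s: %d frames, peak total force %.0f N\n",
    attr(x$trial, "exercise"), x$k_t, x$twist, nrow(x$trial), max(tot)))
  invisible(x)
}

#' Flatten a force trajectory to a data frame
#'
#' One row per frame and muscle with activation, tendon force, normalized
#' fiber length and velocity, and the frame's residual moment (the results
#' CSV dialect).
#'
#' @param x A `force_trajectory`.
#' @param row.names,optional,... Passed for S3 compatibility; unused.
#' @return A data frame.
#' @export
as.data.frame.force_trajectory <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  mus <- colnames(x$force)
  do.call(rbind, lapply(seq_along(mus), function(j) {
    data.frame(frame = seq_len(nrow(x$trial)), time_s = x$trial$time_s,
               muscle = mus[j], activation = x$a[, j],
               force_N = x$force[, j], lm_norm = x$lm_norm[, j],
               vm_norm = x$vm_norm[, j], residual_Nm = x$residual)
  }))
}
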