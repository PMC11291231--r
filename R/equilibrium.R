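## Elastic-tendon fiber equilibrium.
##
## State variable is w, the projection of the fiber on the tendon line of
## action ("horizontal" fiber extent under the fixed-height pennation model),
## so that l_t = l_mt - w, l_m = sqrt(w^2 + h^2).  The equilibrium condition
## in normalized force units is
##    f_T(l_t / l_t_slack) = (a fl(l_m~) fv(v_m~) + fp(l_m~)) cos(alpha).

.eq_residual <- function(w, a, fv_val, l_mt, params, curve) {
  p <- .pennation(w, params)
  lmn <- p$l_m / params$l_m_opt
  ltn <- (l_mt - w) / params$l_t_slack
  fm <- a * active_fl(lmn) * fv_val + passive_fl(lmn)
  tendon_force_norm(ltn, curve) - fm * p$cos_a
}

.eq_residual_d <- function(w, a, fv_val, l_mt, params, curve) {
  p <- .pennation(w, params)
  lmn <- p$l_m / params$l_m_opt
  ltn <- (l_mt - w) / params$l_t_slack
  fm <- a * active_fl(lmn) * fv_val + passive_fl(lmn)
  dfm <- a * active_fl_d(lmn) * fv_val + passive_fl_d(lmn)
  dlmn_dw <- p$cos_a / params$l_m_opt
  dcos_dw <- params$h^2 / p$l_m^3
  -tendon_dforce_norm(ltn, curve) / params$l_t_slack -
    (dfm * dlmn_dw * p$cos_a + fm * dcos_dw)
}

#' Solve the fiber-tendon force equilibrium
#'
#' Given an activation and the musculotendon length, find the fiber length at
#' which the force transmitted by the fiber along the tendon line of action
#' equals the elastic tendon force (a safeguarded Newton iteration with
#' bisection fallback; the residual is driven below `tol` in normalized force
#' units).
#'
#' @param a Activation in `[0, 1]`.
#' @param l_mt Musculotendon length (m); must exceed half the tendon slack
#'   length.
#' @param v_mt Musculotendon lengthening velocity (m/s), used only to form a
#'   default fiber-velocity estimate when `vm_norm` is not given.
#' @param params A [muscle_params()].
#' @param curve A [tendon_curve()].
#' @param vm_norm Normalized fiber velocity held fixed during the solve; if
#'   `NULL`, estimated as `v_mt / (l_m_opt v_m_max cos(alpha_opt))` (tendon
#'   velocity neglected).
#' @param w0 Optional warm-start for the fiber extent (m).
#' @param tol Convergence tolerance on the normalized force residual
#'   (near machine precision by default).
#' @param context Optional string (e.g. a frame label) used in error
#'   messages.
#' @return An object of class `mtu_state`: a list with activation `a`,
#'   normalized fiber length `l_m_norm`, normalized fiber velocity `v_m_norm`,
#'   tendon force `f_t` (N), `f_t_norm`, `l_t_norm`, `cos_alpha`, the achieved
#'   `residual` and the fiber extent `w` (m).
#' @export
#' @examples
#' p <- muscle_params("SOL", 2839, 0.030, 0.268, 25 * pi / 180)
#' st <- solve_fiber_equilibrium(0.5, 0.298, 0, p, tendon_curve(35))
#' st$f_t
solve_fiber_equilibrium <- function(a, l_mt, v_mt = 0, params, curve,
                                    vm_norm = NULL, w0 = NULL, tol = 1e-14,
                                    context = NULL) {
  stopifnot(inherits(params, "muscle_params"), inherits(curve, "tendon_curve"))
  if (!is.finite(a) || a < 0 || a > 1) stop("activation must be in [0, 1]")
  if (!is.finite(l_mt) || l_mt <= 0.5 * params$l_t_slack)
    stop(sprintf("l_mt (%g) must exceed half the tendon slack length for %s",
                 l_mt, params$name))
  if (is.null(vm_norm))
    vm_norm <- v_mt / (params$l_m_opt * params$v_m_max * cos(params$alpha_opt))
  fv_val <- force_velocity(vm_norm)

  co <- .eq_core(a, l_mt, fv_val, params, curve,
                 w0 = if (is.null(w0)) NA_real_ else w0, tol = tol,
                 context = context)
  structure(
    list(a = a, l_m_norm = co$lmn, v_m_norm = vm_norm,
         f_t = co$f, f_t_norm = co$ftn, l_t_norm = co$ltn,
         cos_alpha = co$cosa, residual = co$res, w = co$w),
    class = "mtu_state")
}

#' @export
print.mtu_state <- function(x, ...) {
  cat(sprintf(
    "<mtu_state> a=%.3f  l_m_norm=%.4f  v_m_norm=%.4f  f_t=%.1f N (residual %.2e)\n",
    x$a, x$l_m_norm, x$v_m_norm, x$f_t, x$residual))
  invisible(x)
}

## Tendon-force sensitivity to activation, df_t/da (N per unit activation),
## by implicit differentiation of the equilibrium at a solved state.
.eq_dforce_da <- function(state, l_mt, params, curve) {
  fv_val <- force_velocity(state$v_m_norm)
  R_a <- -active_fl(state$l_m_norm) * fv_val * state$cos_alpha
  R_w <- .eq_residual_d(state$w, state$a, fv_val, l_mt, params, curve)
  if (!is.finite(R_w) || R_w == 0) return(0)
  dw_da <- -R_a / R_w
  dftn <- tendon_dforce_norm(state$l_t_norm, curve) * (-dw_da / params$l_t_slack)
  dftn * params$f_max
}
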