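#' Hill-type muscle parameters
#'
#' Container for the constants of one Hill-type muscle-tendon actuator.
#'
#' @param name Muscle label, e.g. `"SOL"`, `"GM"`, `"GL"`.
#' @param f_max Maximal isometric force (N).
#' @param l_m_opt Optimal fiber length (m).
#' @param l_t_slack Tendon slack length (m).
#' @param alpha_opt Pennation angle at optimal fiber length (rad, in
#'   `[0, pi/2)`).
#' @param v_m_max Maximal shortening velocity (optimal fiber lengths / s).
#' @return An object of class `muscle_params`.
#' @export
#' @examples
#' muscle_params("SOL", 2839, 0.030, 0.268, 25 * pi / 180)
muscle_params <- function(name, f_max, l_m_opt, l_t_slack, alpha_opt,
                          v_m_max = 10) {
  stopifnot(is.character(name), length(name) == 1L)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!num1(f_max) || f_max <= 0) stop("f_max must be > 0")
  if (!num1(l_m_opt) || l_m_opt <= 0) stop("l_m_opt must be > 0")
  if (!num1(l_t_slack) || l_t_slack <= 0) stop("l_t_slack must be > 0")
  if (!num1(alpha_opt) || alpha_opt < 0 || alpha_opt >= pi / 2)
    stop("alpha_opt must be in [0, pi/2)")
  if (!num1(v_m_max) || v_m_max <= 0) stop("v_m_max must be > 0")
  structure(
    list(name = name, f_max = f_max, l_m_opt = l_m_opt,
         l_t_slack = l_t_slack, alpha_opt = alpha_opt, v_m_max = v_m_max,
         # fixed-height pennation model: l_m * sin(alpha) is constant
         h = l_m_opt * sin(alpha_opt)),
    class = "muscle_params")
}

#' @export
print.muscle_params <- function(x, ...) {
  cat(sprintf(
    "<muscle_params> %s: f_max=%g N, l_m_opt=%g m, l_t_slack=%g m, alpha=%.1f deg, v_max=%g l0/s\n",
    x$name, x$f_max, x$l_m_opt, x$l_t_slack, 180 / pi * x$alpha_opt,
    x$v_m_max))
  invisible(x)
}

## Fixed-height pennation: given horizontal fiber extent w (projection of the
## fiber on the tendon line of action), fiber length is sqrt(w^2 + h^2) and
## cos(alpha) = w / l_m.
.pennation <- function(w, params) {
  l_m <- sqrt(w^2 + params$h^2)
  list(l_m = l_m, cos_a = w / l_m)
}
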