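#' Normalized tendon force-strain curve
#'
#' Construct the exponential normalized tendon force-strain law
#' \deqn{f_T(\tilde{l}_T) = c_1 \exp\{k_T (\tilde{l}_T - c_2)\} - c_3,}
#' clipped at zero below its zero crossing, where \eqn{\tilde{l}_T} is tendon
#' length divided by slack length and \eqn{k_T} the dimensionless normalized
#' tendon stiffness.  With the default shape constants the local slope
#' \eqn{df_T/d\tilde{l}_T = k_T (f_T + c_3)} equals \eqn{k_T} exactly at the
#' nominal operating point \eqn{f_T = 1 - c_3}.
#'
#' Lower \eqn{k_T} means a more compliant tendon: the generic healthy model
#' uses \eqn{k_T = 35}, tendinopathic models 28 (mean) and 21 (compliant),
#' and a stiff control bound 47 (see [derive_compliance_models()]).
#'
#' @param k_t Normalized tendon stiffness (dimensionless, > 0).
#' @param c1,c2,c3 Shape constants of the exponential law.
#' @return An object of class `tendon_curve` with fields `k_t`, `c1`, `c2`,
#'   `c3` and `l_t_zero`, the normalized length at which force crosses zero.
#' @seealso [tendon_force_norm()]
#' @export
#' @examples
#' crv <- tendon_curve(35)
#' tendon_force_norm(1.03, crv)
tendon_curve <- function(k_t, c1 = 0.200, c2 = 0.995, c3 = 0.250) {
  stopifnot(is.numeric(k_t), length(k_t) == 1L, is.finite(k_t), k_t > 0,
            c1 > 0, c3 >= 0)
  structure(
    list(k_t = k_t, c1 = c1, c2 = c2, c3 = c3,
         l_t_zero = c2 + log(c3 / c1) / k_t),
    class = "tendon_curve")
}

#' @export
print.tendon_curve <- function(x, ...) {
  cat(sprintf("<tendon_curve> k_t = %g (zero crossing at l_t_norm = %.5f)\n",
              x$k_t, x$l_t_zero))
  invisible(x)
}

#' Normalized tendon force
#'
#' Evaluate the normalized tendon force (force / maximal isometric muscle
#' force) at normalized tendon length `l_t_norm` (tendon length / slack
#' length).  Below the curve's zero crossing the tendon bears no load.
#'
#' @param l_t_norm Numeric vector of normalized tendon lengths (> 0).
#' @param curve A [tendon_curve()].
#' @return Numeric vector of non-negative normalized forces.
#' @export
tendon_force_norm <- function(l_t_norm, curve) {
  stopifnot(inherits(curve, "tendon_curve"))
  if (!is.numeric(l_t_norm) || any(!is.finite(l_t_norm)))
    stop("l_t_norm must be finite numeric")
  if (any(l_t_norm <= 0)) stop("l_t_norm must be > 0")
  pmax(0, curve$c1 * exp(curve$k_t * (l_t_norm - curve$c2)) - curve$c3)
}

#' Slope of the normalized tendon curve
#'
#' Derivative of [tendon_force_norm()] with respect to `l_t_norm`; zero below
#' the zero crossing.
#'
#' @inheritParams tendon_force_norm
#' @return Numeric vector of slopes (dimensionless).
#' @export
tendon_dforce_norm <- function(l_t_norm, curve) {
  stopifnot(inherits(curve, "tendon_curve"))
  d <- curve$c1 * curve$k_t * exp(curve$k_t * (l_t_norm - curve$c2))
  d[l_t_norm <= curve$l_t_zero] <- 0
  d
}

## Gaussian-sum active force-length constants.  The raw sum peaks at
## l_norm = 1.013256 with value 1.0004996; it is recentred and rescaled so
## the maximum sits exactly at (1, 1).
.afl <- list(
  b1 = c(0.814483478343008, 0.433004984392647, 0.100000000000000),
  b2 = c(1.055033428970575, 0.716775413397760, 1.000000000000000),
  b3 = c(0.162384573599574, -0.029947116970696, 0.353553390593274),
  b4 = c(0.063303448465465, 0.200356847296188, 0.000000000000000),
  shift = 1.013255699980505 - 1,
  scale = 1.000499586696081)

.afl_raw <- function(l) {
  f <- 0
  for (i in 1:3) {
    s <- .afl$b3[i] + .afl$b4[i] * l
    f <- f + .afl$b1[i] * exp(-0.5 * (l - .afl$b2[i])^2 / s^2)
  }
  f
}

.afl_raw_d <- function(l) {
  d <- 0
  for (i in 1:3) {
    s <- .afl$b3[i] + .afl$b4[i] * l
    z <- (l - .afl$b2[i]) / s
    e <- .afl$b1[i] * exp(-0.5 * z^2)
    d <- d + e * (-z / s) * (1 - z * .afl$b4[i])
  }
  d
}

#' Active force-length curve
#'
#' Normalized active force-length relation (a recentred Gaussian sum) with its
#' maximum exactly at optimal fiber length: `active_fl(1) == 1`.
#'
#' @param l_m_norm Numeric vector of normalized fiber lengths (> 0).
#' @return Active force scaling factor in (0, 1].
#' @export
active_fl <- function(l_m_norm) {
  if (!is.numeric(l_m_norm) || any(!is.finite(l_m_norm)))
    stop("l_m_norm must be finite numeric")
  if (any(l_m_norm <= 0)) stop("l_m_norm must be > 0")
  .afl_raw(l_m_norm + .afl$shift) / .afl$scale
}

#' @rdname active_fl
#' @export
active_fl_d <- function(l_m_norm) {
  .afl_raw_d(l_m_norm + .afl$shift) / .afl$scale
}

.pfl <- list(kpe = 4.0, e0 = 0.6)

#' Passive force-length curve
#'
#' Normalized passive (parallel elastic) force: zero at and below optimal
#' fiber length, exponential and strictly increasing beyond it, reaching 1 at
#' a passive strain of `e0 = 0.6`.
#'
#' @inheritParams active_fl
#' @return Non-negative passive force scaling factor.
#' @export
passive_fl <- function(l_m_norm) {
  if (!is.numeric(l_m_norm) || any(!is.finite(l_m_norm)))
    stop("l_m_norm must be finite numeric")
  if (any(l_m_norm <= 0)) stop("l_m_norm must be > 0")
  f <- (exp(.pfl$kpe * (l_m_norm - 1) / .pfl$e0) - 1) / (exp(.pfl$kpe) - 1)
  pmax(0, f)
}

#' @rdname passive_fl
#' @export
passive_fl_d <- function(l_m_norm) {
  d <- (.pfl$kpe / .pfl$e0) * exp(.pfl$kpe * (l_m_norm - 1) / .pfl$e0) /
    (exp(.pfl$kpe) - 1)
  d[l_m_norm <= 1] <- 0
  d
}

## Force-velocity: logarithmic-hyperbolic law, affinely rescaled so that
## fv(0) = 1 (isometric) and fv(-1) = 0 (maximal shortening) exactly, with
## the eccentric branch clamped at its value at v_norm = +1.
.fv <- local({
  d1 <- -0.318323436899127; d2 <- -8.149156043475250
  d3 <- -0.374121508647863; d4 <- 0.885644059915004
  raw <- function(v) {
    z <- d2 * v + d3
    d1 * log(z + sqrt(z^2 + 1)) + d4
  }
  f0 <- raw(0); fm1 <- raw(-1)
  list(d1 = d1, d2 = d2, d3 = d3, d4 = d4, raw = raw,
       off = fm1, sc = f0 - fm1, cap = (raw(1) - fm1) / (f0 - fm1))
})

#' Force-velocity curve
#'
#' Normalized force-velocity relation.  `v_m_norm` is fiber velocity divided
#' by maximal shortening velocity, negative for shortening (concentric).
#' `force_velocity(0) == 1`, the concentric branch decreases to 0 at
#' `v_m_norm = -1`, and the eccentric branch rises above 1 to a bounded
#' plateau (clamped at its value at `v_m_norm = 1`).
#'
#' @param v_m_norm Numeric vector of normalized fiber velocities.
#' @return Non-negative force scaling factor.
#' @export
force_velocity <- function(v_m_norm) {
  if (!is.numeric(v_m_norm) || any(!is.finite(v_m_norm)))
    stop("v_m_norm must be finite numeric")
  v <- pmin(v_m_norm, 1)
  pmin(pmax((.fv$raw(v) - .fv$off) / .fv$sc, 0), .fv$cap)
}

#' @rdname force_velocity
#' @export
force_velocity_d <- function(v_m_norm) {
  z <- .fv$d2 * v_m_norm + .fv$d3
  d <- .fv$d1 * .fv$d2 / sqrt(z^2 + 1) / .fv$sc
  d[v_m_norm >= 1 | v_m_norm <= -1] <- 0
  d
}
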