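## Fused scalar core of the fiber-tendon equilibrium solve: all
## characteristic-curve math inlined, residual and derivative computed in a
## single pass, safeguarded Newton with bisection fallback on the bracket
## [~0, tendon-force-free fiber extent].  This is the numerical kernel
## behind solve_fiber_equilibrium() and the redundancy solver's inner loop.

.pfl_den <- exp(4.0) - 1

.eq_core <- function(a, l_mt, fv_val, params, curve, w0 = NA_real_,
                     tol = 1e-14, context = NULL) {
  h <- params$h; lm0 <- params$l_m_opt; lts <- params$l_t_slack
  kt <- curve$k_t; c1 <- curve$c1; c2 <- curve$c2; c3 <- curve$c3
  lt0 <- curve$l_t_zero
  b11 <- 0.814483478343008; b21 <- 1.055033428970575
  b31 <- 0.162384573599574; b41 <- 0.063303448465465
  b12 <- 0.433004984392647; b22 <- 0.716775413397760
  b32 <- -0.029947116970696; b42 <- 0.200356847296188
  b13 <- 0.1; b23 <- 1.0; b33 <- 0.353553390593274
  sh <- 0.013255699980505; sc <- 1.000499586696081
  kpe_e0 <- 4.0 / 0.6

  afv <- a * fv_val
  w_t0 <- l_mt - lt0 * lts

  zero_state <- function(w) {
    l_m <- sqrt(w * w + h * h)
    list(w = w, ftn = 0, f = 0, df = 0, lmn = l_m / lm0,
         cosa = w / l_m, ltn = (l_mt - w) / lts, res = 0)
  }
  if (w_t0 <= 0)
    return(zero_state(max(l_mt - lts, 0.05 * lm0)))
  if (afv == 0 && sqrt(w_t0 * w_t0 + h * h) / lm0 <= 1)
    return(zero_state(w_t0))

  eval_rd <- function(w) {
    l_m <- sqrt(w * w + h * h)
    cosa <- w / l_m
    lmn <- l_m / lm0
    ltn <- (l_mt - w) / lts
    if (ltn > lt0) { e <- c1 * exp(kt * (ltn - c2)); ft <- e - c3
                     dft <- kt * e } else { ft <- 0; dft <- 0 }
    l <- lmn + sh
    s1 <- b31 + b41 * l; z1 <- (l - b21) / s1
    s2 <- b32 + b42 * l; z2 <- (l - b22) / s2
    z3 <- (l - b23) / b33
    e1 <- b11 * exp(-0.5 * z1 * z1)
    e2 <- b12 * exp(-0.5 * z2 * z2)
    e3 <- b13 * exp(-0.5 * z3 * z3)
    fa <- (e1 + e2 + e3) / sc
    dfa <- (e1 * (-z1 / s1) * (1 - z1 * b41) +
            e2 * (-z2 / s2) * (1 - z2 * b42) +
            e3 * (-z3 / b33)) / sc
    if (lmn > 1) { pe <- exp(kpe_e0 * (lmn - 1)); fp <- (pe - 1) / .pfl_den
                   dfp <- kpe_e0 * pe / .pfl_den } else { fp <- 0; dfp <- 0 }
    fm <- afv * fa + fp
    dfm <- afv * dfa + dfp
    mfc <- fm * cosa
    dmfc <- dfm * cosa * cosa / lm0 + fm * h * h / (l_m^3)
    ## log-transformed residual: same root and sign as `res` wherever the
    ## tendon is loaded, but nearly linear in w even for very stiff tendons
    ## (the raw residual is exponential in w, on which Newton creeps)
    lres <- (ltn - c2) - log((mfc + c3) / c1) / kt
    list(res = ft - mfc,
         dres = -dft / lts - dmfc,
         lres = lres,
         dlres = -1 / lts - dmfc / (kt * (mfc + c3)),
         ft = ft, dft = dft, fa = fa, cosa = cosa, lmn = lmn, ltn = ltn,
         l_m = l_m)
  }

  w_lo <- 1e-9
  w_hi <- w_t0
  r_hi <- eval_rd(w_hi)
  if (r_hi$res > tol) {
    r_lo <- eval_rd(w_lo)
    if (r_lo$res < 0)
      stop(sprintf(
        "no equilibrium root bracketed for muscle %s%s (l_mt=%g, a=%g)",
        params$name,
        if (is.null(context)) "" else paste0(" at ", context), l_mt, a))
  }

  w <- if (is.finite(w0) && w0 > w_lo && w0 < w_hi) w0
       else 0.5 * (w_lo + w_hi)
  ed <- eval_rd(w)
  for (it in seq_len(200)) {
    if (abs(ed$res) < tol) break
    if (ed$res > 0) w_lo <- w else w_hi <- w
    w_new <- if (is.finite(ed$dlres) && ed$dlres != 0) w - ed$lres / ed$dlres
             else NA_real_
    if (!is.finite(w_new) || w_new <= w_lo || w_new >= w_hi || w_new == w)
      w_new <- 0.5 * (w_lo + w_hi)  # bisect when Newton stalls or escapes
    if (abs(w_new - w) < 1e-17 && (w_hi - w_lo) < 1e-15) break
    w <- w_new
    ed <- eval_rd(w)
  }

  ## implicit differentiation: d f_t / d a at the equilibrium
  df <- if (is.finite(ed$dres) && ed$dres != 0) {
    dw_da <- (ed$fa * fv_val * ed$cosa) / ed$dres  # = -R_a / R_w
    ed$dft * (-dw_da / lts) * params$f_max
  } else 0
  list(w = w, ftn = ed$ft, f = ed$ft * params$f_max, df = df,
       lmn = ed$lmn, cosa = ed$cosa, ltn = ed$ltn, res = ed$res)
}
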