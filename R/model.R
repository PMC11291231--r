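#' Assemble an ankle model from a configuration
#'
#' Builds the sagittal-plane ankle model used throughout the package: the
#' three triceps surae Hill-type actuators (SOL, GM, GL) sharing the
#' Achilles tendon, their polyline paths, the subtendon insertion set for a
#' twist class, one tendon compliance curve per muscle, and the bounded
#' residual torque actuator.
#'
#' Each path's constant length offset is calibrated once, on the generic
#' (no-twist) insertion, so that at neutral ankle with an unloaded tendon
#' the normalized fiber length equals the configured `neutral_fiber_norm`.
#' The calibration is shared by all twist variants, so moving insertion
#' points changes musculotendon lengths and moment arms exactly as the
#' geometry dictates.
#'
#' @param config Path to a YAML model configuration, or an equivalent list;
#'   defaults to the configuration shipped with the package
#'   (`extdata/default_model.yaml`).
#' @param k_t Optional normalized tendon stiffness overriding the config.
#' @param twist Optional twist class overriding the config
#'   (`"none"`, `"low"`, `"medium"`, `"high"`).
#' @param scale Optional insertion enlargement factor (1.0, 1.5, 2.0).
#' @return An object of class `ts_model`.
#' @export
#' @examples
#' m <- ts_model()
#' m_compliant <- ts_model(k_t = 21, twist = "low")
ts_model <- function(config = NULL, k_t = NULL, twist = NULL, scale = NULL) {
  cfg <- .load_model_config(config)
  if (!is.null(k_t)) cfg$tendon$k_t <- k_t
  if (!is.null(twist)) cfg$twist$class <- twist
  if (!is.null(scale)) cfg$twist$scale <- scale
  .validate_model_config(cfg)

  muscles <- lapply(names(cfg$muscles), function(m) {
    p <- cfg$muscles[[m]]
    muscle_params(m, p$f_max, p$l_m_opt, p$l_t_slack,
                  p$alpha_opt_deg * pi / 180, p$v_m_max)
  })
  names(muscles) <- names(cfg$muscles)

  curve <- tendon_curve(cfg$tendon$k_t, cfg$tendon$c1, cfg$tendon$c2,
                        cfg$tendon$c3)
  geo <- cfg$geometry
  ins_generic <- build_insertions("none", 1.0,
                                  at_midpoint = as.numeric(geo$at_midpoint))
  ins <- build_insertions(cfg$twist$class, cfg$twist$scale,
                          at_midpoint = as.numeric(geo$at_midpoint))

  paths <- list()
  for (m in names(muscles)) {
    pm <- muscles[[m]]
    base <- path_model(as.numeric(geo$origins[[m]]),
                       as.numeric(geo$vias[[m]]),
                       ins_generic$points[[m]],
                       as.numeric(geo$joint_center), 0,
                       as.numeric(geo$knee_arm[[m]]))
    # calibrate constant offset on the generic insertion at neutral ankle
    lmn0 <- as.numeric(geo$neutral_fiber_norm[[m]])
    w0 <- sqrt((lmn0 * pm$l_m_opt)^2 - pm$h^2)
    target <- pm$l_t_slack + w0
    off <- target - mtu_length(0, base)
    paths[[m]] <- path_model(base$origin, base$via, ins$points[[m]],
                             base$joint_center, off, base$knee_arm)
  }

  structure(
    list(muscles = muscles, curve = curve, paths = paths, insertions = ins,
         residual = cfg$residual, config = cfg),
    class = "ts_model")
}

#' @export
print.ts_model <- function(x, ...) {
  cat(sprintf(
    "<ts_model> %s; k_t = %g, twist = %s (scale %.1f)\n",
    paste(names(x$muscles), collapse = "+"), x$curve$k_t,
    x$insertions$twist_class, x$insertions$scale))
  invisible(x)
}

.load_model_config <- function(config) {
  if (is.null(config))
    config <- system.file("extdata", "default_model.yaml",
                          package = "tsforce", mustWork = TRUE)
  if (is.character(config)) {
    if (!file.exists(config)) stop("model config file not found: ", config)
    yaml::read_yaml(config)
  } else if (is.list(config)) {
    config
  } else stop("config must be a file path or a list")
}

.validate_model_config <- function(cfg) {
  need <- function(ok, what) if (!ok) stop("invalid model config: ", what)
  need(is.list(cfg$muscles) && length(cfg$muscles) >= 1, "missing muscles")
  for (m in names(cfg$muscles)) {
    p <- cfg$muscles[[m]]
    need(all(c("f_max", "l_m_opt", "l_t_slack", "alpha_opt_deg", "v_m_max")
             %in% names(p)), paste("incomplete parameters for", m))
  }
  need(is.list(cfg$tendon) && is.numeric(cfg$tendon$k_t) && cfg$tendon$k_t > 0,
       "tendon$k_t must be > 0")
  g <- cfg$geometry
  need(is.list(g), "missing geometry")
  for (f in c("joint_center", "at_midpoint"))
    need(length(g[[f]]) == 3, paste(f, "must have 3 coordinates"))
  for (m in names(cfg$muscles)) {
    need(length(g$origins[[m]]) == 3, paste("missing origin for", m))
    need(length(g$vias[[m]]) == 3, paste("missing via point for", m))
    need(is.numeric(g$neutral_fiber_norm[[m]]),
         paste("missing neutral_fiber_norm for", m))
    need(is.numeric(g$knee_arm[[m]]), paste("missing knee_arm for", m))
  }
  need(is.list(cfg$twist) && cfg$twist$class %in% .twist_classes,
       "twist$class invalid")
  r <- cfg$residual
  need(is.list(r) && r$weight > 0 && r$scale > 0 && r$bound > 0,
       "residual must define positive weight, scale, bound")
  invisible(TRUE)
}
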