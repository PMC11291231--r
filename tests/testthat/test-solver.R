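# exact objective of the frame problem, recomputed independently of the
# solver internals (public equilibrium API only)
frame_objective <- function(model, theta, moment, a, vm = c(0, 0, 0)) {
  mus <- names(model$muscles)
  f <- r <- numeric(length(mus))
  for (j in seq_along(mus)) {
    m <- mus[j]
    lmt <- mtu_length(theta, model$paths[[m]])
    r[j] <- moment_arm(theta, model$paths[[m]])
    f[j] <- solve_fiber_equilibrium(a[j], lmt, 0, model$muscles[[m]],
                                    model$curve, vm_norm = vm[j])$f_t
  }
  w <- model$residual$weight / model$residual$scale^2
  sum(a^2) + w * (moment - sum(r * f))^2
}

test_that("zero demanded moment with slack muscles gives zero activation", {
  m <- ts_model()
  fr <- solve_frame(m, theta = -0.45, moment = 0)  # plantarflexed: no passive
  expect_equal(unname(fr$a), c(0, 0, 0))
  expect_equal(unname(fr$force), c(0, 0, 0), tolerance = 1e-9)
  expect_equal(fr$residual, 0, tolerance = 1e-9)
})

test_that("a single-muscle model matches the closed-form moment inversion", {
  cfg <- yaml::read_yaml(system.file("extdata", "default_model.yaml",
                                     package = "tsforce"))
  cfg$muscles <- cfg$muscles["SOL"]
  cfg$geometry$origins <- cfg$geometry$origins["SOL"]
  cfg$geometry$vias <- cfg$geometry$vias["SOL"]
  cfg$geometry$neutral_fiber_norm <- cfg$geometry$neutral_fiber_norm["SOL"]
  cfg$geometry$knee_arm <- cfg$geometry$knee_arm["SOL"]
  m1 <- ts_model(cfg)
  theta <- 0.1; moment <- 60
  fr <- solve_frame(m1, theta, moment)
  # invert the moment equation by root-finding on the public equilibrium
  lmt <- mtu_length(theta, m1$paths$SOL)
  r <- moment_arm(theta, m1$paths$SOL)
  a_star <- stats::uniroot(function(a)
    r * solve_fiber_equilibrium(a, lmt, 0, m1$muscles$SOL, m1$curve)$f_t -
      moment, c(0, 1), tol = 1e-12)$root
  expect_equal(unname(fr$a["SOL"]), a_star, tolerance = 2e-5)
  expect_equal(fr$kkt, 0, tolerance = 1e-6)
})

test_that("the solver is at least as good as a dense activation grid", {
  set.seed(101)
  m <- ts_model()
  grid_gap <- function(theta, moment, step) {
    fr <- solve_frame(m, theta, moment)
    expect_lt(fr$kkt, 1e-6)
    # moment equilibrium holds exactly by construction
    expect_lt(abs(moment - sum(fr$r * fr$force) - fr$residual), 1e-6)
    # brute-force grid: tabulate each muscle's force over the activation
    # grid, then scan all combinations of the three
    agrid <- seq(0, 1, by = step)
    fs <- lapply(names(m$muscles), function(mu) {
      lmt <- mtu_length(theta, m$paths[[mu]])
      vapply(agrid, function(a)
        solve_fiber_equilibrium(a, lmt, 0, m$muscles[[mu]], m$curve)$f_t,
        numeric(1))
    })
    w <- m$residual$weight / m$residual$scale^2
    tot <- outer(outer(fr$r[1] * fs[[1]], fr$r[2] * fs[[2]], "+"),
                 fr$r[3] * fs[[3]], "+")
    pen <- w * (moment - tot)^2
    a2 <- outer(outer(agrid^2, agrid^2, "+"), agrid^2, "+")
    g_grid <- min(a2 + pen)
    g_solver <- frame_objective(m, theta, moment, unname(fr$a))
    g_solver - g_grid
  }
  # 100 random frames against a 0.01-step grid, plus a handful against the
  # dense 0.005-step grid; the continuous optimum must never be beaten
  worst <- -Inf
  for (i in 1:100)
    worst <- max(worst, grid_gap(stats::runif(1, -15, 15) * pi / 180,
                                 stats::runif(1, 5, 80), 0.01))
  for (i in 1:5)
    worst <- max(worst, grid_gap(stats::runif(1, -15, 15) * pi / 180,
                                 stats::runif(1, 5, 80), 0.005))
  expect_lt(worst, 1e-4)
})

test_that("a constant trial yields time-invariant forces", {
  tr <- ts_trial(seq(0, 0.5, by = 0.05), rep(0.15, 11), rep(40, 11),
                 exercise = "heel_drop")
  traj <- solve_trial(tr, ts_model())
  for (mu in colnames(traj$force))
    expect_lt(diff(range(traj$force[, mu])), 1e-6)
})

test_that("a moment ramp produces non-decreasing total force", {
  n <- 26
  tr <- ts_trial(seq(0, 1, length.out = n), rep(0.1, n),
                 seq(0, 70, length.out = n), exercise = "heel_rise")
  traj <- solve_trial(tr, ts_model())
  tot <- rowSums(traj$force)
  expect_true(all(diff(tot) > -1e-8))
})

test_that("trial solutions are deterministic", {
  tr <- gen_heel_drop(exercise_spec("heel_drop", sample_rate = 25))
  m <- ts_model()
  t1 <- solve_trial(tr, m)
  t2 <- solve_trial(tr, m)
  expect_identical(t1$force, t2$force)
  expect_identical(t1$a, t2$a)
})

test_that("soleus dominates the gastrocnemii at the heel-drop peak", {
  traj <- cached_traj("heel_drop")
  i <- peak_index(traj)
  expect_true(traj$force[i, "SOL"] > traj$force[i, "GM"])
  expect_true(traj$force[i, "GM"] > traj$force[i, "GL"])
})

test_that("compliant tendons shift eccentric-trial fibers toward shorter lengths", {
  # prescribed lengthening ramp under load
  n <- 31
  tr <- ts_trial(seq(0, 1.5, length.out = n),
                 seq(-0.15, 0.2, length.out = n), rep(45, n),
                 exercise = "heel_drop")
  t21 <- solve_trial(tr, ts_model(k_t = 21))
  t35 <- solve_trial(tr, ts_model(k_t = 35))
  expect_true(all(colMeans(t21$lm_norm) < colMeans(t35$lm_norm)))
})

test_that("infeasible moments saturate and flag the residual", {
  m <- ts_model()
  fr <- solve_frame(m, theta = 0.1, moment = 500)  # beyond muscle capacity
  expect_true(fr$flagged)
  expect_true(all(fr$a >= 1 - 1e-9))
  expect_lt(abs(500 - sum(fr$r * fr$force) - fr$residual), 1e-6)
})

test_that("per-frame per-muscle results flatten to the documented layout", {
  traj <- cached_traj("heel_drop", sample_rate = 25)
  df <- as.data.frame(traj)
  expect_setequal(names(df), c("frame", "time_s", "muscle", "activation",
                               "force_N", "lm_norm", "vm_norm",
                               "residual_Nm"))
  expect_identical(nrow(df), nrow(traj$trial) * 3L)
  expect_true(all(df$activation >= 0 & df$activation <= 1))
})
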