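fake_traj <- function(force, lm = NULL, vm = NULL) {
  colnames(force) <- c("SOL", "GM", "GL")
  structure(list(force = force,
                 lm_norm = if (is.null(lm)) force * 0 + 1 else lm,
                 vm_norm = if (is.null(vm)) force * 0 else vm),
            class = "force_trajectory")
}

test_that("compliance models derive from the generic stiffness as specified", {
  cs <- derive_compliance_models(35, 0.20, 3.5, 6.0)
  expect_identical(c(cs$compliant, cs$mean, cs$generic, cs$stiff),
                   c(21, 28, 35, 47))
  expect_equal(unname(cs$exact["mean"]), 28)
  # degenerate no-difference case collapses to the generic value
  cs0 <- derive_compliance_models(35, 0, 0, 0)
  expect_identical(c(cs0$compliant, cs0$mean, cs0$generic, cs0$stiff),
                   c(35, 35, 35, 35))
  expect_error(derive_compliance_models(35, 0.9, 10, 0), "positive")
  expect_error(derive_compliance_models(-1))
})

test_that("peak detection takes the first maximum of the summed forces", {
  tr <- fake_traj(matrix(c(0.5, 1.5, 1, 0.3, 1, 0.7, 0.2, 0.5, 0.3), 3))
  expect_identical(peak_index(tr), 2L)  # sums 1, 3, 2
  tie <- fake_traj(matrix(c(1, 1.5, 1.5, 0.5, 1, 1, 0.5, 0.5, 0.5), 3))
  expect_identical(peak_index(tie), 2L)  # sums 2, 3, 3: first occurrence
  expect_error(peak_index(fake_traj(matrix(0, 2, 3))), "no peak")
})

test_that("peak index agrees with an exhaustive scan on a solved trial", {
  traj <- cached_traj("walk")
  tot <- rowSums(traj$force)
  best <- which(tot == max(tot))[1]
  expect_identical(peak_index(traj), best)
})

test_that("contributions are the force ratios at the peak frame", {
  tr <- fake_traj(matrix(c(66, 10, 24, 5, 10, 2), 2, byrow = FALSE))
  # frame 1 sums to 100 and dominates
  expect_equal(unname(contributions_at_peak(tr)), c(66, 24, 10))
  eq <- fake_traj(matrix(rep(c(5, 5, 5), each = 2), 2))
  expect_equal(unname(contributions_at_peak(eq)), rep(100 / 3, 3))
  expect_true(abs(sum(contributions_at_peak(eq)) - 100) < 1e-9)
})

test_that("time normalization resamples onto the 0-100% cycle", {
  tr <- ts_trial(seq(0, 2, by = 0.01), seq(-0.2, 0.3, length.out = 201),
                 rep(10, 201), exercise = "heel_drop")
  nt <- normalize_time(tr)
  expect_identical(nrow(nt), 101L)
  expect_equal(nt$pct, seq(0, 100, by = 1))
  # a linear ramp resamples to a linear ramp
  expect_equal(nt$theta_rad, seq(-0.2, 0.3, length.out = 101),
               tolerance = 1e-12)
  expect_equal(nt$moment_Nm, rep(10, 101))
  # sub-window resampling
  nt2 <- normalize_time(tr, events = c(0.5, 1.5))
  expect_equal(nt2$theta_rad[1], stats::approx(tr$time_s, tr$theta_rad, 0.5)$y)
  expect_error(normalize_time(tr, events = c(1.5, 0.5)), "increasing")
  expect_error(normalize_time(tr, events = c(-1, 2)), "span")
})

test_that("a 1x1x1 grid equals the direct pipeline composition", {
  gr <- grid_run(exercises = "walk", twists = "none", k_ts = 35,
                 sample_rate = 50)
  direct <- contributions_at_peak(
    solve_trial(gen_trial("walk", seed = 0L, sample_rate = 50), ts_model()))
  expect_identical(nrow(gr$sharing), 1L)
  expect_equal(as.numeric(gr$sharing[1, c("SOL", "GM", "GL")]),
               unname(direct), tolerance = 1e-12)
})

test_that("sharing rows sum to 100 and difference stats recompute exactly", {
  gr <- grid_run(exercises = "walk", twists = c("none", "medium"),
                 k_ts = c(21, 35), sample_rate = 50)
  sums <- rowSums(gr$sharing[, c("SOL", "GM", "GL")])
  expect_true(all(abs(sums - 100) < 1e-9))
  # the summary statistic matches an independent scan of the table
  stats2 <- sharing_change_stats(gr$sharing)
  expect_identical(gr$stats$max_abs_change_twist,
                   stats2$max_abs_change_twist_pp)
  expect_identical(gr$stats$max_abs_change_compliance,
                   stats2$max_abs_change_compliance_pp)
  # reference row differences are zero
  ref <- gr$diffs[gr$diffs$twist == "none" & gr$diffs$k_t == 35, ]
  expect_equal(as.numeric(ref[1, c("SOL", "GM", "GL")]), c(0, 0, 0))
})

test_that("operating points report shorter fibers for compliant tendons", {
  stiff <- cached_traj("heel_drop", k_t = 47, sample_rate = 25)
  comp <- cached_traj("heel_drop", k_t = 21, sample_rate = 25)
  rs <- operating_point_report(stiff)
  rc <- operating_point_report(comp)
  expect_true(all(rc$lm_mean < rs$lm_mean))
})

test_that("an isometric trial has near-zero fiber velocities", {
  tr <- ts_trial(seq(0, 1, by = 0.05), rep(0.1, 21), rep(30, 21),
                 exercise = "heel_drop")
  traj <- solve_trial(tr, ts_model())
  rep_ <- operating_point_report(traj)
  expect_lt(max(abs(c(rep_$vm_min, rep_$vm_max))), 1e-9)
})
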