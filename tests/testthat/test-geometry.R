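test_that("no-twist insertions coincide with the Achilles midpoint", {
  ins <- build_insertions("none", 1.0)
  expect_identical(ins$points$SOL, ins$points$GM)
  expect_identical(ins$points$GM, ins$points$GL)
  expect_identical(ins$points$SOL, ins$at_midpoint)
})

test_that("enlargement scales every offset vector linearly", {
  for (cl in c("low", "medium", "high")) {
    i1 <- build_insertions(cl, 1.0)
    i15 <- build_insertions(cl, 1.5)
    i2 <- build_insertions(cl, 2.0)
    for (m in c("SOL", "GM", "GL")) {
      off1 <- i1$points[[m]] - i1$at_midpoint
      expect_equal(i15$points[[m]] - i15$at_midpoint, 1.5 * off1,
                   tolerance = 1e-12)
      expect_equal(i2$points[[m]] - i2$at_midpoint, 2 * off1,
                   tolerance = 1e-12)
    }
  }
})

test_that("unknown twist classes and scales are rejected with the admissible set", {
  expect_error(build_insertions("extreme"), "none")
  expect_error(build_insertions("low", 1.2), "1.5")
})

test_that("default offsets rotate the soleus subtendon from medial toward lateral", {
  tab <- default_twist_offsets()
  sol_dz <- vapply(c("low", "medium", "high"), function(cl)
    tab$dz[tab$muscle == "SOL" & tab$twist_class == cl], numeric(1))
  # medial (negative z, right leg) and monotonically less medial with twist
  expect_true(all(sol_dz < 0))
  expect_true(all(diff(sol_dz) > 0))
})

test_that("musculotendon length matches an independent polyline recomputation", {
  set.seed(11)
  for (i in 1:25) {
    path <- random_path()
    for (th in stats::runif(4, -0.8, 0.5))
      expect_equal(mtu_length(th, path), polyline_length(th, path),
                   tolerance = 1e-12)
  }
})

test_that("dorsiflexion lengthens the plantarflexor paths", {
  m <- ts_model()
  for (mu in names(m$paths)) {
    th <- seq(-50, 30, by = 2) * pi / 180
    len <- mtu_length(th, m$paths[[mu]])
    expect_true(all(diff(len) > 0))
  }
})

test_that("a single-segment lever has moment arm equal to its radius", {
  r <- 0.05
  path <- path_model(origin = c(-r, 1, 0), via = c(-r, 1, 0),
                     insertion = c(-r, 0, 0))
  expect_equal(moment_arm(0, path), r, tolerance = 1e-12)
})

test_that("moment arm equals the finite-difference length derivative", {
  set.seed(13)
  h <- 1e-5
  for (i in 1:25) {
    path <- random_path()
    for (th in stats::runif(4, -0.5, 0.5)) {
      fd <- (mtu_length(th + h, path) - mtu_length(th - h, path)) / (2 * h)
      expect_equal(moment_arm(th, path), fd, tolerance = 1e-6)
    }
  }
})

test_that("twisted insertions change moment arms by at most 3 mm", {
  m <- ts_model()
  th <- seq(-20, 20, by = 1) * pi / 180
  for (cl in c("low", "medium", "high")) {
    for (sc in c(1.0, 1.5, 2.0)) {
      mt <- ts_model(twist = cl, scale = sc)
      for (mu in names(m$paths)) {
        d <- moment_arm(th, mt$paths[[mu]]) - moment_arm(th, m$paths[[mu]])
        expect_lt(max(abs(d)), 3e-3)
        # twist never flips the plantarflexion moment arm sign
        expect_true(all(moment_arm(th, mt$paths[[mu]]) > 0))
      }
    }
  }
})

test_that("the no-twist scale-1 model reproduces generic lengths exactly", {
  m1 <- ts_model()
  m2 <- ts_model(twist = "none", scale = 1.0)
  th <- seq(-0.4, 0.3, by = 0.05)
  for (mu in names(m1$paths)) {
    expect_identical(mtu_length(th, m1$paths[[mu]]),
                     mtu_length(th, m2$paths[[mu]]))
    expect_identical(moment_arm(th, m1$paths[[mu]]),
                     moment_arm(th, m2$paths[[mu]]))
  }
})

test_that("model calibration hits the configured neutral fiber length", {
  m <- ts_model()
  for (mu in names(m$muscles)) {
    p <- m$muscles[[mu]]
    lmn0 <- m$config$geometry$neutral_fiber_norm[[mu]]
    w0 <- sqrt((lmn0 * p$l_m_opt)^2 - p$h^2)
    expect_equal(mtu_length(0, m$paths[[mu]]), p$l_t_slack + w0,
                 tolerance = 1e-12)
  }
})
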