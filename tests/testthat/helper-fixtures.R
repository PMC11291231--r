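# Shared fixtures: small muscles, toy paths, and a cross-test cache of
# solved trajectories (several acceptance checks reuse the same solves).

sol_params <- function() muscle_params("SOL", 2839, 0.030, 0.268, 25 * pi / 180)
gm_params <- function() muscle_params("GM", 1113, 0.045, 0.408, 17 * pi / 180)

random_path <- function() {
  path_model(origin = c(stats::runif(1, -0.05, 0.02),
                        stats::runif(1, 0.15, 0.40),
                        stats::runif(1, -0.03, 0.03)),
             via = c(stats::runif(1, -0.06, -0.03),
                     stats::runif(1, 0.05, 0.12),
                     stats::runif(1, -0.02, 0.02)),
             insertion = c(stats::runif(1, -0.06, -0.03),
                           stats::runif(1, -0.05, -0.02),
                           stats::runif(1, -0.01, 0.01)),
             const_offset = stats::runif(1, 0, 0.1))
}

# independent polyline length recomputation (oracle for mtu_length)
polyline_length <- function(theta, path, knee = 0) {
  p <- path$insertion - path$joint_center
  q <- path$joint_center + c(cos(theta) * p[1] - sin(theta) * p[2],
                             sin(theta) * p[1] + cos(theta) * p[2], p[3])
  seg <- function(u, v) sqrt(sum((u - v)^2))
  seg(path$origin, path$via) + seg(path$via, q) +
    path$const_offset - path$knee_arm * knee
}

# lazily solved, cached trajectories for the pipeline-level tests
.traj_cache <- new.env(parent = emptyenv())
cached_traj <- function(exercise, k_t = 35, twist = "none", scale = 1,
                        sample_rate = 100) {
  key <- paste(exercise, k_t, twist, scale, sample_rate, sep = "|")
  if (is.null(.traj_cache[[key]])) {
    trial <- gen_trial(exercise, seed = 0L, sample_rate = sample_rate)
    model <- ts_model(k_t = k_t, twist = twist, scale = scale)
    .traj_cache[[key]] <- solve_trial(trial, model)
  }
  .traj_cache[[key]]
}
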