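# Default sagittal-plane ankle model: three triceps surae Hill-type
# actuators sharing the Achilles tendon, plus a bounded residual torque
# actuator.  Muscle constants follow the gait2392 triceps surae values
# (the source model never prints them; recorded here as configuration).
# Lengths in m, angles in deg, forces in N.
muscles:
  SOL: {f_max: 3549.0, l_m_opt: 0.030, l_t_slack: 0.268, alpha_opt_deg: 25.0, v_m_max: 10.0}
  GM:  {f_max: 1558.0, l_m_opt: 0.060, l_t_slack: 0.390, alpha_opt_deg: 17.0, v_m_max: 10.0}
  GL:  {f_max: 683.0,  l_m_opt: 0.064, l_t_slack: 0.385, alpha_opt_deg: 8.0,  v_m_max: 10.0}
tendon:
  k_t: 35.0
  c1: 0.2
  c2: 0.995
  c3: 0.25
geometry:
  # shank-fixed frame, right leg: x anterior, y superior, z lateral;
  # ankle joint center at the origin; dorsiflexion positive.
  joint_center: [0.0, 0.0, 0.0]
  at_midpoint: [-0.066, -0.035, -0.003]
  origins:
    SOL: [-0.010, 0.210,  0.005]
    GM:  [-0.020, 0.380, -0.010]
    GL:  [-0.022, 0.380,  0.020]
  vias:
    SOL: [-0.046, 0.080, -0.003]
    GM:  [-0.046, 0.080, -0.008]
    GL:  [-0.046, 0.080,  0.004]
  # Calibration: normalized fiber length at neutral ankle with the tendon
  # unloaded; fixes each path's constant length offset (see vignette).
  neutral_fiber_norm: {SOL: 0.92, GM: 0.98, GL: 1.20}
  # Path-length change per rad of knee flexion (bi-articular gastrocnemii).
  knee_arm: {SOL: 0.0, GM: 0.020, GL: 0.020}
twist:
  class: none
  scale: 1.0
residual:
  weight: 1000.0
  scale: 1.0
  bound: 50.0
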