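# Shared fixtures: a reference device, medium, and small simulated scenes.
# Everything is generated in code; no binary fixtures.

ref_config <- maglev_config()           # d = 2.8 cm, B0 = 0.5 T
ref_medium <- paramagnetic_medium()     # 80 mg/mL Dy(NO3)3, rho = 1060

# A flat blank profile at the optics background level, standing in for a
# pre-injection blank frame (exact background, no noise).
flat_blank <- function(series, level) {
  p <- vertical_profile(series$frames[[1]], series$roi, series$pixel_to_mm)
  p$intensities <- rep(level, length(p$intensities))
  p
}

# Simulate + render a single-class scene: n particles of one density,
# initialized near their equilibrium height (or at `z0_mm` if given).
render_scene <- function(density, n = 30, radius = 15e-6, z0_mm = NULL,
                         jitter_mm = 0.5, duration = 1200, dt = 2,
                         optics = maglev_optics(noise_sigma = 1),
                         seed = 1) {
  set.seed(seed)
  if (is.null(z0_mm)) {
    h <- levitation_height(analyte(density, radius = radius),
                           ref_medium, ref_config)
    z0_mm <- if (h$in_range) h$height * 1e3 else 14
  }
  z0 <- pmin(pmax(rnorm(n, z0_mm, jitter_mm) / 1e3, 1e-4),
             ref_config$separation_d - 1e-4)
  pop <- particle_population(densities = density, radii = radius,
                             initial_positions = z0, n_particles = n)
  traj <- simulate_trajectories(pop, ref_medium, ref_config,
                                duration = duration, dt = dt)
  list(trajectory = traj,
       series = render_frames(traj, optics, seed = seed + 1000))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / max(abs(expected), 1e-300), tol)
}
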