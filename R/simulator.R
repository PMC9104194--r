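# Levitation simulator: overdamped migration of a particle population along
# the axial field gradient, plus rendering of synthetic time-lapse frames.

#' Particle population for a levitation run
#'
#' An ensemble of corona-coated particles. Scalars are recycled to
#' `n_particles`.
#'
#' @param densities Particle mass densities, kg/m^3.
#' @param radii Hydrodynamic radii, metres. GO-plasma complexes aggregate;
#'   the effective sedimentation radius is micron-scale.
#' @param susceptibilities SI volume susceptibilities.
#' @param initial_positions Initial heights, metres, within the magnet gap.
#' @param n_particles Number of particles (defaults to the longest field).
#' @return Object of class `particle_population`.
#' @export
particle_population <- function(densities, radii = 10e-6,
                                susceptibilities = -9.0e-6,
                                initial_positions = 0.014,
                                n_particles = NULL) {
  if (is.null(n_particles))
    n_particles <- max(length(densities), length(radii),
                       length(susceptibilities), length(initial_positions))
  stopifnot(n_particles >= 1)
  rec <- function(x) rep_len(x, n_particles)
  out <- list(n = n_particles,
              densities = rec(densities),
              radii = rec(radii),
              susceptibilities = rec(susceptibilities),
              initial_positions = rec(initial_positions))
  stopifnot(all(out$densities > 0), all(out$radii > 0))
  structure(out, class = "particle_population")
}

#' Simulate overdamped particle trajectories
#'
#' Integrates `dz/dt = F(z) / (6 pi eta r)` per particle (Stokes drag,
#' inertia neglected) with explicit Euler steps. Steps are automatically
#' subdivided so that no particle moves more than `separation_d / 100` in a
#' single sub-step. The boundaries are absorbing: a particle reaching z = 0
#' is `"precipitated"`, one reaching z = d is `"floated"`; both stay put.
#'
#' @param population A [particle_population()].
#' @param medium A [paramagnetic_medium()].
#' @param config A [maglev_config()].
#' @param duration Total simulated time, seconds (default 20 min).
#' @param dt Recording time step, seconds.
#' @return Object of class `maglev_trajectory`: `times` (length T),
#'   `positions` (T x n matrix, metres), `terminal_state` (factor per
#'   particle: levitating / precipitated / floated), and the inputs.
#' @export
simulate_trajectories <- function(population, medium,
                                  config = maglev_config(),
                                  duration = 1200, dt = 1) {
  stopifnot(duration > 0, dt > 0)
  d <- config$separation_d
  if (any(population$initial_positions < 0 |
          population$initial_positions > d))
    stop("initial positions must lie within [0, separation_d]")
  n <- population$n
  V <- 4 / 3 * pi * population$radii^3
  drag <- 6 * pi * medium$viscosity * population$radii
  dchi <- population$susceptibilities - medium$susceptibility
  drho <- population$densities - medium$density
  B0 <- config$surface_field_B0
  use_linear <- config$field_model == "linear_axial"

  force <- function(z) {
    if (use_linear) {
      Bz <- B0 * (1 - 2 * z / d)
      dBz <- -2 * B0 / d
    } else {
      fld <- axial_field(z, config)
      Bz <- fld$Bz; dBz <- fld$dBz_dz
    }
    dchi / .const$mu0 * V * Bz * dBz - drho * V * .const$g
  }

  times <- seq(0, duration, by = dt)
  pos <- matrix(NA_real_, nrow = length(times), ncol = n)
  z <- population$initial_positions
  absorbed_lo <- rep(FALSE, n)
  absorbed_hi <- rep(FALSE, n)
  pos[1, ] <- z
  max_dz <- d / 100
  for (k in seq_along(times)[-1]) {
    remaining <- dt
    while (remaining > 0) {
      f <- force(z)
      if (any(!is.finite(f)))
        stop("non-finite force encountered; check medium/analyte parameters")
      v <- f / drag
      v[absorbed_lo | absorbed_hi] <- 0
      vmax <- max(abs(v))
      step <- if (vmax * remaining > max_dz) max_dz / vmax else remaining
      z <- z + v * step
      absorbed_lo <- absorbed_lo | z <= 0
      absorbed_hi <- absorbed_hi | z >= d
      z[absorbed_lo] <- 0
      z[absorbed_hi] <- d
      remaining <- remaining - step
    }
    pos[k, ] <- z
  }
  terminal <- factor(ifelse(absorbed_lo, "precipitated",
                            ifelse(absorbed_hi, "floated", "levitating")),
                     levels = c("levitating", "precipitated", "floated"))
  structure(list(times = times, positions = pos, terminal_state = terminal,
                 population = population, medium = medium, config = config),
            class = "maglev_trajectory")
}

#' Terminal-state fractions of a simulated run
#'
#' @param trajectory A `maglev_trajectory`.
#' @return Named numeric vector `(levitating, precipitated, floated)`
#'   summing to one.
#' @export
classify_fractions <- function(trajectory) {
  stopifnot(inherits(trajectory, "maglev_trajectory"))
  tab <- table(trajectory$terminal_state)
  as.vector(tab / sum(tab)) |> stats::setNames(names(tab))
}

#' Optical model for frame rendering
#'
#' @param image_height_px,image_width_px Frame size in pixels. The vertical
#'   pixel axis spans the full magnet gap `[0, d]`.
#' @param psf_sigma_px Gaussian point-spread sigma, pixels.
#' @param background_level Constant background intensity.
#' @param noise_sigma Additive Gaussian read-noise sigma.
#' @param frame_interval Seconds between frames (1 frame / 20 s by default).
#' @param intensity_per_volume Intensity integral contributed by a particle
#'   per m^3 of particle volume.
#' @return List of class `maglev_optics`.
#' @export
maglev_optics <- function(image_height_px = 240, image_width_px = 64,
                          psf_sigma_px = 2, background_level = 100,
                          noise_sigma = 2, frame_interval = 20,
                          intensity_per_volume = 1e18) {
  stopifnot(image_height_px > 0, image_width_px > 0, psf_sigma_px > 0,
            frame_interval > 0, noise_sigma >= 0)
  structure(list(image_height_px = image_height_px,
                 image_width_px = image_width_px,
                 psf_sigma_px = psf_sigma_px,
                 background_level = background_level,
                 noise_sigma = noise_sigma,
                 frame_interval = frame_interval,
                 intensity_per_volume = intensity_per_volume),
            class = "maglev_optics")
}

#' Render synthetic time-lapse frames from a trajectory
#'
#' Each frame is `background + sum of Gaussian particle kernels + noise`.
#' A particle's kernel integrates (sums) to `intensity_per_volume * V`, so
#' integrated above-background intensity is conserved while particles stay
#' in the field of view. Particle lateral (column) positions are assigned
#' deterministically, evenly spaced across the central 60% of the width.
#' Frames use a bottom-up row convention: row 1 is the bottom of the gap.
#'
#' @param trajectory A `maglev_trajectory`.
#' @param optics A [maglev_optics()].
#' @param seed Integer seed for the noise draws (`NULL`: do not reseed).
#' @return A [frame_series()] whose metadata records the pixel-to-mm scale
#'   and the ground-truth trajectory.
#' @export
render_frames <- function(trajectory, optics = maglev_optics(), seed = NULL) {
  stopifnot(inherits(trajectory, "maglev_trajectory"))
  if (!is.null(seed)) set.seed(seed)
  d <- trajectory$config$separation_d
  H <- optics$image_height_px
  W <- optics$image_width_px
  px_m <- d / H                       # metres per pixel
  ft <- optics$frame_interval
  keep <- which(abs(trajectory$times / ft - round(trajectory$times / ft)) < 1e-9)
  if (length(keep) == 0)
    stop("frame_interval does not divide any sampled times")
  times <- trajectory$times[keep]
  n <- trajectory$population$n
  V <- 4 / 3 * pi * trajectory$population$radii^3
  amp <- optics$intensity_per_volume * V
  cols <- W / 2 + (seq_len(n) - (n + 1) / 2) / max(n, 1) * 0.6 * W
  sig <- optics$psf_sigma_px
  rr <- seq_len(H); cc <- seq_len(W)
  frames <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    img <- matrix(optics$background_level, nrow = H, ncol = W)
    z <- trajectory$positions[keep[j], ]
    rows <- z / px_m + 0.5            # bottom-up pixel row of particle centre
    for (p in seq_len(n)) {
      kr <- exp(-(rr - rows[p])^2 / (2 * sig^2))
      kc <- exp(-(cc - cols[p])^2 / (2 * sig^2))
      ker <- outer(kr, kc)
      s <- sum(ker)
      if (s > 0) img <- img + amp[p] / s * ker
    }
    if (optics$noise_sigma > 0)
      img <- img + matrix(stats::rnorm(H * W, 0, optics$noise_sigma), H, W)
    frames[[j]] <- img
  }
  frame_series(frames, times, pixel_to_mm = px_m * 1e3,
               meta = list(seed = seed, optics = unclass(optics),
                           terminal_state = as.character(trajectory$terminal_state),
                           true_final_z = trajectory$positions[nrow(trajectory$positions), ],
                           true_initial_z = trajectory$positions[1, ]))
}
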