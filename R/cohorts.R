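# Synthetic cohort generators. Two levels of realism:
#  - fingerprint-space cohorts (bivariate normal donor effects + replicate
#    noise), the fast stand-in for donor plasma samples;
#  - image-space cohorts, where class-specific particle-density mixtures are
#    pushed through the levitation simulator and renderer so the full
#    pipeline can be exercised end to end.
# No fingerprint coordinates are published for the real samples; all default
# class locations below are explicitly synthetic, chosen to mimic the
# qualitative structure of the study (PDAC shifted most in starting
# position relative to healthy controls, breast shifted oppositely, prostate
# and colorectal nearly overlapping).

#' Class specification for cohort generation
#'
#' @param class_name Class label (e.g. `"NOP"`, `"PDAC"`).
#' @param fingerprint_mean Length-2 vector: class mean (starting position
#'   mm, levitating area).
#' @param fingerprint_cov 2 x 2 donor-level covariance (symmetric PSD).
#' @param n_donors Number of donors.
#' @param n_replicates Replicates per donor (default 3, averaged downstream).
#' @param replicate_cov 2 x 2 within-donor replicate covariance; default
#'   one quarter of `fingerprint_cov`.
#' @param density_mixture Data frame with columns `mean`, `sd` (kg/m^3) and
#'   `weight` (summing to 1) describing the particle-density mixture used
#'   for image-level generation; `NULL` for fingerprint-only specs.
#' @param n_particles Particles per donor sample for image-level generation.
#' @param radius_m Mean aggregate hydrodynamic radius for image generation.
#' @return Object of class `maglev_class_spec`.
#' @export
class_spec <- function(class_name, fingerprint_mean, fingerprint_cov,
                       n_donors, n_replicates = 3,
                       replicate_cov = fingerprint_cov / 4,
                       density_mixture = NULL, n_particles = 60,
                       radius_m = 10e-6) {
  fingerprint_cov <- as.matrix(fingerprint_cov)
  stopifnot(length(fingerprint_mean) == 2,
            all(dim(fingerprint_cov) == c(2, 2)),
            isTRUE(all.equal(fingerprint_cov, t(fingerprint_cov))),
            all(eigen(fingerprint_cov, only.values = TRUE)$values > -1e-12),
            n_donors >= 0, n_replicates >= 1)
  if (!is.null(density_mixture)) {
    stopifnot(all(c("mean", "sd", "weight") %in% names(density_mixture)),
              abs(sum(density_mixture$weight) - 1) < 1e-9)
  }
  structure(list(class_name = class_name,
                 fingerprint_mean = fingerprint_mean,
                 fingerprint_cov = fingerprint_cov,
                 replicate_cov = as.matrix(replicate_cov),
                 n_donors = n_donors, n_replicates = n_replicates,
                 density_mixture = density_mixture,
                 n_particles = n_particles, radius_m = radius_m),
            class = "maglev_class_spec")
}

#' Default synthetic class specifications
#'
#' Five classes with the study's cohort sizes (15 healthy controls, 5
#' breast, 5 prostate, 5 colorectal, 15 PDAC donors, 3 replicates each).
#' Locations are synthetic: PDAC is shifted upward in starting position
#' relative to controls, breast downward, prostate/colorectal overlap the
#' controls; levitating areas differ little except a modest PDAC shift.
#'
#' @param n_donors Optional named vector overriding donor counts per class.
#' @return Named list of [class_spec()]s.
#' @export
default_class_specs <- function(n_donors = c(NOP = 15, breast = 5,
                                             prostate = 5, colorectal = 5,
                                             PDAC = 15)) {
  cov0 <- matrix(c(1.0^2, 0.1, 0.1, 0.6^2), 2, 2)
  means <- list(NOP = c(12.0, 5.0), breast = c(10.4, 5.1),
                prostate = c(12.4, 5.0), colorectal = c(12.6, 4.9),
                PDAC = c(15.2, 4.2))
  mix <- list(
    NOP        = data.frame(mean = c(1075, 1400), sd = c(8, 60),
                            weight = c(0.45, 0.55)),
    breast     = data.frame(mean = c(1090, 1400), sd = c(8, 60),
                            weight = c(0.45, 0.55)),
    prostate   = data.frame(mean = c(1071, 1400), sd = c(8, 60),
                            weight = c(0.45, 0.55)),
    colorectal = data.frame(mean = c(1069, 1400), sd = c(8, 60),
                            weight = c(0.45, 0.55)),
    PDAC       = data.frame(mean = c(1045, 1400), sd = c(8, 60),
                            weight = c(0.30, 0.70)))
  out <- lapply(names(means), function(cl)
    class_spec(cl, means[[cl]], cov0, n_donors = unname(n_donors[cl]),
               density_mixture = mix[[cl]]))
  stats::setNames(out, names(means))
}

# Bivariate normal draws via Cholesky (degenerate covariances allowed).
.rmvn2 <- function(n, mean, cov) {
  ev <- eigen(cov, symmetric = TRUE)
  A <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 2)
  z <- matrix(stats::rnorm(2 * n), ncol = 2)
  sweep(z %*% t(A), 2, mean, `+`)
}

#' Generate a fingerprint-space cohort
#'
#' Hierarchical draw per donor: a donor-level mean from the class
#' distribution, then `n_replicates` replicate fingerprints around it.
#' Donor points (replicate averages) form the returned cohort, mirroring the
#' one-dot-per-donor, triplicate-averaged design.
#'
#' @param specs List of [class_spec()]s.
#' @param seed Integer seed; the draw is reproducible.
#' @return List: `cohort` (a [maglev_cohort()] of donor averages),
#'   `replicates` (data frame of all replicate fingerprints),
#'   `donor_means` (data frame of the latent donor effects).
#' @export
generate_fingerprint_cohort <- function(specs, seed = 1) {
  set.seed(seed)
  reps <- list(); donors <- list(); pts <- list(); labs <- character(0)
  ids <- character(0)
  for (spec in specs) {
    for (i in seq_len(spec$n_donors)) {
      id <- sprintf("%s_%02d", spec$class_name, i)
      dm <- drop(.rmvn2(1, spec$fingerprint_mean, spec$fingerprint_cov))
      rep_pts <- .rmvn2(spec$n_replicates, dm, spec$replicate_cov)
      reps[[id]] <- data.frame(donor_id = id, class = spec$class_name,
                               replicate_id = seq_len(spec$n_replicates),
                               starting_position_mm = rep_pts[, 1],
                               levitating_area = rep_pts[, 2])
      donors[[id]] <- data.frame(donor_id = id, class = spec$class_name,
                                 mean_start = dm[1], mean_area = dm[2])
      pts[[id]] <- colMeans(rep_pts)
      labs <- c(labs, spec$class_name)
      ids <- c(ids, id)
    }
  }
  list(cohort = maglev_cohort(do.call(rbind, pts), labs, ids),
       replicates = do.call(rbind, c(reps, make.row.names = FALSE)),
       donor_means = do.call(rbind, c(donors, make.row.names = FALSE)))
}

#' Generate an image-space cohort
#'
#' For each donor, particle densities are drawn from the class density
#' mixture, initial positions are set near the particles' equilibrium
#' heights (the injected sample redistributes before imaging starts), the
#' population is integrated with [simulate_trajectories()] and rendered
#' with [render_frames()]. Ground truth (true fractions, equilibrium
#' heights) is returned alongside the frames.
#'
#' @param specs List of [class_spec()]s with `density_mixture` set.
#' @param medium,config,optics Device and optics descriptions.
#' @param seed Integer seed.
#' @param duration,dt Simulation time grid, seconds.
#' @param position_jitter_mm Jitter (sd) around equilibrium heights for the
#'   initial positions, mm.
#' @return List: `series` (named list of [frame_series()] per donor),
#'   `truth` (data frame: donor, class, levitating/precipitated fractions,
#'   mean equilibrium height of the levitating component).
#' @export
generate_image_cohort <- function(specs, medium = paramagnetic_medium(),
                                  config = maglev_config(),
                                  optics = maglev_optics(),
                                  seed = 1, duration = 1200, dt = 2,
                                  position_jitter_mm = 1.0) {
  set.seed(seed)
  d <- config$separation_d
  series <- list(); truth <- list()
  for (spec in specs) {
    if (is.null(spec$density_mixture))
      stop("class ", spec$class_name, " has no density_mixture")
    mx <- spec$density_mixture
    for (i in seq_len(spec$n_donors)) {
      id <- sprintf("%s_%02d", spec$class_name, i)
      comp <- sample.int(nrow(mx), spec$n_particles, replace = TRUE,
                         prob = mx$weight)
      dens <- stats::rnorm(spec$n_particles, mx$mean[comp], mx$sd[comp])
      dens <- pmax(dens, 900)
      radii <- spec$radius_m * exp(stats::rnorm(spec$n_particles, 0, 0.1))
      # closed-form equilibrium heights; out-of-range particles start where
      # the levitating component sits (homogeneous initial distribution)
      eq <- vapply(dens, function(rho)
        levitation_height(analyte(rho, radius = spec$radius_m),
                          medium, config)$height, numeric(1))
      in_rng <- eq >= 0 & eq <= d
      base <- ifelse(in_rng, eq,
                     if (any(in_rng)) mean(eq[in_rng]) else d / 2)
      z0 <- base + stats::rnorm(spec$n_particles, 0, position_jitter_mm / 1e3)
      z0 <- pmin(pmax(z0, 1e-4), d - 1e-4)
      pop <- particle_population(densities = dens, radii = radii,
                                 initial_positions = z0)
      traj <- simulate_trajectories(pop, medium, config,
                                    duration = duration, dt = dt)
      fs <- render_frames(traj, optics,
                          seed = (seed + 7 * length(series)) %% 2147483647)
      series[[id]] <- fs
      fr <- classify_fractions(traj)
      truth[[id]] <- data.frame(
        donor_id = id, class = spec$class_name,
        levitating_fraction = fr["levitating"],
        precipitated_fraction = fr["precipitated"],
        floated_fraction = fr["floated"],
        mean_eq_height_mm = if (any(in_rng)) mean(eq[in_rng]) * 1e3 else NA_real_)
    }
  }
  list(series = series,
       truth = do.call(rbind, c(truth, make.row.names = FALSE)))
}

#' Generate a synthetic SAXS power-law curve
#'
#' `I(q) = A q^-D` on log-spaced q with multiplicative lognormal noise whose
#' log-mean is zero (so the log-log fit is unbiased) and coefficient of
#' variation `noise_cv`.
#'
#' @param exponent Mass fractal dimension D (> 0). Default 2.01, the value
#'   typical of sheet-like graphene oxide scatterers.
#' @param q_range `c(min, max)` in 1/nm, positive.
#' @param n_points Number of log-spaced q points.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param amplitude Prefactor A.
#' @param seed Integer seed (`NULL`: do not reseed).
#' @return List with numeric vectors `q` and `intensity`.
#' @export
generate_saxs_curve <- function(exponent = 2.01, q_range = c(0.1, 1),
                                n_points = 100, noise_cv = 0.02,
                                amplitude = 1, seed = NULL) {
  stopifnot(exponent > 0, all(q_range > 0), q_range[1] < q_range[2],
            n_points >= 2, noise_cv >= 0)
  if (!is.null(seed)) set.seed(seed)
  q <- 10^seq(log10(q_range[1]), log10(q_range[2]), length.out = n_points)
  I <- amplitude * q^(-exponent)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    I <- I * exp(stats::rnorm(n_points, 0, sdlog))
  }
  list(q = q, intensity = I)
}
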