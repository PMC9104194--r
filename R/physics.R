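# Magneto-Archimedes levitation physics: device geometry, medium and analyte
# descriptions, axial field models, force balance and equilibrium height.
#
# Coordinate convention: z = 0 at the face of the lower magnet, +z upward,
# valid positions z in [0, d] where d is the magnet separation.

#' MagLev device configuration
#'
#' Describes the two-magnet MagLev device: two like-pole-facing square
#' permanent magnets separated by a gap `separation_d` with surface field
#' `surface_field_B0`. Defaults follow the reference device: N42 NdFeB
#' magnets 2.5 x 2.5 x 5.0 cm, d = 2.8 cm, ~0.5 T at the magnet surface.
#'
#' @param separation_d Magnet separation d in metres.
#' @param surface_field_B0 Magnitude of the axial field at a magnet face, tesla.
#' @param magnet_width,magnet_length,magnet_height Magnet dimensions, metres.
#' @param field_model `"linear_axial"` (field component falls linearly from
#'   +B0 at the bottom face to -B0 at the top face; the closed-form height
#'   equation is exact for this model) or `"cuboid_analytic"` (superposition
#'   of two analytic cuboid-magnet axial fields, rescaled so |Bz(0)| = B0).
#' @return Object of class `maglev_config`.
#' @export
maglev_config <- function(separation_d = 0.028,
                          surface_field_B0 = 0.5,
                          magnet_width = 0.025,
                          magnet_length = 0.025,
                          magnet_height = 0.050,
                          field_model = c("linear_axial", "cuboid_analytic")) {
  field_model <- match.arg(field_model)
  stopifnot(separation_d > 0, surface_field_B0 > 0,
            magnet_width > 0, magnet_length > 0, magnet_height > 0)
  structure(list(separation_d = separation_d,
                 surface_field_B0 = surface_field_B0,
                 magnet_width = magnet_width,
                 magnet_length = magnet_length,
                 magnet_height = magnet_height,
                 field_model = field_model),
            class = "maglev_config")
}

#' Volume susceptibility of a Dy(III) paramagnetic solution
#'
#' Estimates the SI volume magnetic susceptibility of an aqueous
#' dysprosium(III) nitrate solution from its concentration. The default
#' molar susceptibility comes from the Curie law for the Dy3+ free ion
#' (effective moment ~10.6 Bohr magnetons), which at room temperature gives
#' chi_mol ~ 5.9e-7 m^3/mol; the diamagnetic background of water is added.
#'
#' @param dy_concentration Salt concentration in mg/mL.
#' @param molar_mass Salt molar mass in g/mol (default: anhydrous Dy(NO3)3).
#' @param molar_susceptibility Molar susceptibility in m^3/mol; if `NULL`,
#'   computed by the Curie law at `temperature` with `mu_eff_bohr`.
#' @param solvent_susceptibility Volume susceptibility of the solvent
#'   (water, about -9.0e-6 SI).
#' @param temperature Temperature in kelvin (Curie-law default only).
#' @param mu_eff_bohr Effective magnetic moment of Dy3+ in Bohr magnetons.
#' @return Dimensionless SI volume susceptibility.
#' @export
medium_susceptibility <- function(dy_concentration = 80,
                                  molar_mass = 348.5,
                                  molar_susceptibility = NULL,
                                  solvent_susceptibility = -9.05e-6,
                                  temperature = 298.15,
                                  mu_eff_bohr = 10.6) {
  if (dy_concentration < 0) stop("`dy_concentration` must be non-negative")
  stopifnot(molar_mass > 0, temperature > 0)
  if (is.null(molar_susceptibility)) {
    mu2 <- (mu_eff_bohr * .const$muB)^2
    molar_susceptibility <- .const$mu0 * .const$NA_ * mu2 /
      (3 * .const$kB * temperature)
  }
  # mg/mL == g/L; mol/m^3 = 1000 * (g/L) / (g/mol)
  conc_mol_m3 <- 1000 * dy_concentration / molar_mass
  molar_susceptibility * conc_mol_m3 + solvent_susceptibility
}

#' Paramagnetic levitation medium
#'
#' @param density Mass density rho_m in kg/m^3. The default approximates an
#'   80 mg/mL aqueous Dy(NO3)3 solution at 25 C.
#' @param susceptibility SI volume susceptibility chi_m (> 0, paramagnetic);
#'   default from [medium_susceptibility()] at `dy_concentration`.
#' @param dy_concentration Dy(III) nitrate concentration, mg/mL.
#' @param viscosity Dynamic viscosity in Pa s (water at 25 C by default).
#' @param temperature Kelvin.
#' @return Object of class `paramagnetic_medium`.
#' @export
paramagnetic_medium <- function(density = 1060,
                                susceptibility = NULL,
                                dy_concentration = 80,
                                viscosity = 0.9e-3,
                                temperature = 298.15) {
  if (is.null(susceptibility))
    susceptibility <- medium_susceptibility(dy_concentration,
                                            temperature = temperature)
  stopifnot(density > 0, viscosity > 0, susceptibility > 0)
  structure(list(density = density,
                 susceptibility = susceptibility,
                 dy_concentration = dy_concentration,
                 viscosity = viscosity,
                 temperature = temperature),
            class = "paramagnetic_medium")
}

#' Diamagnetic analyte (corona-coated particle or particle ensemble average)
#'
#' @param density Mass density rho_s, kg/m^3.
#' @param susceptibility SI volume susceptibility chi_s (diamagnetic objects
#'   have small negative values; default is close to water/organic matter).
#' @param radius Hydrodynamic radius in metres (used for Stokes drag and,
#'   if `volume` is missing, to compute a spherical volume).
#' @param volume Particle volume in m^3; defaults to `4/3 pi radius^3`.
#' @return Object of class `maglev_analyte`.
#' @export
analyte <- function(density,
                    susceptibility = -9.0e-6,
                    radius = 10e-6,
                    volume = NULL) {
  if (is.null(volume)) volume <- 4 / 3 * pi * radius^3
  stopifnot(density > 0, volume > 0, radius > 0)
  structure(list(density = density,
                 susceptibility = susceptibility,
                 radius = radius,
                 volume = volume),
            class = "maglev_analyte")
}

# Axial field of a single cuboid magnet magnetized along +z, evaluated at
# distance z above its top face; a, b are the half-widths, L the height.
# Standard expression for the on-axis field of a uniformly magnetized block.
.cuboid_axial <- function(z, a, b, L, Br) {
  f <- function(u) atan2(a * b, u * sqrt(a^2 + b^2 + u^2))
  Br / pi * (f(z) - f(z + L))
}

#' Axial magnetic field between the magnets
#'
#' Returns the signed axial field component Bz and its gradient dBz/dz on
#' the central axis at height `z` above the lower magnet face.
#'
#' With `field_model = "linear_axial"`, Bz(z) = B0 (1 - 2 z / d) and
#' dBz/dz = -2 B0 / d: the linear profile whose consequence is the
#' closed-form levitation height. With `"cuboid_analytic"`, the field is
#' the superposition of two analytic cuboid-magnet fields (opposing like
#' poles), rescaled so that |Bz(0)| = B0; its gradient is evaluated by
#' central differences.
#'
#' @param z Height(s) in metres, within `[0, separation_d]`.
#' @param config A [maglev_config()].
#' @return List with numeric vectors `Bz` (T) and `dBz_dz` (T/m).
#' @export
axial_field <- function(z, config = maglev_config()) {
  d <- config$separation_d
  if (any(z < -1e-12 | z > d + 1e-12))
    stop("`z` must lie within [0, separation_d]")
  z <- pmin(pmax(z, 0), d)
  B0 <- config$surface_field_B0
  if (config$field_model == "linear_axial") {
    list(Bz = B0 * (1 - 2 * z / d), dBz_dz = rep(-2 * B0 / d, length(z)))
  } else {
    a <- config$magnet_width / 2
    b <- config$magnet_length / 2
    L <- config$magnet_height
    raw <- function(zz) .cuboid_axial(zz, a, b, L, 1) -
      .cuboid_axial(d - zz, a, b, L, 1)
    scale <- B0 / abs(raw(0))
    h <- d * 1e-6
    Bz <- scale * raw(z)
    dBz <- scale * (raw(pmin(z + h, d + h)) - raw(pmax(z - h, -h))) /
      (pmin(z + h, d + h) - pmax(z - h, -h))
    list(Bz = Bz, dBz_dz = dBz)
  }
}

#' Net vertical force on an analyte (magnetic + buoyancy-corrected gravity)
#'
#' Computes `F = (chi_s - chi_m)/mu0 * V * Bz * dBz/dz - (rho_s - rho_m) * V * g`
#' (signed, positive upward) at height(s) `z`.
#'
#' @param z Height(s), metres, in `[0, separation_d]`.
#' @param analyte A [analyte()].
#' @param medium A [paramagnetic_medium()].
#' @param config A [maglev_config()].
#' @return Numeric vector of forces in newtons.
#' @export
net_force <- function(z, analyte, medium, config = maglev_config()) {
  fld <- axial_field(z, config)
  dchi <- analyte$susceptibility - medium$susceptibility
  drho <- analyte$density - medium$density
  V <- analyte$volume
  dchi / .const$mu0 * V * fld$Bz * fld$dBz_dz - drho * V * .const$g
}

.levitation_result <- function(height, d) {
  in_range <- height >= 0 && height <= d
  status <- if (in_range) "levitates" else if (height < 0) "precipitates" else "floats"
  structure(list(height = height, in_range = in_range, status = status),
            class = "levitation_result")
}

#' @export
print.levitation_result <- function(x, ...) {
  if (x$in_range)
    cat(sprintf("Levitation height: %.3f mm\n", x$height * 1e3))
  else
    cat(sprintf("Out of range (%s); nominal height %.3f mm\n",
                x$status, x$height * 1e3))
  invisible(x)
}

#' Closed-form levitation height
#'
#' Equilibrium height of a diamagnetic analyte between the magnets, exact
#' for the linear axial field:
#' `h = d/2 + (rho_s - rho_m) g mu0 d^2 / (4 (chi_s - chi_m) B0^2)`.
#' A density-matched sample (`rho_s = rho_m`) levitates at mid-gap, h = d/2.
#'
#' @inheritParams net_force
#' @return A `levitation_result`: `height` (m, possibly outside `[0, d]`),
#'   `in_range`, and `status` (`"levitates"`, `"precipitates"` when the
#'   nominal height falls below the cuvette bottom, `"floats"` above the top).
#' @export
levitation_height <- function(analyte, medium, config = maglev_config()) {
  dchi <- analyte$susceptibility - medium$susceptibility
  if (dchi == 0) stop("singular parameters: chi_s equals chi_m")
  d <- config$separation_d
  B0 <- config$surface_field_B0
  drho <- analyte$density - medium$density
  h <- d / 2 + drho * .const$g * .const$mu0 * d^2 / (4 * dchi * B0^2)
  .levitation_result(h, d)
}

#' Numerical force-balance equilibrium
#'
#' Finds the height at which [net_force()] vanishes by bracketed root
#' finding on `[0, d]`. With the linear field model this agrees with
#' [levitation_height()] to better than 1e-6 relative. If several roots
#' exist (possible under the cuboid field model) the stable one (negative
#' force gradient) is returned with a warning. If the force does not change
#' sign in the gap, the outcome is categorical: `"precipitates"` when the
#' force is downward throughout, `"floats"` when upward.
#'
#' @inheritParams net_force
#' @param tol Absolute height tolerance of the root, metres.
#' @return A `levitation_result` (height is `NA` when out of range).
#' @export
solve_equilibrium <- function(analyte, medium, config = maglev_config(),
                              tol = 1e-9) {
  d <- config$separation_d
  zs <- seq(0, d, length.out = 513)
  f <- net_force(zs, analyte, medium, config)
  sgn <- sign(f)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  roots <- numeric(0)
  for (i in idx) {
    r <- stats::uniroot(function(z) net_force(z, analyte, medium, config),
                        lower = zs[i], upper = zs[i + 1], tol = tol)
    roots <- c(roots, r$root)
  }
  exact <- zs[sgn == 0]          # grid point exactly at equilibrium
  roots <- unique(c(roots, exact))
  if (length(roots) == 0) {
    out <- .levitation_result(if (mean(f) < 0) -Inf else Inf, d)
    out$height <- NA_real_
    return(out)
  }
  grad <- vapply(roots, function(z) {
    h <- d * 1e-5
    (net_force(min(z + h, d), analyte, medium, config) -
       net_force(max(z - h, 0), analyte, medium, config)) /
      (min(z + h, d) - max(z - h, 0))
  }, numeric(1))
  stable <- roots[grad < 0]
  if (length(roots) > 1)
    warning("multiple force-balance roots; returning the stable one")
  z <- if (length(stable)) stable[1] else roots[1]
  .levitation_result(z, d)
}
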