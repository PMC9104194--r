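# maglev_physics: susceptibility estimate, axial field, force balance,
# closed-form and numerical equilibrium heights.

test_that("medium susceptibility follows the Curie-law construction", {
  # zero-concentration limit: solvent only
  expect_equal(medium_susceptibility(0), -9.05e-6)
  # 80 mg/mL at 298 K: independent hand calculation gives ~1.27e-4 SI
  chi80 <- medium_susceptibility(80, temperature = 298.15)
  expect_lt(abs(chi80 - 1.3e-4), 1.5e-5)
  # linearity: doubling concentration doubles the paramagnetic term
  solv <- -9.05e-6
  expect_equal(medium_susceptibility(160) - solv,
               2 * (medium_susceptibility(80) - solv), tolerance = 1e-12)
  expect_error(medium_susceptibility(-1), "non-negative")
})

test_that("axial field models have the stated shape and symmetry", {
  d <- ref_config$separation_d
  lin <- axial_field(c(0, d / 2, d), ref_config)
  expect_equal(lin$Bz, c(0.5, 0, -0.5))           # B0 at faces, 0 midway
  expect_equal(lin$dBz_dz, rep(-2 * 0.5 / d, 3))
  cub_cfg <- maglev_config(field_model = "cuboid_analytic")
  cub <- axial_field(c(0, d / 2, d), cub_cfg)
  expect_equal(abs(cub$Bz[1]), 0.5)               # calibrated surface field
  expect_equal(cub$Bz[2], 0)                      # mirror symmetry
  expect_equal(cub$Bz[3], -cub$Bz[1])
  expect_error(axial_field(-0.001, ref_config), "within")
  expect_error(axial_field(d + 0.001, ref_config), "within")
})

test_that("net force matches the potential-energy gradient oracle", {
  # U(z) = -(dchi/(2 mu0)) V Bz^2 + drho V g z; F = -dU/dz. For the linear
  # field U is quadratic in z, so the central difference is exact.
  const <- maglev_constants()
  set.seed(11)
  for (i in 1:25) {
    a <- analyte(density = runif(1, 1000, 1300),
                 susceptibility = runif(1, -2e-5, -5e-6),
                 radius = runif(1, 1e-6, 2e-5))
    z <- runif(1, 0.002, 0.026)
    U <- function(zz) {
      Bz <- 0.5 * (1 - 2 * zz / 0.028)
      -(a$susceptibility - ref_medium$susceptibility) / (2 * const$mu0) *
        a$volume * Bz^2 +
        (a$density - ref_medium$density) * a$volume * const$g * zz
    }
    h <- 1e-5
    f_oracle <- -(U(z + h) - U(z - h)) / (2 * h)
    expect_rel_equal(net_force(z, a, ref_medium, ref_config), f_oracle, 1e-8)
  }
})

test_that("net force signs and V-independence of the zero crossing", {
  matched <- analyte(ref_medium$density)
  expect_equal(net_force(0.014, matched, ref_medium, ref_config), 0)
  heavy <- analyte(ref_medium$density + 50)
  expect_lt(net_force(0.014, heavy, ref_medium, ref_config), 0)
  # V cancels in the force balance: equilibrium independent of radius
  h1 <- solve_equilibrium(analyte(1075, radius = 1e-6), ref_medium, ref_config)
  h2 <- solve_equilibrium(analyte(1075, radius = 5e-5), ref_medium, ref_config)
  expect_equal(h1$height, h2$height, tolerance = 1e-9)
})

test_that("closed-form height reproduces hand-derived values", {
  d <- 0.028
  # density-matched: mid-gap
  hm <- levitation_height(analyte(ref_medium$density), ref_medium, ref_config)
  expect_equal(hm$height, d / 2)
  expect_equal(hm$status, "levitates")
  # drho = +10, dchi = -1.4e-4: hand evaluation gives 13.3099 mm
  med <- paramagnetic_medium(density = 1060, susceptibility = 1.31e-4)
  a <- analyte(1070, susceptibility = 1.31e-4 - 1.4e-4)
  h <- levitation_height(a, med, ref_config)
  expect_equal(h$height * 1e3, 13.3099, tolerance = 1e-4)
  # |dchi| reduced 100x: equilibrium far below the cuvette -> precipitates
  a2 <- analyte(1070, susceptibility = 1.31e-4 - 1.4e-6)
  h2 <- levitation_height(a2, med, ref_config)
  expect_false(h2$in_range)
  expect_equal(h2$status, "precipitates")
  expect_error(levitation_height(analyte(1070, susceptibility = med$susceptibility),
                                 med, ref_config), "singular")
})

test_that("numerical root agrees with the closed form on random parameters", {
  set.seed(42)
  n_ok <- 0
  for (i in 1:1000) {
    a <- analyte(density = runif(1, 900, 1250),
                 susceptibility = runif(1, -2e-5, -5e-6),
                 radius = 1e-5)
    cf <- levitation_height(a, ref_medium, ref_config)
    num <- solve_equilibrium(a, ref_medium, ref_config)
    if (cf$in_range) {
      n_ok <- n_ok + 1
      expect_rel_equal(num$height, cf$height, 1e-6)
    } else {
      expect_equal(num$status, cf$status)
    }
  }
  expect_gt(n_ok, 100)   # the sweep must actually exercise in-range cases
})

test_that("equilibrium height is monotone in density and susceptibility", {
  rhos <- seq(1000, 1150, by = 25)
  hs <- vapply(rhos, function(r)
    levitation_height(analyte(r), ref_medium, ref_config)$height, numeric(1))
  expect_true(all(diff(hs) < 0))       # denser -> lower
  # for rho_s > rho_m, larger |dchi| pulls the equilibrium back toward d/2
  chis <- -c(5, 10, 20, 40) * 1e-6
  hs2 <- vapply(chis, function(ch)
    levitation_height(analyte(1100, susceptibility = ch),
                      ref_medium, ref_config)$height, numeric(1))
  expect_true(all(diff(hs2) < 0) || all(diff(hs2) > 0))
  expect_true(all(diff(abs(hs2 - 0.014)) < 0))
})

test_that("cuboid model equilibrium is close to linear-model prediction", {
  cub <- maglev_config(field_model = "cuboid_analytic")
  a <- analyte(1075)
  h_lin <- solve_equilibrium(a, ref_medium, ref_config)$height
  h_cub <- solve_equilibrium(a, ref_medium, cub)$height
  expect_equal(solve_equilibrium(analyte(ref_medium$density),
                                 ref_medium, cub)$height, 0.014,
               tolerance = 1e-6)      # symmetry: density match -> mid-gap
  expect_lt(abs(h_cub - h_lin), 0.004)  # same physics, different field shape
})
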