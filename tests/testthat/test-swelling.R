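test_that("fixed charge density dilutes with swelling", {
  expect_equal(fixed_charge_density(250, 0.77, 1), 250)
  r <- 1.1^(1 / 3)
  expect_equal(fixed_charge_density(250, 0.77, r),
               oracle_fcd(250, 0.77, r), tolerance = 1e-14)
  expect_equal(fixed_charge_density(250, 0.77, r), 250 * 0.77 / 0.87,
               tolerance = 1e-12)
  # doubling the water volume halves the FCD
  r2 <- (1 + 0.77)^(1 / 3)
  expect_equal(fixed_charge_density(250, 0.77, r2), 125, tolerance = 1e-9)
  # strictly decreasing in r
  rs <- seq(0.8, 1.6, by = 0.01)
  expect_true(all(diff(fixed_charge_density(250, 0.77, rs)) < 0))
  expect_error(fixed_charge_density(250, 0.77, 0.5), "r > ")
})

test_that("Donnan pressure is zero without fixed charge and matches the closed form", {
  expect_equal(donnan_pressure(0), 0)
  # cF = c* at body temperature
  expect_equal(donnan_pressure(150), oracle_donnan_kpa(150), tolerance = 1e-14)
  expect_equal(donnan_pressure(150),
               8.3144 * 310.15 * 150 * (sqrt(5) - 2) / 1000, tolerance = 1e-12)
  expect_error(donnan_pressure(-1), "nonnegative")
})

test_that("Donnan pressure is strictly increasing with the ideal large-cF asymptote", {
  cF <- sort(runif(200, 0, 1000))
  p <- donnan_pressure(cF)
  expect_true(all(diff(p) > 0))
  expect_true(all(p >= 0))
  constants <- osmotic_constants()
  big <- 1e6
  expect_equal(donnan_pressure(big) * 1000 /
                 (constants$R * constants$T_kelvin * big), 1, tolerance = 1e-3)
})

test_that("deformed water content matches the volume-conservation form", {
  phis <- seq(0.05, 0.95, by = 0.05)
  expect_equal(deformed_water_content(phis[1], 1), phis[1])
  for (p in phis) expect_equal(deformed_water_content(p, 1), p)
  expect_equal(deformed_water_content(0.77, 1.05), oracle_phi(0.77, 1.05),
               tolerance = 1e-15)
  expect_equal(deformed_water_content(0.77, 1.05), 0.927625 / 1.157625,
               tolerance = 1e-12)
  rs <- seq(0.9, 2, by = 0.01)
  expect_true(all(diff(deformed_water_content(0.77, rs)) > 0))
  expect_equal(deformed_water_content(0.77, 1e4), 1, tolerance = 1e-6)
  expect_error(deformed_water_content(0.77, 0.3), "r > ")
})

test_that("water content inverts back to the height ratio", {
  for (r in c(0.95, 1, 1.05, 1.3)) {
    phi <- deformed_water_content(0.77, r)
    expect_equal(height_ratio_from_phi(phi, 0.77), r, tolerance = 1e-10)
  }
})

test_that("NP/AF partition satisfies the area-weighted mixture identity", {
  ref <- disc_reference()[1, ]
  at_ref <- partition_water_content(1, ref)
  expect_equal(at_ref$phi_np, 0.80)
  expect_equal(at_ref$phi_af, 0.75)
  expect_equal(at_ref$phi_combined, 0.77)
  p105 <- partition_water_content(1.05, ref)
  expect_equal(p105$phi_np, oracle_phi(0.80, 1.05), tolerance = 1e-15)
  expect_equal(p105$phi_af, oracle_phi(0.75, 1.05), tolerance = 1e-15)
  # the combined fraction equals the update applied to the mixed reference
  for (r in seq(0.85, 1.8, by = 0.05)) {
    p <- partition_water_content(r, ref)
    expect_equal(p$phi_combined, deformed_water_content(0.77, r),
                 tolerance = 1e-12)
  }
})

test_that("disc swelling stress composes compartment pressures and decreases with r", {
  ref <- make_test_ref()
  expect_equal(disc_swelling_stress(1, ref),
               0.4 * donnan_pressure(250) + 0.6 * donnan_pressure(200),
               tolerance = 1e-12)
  expect_equal(disc_swelling_stress(1, ref),
               oracle_stress_kpa(1, 250, 0.80, 0.75), tolerance = 1e-14)
  expect_lt(disc_swelling_stress(1.01, ref), disc_swelling_stress(1.0, ref))
  rs <- seq(0.8, 2, by = 0.02)
  expect_true(all(diff(disc_swelling_stress(rs, ref)) < 0))
})

test_that("equilibrium solver is self-consistent and orders loads correctly", {
  ref <- disc_reference()[1, ]   # C2C3
  F_ref <- disc_swelling_stress(1, ref) * ref$A0_mm2 / 1000
  sol <- solve_equilibrium(F_ref, ref)
  expect_equal(sol$r, 1, tolerance = 1e-8)
  expect_lte(sol$residual_N, 1e-6)
  unloaded <- solve_equilibrium(21.5, ref)   # the two reported C2C3 loads
  loaded <- solve_equilibrium(91.83, ref)
  expect_gt(unloaded$r, loaded$r)
  expect_gt(unloaded$phi_np, loaded$phi_np)
})

test_that("zero load reports the free-swelling asymptote cleanly", {
  sol <- solve_equilibrium(0, disc_reference()[1, ])
  expect_identical(sol$r, Inf)
  expect_identical(sol$Fs_kPa, 0)
  expect_identical(sol$residual_N, 0)
})

test_that("unattainable loads raise a bracketing error reporting the range", {
  ref <- disc_reference()[1, ]
  expect_error(solve_equilibrium(1e13, ref), "attainable range")
  expect_error(solve_equilibrium(-5, ref), "nonnegative")
})

test_that("solver agrees with an independent grid-scan oracle", {
  set.seed(7)
  for (i in 1:10) {
    phi_np <- runif(1, 0.72, 0.9)
    ref <- make_test_ref(A0 = runif(1, 300, 600),
                         phi0_np = phi_np,
                         phi0_af = runif(1, 0.65, phi_np),
                         c0F_np = runif(1, 100, 500))
    F_max <- disc_swelling_stress(0.95, ref) * ref$A0_mm2 / 1000
    F_N <- runif(1, 0.05, 0.9) * F_max
    grid <- oracle_grid_solve(F_N, ref, n_grid = 1e5)
    sol <- solve_equilibrium(F_N, ref)
    expect_lt(abs(sol$r - grid$r), grid$step)
  }
})

test_that("equilibrium table solves each level against its own reference row", {
  ref <- disc_reference()
  loads <- data.frame(level = disc_levels(),
                      compression_N = c(91.83, 101.69, 110.37, 121.15,
                                        144.87, 178.07))
  eq <- solve_equilibrium_table(loads, ref)
  expect_equal(nrow(eq), 6)
  expect_equal(eq$h_mm, eq$r * ref$h0_mm, tolerance = 1e-12)
  expect_true(all(eq$residual_N < 1e-6))
  # mixture identity holds row-wise
  expect_equal(eq$phi_combined, 0.4 * eq$phi_np + 0.6 * eq$phi_af,
               tolerance = 1e-12)
})
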