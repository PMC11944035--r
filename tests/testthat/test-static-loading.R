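test_that("packaged posture scenarios carry the reported joint angles", {
  nbp1g <- read_scenario("nbp1g")
  expect_equal(nbp1g$gravity_factor, 1)
  expect_equal(nbp1g$joint_angles$sternoclavicular_protraction, 23)
  expect_equal(nbp1g$joint_angles$sternoclavicular_elevation, 11.5)
  expect_equal(nbp1g$joint_angles$shoulder_flexion, 8)
  expect_equal(nbp1g$joint_angles$elbow_pronation, -20)
  expect_equal(nbp1g$joint_angles$hip_flexion, -6)
  sm0g <- read_scenario("sm0g")
  expect_equal(sm0g$gravity_factor, 0)
  expect_equal(sm0g$joint_angles, nbp1g$joint_angles)   # same stance, no gravity
  nbp0g <- read_scenario("nbp0g")
  expect_equal(nbp0g$gravity_factor, 0)
  expect_equal(nbp0g$joint_angles$neck_flexion, 24)
  expect_equal(nbp0g$joint_angles$shoulder_flexion, 39)
  expect_equal(nbp0g$joint_angles$knee_flexion, 55)
  expect_equal(nbp0g$joint_angles$ankle_plantarflexion, 21)
  expect_error(read_scenario("nope.yaml"), "not found")
})

test_that("scenario validation rejects malformed inputs", {
  expect_error(posture_scenario("x", -1), "nonnegative")
  expect_error(posture_scenario("x", 1, list(5)), "named")
  expect_error(posture_scenario("x", 1, list(neck_flexion = NaN)), "finite")
  expect_error(posture_scenario("x", 1, cervical_tilt_per_level = c(L1L2 = 3)),
               "unknown level")
})

test_that("supported weight accumulates mass cranio-caudally and scales with gravity", {
  anthro <- anthropometry()
  expect_equal(supported_weight(disc_levels(), anthro, 0), rep(0, 6))
  w <- supported_weight(disc_levels(), anthro, 1)
  expect_true(all(diff(w) > 0))
  expect_gt(supported_weight("C7T1", anthro, 1),
            supported_weight("C2C3", anthro, 1))
  # head-only check: 5 kg head, no cervical segment mass
  head5 <- anthropometry(total_mass = 72, head_mass_fraction = 5 / 72,
                         cervical_segment_mass_kg = stats::setNames(
                           rep(0, 6), disc_levels()))
  expect_equal(supported_weight("C2C3", head5, 1), 5 * 9.81, tolerance = 1e-9)
  expect_error(supported_weight("T1T2", anthro, 1), "unknown disc level")
})

test_that("weightlessness without co-contraction unloads every disc", {
  sc <- read_scenario("sm0g")
  loads <- disc_loads(sc, muscle_cocontraction = 0)
  expect_equal(loads$compression_N, rep(0, 6))
  expect_equal(loads$shear_N, rep(0, 6))
})

test_that("upright zero-tilt posture is pure axial compression", {
  sc <- posture_scenario("upright", 1,
                         cervical_tilt_per_level = stats::setNames(
                           rep(0, 6), disc_levels()))
  loads <- disc_loads(sc, muscle_cocontraction = 0)
  expect_equal(loads$shear_N, rep(0, 6))
  expect_equal(loads$compression_N,
               supported_weight(disc_levels(), anthropometry(), 1),
               tolerance = 1e-12)
})

test_that("standing at 1 g: compression grows caudally, shear is anterior", {
  loads <- disc_loads(read_scenario("nbp1g"))
  expect_true(all(diff(loads$compression_N) > 0))
  expect_true(all(loads$shear_N < 0))
})

test_that("loads are linear in the gravity factor when muscle terms are linear", {
  mk <- function(g) posture_scenario("g", g)
  l0 <- disc_loads(mk(0), muscle_cocontraction = 0)
  l1 <- disc_loads(mk(1), muscle_cocontraction = 0)
  lh <- disc_loads(mk(0.5), muscle_cocontraction = 0)
  expect_equal(lh$compression_N, (l0$compression_N + l1$compression_N) / 2,
               tolerance = 1e-12)
  expect_equal(lh$shear_N, (l0$shear_N + l1$shear_N) / 2, tolerance = 1e-12)
})

test_that("without muscle terms the resolved load preserves the weight magnitude", {
  sc <- read_scenario("nbp1g")
  loads <- disc_loads(sc, muscle_cocontraction = 0, include_extensor = FALSE)
  w <- supported_weight(disc_levels(), anthropometry(), 1)
  expect_equal(sqrt(loads$compression_N^2 + loads$shear_N^2), w,
               tolerance = 1e-12)
})

test_that("co-contraction keeps microgravity compression in a plausible band", {
  loads <- disc_loads(read_scenario("nbp0g"))
  expect_true(all(loads$compression_N >= 20 & loads$compression_N <= 45))
})
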