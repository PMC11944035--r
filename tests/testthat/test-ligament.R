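test_that("packaged ligament table carries the cadaveric stiffness segments", {
  specs <- ligament_specs()
  expect_equal(nrow(specs), 6)
  key <- paste(specs$ligament, specs$region)
  expect_setequal(key, c("ALL C2C5", "ALL C5T1", "PLL C2C5", "PLL C5T1",
                         "LF C2C5", "LF C5T1"))
  expect_equal(specs$stiffness_N_per_mm[match("ALL C2C5", key)], 16)
  expect_equal(specs$stiffness_N_per_mm[match("ALL C5T1", key)], 17.9)
  expect_equal(specs$stiffness_N_per_mm[match("PLL C2C5", key)], 25.4)
  expect_equal(specs$stiffness_N_per_mm[match("PLL C5T1", key)], 23)
  expect_equal(specs$stiffness_N_per_mm[match("LF C2C5", key)], 25)
  expect_equal(specs$stiffness_N_per_mm[match("LF C5T1", key)], 21.6)
  # LF C5T1 range stored ascending after normalisation
  lf2 <- specs[key == "LF C5T1", ]
  expect_equal(c(lf2$strain_lo_pct, lf2$strain_hi_pct), c(75.3, 101.5))
  expect_true(all(specs$strain_lo_pct < specs$strain_hi_pct))
})

test_that("ligament force is a clamped piecewise-linear spring", {
  specs <- ligament_specs()
  all_c2c5 <- specs[specs$ligament == "ALL" & specs$region == "C2C5", ]
  expect_equal(ligament_force(0, all_c2c5), 0)       # at slack
  expect_equal(ligament_force(30, all_c2c5), 96)     # 16 N/mm x 6 mm
  expect_error(ligament_force(-1, all_c2c5), "nonnegative")
  # linear in elongation within a segment (slack = 0)
  expect_equal(ligament_force(20, all_c2c5), 2 * ligament_force(10, all_c2c5))
})

test_that("force is continuous and non-decreasing for every packaged profile", {
  specs <- ligament_specs()
  grid <- seq(0, 120, by = 0.1)
  for (lg in unique(specs$ligament)) {
    for (rg in unique(specs$region[specs$ligament == lg])) {
      prof <- specs[specs$ligament == lg & specs$region == rg, ]
      f <- ligament_force(grid, prof)
      expect_true(all(diff(f) >= 0), info = paste(lg, rg))
      # continuity at segment boundaries to 1e-9 N
      for (s in c(prof$strain_lo_pct, prof$strain_hi_pct)) {
        expect_lt(abs(ligament_force(s + 1e-9, prof) -
                        ligament_force(s - 1e-9, prof)), 1e-6)
      }
    }
  }
})

test_that("stiffness interpolates continuously across a multi-segment profile", {
  prof <- data.frame(ligament = "X", region = "R",
                     stiffness_N_per_mm = c(10, 20),
                     strain_lo_pct = c(5, 30), strain_hi_pct = c(15, 40),
                     slack_strain_pct = 0, reference_length_mm = 20)
  k <- cervdisc:::piecewise_stiffness(c(0, 10, 15, 22.5, 30, 50), prof)
  expect_equal(k, c(10, 10, 10, 15, 20, 20))
  f <- ligament_force(seq(0, 50, by = 0.01), prof)
  expect_lt(max(abs(diff(f))), 0.1)   # no jumps
})

test_that("per-ligament totals sum regions and respect slack", {
  specs <- ligament_specs()
  slack <- data.frame(ligament = specs$ligament, region = specs$region,
                      strain_pct = 0)
  tot0 <- total_ligament_force(slack, specs)
  expect_equal(tot0$force_N, c(0, 0, 0))
  expect_error(total_ligament_force(slack[-1, ], specs), "missing strain")
  # doubling all strains within the linear regime doubles each total
  s1 <- slack; s1$strain_pct <- 5
  s2 <- slack; s2$strain_pct <- 10
  expect_equal(2 * total_ligament_force(s1, specs)$force_N,
               total_ligament_force(s2, specs)$force_N, tolerance = 1e-12)
})

test_that("reported per-ligament totals are reproduced from calibrated strains", {
  specs <- ligament_specs()
  targets <- data.frame(ligament = c("ALL", "PLL", "LF"),
                        force_N = c(38.46, 59.95, 41.86))   # 1 g posture
  strains <- calibrate_ligament_strains(targets, specs)
  tot <- total_ligament_force(strains, specs)
  expect_equal(tot$force_N[match(targets$ligament, tot$ligament)],
               targets$force_N, tolerance = 1e-9)
})

test_that("microgravity ligament totals sit below the failure thresholds", {
  totals <- data.frame(ligament = c("ALL", "PLL", "LF"),
                       force_N = c(92.76, 183.26, 85.97))
  ann <- ligament_failure_check(totals)
  expect_identical(ann$below_threshold, c(TRUE, TRUE, TRUE))
  expect_equal(ann$threshold_N, c(494, 462.9, 315.8))
  expect_true(all(ann$margin_N > 0))
  expect_error(
    ligament_failure_check(data.frame(ligament = "ISL", force_N = 1)),
    "no failure threshold")
})
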