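# Independent one-line oracles for the swelling model, kept deliberately
# separate from the package's implementation path.

oracle_fcd <- function(c0F, phi0, r) c0F * phi0 / (phi0 + r^3 - 1)

oracle_phi <- function(phi0, r) (phi0 + r^3 - 1) / r^3

oracle_donnan_kpa <- function(cF, R = 8.3144, Tk = 310.15, cs = 150) {
  R * Tk * (sqrt(cF^2 + 4 * cs^2) - 2 * cs) / 1000
}

# area-weighted compartment pressure, written out longhand
oracle_stress_kpa <- function(r, c0F_np, phi0_np, phi0_af, f_np = 0.4,
                              af_ratio = 0.8, R = 8.3144, Tk = 310.15,
                              cs = 150) {
  f_np * oracle_donnan_kpa(oracle_fcd(c0F_np, phi0_np, r), R, Tk, cs) +
    (1 - f_np) * oracle_donnan_kpa(oracle_fcd(af_ratio * c0F_np, phi0_af, r),
                                   R, Tk, cs)
}

# brute-force equilibrium: argmin over a dense height-ratio grid of the
# force-balance residual |Fs(r) * A0 - F|
oracle_grid_solve <- function(F_N, ref, n_grid = 1e6, r_max = 3) {
  r_min <- (1 - ref$phi0_af)^(1 / 3) * (1 + 1e-6)
  grid <- seq(r_min, r_max, length.out = n_grid)
  force <- oracle_stress_kpa(grid, ref$c0F_np, ref$phi0_np, ref$phi0_af,
                             ref$np_area_fraction, ref$fcd_ratio_af_np) *
    ref$A0_mm2 / 1000
  list(r = grid[which.min(abs(force - F_N))],
       step = (r_max - r_min) / (n_grid - 1))
}

# single-row reference table with free parameters, for randomized tests
make_test_ref <- function(A0 = 400, h0 = 4, phi0_np = 0.80, phi0_af = 0.75,
                          c0F_np = 250, np_area_fraction = 0.4,
                          fcd_ratio_af_np = 0.8, level = "C2C3") {
  data.frame(level = level, A0_mm2 = A0, h0_mm = h0, phi0_np = phi0_np,
             phi0_af = phi0_af, np_area_fraction = np_area_fraction,
             fcd_ratio_af_np = fcd_ratio_af_np, c0F_np = c0F_np)
}
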