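#' Osmotic constants for the Donnan swelling model
#'
#' @param R universal gas constant, J K^-1 mol^-1.
#' @param T_kelvin absolute temperature, K (body temperature by default).
#' @param c_star external Na+/Cl- bath concentration around the disc,
#'   mol/m^3 (numerically equal to mM); physiological saline by default.
#' @return named list with class `"osmotic_constants"`.
#' @export
#' @examples
#' osmotic_constants()
osmotic_constants <- function(R = 8.3144, T_kelvin = 310.15, c_star = 150) {
  stopifnot(R > 0, T_kelvin > 0, c_star > 0)
  structure(list(R = R, T_kelvin = T_kelvin, c_star = c_star),
            class = "osmotic_constants")
}

#' @export
print.osmotic_constants <- function(x, ...) {
  cat(sprintf("Osmotic constants: R = %g J/(K mol), T = %g K, c* = %g mol/m^3\n",
              x$R, x$T_kelvin, x$c_star))
  invisible(x)
}

# lower admissible height ratio for a compartment: r^3 > 1 - phi0
r_lower_bound <- function(phi0) (1 - phi0)^(1 / 3)

check_r_domain <- function(r, phi0) {
  bad <- r^3 <= 1 - phi0
  if (any(bad)) {
    stop(sprintf(
      "height ratio out of domain: need r^3 > 1 - phi0 = %.6g (r > %.6g), got r = %.6g",
      1 - phi0, r_lower_bound(phi0), min(r[bad])), call. = FALSE)
  }
  invisible(TRUE)
}

#' Deformation-dependent fixed charge density
#'
#' The fixed charges (glycosaminoglycans) are bound to the solid matrix, so
#' their total amount is conserved while the tissue water volume changes with
#' deformation. With an isotropic volume ratio `r^3` (r = h/h0), the FCD
#' dilutes as `cF = c0F * phi0 / (phi0 + r^3 - 1)`: swelling (r > 1) dilutes
#' the charge, compression concentrates it.
#'
#' @param c0F reference fixed charge density, mol/m^3.
#' @param phi0 reference water fraction, in (0,1).
#' @param r height ratio h/h0; must satisfy `r^3 > 1 - phi0` so the deformed
#'   water volume stays positive.
#' @return current fixed charge density, mol/m^3; strictly decreasing in `r`.
#' @export
#' @examples
#' fixed_charge_density(250, 0.77, 1)        # reference state: 250
#' fixed_charge_density(250, 0.77, 1.1^(1/3))  # diluted by 10% volume gain
fixed_charge_density <- function(c0F, phi0, r) {
  stopifnot(c0F >= 0, phi0 > 0, phi0 < 1)
  check_r_domain(r, phi0)
  c0F * phi0 / (phi0 + r^3 - 1)
}

#' Ideal Donnan swelling pressure
#'
#' Osmotic pressure difference between the charged tissue and the external
#' bath under ideal Donnan equilibrium with a 1:1 salt:
#' `Fs = R T (sqrt(cF^2 + 4 c*^2) - 2 c*)`. It vanishes when the fixed charge
#' density is zero and grows monotonically with it, approaching `R T cF` for
#' `cF >> c*`.
#'
#' @param cF fixed charge density, mol/m^3 (nonnegative).
#' @param constants an [osmotic_constants()] object.
#' @return swelling pressure in kPa.
#' @export
#' @examples
#' donnan_pressure(0)     # 0
#' donnan_pressure(150)   # approx 91.3 kPa at body temperature
donnan_pressure <- function(cF, constants = osmotic_constants()) {
  stopifnot(inherits(constants, "osmotic_constants"))
  if (any(cF < 0)) {
    stop("donnan_pressure(): cF must be nonnegative", call. = FALSE)
  }
  cs <- constants$c_star
  # Pa -> kPa at the interface boundary
  constants$R * constants$T_kelvin * (sqrt(cF^2 + 4 * cs^2) - 2 * cs) / 1000
}

#' Water fraction of the deformed disc
#'
#' With solid matrix volume conserved and total volume scaled by `r^3`, the
#' deformed water fraction is `phi = (phi0 + r^3 - 1) / r^3`. It equals `phi0`
#' at the reference height and tends to 1 as the disc swells without bound.
#'
#' @inheritParams fixed_charge_density
#' @return water fraction in (0,1); strictly increasing in `r`.
#' @export
#' @examples
#' deformed_water_content(0.77, 1)     # 0.77
#' deformed_water_content(0.77, 1.05)  # about 0.8013
deformed_water_content <- function(phi0, r) {
  stopifnot(phi0 > 0, phi0 < 1)
  check_r_domain(r, phi0)
  (phi0 + r^3 - 1) / r^3
}

#' Height ratio implied by an observed water fraction
#'
#' Inverse of [deformed_water_content()]: `r = ((1 - phi0)/(1 - phi))^(1/3)`.
#'
#' @param phi observed water fraction, in (0,1).
#' @param phi0 reference water fraction, in (0,1).
#' @return height ratio r.
#' @export
height_ratio_from_phi <- function(phi, phi0) {
  stopifnot(phi > 0, phi < 1, phi0 > 0, phi0 < 1)
  ((1 - phi0) / (1 - phi))^(1 / 3)
}

#' NP/AF water-content partition
#'
#' Applies the water-content update compartment-wise and mixes by NP area
#' fraction: `phi = f_np * phi_NP + (1 - f_np) * phi_AF`. Because the update
#' is affine in `phi0` at fixed `r`, the mixture equals the update applied to
#' the mixed reference fraction — an identity the test-suite asserts.
#'
#' @param r height ratio h/h0 (shared by both compartments: single rigid
#'   endplate assumption).
#' @param ref one row of a [disc_reference()] table (or a list with fields
#'   `phi0_np`, `phi0_af`, `np_area_fraction`).
#' @return named list with `phi_np`, `phi_af`, `phi_combined`.
#' @export
#' @examples
#' partition_water_content(1, disc_reference()[1, ])  # (0.80, 0.75, 0.77)
partition_water_content <- function(r, ref) {
  f <- ref$np_area_fraction
  phi_np <- deformed_water_content(ref$phi0_np, r)
  phi_af <- deformed_water_content(ref$phi0_af, r)
  list(phi_np = phi_np, phi_af = phi_af,
       phi_combined = f * phi_np + (1 - f) * phi_af)
}

#' Area-weighted disc swelling pressure
#'
#' Composes FCD dilution and Donnan pressure per compartment and weights by
#' cross-sectional area: the NP contributes `np_area_fraction` of the disc
#' face with reference FCD `c0F_np`, the AF the remainder with reference FCD
#' `fcd_ratio_af_np * c0F_np`.
#'
#' @inheritParams partition_water_content
#' @param constants an [osmotic_constants()] object.
#' @return swelling pressure in kPa; strictly decreasing in `r`.
#' @export
disc_swelling_stress <- function(r, ref, constants = osmotic_constants()) {
  f <- ref$np_area_fraction
  cF_np <- fixed_charge_density(ref$c0F_np, ref$phi0_np, r)
  cF_af <- fixed_charge_density(ref$fcd_ratio_af_np * ref$c0F_np,
                                ref$phi0_af, r)
  f * donnan_pressure(cF_np, constants) +
    (1 - f) * donnan_pressure(cF_af, constants)
}

# Vectorised bisection for the load-height equilibrium. F_N may be a vector;
# returns the height ratio r at which stress(r) * area = F for each element.
solve_r_vec <- function(F_N, ref, constants = osmotic_constants(),
                        tol = 1e-10, max_iter = 200L, area_mode = "reference") {
  area_mode <- match.arg(area_mode, c("reference", "deformed"))
  A0 <- ref$A0_mm2
  stress_force <- function(r) {
    A <- if (area_mode == "deformed") A0 * r^2 else A0
    # kPa * mm^2 = 1e-3 N
    disc_swelling_stress(r, ref, constants) * A / 1000
  }
  r_min <- r_lower_bound(ref$phi0_af) * (1 + 1e-9) + 1e-12
  f_max <- stress_force(r_min)
  out <- rep(NA_real_, length(F_N))
  iters <- integer(length(F_N))
  if (any(F_N < 0)) stop("applied force must be nonnegative", call. = FALSE)
  if (any(F_N >= f_max)) {
    stop(sprintf(
      "applied force outside attainable range [0, %.6g) N for this disc",
      f_max), call. = FALSE)
  }
  zero <- F_N == 0
  out[zero] <- Inf   # free swelling: pressure only vanishes asymptotically
  todo <- which(!zero)
  if (length(todo)) {
    Fv <- F_N[todo]
    lo <- rep(r_min, length(Fv))
    hi <- rep(1, length(Fv))
    # expand upper bracket until the residual changes sign
    for (k in 1:60) {
      need <- stress_force(hi) > Fv
      if (!any(need)) break
      hi[need] <- hi[need] * 2
    }
    it <- 0L
    repeat {
      it <- it + 1L
      mid <- (lo + hi) / 2
      high <- stress_force(mid) > Fv   # stress too high -> r must grow
      lo[high] <- mid[high]
      hi[!high] <- mid[!high]
      if (all(hi - lo <= tol * pmax(lo, 1)) || it >= max_iter) break
    }
    out[todo] <- (lo + hi) / 2
    iters[todo] <- it
  }
  attr(out, "iterations") <- iters
  out
}

#' Solve the axial load-height equilibrium of a disc
#'
#' Finds the height ratio `r` at which the disc's Donnan swelling pressure,
#' acting over the disc face, balances the applied axial force:
#' `Fs(r) * A = F`. Because `Fs` is strictly decreasing in `r` the root is
#' unique; it is bracketed and found by bisection. Unloading (smaller `F`)
#' yields a larger `r` — the disc swells. `F = 0` has no finite root (the
#' pressure only vanishes asymptotically); the solver reports `r = Inf` with
#' zero residual in that case.
#'
#' @param F_applied axial compressive force, N (nonnegative scalar).
#' @param ref one row of a [disc_reference()] table.
#' @param constants an [osmotic_constants()] object.
#' @param tol relative tolerance on `r` (default 1e-10).
#' @param max_iter maximum bisection iterations.
#' @param area_mode `"reference"` (default) balances the load over the
#'   reference area `A0`; `"deformed"` scales the face area by `r^2`.
#' @return object of class `"equilibrium_solution"`: list with `r`, `Fs_kPa`,
#'   `residual_N`, `iterations`, and the derived `h_mm`, `phi_np`, `phi_af`,
#'   `phi_combined`.
#' @export
#' @examples
#' ref <- disc_reference()[1, ]   # C2C3
#' solve_equilibrium(91.83, ref)  # loaded at 1 g
#' solve_equilibrium(21.5, ref)   # unloaded: larger r, wetter disc
solve_equilibrium <- function(F_applied, ref, constants = osmotic_constants(),
                              tol = 1e-10, max_iter = 200L,
                              area_mode = "reference") {
  stopifnot(length(F_applied) == 1, is.finite(F_applied))
  r <- solve_r_vec(F_applied, ref, constants, tol, max_iter, area_mode)
  iters <- attr(r, "iterations")
  r <- as.numeric(r)
  if (is.infinite(r)) {
    sol <- list(r = Inf, Fs_kPa = 0, residual_N = 0, iterations = 0L,
                h_mm = Inf, phi_np = 1, phi_af = 1, phi_combined = 1,
                level = as.character(ref$level %||% NA))
    class(sol) <- "equilibrium_solution"
    return(sol)
  }
  Fs <- disc_swelling_stress(r, ref, constants)
  A <- if (area_mode == "deformed") ref$A0_mm2 * r^2 else ref$A0_mm2
  phi <- partition_water_content(r, ref)
  sol <- list(r = r, Fs_kPa = Fs,
              residual_N = abs(Fs * A / 1000 - F_applied),
              iterations = iters,
              h_mm = r * ref$h0_mm,
              phi_np = phi$phi_np, phi_af = phi$phi_af,
              phi_combined = phi$phi_combined,
              level = as.character(ref$level %||% NA))
  class(sol) <- "equilibrium_solution"
  sol
}

#' @export
print.equilibrium_solution <- function(x, ...) {
  cat(sprintf(
    "Disc swelling equilibrium%s\n  r = h/h0 : %.6f\n  height   : %.4f mm\n  Fs       : %.4f kPa\n  phi NP/AF: %.4f / %.4f (combined %.4f)\n  residual : %.3g N in %d iterations\n",
    if (!is.na(x$level)) paste0(" (", x$level, ")") else "",
    x$r, x$h_mm, x$Fs_kPa, x$phi_np, x$phi_af, x$phi_combined,
    x$residual_N, x$iterations))
  invisible(x)
}

#' Swelling equilibrium for a full load table
#'
#' Runs [solve_equilibrium()] for each level of a load table against the
#' matching rows of a reference table.
#'
#' @param loads data.frame with columns `level` and `compression_N`.
#' @param ref a [disc_reference()] table.
#' @param constants,tol,max_iter,area_mode passed to [solve_equilibrium()].
#' @return data.frame with one row per level: `level`, `r`, `h_mm`, `Fs_kPa`,
#'   `phi_np`, `phi_af`, `phi_combined`, `residual_N`.
#' @export
solve_equilibrium_table <- function(loads, ref,
                                    constants = osmotic_constants(),
                                    tol = 1e-10, max_iter = 200L,
                                    area_mode = "reference") {
  loads$level <- as_disc_level(loads$level)
  rows <- lapply(seq_len(nrow(loads)), function(i) {
    rr <- ref[as.character(ref$level) == as.character(loads$level[i]), ]
    if (nrow(rr) != 1) {
      stop("no reference row for level ", loads$level[i], call. = FALSE)
    }
    s <- solve_equilibrium(loads$compression_N[i], rr, constants, tol,
                           max_iter, area_mode)
    data.frame(level = as.character(loads$level[i]), r = s$r, h_mm = s$h_mm,
               Fs_kPa = s$Fs_kPa, phi_np = s$phi_np, phi_af = s$phi_af,
               phi_combined = s$phi_combined, residual_N = s$residual_N)
  })
  out <- do.call(rbind, rows)
  out$level <- as_disc_level(out$level)
  out
}
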