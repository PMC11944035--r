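#' Configuration for the synthetic-data generators
#'
#' @param seed integer seed fixing every random draw the generators make.
#' @param n_subjects number of synthetic subjects.
#' @param cv_geometry coefficient of variation of the lognormal perturbations
#'   applied to disc geometry (A0, h0).
#' @param noise_sd_phi standard deviation of Gaussian water-fraction
#'   observation noise.
#' @param load_range length-2 numeric, min/max of random axial loads in N.
#' @return object of class `"generator_config"`.
#' @export
generator_config <- function(seed = 1L, n_subjects = 10L, cv_geometry = 0.05,
                             noise_sd_phi = 0.005, load_range = c(10, 200)) {
  stopifnot(is.numeric(seed), length(seed) == 1,
            n_subjects >= 1, cv_geometry >= 0, noise_sd_phi >= 0,
            length(load_range) == 2, load_range[1] > 0,
            load_range[2] >= load_range[1])
  structure(list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
                 cv_geometry = cv_geometry, noise_sd_phi = noise_sd_phi,
                 load_range = load_range),
            class = "generator_config")
}

#' Simulate a population of disc parameter sets
#'
#' Perturbs the reference disc geometry (A0, h0) of each level with
#' independent lognormal factors of unit mean and the configured coefficient
#' of variation. Lognormal (not Gaussian) perturbation keeps geometric
#' quantities strictly positive, so every generated set satisfies the
#' reference-table invariants by construction.
#'
#' @param config a [generator_config()].
#' @param ref baseline [disc_reference()] table.
#' @return list of `n_subjects` reference tables; fully determined by
#'   `config$seed`.
#' @export
#' @examples
#' pop <- make_disc_population(generator_config(seed = 1, n_subjects = 3))
#' length(pop)
make_disc_population <- function(config, ref = disc_reference()) {
  stopifnot(inherits(config, "generator_config"))
  cv <- config$cv_geometry
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- -sdlog^2 / 2          # unit-mean multipliers
  with_seed(config$seed, {
    lapply(seq_len(config$n_subjects), function(i) {
      subj <- ref
      n <- nrow(ref)
      if (cv > 0) {
        subj$A0_mm2 <- ref$A0_mm2 * stats::rlnorm(n, meanlog, sdlog)
        subj$h0_mm <- ref$h0_mm * stats::rlnorm(n, meanlog, sdlog)
      }
      validate_disc_reference(subj)
      subj
    })
  })
}

#' Simulate random admissible postures
#'
#' Draws posture scenarios with a random gravity factor (0 or 1 with equal
#' probability) and joint angles uniform within anatomically plausible
#' sagittal ranges.
#'
#' @param config a [generator_config()].
#' @param n number of postures (default `config$n_subjects`).
#' @return list of [posture_scenario()] objects.
#' @export
make_random_postures <- function(config, n = config$n_subjects) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed + 1L, {
    lapply(seq_len(n), function(i) {
      posture_scenario(
        name = sprintf("synthetic_%03d", i),
        gravity_factor = stats::rbinom(1, 1, 0.5),
        joint_angles = list(
          neck_flexion = stats::runif(1, 0, 30),
          shoulder_flexion = stats::runif(1, 0, 40),
          elbow_flexion = stats::runif(1, 0, 80),
          hip_flexion = stats::runif(1, -10, 60),
          knee_flexion = stats::runif(1, 0, 60)))
    })
  })
}

#' Simulate noisy water-content observations
#'
#' Generates NP/AF water-fraction observations at a known height ratio under
#' the deformation model, with additive Gaussian noise. Draws outside (0,1)
#' are resampled rather than clipped, so the observation distribution carries
#' no boundary point mass.
#'
#' @param ref one row of a [disc_reference()] table.
#' @param r_true true height ratio.
#' @param noise_sd Gaussian noise standard deviation (on the fraction scale).
#' @param seed integer seed.
#' @param n number of observation pairs.
#' @return data.frame with columns `phi_np`, `phi_af`.
#' @export
simulate_observed_phi <- function(ref, r_true, noise_sd, seed, n = 1L) {
  phi <- partition_water_content(r_true, ref)
  with_seed(seed, {
    draw <- function(mu) {
      x <- mu + stats::rnorm(n, 0, noise_sd)
      while (any(bad <- x <= 0 | x >= 1)) {
        x[bad] <- mu + stats::rnorm(sum(bad), 0, noise_sd)
      }
      x
    }
    if (noise_sd == 0) {
      data.frame(phi_np = rep(phi$phi_np, n), phi_af = rep(phi$phi_af, n))
    } else {
      data.frame(phi_np = draw(phi$phi_np), phi_af = draw(phi$phi_af))
    }
  })
}

#' Recover the NP reference fixed charge density from observations
#'
#' Calibrates `c0F_np` against paired (axial load, observed water fraction)
#' data: for a candidate `c0F_np` the equilibrium height ratio is solved for
#' every load, the implied NP and AF water fractions are computed, and the
#' sum of squared deviations from the observations is minimised by a
#' bracketed scalar search. With a single exact pair this is one equation in
#' one unknown and recovery is exact to the search tolerance.
#'
#' @param observed data.frame with columns `load_N` and `phi_np` (optionally
#'   `phi_af`, which then enters the fit too).
#' @param ref one row of a [disc_reference()] table (its `c0F_np` is ignored).
#' @param constants an [osmotic_constants()] object.
#' @param interval search interval for `c0F_np`, mol/m^3.
#' @param tol solver and search tolerance.
#' @return list with `c0F_np` (estimate), `sse`, and `n_obs`.
#' @export
#' @examples
#' ref <- disc_reference()[1, ]
#' r <- solve_equilibrium(50, ref)$r
#' obs <- data.frame(load_N = 50, phi_np = deformed_water_content(ref$phi0_np, r))
#' recover_c0F(obs, ref)$c0F_np   # about 250
recover_c0F <- function(observed, ref, constants = osmotic_constants(),
                        interval = c(20, 2000), tol = 1e-9) {
  if (!nrow(observed)) {
    stop("recover_c0F(): need at least one (load, phi) observation",
         call. = FALSE)
  }
  if (all(observed$load_N == 0)) {
    stop("recover_c0F(): all loads are zero; c0F is not identifiable from ",
         "free-swelling observations", call. = FALSE)
  }
  use_af <- "phi_af" %in% names(observed)
  sse <- function(c0F) {
    cand <- ref
    cand$c0F_np <- c0F
    r <- solve_r_vec(observed$load_N, cand, constants, tol = 1e-12)
    pred_np <- deformed_water_content(ref$phi0_np, r)
    out <- sum((pred_np - observed$phi_np)^2)
    if (use_af) {
      pred_af <- deformed_water_content(ref$phi0_af, r)
      out <- out + sum((pred_af - observed$phi_af)^2)
    }
    out
  }
  fit <- stats::optimize(sse, interval, tol = tol)
  list(c0F_np = fit$minimum, sse = fit$objective, n_obs = nrow(observed))
}

#' Write synthetic pipeline inputs to disk
#'
#' Emits, for each synthetic subject, a disc reference CSV and a random-load
#' CSV in the same dialect the pipeline reads.
#'
#' @param config a [generator_config()].
#' @param dir output directory (created if absent).
#' @return character vector of written file paths, invisibly.
#' @export
write_synthetic_inputs <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pop <- make_disc_population(config)
  loads <- with_seed(config$seed + 2L, {
    lapply(seq_along(pop), function(i) {
      data.frame(level = disc_levels(),
                 compression_N = stats::runif(length(disc_levels()),
                                              config$load_range[1],
                                              config$load_range[2]),
                 shear_N = 0)
    })
  })
  paths <- character(0)
  for (i in seq_along(pop)) {
    p1 <- file.path(dir, sprintf("disc_reference_subject%03d.csv", i))
    write_disc_reference(pop[[i]], p1)
    p2 <- file.path(dir, sprintf("disc_loads_subject%03d.csv", i))
    utils::write.csv(loads[[i]], p2, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p1, p2)
  }
  invisible(paths)
}
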