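#' Posture scenario definition
#'
#' A named posture: a gravity factor (1 for Earth gravity, 0 for
#' microgravity; intermediate values admitted) plus a set of named joint
#' angles in degrees and an optional per-level sagittal tilt of the cervical
#' discs. Unspecified joint angles default to 0.
#'
#' @param name scenario name.
#' @param gravity_factor nonnegative multiplier on standard gravity.
#' @param joint_angles named list/vector of joint angles, degrees.
#' @param cervical_tilt_per_level optional named vector (levels as names) of
#'   sagittal tilt angles in degrees, positive = anterior (forward) tilt of
#'   the disc plane normal.
#' @return object of class `"posture_scenario"`.
#' @export
posture_scenario <- function(name, gravity_factor, joint_angles = list(),
                             cervical_tilt_per_level = NULL) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.numeric(gravity_factor) || gravity_factor < 0) {
    stop("gravity_factor must be a nonnegative number", call. = FALSE)
  }
  angles <- as.list(joint_angles)
  if (length(angles) && (is.null(names(angles)) || any(!nzchar(names(angles))))) {
    stop("joint_angles must be named", call. = FALSE)
  }
  if (any(!vapply(angles, function(a) is.numeric(a) && is.finite(a), logical(1)))) {
    stop("joint_angles must be finite numbers", call. = FALSE)
  }
  if (!is.null(cervical_tilt_per_level)) {
    bad <- setdiff(names(cervical_tilt_per_level), disc_levels())
    if (length(bad)) {
      stop("unknown level(s) in cervical_tilt_per_level: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(name = name, gravity_factor = gravity_factor,
                 joint_angles = angles,
                 cervical_tilt_per_level = cervical_tilt_per_level),
            class = "posture_scenario")
}

#' @export
print.posture_scenario <- function(x, ...) {
  cat(sprintf("Posture scenario '%s' (gravity factor %g)\n", x$name,
              x$gravity_factor))
  if (length(x$joint_angles)) {
    ang <- unlist(x$joint_angles)
    cat("  joint angles (deg):",
        paste(sprintf("%s=%g", names(ang), ang), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a posture scenario from YAML
#'
#' @param source a YAML file path, or one of the packaged scenario names
#'   `"nbp1g"`, `"sm0g"`, `"nbp0g"`.
#' @return a [posture_scenario()].
#' @export
#' @examples
#' read_scenario("nbp0g")
read_scenario <- function(source) {
  if (source %in% c("nbp1g", "sm0g", "nbp0g")) {
    source <- cd_extdata("scenarios", paste0(source, ".yaml"))
  }
  if (!file.exists(source)) {
    stop("scenario file not found: ", source, call. = FALSE)
  }
  y <- yaml::read_yaml(source)
  for (field in c("name", "gravity_factor")) {
    if (is.null(y[[field]])) {
      stop("scenario YAML missing field '", field, "': ", source, call. = FALSE)
    }
  }
  tilt <- y$cervical_tilt_per_level
  posture_scenario(y$name, y$gravity_factor, y$joint_angles %||% list(),
                   if (!is.null(tilt)) unlist(tilt))
}

#' Head and neck anthropometry
#'
#' Segment masses and lever geometry used by the quasi-static load estimator.
#' Defaults follow standard adult-male anthropometry scaled to a 72 kg
#' subject: the head is 6.94% of body mass and each cervical motion segment
#' adds roughly 0.23 kg of vertebra plus soft tissue. The lever arm from each
#' disc to the head centre of mass grows cranio-caudally, and the posterior
#' extensor musculature acts at a fixed moment arm behind the disc centres.
#'
#' @param total_mass body mass, kg.
#' @param head_mass_fraction head mass as a fraction of body mass.
#' @param cervical_segment_mass_kg per-level segment masses (named by level).
#' @param com_lever_mm per-level horizontal lever from disc to head centre of
#'   mass at 1 unit of sagittal sine, mm.
#' @param extensor_moment_arm_mm moment arm of the lumped extensor, mm.
#' @return object of class `"anthropometry"`.
#' @export
anthropometry <- function(total_mass = 72,
                          head_mass_fraction = 0.0694,
                          cervical_segment_mass_kg = stats::setNames(
                            rep(0.23, 6), disc_levels()),
                          com_lever_mm = stats::setNames(
                            seq(60, 140, length.out = 6), disc_levels()),
                          extensor_moment_arm_mm = 35) {
  stopifnot(total_mass > 0, head_mass_fraction > 0, head_mass_fraction < 1,
            all(cervical_segment_mass_kg >= 0), extensor_moment_arm_mm > 0)
  structure(list(total_mass = total_mass,
                 head_mass_fraction = head_mass_fraction,
                 cervical_segment_mass_kg = cervical_segment_mass_kg,
                 com_lever_mm = com_lever_mm,
                 extensor_moment_arm_mm = extensor_moment_arm_mm),
            class = "anthropometry")
}

#' Weight supported above a cervical disc
#'
#' Gravitational load carried by a disc: the head mass plus the cumulative
#' cervical segment mass cranial to the level, times standard gravity and the
#' scenario's gravity factor. Strictly increasing cranio-caudally whenever
#' gravity acts.
#'
#' @param level a disc level (see [disc_levels()]).
#' @param anthro an [anthropometry()] object.
#' @param gravity_factor multiplier on standard gravity (9.81 m/s^2).
#' @return supported weight in N.
#' @export
#' @examples
#' supported_weight("C2C3", anthropometry(), 1)
supported_weight <- function(level, anthro = anthropometry(),
                             gravity_factor = 1) {
  level <- as.character(as_disc_level(level))
  g0 <- 9.81
  idx <- match(level, disc_levels())
  head_mass <- anthro$total_mass * anthro$head_mass_fraction
  seg <- anthro$cervical_segment_mass_kg[disc_levels()]
  supported <- head_mass + vapply(idx, function(i) sum(seg[seq_len(i)]),
                                  numeric(1))
  unname(gravity_factor * g0 * supported)
}

# Default sagittal disc tilts (degrees, anterior positive) for a neutral
# lordotic cervical spine; a single linear distribution stands in for
# per-vertebra kinematics.
default_cervical_tilt <- function() {
  stats::setNames(seq(6, 10, length.out = 6), disc_levels())
}

#' Quasi-static disc loads for a posture
#'
#' A transparent stand-in for full inverse-dynamics: per level, the supported
#' weight is resolved into the disc's local frame through the level's sagittal
#' tilt (plus any whole-neck flexion in the scenario), an equivalent lumped
#' extensor balancing the gravitational flexion moment adds compression, and
#' a constant co-contraction offset keeps compression nonzero in
#' weightlessness, where residual muscle and ligament tension — not gravity —
#' loads the disc.
#'
#' Sign convention for shear: positive points posterior to the coronal plane,
#' so gravity acting over an anteriorly tilted disc produces negative
#' (anterior) shear.
#'
#' @param scenario a [posture_scenario()].
#' @param anthro an [anthropometry()] object.
#' @param muscle_cocontraction constant compression offset, N (default 30).
#' @param include_extensor include the lumped-extensor moment-balance term
#'   (default TRUE; disable to obtain a pure weight resolution).
#' @return data.frame with columns `level`, `scenario`, `compression_N`,
#'   `shear_N`.
#' @export
#' @examples
#' disc_loads(read_scenario("nbp1g"))
disc_loads <- function(scenario, anthro = anthropometry(),
                       muscle_cocontraction = 30, include_extensor = TRUE) {
  stopifnot(inherits(scenario, "posture_scenario"))
  lv <- disc_levels()
  tilt <- default_cervical_tilt()
  if (!is.null(scenario$cervical_tilt_per_level)) {
    tilt[names(scenario$cervical_tilt_per_level)] <-
      scenario$cervical_tilt_per_level
  }
  flex <- scenario$joint_angles$neck_flexion %||% 0
  theta <- (tilt[lv] + flex) * pi / 180
  W <- supported_weight(lv, anthro, scenario$gravity_factor)
  compression <- W * cos(theta)
  shear <- -W * sin(theta)          # anterior shear is negative
  if (include_extensor) {
    moment_Nmm <- W * anthro$com_lever_mm[lv] * sin(theta)
    compression <- compression + pmax(0, moment_Nmm) / anthro$extensor_moment_arm_mm
  }
  compression <- compression + muscle_cocontraction
  data.frame(level = as_disc_level(lv), scenario = scenario$name,
             compression_N = unname(compression), shear_N = unname(shear),
             row.names = NULL)
}
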