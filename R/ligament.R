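#' Piecewise-linear cervical ligament specifications
#'
#' Loads the stiffness table for the anterior longitudinal ligament (ALL),
#' posterior longitudinal ligament (PLL) and ligamentum flavum (LF). Each
#' ligament carries one segment per cervical region (C2-C5 and C5-T1) with a
#' stiffness (N/mm) valid over a strain range (% elongation). Strain is
#' converted to elongation through a `reference_length_mm` (cadaveric data
#' report strain only, so the resting length is a modelling choice, 20 mm by
#' default), and force is zero below `slack_strain_pct` (default 0: no
#' toe-region data are available).
#'
#' The packaged LF C5-T1 strain range is stored in ascending order (75.3 to
#' 101.5); see `specs` metadata attribute.
#'
#' @param source CSV path or `NULL` for the packaged table. Columns:
#'   `ligament,region,stiffness_N_per_mm,strain_lo_pct,strain_hi_pct,
#'   slack_strain_pct,reference_length_mm`.
#' @return data.frame of ligament segments, attribute `"notes"` carrying
#'   fixture caveats.
#' @export
#' @examples
#' ligament_specs()
ligament_specs <- function(source = NULL) {
  path <- source %||% cd_extdata("ligaments.csv")
  specs <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("ligament", "region", "stiffness_N_per_mm", "strain_lo_pct",
            "strain_hi_pct", "slack_strain_pct", "reference_length_mm")
  miss <- setdiff(need, names(specs))
  if (length(miss)) {
    stop("ligament table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(specs$stiffness_N_per_mm <= 0)) {
    stop("ligament table: stiffness must be > 0", call. = FALSE)
  }
  if (any(specs$strain_lo_pct >= specs$strain_hi_pct)) {
    stop("ligament table: strain_lo_pct must be < strain_hi_pct", call. = FALSE)
  }
  if (any(specs$reference_length_mm <= 0)) {
    stop("ligament table: reference_length_mm must be > 0", call. = FALSE)
  }
  attr(specs, "notes") <- paste(
    "LF C5T1 strain range normalised to ascending order (75.3-101.5);",
    "reference_length_mm and slack_strain_pct are modelling defaults,",
    "not measured values.")
  specs
}

# Strain-dependent stiffness for the ordered segments of one ligament-region
# profile: constant below the first segment and above the last, the segment's
# own stiffness inside it, linear interpolation of stiffness between segments.
piecewise_stiffness <- function(strain, profile) {
  profile <- profile[order(profile$strain_lo_pct), ]
  k <- numeric(length(strain))
  for (i in seq_along(strain)) {
    s <- strain[i]
    seg <- which(s >= profile$strain_lo_pct & s <= profile$strain_hi_pct)
    if (length(seg)) {
      k[i] <- profile$stiffness_N_per_mm[seg[1]]
    } else if (s < profile$strain_lo_pct[1]) {
      k[i] <- profile$stiffness_N_per_mm[1]
    } else if (s > profile$strain_hi_pct[nrow(profile)]) {
      k[i] <- profile$stiffness_N_per_mm[nrow(profile)]
    } else {
      # in a gap between two segments: interpolate stiffness in strain
      below <- max(which(profile$strain_hi_pct < s))
      above <- below + 1L
      s0 <- profile$strain_hi_pct[below]
      s1 <- profile$strain_lo_pct[above]
      w <- (s - s0) / (s1 - s0)
      k[i] <- (1 - w) * profile$stiffness_N_per_mm[below] +
        w * profile$stiffness_N_per_mm[above]
    }
  }
  k
}

#' Ligament force at a given strain
#'
#' Piecewise-linear spring: elongation is
#' `(strain - slack_strain)/100 * reference_length`, clamped at zero, and
#' force is the strain-dependent stiffness times elongation. With the
#' packaged one-segment-per-region profiles this reduces to a linear spring
#' per region; the interpolation rules keep force continuous for
#' multi-segment profiles.
#'
#' @param strain strain in percent (nonnegative; vectorised).
#' @param spec one or more rows of a [ligament_specs()] table describing a
#'   single ligament-region profile.
#' @return force in N.
#' @export
#' @examples
#' specs <- ligament_specs()
#' all_c2c5 <- specs[specs$ligament == "ALL" & specs$region == "C2C5", ]
#' ligament_force(30, all_c2c5)   # 16 N/mm x 6 mm = 96 N
ligament_force <- function(strain, spec) {
  if (any(strain < 0)) {
    stop("ligament_force(): strain must be nonnegative", call. = FALSE)
  }
  slack <- spec$slack_strain_pct[1]
  L0 <- spec$reference_length_mm[1]
  delta <- pmax(0, (strain - slack) / 100 * L0)
  piecewise_stiffness(strain, spec) * delta
}

#' Total force per ligament across cervical regions
#'
#' Sums regional ligament forces per ligament type, yielding per-ligament
#' totals comparable across posture scenarios.
#'
#' @param strains data.frame with columns `ligament`, `region`, `strain_pct`;
#'   every (ligament, region) pair of `specs` must be present.
#' @param specs a [ligament_specs()] table.
#' @return data.frame with columns `ligament`, `force_N` (one row per
#'   ligament, in the table's ligament order).
#' @export
total_ligament_force <- function(strains, specs = ligament_specs()) {
  need <- unique(specs[, c("ligament", "region")])
  key <- function(d) paste(d$ligament, d$region)
  miss <- setdiff(key(need), key(strains))
  if (length(miss)) {
    stop("total_ligament_force(): missing strain for ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ligaments <- unique(specs$ligament)
  force <- vapply(ligaments, function(lg) {
    regions <- unique(specs$region[specs$ligament == lg])
    sum(vapply(regions, function(rg) {
      prof <- specs[specs$ligament == lg & specs$region == rg, ]
      eps <- strains$strain_pct[strains$ligament == lg & strains$region == rg][1]
      ligament_force(eps, prof)
    }, numeric(1)))
  }, numeric(1))
  data.frame(ligament = ligaments, force_N = unname(force))
}

#' Back-calculate regional strains from per-ligament force totals
#'
#' Utility for treating reported per-ligament totals as a calibration target:
#' splits each ligament's total equally between its regions and inverts the
#' (linear, packaged) force law per region. Round-trips through
#' [total_ligament_force()].
#'
#' @param totals data.frame with columns `ligament`, `force_N`.
#' @param specs a [ligament_specs()] table.
#' @return strains data.frame (`ligament`, `region`, `strain_pct`).
#' @export
calibrate_ligament_strains <- function(totals, specs = ligament_specs()) {
  rows <- lapply(seq_len(nrow(specs)), function(i) {
    sp <- specs[i, ]
    tot <- totals$force_N[totals$ligament == sp$ligament]
    if (!length(tot)) {
      stop("no total for ligament ", sp$ligament, call. = FALSE)
    }
    n_regions <- sum(specs$ligament == sp$ligament)
    share <- tot / n_regions
    eps <- sp$slack_strain_pct +
      100 * share / (sp$stiffness_N_per_mm * sp$reference_length_mm)
    data.frame(ligament = sp$ligament, region = sp$region, strain_pct = eps)
  })
  do.call(rbind, rows)
}

#' Cervical ligament failure thresholds
#'
#' Quasi-static failure loads reported in cadaveric testing of the cervical
#' ALL, PLL and LF, used to annotate whether modelled ligament forces approach
#' rupture.
#'
#' @return named numeric vector of thresholds in N.
#' @export
ligament_failure_thresholds <- function() {
  c(ALL = 494, PLL = 462.9, LF = 315.8)
}

#' Annotate ligament totals with failure margins
#'
#' @param totals data.frame with columns `ligament`, `force_N`.
#' @param thresholds named thresholds in N, per ligament.
#' @return `totals` with added `threshold_N`, `below_threshold` (logical) and
#'   `margin_N` (threshold minus force) columns.
#' @export
#' @examples
#' ligament_failure_check(
#'   data.frame(ligament = c("ALL", "PLL", "LF"),
#'              force_N = c(92.76, 183.26, 85.97)))
ligament_failure_check <- function(totals,
                                   thresholds = ligament_failure_thresholds()) {
  unknown <- setdiff(totals$ligament, names(thresholds))
  if (length(unknown)) {
    stop("no failure threshold for ligament(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  totals$threshold_N <- unname(thresholds[totals$ligament])
  totals$below_threshold <- totals$force_N < totals$threshold_N
  totals$margin_N <- totals$threshold_N - totals$force_N
  totals
}
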