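#' Cervical disc levels
#'
#' The six intervertebral discs of the lower cervical spine, ordered
#' cranio-caudally. All per-level tables in the package use this ordering.
#'
#' @return character vector `c("C2C3", ..., "C7T1")`.
#' @export
disc_levels <- function() {
  c("C2C3", "C3C4", "C4C5", "C5C6", "C6C7", "C7T1")
}

# Coerce a level column to the canonical ordered factor, erroring on unknowns.
as_disc_level <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), disc_levels())
  if (length(bad)) {
    stop("unknown disc level(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  factor(x, levels = disc_levels(), ordered = TRUE)
}

#' Disc volume from height and cross-sectional area
#'
#' The disc is treated as a lumped cylinder-like element, so its volume is
#' height times cross-sectional area. This is the relation that links the
#' per-level height, area and volume columns of the packaged state tables.
#'
#' @param h disc height, mm (nonnegative).
#' @param A cross-sectional area, mm^2 (nonnegative).
#' @return volume in mm^3.
#' @export
#' @examples
#' disc_volume(3.1, 380)  # 1178
disc_volume <- function(h, A) {
  stopifnot(is.numeric(h), is.numeric(A))
  if (any(h < 0) || any(A < 0)) {
    stop("disc_volume(): height and area must be nonnegative", call. = FALSE)
  }
  h * A
}

#' Per-level disc reference parameters
#'
#' Loads the reference disc table: cross-sectional area `A0_mm2`, height
#' `h0_mm` and reference water fractions of nucleus pulposus (`phi0_np`) and
#' annulus fibrosus (`phi0_af`) for each level, and attaches the osmotic
#' model's structural assumptions: the NP occupies `np_area_fraction` of the
#' disc cross-section (default 0.40), the AF reference fixed charge density
#' (FCD) is `fcd_ratio_af_np` times the NP's (default 0.80), and the NP
#' reference FCD is `c0F_np` mol/m^3 (default 250; no consensus measured value
#' exists for this parameter, see the package vignette).
#'
#' @param source path to a CSV with columns
#'   `level,A0_mm2,h0_mm,phi0_np,phi0_af`, or `NULL` for the packaged table.
#' @param c0F_np NP reference fixed charge density, mol/m^3.
#' @param np_area_fraction fraction of disc area occupied by the NP, in (0,1).
#' @param fcd_ratio_af_np AF/NP reference FCD ratio, in (0,1].
#' @return data.frame with one row per level in cranio-caudal order, columns
#'   `level`, `A0_mm2`, `h0_mm`, `phi0_np`, `phi0_af`, `np_area_fraction`,
#'   `fcd_ratio_af_np`, `c0F_np`.
#' @export
#' @examples
#' ref <- disc_reference()
#' ref[ref$level == "C2C3", c("A0_mm2", "h0_mm")]
disc_reference <- function(source = NULL, c0F_np = 250,
                           np_area_fraction = 0.40,
                           fcd_ratio_af_np = 0.80) {
  path <- source %||% cd_extdata("disc_reference.csv")
  ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("level", "A0_mm2", "h0_mm", "phi0_np", "phi0_af")
  miss <- setdiff(need, names(ref))
  if (length(miss)) {
    stop("disc reference table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  ref$level <- as_disc_level(ref$level)
  ref <- ref[order(ref$level), need]
  ref$np_area_fraction <- np_area_fraction
  ref$fcd_ratio_af_np <- fcd_ratio_af_np
  ref$c0F_np <- c0F_np
  validate_disc_reference(ref)
  rownames(ref) <- NULL
  ref
}

#' Validate a disc reference table
#'
#' Checks the structural invariants of a reference table: all six levels
#' present exactly once, positive geometry, water fractions in (0,1) with
#' `phi0_af <= phi0_np`, and admissible osmotic assumptions.
#'
#' @param ref data.frame as returned by [disc_reference()].
#' @return `ref`, invisibly, if valid; otherwise an error naming the field.
#' @export
validate_disc_reference <- function(ref) {
  if (!setequal(as.character(ref$level), disc_levels()) ||
      nrow(ref) != length(disc_levels())) {
    stop("disc reference: expected exactly one row per level ",
         paste(disc_levels(), collapse = ", "), call. = FALSE)
  }
  chk <- function(ok, field, what) {
    if (!all(ok)) {
      stop("disc reference: invalid '", field, "': ", what, " (level ",
           paste(ref$level[!ok], collapse = ", "), ")", call. = FALSE)
    }
  }
  chk(ref$A0_mm2 > 0, "A0_mm2", "must be > 0")
  chk(ref$h0_mm > 0, "h0_mm", "must be > 0")
  chk(ref$phi0_np > 0 & ref$phi0_np < 1, "phi0_np", "must be in (0,1)")
  chk(ref$phi0_af > 0 & ref$phi0_af < 1, "phi0_af", "must be in (0,1)")
  chk(ref$phi0_af <= ref$phi0_np, "phi0_af", "must be <= phi0_np")
  chk(ref$np_area_fraction > 0 & ref$np_area_fraction < 1,
      "np_area_fraction", "must be in (0,1)")
  chk(ref$fcd_ratio_af_np > 0 & ref$fcd_ratio_af_np <= 1,
      "fcd_ratio_af_np", "must be in (0,1]")
  chk(ref$c0F_np > 0, "c0F_np", "must be > 0")
  invisible(ref)
}

#' Write a disc reference table to CSV
#'
#' Writes the geometry/water-fraction columns in the package's CSV dialect
#' (UTF-8, '.' decimal separator, header row), such that
#' `disc_reference(path)` reads them back bit-identically.
#'
#' @param ref data.frame from [disc_reference()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_disc_reference <- function(ref, path) {
  out <- ref[, c("level", "A0_mm2", "h0_mm", "phi0_np", "phi0_af")]
  out$level <- as.character(out$level)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
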