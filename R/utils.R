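#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (so 0.15 -> 0.2 and
#' -0.15 -> -0.2), the convention used by the packaged report tables.
#' Base [round()] rounds ties to even and is deliberately not used here.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 1).
#' @return `x` rounded to `digits` decimals.
#' @export
#' @examples
#' round_half_away(c(6.25, -6.25), 1)
round_half_away <- function(x, digits = 1) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1)
  p <- 10^digits
  # nudge by a relative epsilon so exact decimal ties survive binary fp
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9 * abs(x) * p) / p
}

#' Relative change in percent
#'
#' `100 * (new - reference) / reference`, the relative-change convention used
#' throughout the packaged contrast tables (water-content changes are relative,
#' not percentage-point differences).
#'
#' @param reference baseline value(s); must be nonzero.
#' @param new comparison value(s).
#' @return percent change, unrounded. Pair with [round_half_away()] for
#'   report-style one-decimal output.
#' @export
#' @examples
#' percent_change(91.83, 21.5)   # about -76.6
percent_change <- function(reference, new) {
  stopifnot(is.numeric(reference), is.numeric(new))
  if (any(reference == 0)) {
    stop("percent_change(): 'reference' must be nonzero", call. = FALSE)
  }
  100 * (new - reference) / reference
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Locate a packaged fixture under inst/extdata.
cd_extdata <- function(...) {
  path <- system.file("extdata", ..., package = "cervdisc", mustWork = FALSE)
  if (!nzchar(path)) {
    stop("packaged fixture not found: ", file.path(...), call. = FALSE)
  }
  path
}

`%||%` <- function(x, y) if (is.null(x)) y else x
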