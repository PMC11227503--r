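#' Round half-up to a fixed resolution
#'
#' Field sheets and the census database both use half-up rounding: girths are
#' recorded to the nearest 0.5 cm (ties go up) and diameters are stored at
#' 0.1 cm. A single shared utility keeps the convention changeable in one
#' place.
#'
#' @param x Numeric vector (must be non-negative for census quantities, but
#'   the function itself accepts any finite numeric).
#' @param step Resolution to round to, e.g. `0.5` or `0.1`. Must be positive.
#' @return `x` rounded half-up to the nearest multiple of `step`.
#' @examples
#' round_half_up(29.845, 0.5) # 30.0
#' round_half_up(9.5493, 0.1) # 9.5
#' @export
round_half_up <- function(x, step) {
  stopifnot(is.numeric(x), is.numeric(step), length(step) == 1, step > 0)
  # the tiny epsilon keeps exact decimal halves (binary-underrepresented) on
  # the "up" side; census values are far coarser than 1e-9
  out <- floor(x / step + 0.5 + 1e-9) * step
  round(out, 10)
}

#' Decimal calendar year of a date
#'
#' Census intervals are expressed in decimal years so that annualized
#' increments and demographic rates are correct across skipped campaigns.
#'
#' @param date A `Date` vector.
#' @return Numeric decimal years.
#' @export
decimal_year <- function(date) {
  lubridate::decimal_date(date)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom rlang .data
NULL

# stop() with a classed condition so the CLI can map error families to exit codes
psp_stop <- function(message, class) {
  rlang::abort(message, class = c(class, "pspcensus_error"))
}

# all character data in archive files must be plain ASCII
is_ascii <- function(x) {
  !vapply(x, function(s) !is.na(s) && grepl("[^\x01-\x7F]", s, useBytes = TRUE),
          logical(1))
}
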