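#' Default PSP campaign calendar
#'
#' The M'Baiki permanent sample plots were censused annually over 1982-2022
#' except in 1997, 1999, 2001, 2013, 2014 and 2016, giving 35 inventory
#' campaigns. This is the default calendar used by the synthetic generator
#' and by archive constructors.
#'
#' @return Integer vector of campaign years (length 35 for the default).
#' @examples
#' length(default_campaign_years()) # 35
#' @export
default_campaign_years <- function() {
  setdiff(1982:2022, c(1997L, 1999L, 2001L, 2013L, 2014L, 2016L))
}

#' Build an inventories (campaign) table
#'
#' Each campaign carries a nominal census date. Field campaigns run from
#' April to June; 15 May, the midpoint of that window, is used unless a date
#' is supplied, which makes decimal-year census intervals well defined.
#'
#' @param years Integer vector of campaign years, strictly increasing,
#'   all `>= 1982`.
#' @param census_dates Optional `Date` vector of the same length.
#' @param notes Optional character vector of the same length.
#' @return A tibble with columns `campaign_year`, `census_date`, `notes`.
#' @export
campaign_calendar <- function(years = default_campaign_years(),
                              census_dates = NULL, notes = NULL) {
  years <- as.integer(years)
  if (anyDuplicated(years) > 0) {
    psp_stop("campaign years must be unique", "psp_schema_error")
  }
  if (any(diff(years) <= 0)) {
    psp_stop("campaign years must be strictly increasing", "psp_schema_error")
  }
  if (length(years) && any(years < 1982L)) {
    psp_stop("campaign years before 1982 are not valid", "psp_schema_error")
  }
  if (is.null(census_dates)) {
    census_dates <- as.Date(sprintf("%d-05-15", years))
  }
  stopifnot(length(census_dates) == length(years))
  if (is.null(notes)) notes <- rep(NA_character_, length(years))
  tibble::tibble(
    campaign_year = years,
    census_date = as.Date(census_dates),
    notes = as.character(notes)
  )
}
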