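#' The valuable timber species recognized at plot installation
#'
#' Thirty-six valuable timber species or species complexes were recognized
#' when the plots were installed: 15 of category A (international market
#' interest) and 21 of category B (local market interest); every other taxon
#' is category C. The packaged table carries the historical species name,
#' the currently valid name where it differs, the commercial name, the
#' two-digit vernacular code and the Issongo name (ASCII-transliterated).
#'
#' @return A 36-row tibble with columns `species`, `valid_name`,
#'   `commercial_name`, `code`, `issongo_name`, `category`.
#' @examples
#' sp <- load_valuable_species_fixture()
#' table(sp$category) # A: 15, B: 21
#' @export
load_valuable_species_fixture <- function() {
  path <- system.file("extdata", "valuable_species.csv", package = "pspcensus",
                      mustWork = TRUE)
  fx <- readr::read_csv(path, col_types = readr::cols(
    species = readr::col_character(), valid_name = readr::col_character(),
    commercial_name = readr::col_character(), code = readr::col_character(),
    issongo_name = readr::col_character(), category = readr::col_character()
  ), na = "", progress = FALSE)
  if (nrow(fx) != 36 || !all(fx$category %in% c("A", "B")) ||
      !identical(fx$code, sprintf("%02d", 1:36))) {
    psp_stop("valuable-species fixture is damaged (expected 36 coded A/B rows)",
             "psp_schema_error")
  }
  fx
}
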