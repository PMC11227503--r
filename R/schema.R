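# Relational archive schema: eight CSV tables + two GeoJSON layers.
#
# The released archive names its files (tree.csv, taxonomy.csv, ...); column
# names and types below are this package's own data dictionary, documented in
# ?census_dictionary. They are a convention of this artifact, not a
# transcription of the upstream database dictionary.

# column type codes: c = character, i = integer, d1/d2 = double written with
# 1/2 decimals, D = ISO date
psp_dictionary <- function() {
  list(
    tree = c(tree_id = "c", plot_no = "i", subplot_no = "i", tree_no = "i",
             x_m = "d1", y_m = "d1", id_taxonomy = "i", vernacular_name = "c"),
    taxonomy = c(id_taxonomy = "i", sci_name_1991 = "c", sci_name_2010 = "c",
                 sci_name_2011 = "c", valuable_code = "c",
                 valuable_category = "c"),
    vernacular = c(id_vernacular = "i", vernacular_name = "c",
                   issongo_name = "c", id_taxonomy = "i"),
    trees_context = c(plot_no = "i", treatment = "c", block = "c",
                      area_ha = "d1"),
    measures = c(tree_id = "c", campaign_year = "i", girth_cm = "d1",
                 dbh_cm = "d1", hom_m = "d2", method = "c", status = "c",
                 mortality_code = "c", observation_codes = "c"),
    inventories = c(campaign_year = "i", census_date = "D", notes = "c"),
    observation_codes = c(code = "c", description = "c"),
    mortality_codes = c(code = "c", description = "c")
  )
}

psp_table_names <- function() names(psp_dictionary())

#' The archive data dictionary
#'
#' Returns, per table, the column names and storage types of the flat-file
#' census archive: eight comma-separated ASCII tables (`tree`, `taxonomy`,
#' `vernacular`, `trees_context`, `measures`, `inventories`,
#' `observation_codes`, `mortality_codes`) plus the two GeoJSON layers
#' (`plots`, `subplots`). Missing numeric fields are encoded as empty strings
#' on disk, never as sentinel numbers. Corrected archives add a `provenance`
#' column to `measures`.
#'
#' @return Named list of named character vectors (column -> type code,
#'   where `c` = text, `i` = integer, `d1`/`d2` = decimal with 1 or 2 digits,
#'   `D` = ISO-8601 date).
#' @export
census_dictionary <- function() psp_dictionary()

default_observation_codes <- function() {
  tibble::tibble(
    code = c("SHAPE_IRREGULAR", "TERMITES", "LIANAS", "DAMAGE"),
    description = c("irregular stem shape (bumps, buttresses, aerial roots)",
                    "termites present on the stem",
                    "lianas on the stem",
                    "mechanical damage to the stem")
  )
}

default_mortality_codes <- function() {
  tibble::tibble(
    code = c("standing_death", "primary_treefall", "secondary_treefall"),
    description = c("tree died upright",
                    "tree fell on its own",
                    "tree knocked down by another falling tree")
  )
}

valid_statuses <- function() c("alive", "dead", "missing", "not_yet_recruited")
valid_methods_raw <- function() c("tape", "relascope", "diameter_class")
valid_methods_corrected <- function() {
  c(valid_methods_raw(), "carried_forward", "interpolated", "taper_converted",
    "reborn_backfill")
}
valid_plot_nos <- function() c(11:16, 21:24)

#' Experimental block of a plot
#'
#' Plots 11-13 belong to Boukoko1, 14-16 to Boukoko2 and 21-24 to LaLole.
#'
#' @param plot_no Integer plot number(s).
#' @return Character vector of block names.
#' @export
block_for_plot <- function(plot_no) {
  dplyr::case_when(
    plot_no %in% 11:13 ~ "Boukoko1",
    plot_no %in% 14:16 ~ "Boukoko2",
    plot_no %in% 21:24 ~ "LaLole",
    TRUE ~ NA_character_
  )
}

#' Compose a tree identifier
#'
#' Tree identity is the composite (plot, subplot, tree number): trees are
#' numbered within their 1-ha subplot.
#'
#' @param plot_no,subplot_no,tree_no Integer vectors.
#' @return Character ids of the form `"11_1_0042"`.
#' @export
make_tree_id <- function(plot_no, subplot_no, tree_no) {
  sprintf("%d_%d_%04d", as.integer(plot_no), as.integer(subplot_no),
          as.integer(tree_no))
}

empty_table <- function(name) {
  spec <- psp_dictionary()[[name]]
  cols <- lapply(spec, function(tc) {
    switch(tc,
           c = character(0), i = integer(0), d1 = numeric(0), d2 = numeric(0),
           D = as.Date(character(0)))
  })
  tibble::as_tibble(cols)
}

empty_plots <- function() {
  tibble::tibble(plot_no = integer(0), treatment = character(0),
                 block = character(0), area_ha = numeric(0),
                 ref_lon = numeric(0), ref_lat = numeric(0),
                 geometry = list())
}

empty_subplots <- function() {
  tibble::tibble(plot_no = integer(0), subplot_no = integer(0),
                 area_ha = numeric(0), geometry = list())
}

coerce_table <- function(df, name) {
  spec <- psp_dictionary()[[name]]
  extra <- setdiff(names(df), c(names(spec), "provenance"))
  if (length(extra)) {
    psp_stop(sprintf("table '%s' has unknown columns: %s", name,
                     paste(extra, collapse = ", ")), "psp_schema_error")
  }
  missing <- setdiff(names(spec), names(df))
  if (length(missing)) {
    psp_stop(sprintf("table '%s' lacks columns: %s", name,
                     paste(missing, collapse = ", ")), "psp_schema_error")
  }
  out <- df
  for (col in names(spec)) {
    out[[col]] <- switch(spec[[col]],
      c = {
        v <- as.character(out[[col]])
        v[!is.na(v) & v == ""] <- NA_character_
        v
      },
      i = as.integer(out[[col]]),
      d1 = round(as.numeric(out[[col]]), 6),
      d2 = round(as.numeric(out[[col]]), 6),
      D = as.Date(out[[col]])
    )
  }
  ord <- c(names(spec), intersect("provenance", names(out)))
  tibble::as_tibble(out[ord])
}

#' Construct an in-memory census archive
#'
#' Assembles the relational model mirroring the released archive: eight
#' tables plus the two spatial layers. Tables not supplied default to empty.
#' Column types are coerced per the data dictionary; empty strings in
#' character columns are normalized to `NA`.
#'
#' @param tree,taxonomy,vernacular,trees_context,measures,inventories
#'   Tibbles following [census_dictionary()].
#' @param observation_codes,mortality_codes Code description tables; default
#'   to the packaged code lists when rows exist elsewhere, otherwise empty.
#' @param plots,subplots Spatial layers as tibbles with a `geometry`
#'   list-column of closed lon/lat rings (see [plot_geometry()]).
#' @param corrected Logical; `TRUE` marks an analysis-ready archive whose
#'   `measures` carry a `provenance` column and corrected diameters.
#' @return An object of class `census_archive` (a named list of tibbles).
#' @export
census_archive <- function(tree = NULL, taxonomy = NULL, vernacular = NULL,
                           trees_context = NULL, measures = NULL,
                           inventories = NULL, observation_codes = NULL,
                           mortality_codes = NULL, plots = NULL,
                           subplots = NULL, corrected = FALSE) {
  tabs <- list(
    tree = tree %||% empty_table("tree"),
    taxonomy = taxonomy %||% empty_table("taxonomy"),
    vernacular = vernacular %||% empty_table("vernacular"),
    trees_context = trees_context %||% empty_table("trees_context"),
    measures = measures %||% empty_table("measures"),
    inventories = inventories %||% empty_table("inventories"),
    observation_codes = observation_codes %||% empty_table("observation_codes"),
    mortality_codes = mortality_codes %||% empty_table("mortality_codes")
  )
  tabs <- lapply(stats::setNames(names(tabs), names(tabs)),
                 function(nm) coerce_table(tabs[[nm]], nm))
  if (corrected && !"provenance" %in% names(tabs$measures)) {
    tabs$measures$provenance <- rep(NA_character_, nrow(tabs$measures))
  }
  arc <- c(tabs, list(plots = plots %||% empty_plots(),
                      subplots = subplots %||% empty_subplots()))
  structure(arc, class = "census_archive", corrected = corrected)
}

#' @export
print.census_archive <- function(x, ...) {
  cat(sprintf("<census_archive%s>\n",
              if (isTRUE(attr(x, "corrected"))) " (corrected)" else ""))
  cat(sprintf("  plots: %d  subplots: %d  trees: %d  campaigns: %d  measures: %d\n",
              nrow(x$plots), nrow(x$subplots), nrow(x$tree),
              nrow(x$inventories), nrow(x$measures)))
  invisible(x)
}

#' Is an archive marked as corrected?
#' @param archive A `census_archive`.
#' @return Logical.
#' @export
is_corrected <- function(archive) {
  isTRUE(attr(archive, "corrected")) ||
    "provenance" %in% names(archive$measures)
}

#' Field-level equality of two archives
#'
#' Compares every table (and the spatial layers) column by column; used for
#' the read/write round-trip contract.
#'
#' @param a,b `census_archive` objects.
#' @return `TRUE` or a character vector describing the first differences.
#' @export
archive_equal <- function(a, b) {
  diffs <- character(0)
  for (nm in c(psp_table_names(), "plots", "subplots")) {
    ta <- as.data.frame(a[[nm]])
    tb <- as.data.frame(b[[nm]])
    eq <- isTRUE(all.equal(ta, tb, check.attributes = FALSE,
                           tolerance = 1e-9))
    if (!eq) diffs <- c(diffs, sprintf("table '%s' differs", nm))
  }
  if (length(diffs)) diffs else TRUE
}
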