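#' Validate an archive against the schema invariants
#'
#' Checks type invariants, domain rules, referential integrity between the
#' eight tables and the two spatial layers, and plot-geometry areas.
#' Violations are returned as data, one row each, never raised as errors.
#'
#' @param archive A `census_archive`.
#' @return A tibble with columns `table`, `row_key`, `rule_id`, `detail`;
#'   zero rows when the archive is fully consistent.
#' @export
validate_archive <- function(archive) {
  stopifnot(inherits(archive, "census_archive"))
  v <- list()
  add <- function(table, row_key, rule_id, detail) {
    if (!length(row_key)) return()
    v[[length(v) + 1]] <<- tibble::tibble(
      table = table, row_key = as.character(row_key), rule_id = rule_id,
      detail = detail)
  }
  tr <- archive$tree
  tx <- archive$taxonomy
  vn <- archive$vernacular
  ctx <- archive$trees_context
  ms <- archive$measures
  inv <- archive$inventories
  corrected <- is_corrected(archive)

  # --- keys and domains -----------------------------------------------------
  dup <- tr$tree_id[duplicated(tr$tree_id)]
  add("tree", unique(dup), "TREE_UNIQUE", "duplicated tree_id")
  dup <- inv$campaign_year[duplicated(inv$campaign_year)]
  add("inventories", unique(dup), "CAMPAIGN_UNIQUE", "duplicated campaign_year")
  bad <- inv$campaign_year[!is.na(inv$campaign_year) & inv$campaign_year < 1982]
  add("inventories", bad, "CAMPAIGN_MIN", "campaign_year before 1982")

  bad <- tr$tree_id[!tr$plot_no %in% valid_plot_nos()]
  add("tree", bad, "PLOT_NO_DOMAIN", "plot_no outside {11..16, 21..24}")
  bad <- tr$tree_id[!tr$subplot_no %in% 1:4]
  add("tree", bad, "SUBPLOT_DOMAIN", "subplot_no outside {1..4}")
  oob <- !is.na(tr$x_m) & !is.na(tr$y_m) &
    (tr$x_m < 0 | tr$x_m > 200 | tr$y_m < 0 | tr$y_m > 200)
  add("tree", tr$tree_id[oob], "COORD_RANGE",
      sprintf("coordinate out of [0,200]: (%.1f, %.1f)",
              tr$x_m[oob], tr$y_m[oob]))

  bad <- !is.na(tx$valuable_category) & !tx$valuable_category %in% c("A", "B", "C")
  add("taxonomy", tx$id_taxonomy[bad], "CATEGORY_DOMAIN",
      "valuable_category outside {A, B, C}")

  # A/B membership must match the packaged valuable-species list
  if (nrow(tx)) {
    fx <- load_valuable_species_fixture()
    ab <- tx[!is.na(tx$valuable_category) & tx$valuable_category %in% c("A", "B"), ]
    if (nrow(ab)) {
      key <- ifelse(is.na(fx$valid_name) | fx$valid_name == "", fx$species,
                    fx$valid_name)
      cat_for <- stats::setNames(fx$category, key)
      cat_for2 <- stats::setNames(fx$category, fx$species)
      nm <- ab$sci_name_1991
      expected <- ifelse(nm %in% names(cat_for), cat_for[nm],
                         ifelse(nm %in% names(cat_for2), cat_for2[nm],
                                NA_character_))
      bad <- is.na(expected) | expected != ab$valuable_category
      add("taxonomy", ab$id_taxonomy[bad], "CATEGORY_FIXTURE",
          sprintf("category %s for '%s' does not match the valuable-species list",
                  ab$valuable_category[bad], nm[bad]))
    }
  }

  # --- foreign keys ---------------------------------------------------------
  bad <- ms$tree_id[!ms$tree_id %in% tr$tree_id]
  add("measures", unique(bad), "FK_MEASURES_TREE",
      "tree_id not present in tree.csv")
  bad <- ms$campaign_year[!ms$campaign_year %in% inv$campaign_year]
  add("measures", unique(bad), "FK_MEASURES_INVENTORY",
      "campaign_year not present in inventories.csv")
  bad <- tr$tree_id[!is.na(tr$id_taxonomy) & !tr$id_taxonomy %in% tx$id_taxonomy]
  add("tree", bad, "FK_TREE_TAXONOMY", "id_taxonomy not present in taxonomy.csv")
  bad <- vn$id_vernacular[!is.na(vn$id_taxonomy) &
                            !vn$id_taxonomy %in% tx$id_taxonomy]
  add("vernacular", bad, "FK_VERNACULAR_TAXONOMY",
      "id_taxonomy not present in taxonomy.csv")
  bad <- unique(tr$plot_no[!tr$plot_no %in% ctx$plot_no])
  add("tree", bad, "FK_TREE_CONTEXT", "plot_no not present in trees_context.csv")
  if (nrow(ctx)) {
    bad <- ctx$plot_no[!ctx$plot_no %in% archive$plots$plot_no]
    add("trees_context", bad, "FK_CONTEXT_PLOTS",
        "plot_no has no feature in plots.geojson")
  }
  mc <- ms$mortality_code
  bad <- ms$tree_id[!is.na(mc) & mc != "none" &
                      !mc %in% archive$mortality_codes$code]
  add("measures", unique(bad), "FK_MEASURES_MORTCODE",
      "mortality_code not present in mortality_codes.csv")

  # --- measurement invariants ----------------------------------------------
  key <- paste0(ms$tree_id, "@", ms$campaign_year)
  living <- ms$status %in% c("alive", "not_yet_recruited")
  bad <- living & !is.na(ms$dbh_cm) & ms$dbh_cm <= 0
  add("measures", key[bad], "DBH_POSITIVE", "non-positive dbh for a living tree")
  is_dead <- !is.na(ms$status) & ms$status == "dead"
  has_code <- !is.na(mc) & mc != "none"
  bad <- is_dead & !has_code
  add("measures", key[bad], "MORTALITY_STATUS", "dead record without mortality code")
  bad <- !is_dead & has_code
  add("measures", key[bad], "MORTALITY_STATUS",
      sprintf("mortality_code '%s' on a non-dead record", mc[bad]))
  bad <- !is.na(ms$hom_m) & ms$hom_m < 1.5
  add("measures", key[bad], "HOM_MIN", "hom below the 1.50 m minimum")
  bad <- !is.na(ms$status) & !ms$status %in% valid_statuses()
  add("measures", key[bad], "STATUS_DOMAIN",
      sprintf("unknown status '%s'", ms$status[bad]))
  ok_methods <- if (corrected) valid_methods_corrected() else valid_methods_raw()
  bad <- !is.na(ms$method) & !ms$method %in% ok_methods
  add("measures", key[bad], "METHOD_RAW",
      sprintf("method '%s' not allowed in a %s archive", ms$method[bad],
              if (corrected) "corrected" else "raw"))

  # in a corrected archive every recruit must enter at >= 10 cm dbh
  if (corrected && nrow(ms)) {
    first_alive <- ms |>
      dplyr::filter(.data$status == "alive", !is.na(.data$dbh_cm)) |>
      dplyr::group_by(.data$tree_id) |>
      dplyr::slice_min(.data$campaign_year, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
    bad <- first_alive |> dplyr::filter(.data$dbh_cm < 10)
    add("measures", paste0(bad$tree_id, "@", bad$campaign_year),
        "RECRUIT_MIN_DBH",
        sprintf("recruit below 10 cm dbh (%.1f cm)", bad$dbh_cm))
  }

  # --- geometry -------------------------------------------------------------
  pl <- archive$plots
  if (nrow(pl)) {
    areas <- vapply(seq_len(nrow(pl)), function(i) {
      ring_area_m2(pl$geometry[[i]], pl$ref_lon[i], pl$ref_lat[i])
    }, numeric(1))
    bad <- abs(areas - 40000) / 40000 > 0.001
    add("plots", pl$plot_no[bad], "GEOM_AREA",
        sprintf("plot polygon area %.1f m2 deviates >0.1%% from 40000", areas[bad]))
    sp <- archive$subplots
    if (nrow(sp)) {
      ref <- pl[match(sp$plot_no, pl$plot_no), c("ref_lon", "ref_lat")]
      sareas <- vapply(seq_len(nrow(sp)), function(i) {
        ring_area_m2(sp$geometry[[i]], ref$ref_lon[i], ref$ref_lat[i])
      }, numeric(1))
      bad <- !is.na(sareas) & abs(sareas - 10000) / 10000 > 0.001
      add("subplots", paste0(sp$plot_no[bad], "_", sp$subplot_no[bad]),
          "GEOM_AREA",
          sprintf("subplot polygon area %.1f m2 deviates >0.1%% from 10000",
                  sareas[bad]))
    }
  }

  if (!length(v)) {
    return(tibble::tibble(table = character(0), row_key = character(0),
                          rule_id = character(0), detail = character(0)))
  }
  dplyr::bind_rows(v)
}
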