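# Builders for tiny hand-made archives and tree series used across tests.

h_taxonomy <- function() {
  tibble::tibble(id_taxonomy = 1L,
                 sci_name_1991 = "Indet morphospecies 01",
                 sci_name_2010 = "Indet morphospecies 01",
                 sci_name_2011 = "Indet morphospecies 01",
                 valuable_code = NA_character_, valuable_category = "C")
}

h_trees <- function(n = 1, plot_no = 11, subplot_no = 1) {
  tibble::tibble(
    tree_id = make_tree_id(plot_no, subplot_no, seq_len(n)),
    plot_no = plot_no, subplot_no = subplot_no, tree_no = seq_len(n),
    x_m = round(seq(5, 95, length.out = n), 1),
    y_m = round(seq(5, 95, length.out = n), 1),
    id_taxonomy = 1L, vernacular_name = NA_character_)
}

# measures: supply tree_id, campaign_year, dbh_cm and any overriding columns
h_measures <- function(df) {
  out <- tibble::tibble(
    tree_id = df$tree_id,
    campaign_year = as.integer(df$campaign_year),
    girth_cm = if ("girth_cm" %in% names(df)) df$girth_cm else
      dbh_to_gbh(ifelse(is.na(df$dbh_cm), 0, df$dbh_cm)) |>
        (\(g) ifelse(is.na(df$dbh_cm), NA_real_, g))(),
    dbh_cm = df$dbh_cm,
    hom_m = if ("hom_m" %in% names(df)) df$hom_m else
      ifelse(is.na(df$dbh_cm), NA_real_, 1.5),
    method = if ("method" %in% names(df)) df$method else
      ifelse(is.na(df$dbh_cm), NA_character_, "tape"),
    status = if ("status" %in% names(df)) df$status else "alive",
    mortality_code = if ("mortality_code" %in% names(df)) df$mortality_code
      else NA_character_,
    observation_codes = NA_character_)
  out
}

h_archive <- function(measures, trees = NULL, years = NULL,
                      plot_no = 11, corrected = FALSE) {
  if (is.null(years)) years <- sort(unique(measures$campaign_year))
  if (is.null(trees)) {
    ids <- unique(measures$tree_id)
    trees <- h_trees(length(ids), plot_no = plot_no)
    trees$tree_id <- ids
  }
  geom <- plot_geometry(plot_no, "control", ref_lon = 17.5, ref_lat = 3.45)
  census_archive(
    tree = trees, taxonomy = h_taxonomy(),
    trees_context = tibble::tibble(plot_no = plot_no, treatment = "control",
                                   block = block_for_plot(plot_no),
                                   area_ha = 4),
    measures = measures, inventories = campaign_calendar(years),
    observation_codes = default_observation_codes(),
    mortality_codes = default_mortality_codes(),
    plots = geom$plots, subplots = geom$subplots, corrected = corrected)
}

# a bare per-tree series for the correction engine
h_series <- function(years, dbh, hom = 1.5, status = NULL, tree_id = "11_1_0001") {
  n <- length(years)
  hom <- rep_len(hom, n)
  if (is.null(status)) status <- ifelse(is.na(dbh), "missing", "alive")
  tibble::tibble(
    campaign_year = as.integer(years),
    census_date = as.Date(sprintf("%d-05-15", years)),
    tree_id = tree_id,
    girth_cm = ifelse(is.na(dbh), NA_real_, dbh_to_gbh(dbh)),
    dbh_cm = dbh,
    hom_m = ifelse(status == "dead", NA_real_, hom),
    method = ifelse(is.na(dbh), NA_character_, "tape"),
    status = status,
    mortality_code = ifelse(status == "dead", "standing_death", NA_character_))
}

h_key <- function(d) paste(d$tree_id, d$campaign_year, d$rule_id)

dir_bytes <- function(dir) {
  fs <- sort(list.files(dir, full.names = TRUE))
  lapply(fs, function(f) readBin(f, "raw", file.size(f)))
}
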