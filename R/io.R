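# Readers/writers for the flat-file archive: eight comma-separated ASCII
# tables plus two RFC 7946 GeoJSON FeatureCollections. Writing is
# deterministic (fixed column order, fixed numeric formats) so that
# write -> read -> write is byte-identical.

format_column <- function(x, type_code) {
  out <- switch(type_code,
    c = as.character(x),
    i = ifelse(is.na(x), NA_character_, format(as.integer(x),
                                               scientific = FALSE)),
    d1 = ifelse(is.na(x), NA_character_, sprintf("%.1f", x)),
    d2 = ifelse(is.na(x), NA_character_, sprintf("%.2f", x)),
    D = ifelse(is.na(x), NA_character_, format(x, "%Y-%m-%d"))
  )
  out
}

write_psp_csv <- function(df, name, path) {
  spec <- psp_dictionary()[[name]]
  cols <- c(names(spec), intersect("provenance", names(df)))
  out <- df[cols]
  for (col in cols) {
    tc <- if (col == "provenance") "c" else spec[[col]]
    v <- format_column(out[[col]], tc)
    bad <- which(!is_ascii(v))
    if (length(bad)) {
      psp_stop(sprintf("non-ASCII content in %s.csv, column '%s', row %d",
                       name, col, bad[1]), "psp_encoding_error")
    }
    out[[col]] <- v
  }
  readr::write_csv(out, path, na = "", quote = "needed", progress = FALSE)
  invisible(path)
}

read_psp_csv <- function(path, name) {
  spec <- psp_dictionary()[[name]]
  raw <- readBin(path, "raw", file.size(path))
  if (any(raw > as.raw(0x7f))) {
    warning(sprintf("non-ASCII bytes found in %s", basename(path)),
            call. = FALSE)
  }
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  col_for <- function(tc) switch(tc,
    c = readr::col_character(), i = readr::col_integer(),
    d1 = readr::col_double(), d2 = readr::col_double(),
    D = readr::col_date(format = "%Y-%m-%d"))
  types <- lapply(header, function(h) {
    if (h == "provenance") readr::col_character() else col_for(spec[[h]])
  })
  names(types) <- header
  df <- readr::read_csv(path, col_types = do.call(readr::cols, types),
                        na = "", progress = FALSE)
  df
}

feature <- function(properties, ring) {
  list(type = "Feature",
       properties = properties,
       geometry = list(type = "Polygon",
                       coordinates = list(lapply(seq_len(nrow(ring)),
                                                 function(i) unname(ring[i, ])))))
}

write_geojson <- function(features, path) {
  fc <- list(type = "FeatureCollection", features = features)
  json <- jsonlite::toJSON(fc, auto_unbox = TRUE, digits = 8, null = "null",
                           na = "null")
  writeLines(json, path)
  invisible(path)
}

plots_to_features <- function(plots) {
  lapply(seq_len(nrow(plots)), function(i) {
    feature(list(plot_no = plots$plot_no[i],
                 treatment = plots$treatment[i],
                 block = plots$block[i],
                 area_ha = plots$area_ha[i],
                 ref_lon = plots$ref_lon[i],
                 ref_lat = plots$ref_lat[i]),
            plots$geometry[[i]])
  })
}

subplots_to_features <- function(subplots) {
  lapply(seq_len(nrow(subplots)), function(i) {
    feature(list(plot_no = subplots$plot_no[i],
                 subplot_no = subplots$subplot_no[i],
                 area_ha = subplots$area_ha[i]),
            subplots$geometry[[i]])
  })
}

read_geojson <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

ring_from_feature <- function(f) {
  coords <- f$geometry$coordinates[[1]]
  m <- do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
  colnames(m) <- c("lon", "lat")
  m
}

features_to_plots <- function(fc) {
  if (!length(fc$features)) return(empty_plots())
  rows <- lapply(fc$features, function(f) {
    p <- f$properties
    tibble::tibble(plot_no = as.integer(p$plot_no),
                   treatment = as.character(p$treatment),
                   block = as.character(p$block),
                   area_ha = as.numeric(p$area_ha),
                   ref_lon = as.numeric(p$ref_lon),
                   ref_lat = as.numeric(p$ref_lat),
                   geometry = list(ring_from_feature(f)))
  })
  dplyr::bind_rows(rows)
}

features_to_subplots <- function(fc) {
  if (!length(fc$features)) return(empty_subplots())
  rows <- lapply(fc$features, function(f) {
    p <- f$properties
    tibble::tibble(plot_no = as.integer(p$plot_no),
                   subplot_no = as.integer(p$subplot_no),
                   area_ha = as.numeric(p$area_ha),
                   geometry = list(ring_from_feature(f)))
  })
  dplyr::bind_rows(rows)
}

archive_file_names <- function() {
  c(paste0(psp_table_names(), ".csv"), "plots.geojson", "subplots.geojson")
}

#' Write a census archive to a directory
#'
#' Emits the ten-file flat archive: eight comma-separated ASCII tables with a
#' header row and stable column order, and two GeoJSON FeatureCollections.
#' Missing numeric fields are written as empty strings. Re-reading the
#' directory with [read_archive()] reproduces the archive exactly, and a
#' second write is byte-identical.
#'
#' @param archive A `census_archive`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_archive <- function(archive, dir) {
  stopifnot(inherits(archive, "census_archive"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in psp_table_names()) {
    write_psp_csv(archive[[nm]], nm, file.path(dir, paste0(nm, ".csv")))
  }
  write_geojson(plots_to_features(archive$plots),
                file.path(dir, "plots.geojson"))
  write_geojson(subplots_to_features(archive$subplots),
                file.path(dir, "subplots.geojson"))
  invisible(dir)
}

#' Read a census archive from a directory
#'
#' Expects the eight named CSV tables and two GeoJSON layers. Foreign keys
#' are checked on load: a dangling reference raises a referential-integrity
#' error listing the offending rows (set `check_fk = FALSE` to load anyway
#' and inspect with [validate_archive()]). Non-ASCII bytes raise a warning.
#'
#' @param dir Directory containing the archive files.
#' @param check_fk Logical; check referential integrity (default `TRUE`).
#' @return A `census_archive`. Archives whose `measures` carry a
#'   `provenance` column are marked corrected.
#' @export
read_archive <- function(dir, check_fk = TRUE) {
  missing <- archive_file_names()[!file.exists(file.path(dir,
                                                         archive_file_names()))]
  if (length(missing)) {
    psp_stop(sprintf("archive at '%s' is missing file(s): %s", dir,
                     paste(missing, collapse = ", ")), "psp_schema_error")
  }
  tabs <- lapply(stats::setNames(psp_table_names(), psp_table_names()),
                 function(nm) read_psp_csv(file.path(dir, paste0(nm, ".csv")),
                                           nm))
  plots <- features_to_plots(read_geojson(file.path(dir, "plots.geojson")))
  subplots <- features_to_subplots(read_geojson(file.path(dir,
                                                          "subplots.geojson")))
  corrected <- "provenance" %in% names(tabs$measures)
  arc <- census_archive(tree = tabs$tree, taxonomy = tabs$taxonomy,
                        vernacular = tabs$vernacular,
                        trees_context = tabs$trees_context,
                        measures = tabs$measures,
                        inventories = tabs$inventories,
                        observation_codes = tabs$observation_codes,
                        mortality_codes = tabs$mortality_codes,
                        plots = plots, subplots = subplots,
                        corrected = corrected)
  if (check_fk) {
    v <- validate_archive(arc)
    fk <- v[grepl("^FK_", v$rule_id), , drop = FALSE]
    if (nrow(fk)) {
      psp_stop(paste0("referential-integrity error:\n",
                      paste(utils::head(sprintf("  %s [%s]: %s", fk$table,
                                                fk$row_key, fk$detail), 20),
                            collapse = "\n")),
               "psp_integrity_error")
    }
  }
  arc
}
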