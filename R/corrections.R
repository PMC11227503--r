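# Deterministic correction engine producing an analysis-ready diameter
# series per tree. Raw data are immutable: corrections are derived values
# with full provenance (raw | manual_override | reborn_backfill |
# taper_converted | interpolated | carried_forward | unfilled).
#
# Pipeline order (correct_tree): manual overrides -> re-born back-fill ->
# taper-ratio conversion of hom raises -> increment-sign-dependent gap
# filling -> status recomputation. Overrides are applied first so every
# automated procedure integrates them.

LIVING_STATUSES <- c("alive", "not_yet_recruited")

#' Extract one tree's full-grid measurement series
#'
#' Returns one row per archive campaign between the tree's first and last
#' record; campaigns with no record for the tree are inserted with status
#' `"missing"` (the "empty inventory campaign" of the correction procedure).
#'
#' @param archive A `census_archive`.
#' @param tree_id Tree identifier.
#' @return Tibble ordered by campaign with the measures columns plus
#'   `census_date`.
#' @export
tree_series <- function(archive, tree_id) {
  ms <- archive$measures[archive$measures$tree_id == tree_id, , drop = FALSE]
  if (!nrow(ms)) {
    psp_stop(sprintf("tree '%s' has no measurements", tree_id),
             "psp_domain_error")
  }
  expand_series_grid(ms, archive$inventories)
}

expand_series_grid <- function(ms, inventories) {
  inv <- dplyr::arrange(inventories, .data$campaign_year)
  span <- inv[inv$campaign_year >= min(ms$campaign_year) &
                inv$campaign_year <= max(ms$campaign_year), ]
  out <- dplyr::left_join(span[c("campaign_year", "census_date")], ms,
                          by = "campaign_year")
  out$tree_id <- ms$tree_id[1]
  out$status[is.na(out$status)] <- "missing"
  dplyr::arrange(out, .data$campaign_year)
}

ensure_provenance <- function(series) {
  if (!"provenance" %in% names(series)) {
    series$provenance <- ifelse(is.na(series$dbh_cm), NA_character_, "raw")
  }
  series
}

#' Apply expert manual overrides to a series
#'
#' Expert-based diameter corrections live in a sidecar table and are applied
#' before the automated procedures, which then integrate the overridden
#' values.
#'
#' @param series A tree series (see [tree_series()]).
#' @param overrides Tibble with `tree_id`, `campaign_year`, `dbh_cm`,
#'   `note`; rows for other trees are ignored.
#' @return The series with overridden values and
#'   `provenance = "manual_override"`.
#' @export
apply_overrides <- function(series, overrides) {
  series <- ensure_provenance(series)
  if (is.null(overrides) || !nrow(overrides)) return(series)
  ov <- overrides[overrides$tree_id == series$tree_id[1], , drop = FALSE]
  idx <- match(ov$campaign_year, series$campaign_year)
  keep <- !is.na(idx)
  series$dbh_cm[idx[keep]] <- round_half_up(ov$dbh_cm[keep], 0.1)
  series$provenance[idx[keep]] <- "manual_override"
  series$status[idx[keep]] <- ifelse(
    series$status[idx[keep]] %in% c("missing", "dead"), "alive",
    series$status[idx[keep]])
  series
}

#' Back-fill re-born trees
#'
#' A tree recorded dead for one or more campaigns and later recorded alive
#' again is a re-born tree: its presumed-dead records are replaced with the
#' diameter at the re-born date and the death is annulled. A terminal dead
#' run (no later living record) is a real death and is kept.
#'
#' @param series A tree series.
#' @return Series with re-born intervals filled
#'   (`provenance = "reborn_backfill"`).
#' @export
backfill_reborn <- function(series) {
  s <- ensure_provenance(series)
  dead <- which(!is.na(s$status) & s$status == "dead")
  if (!length(dead)) return(s)
  living <- which(s$status %in% LIVING_STATUSES)
  runs <- split(dead, cumsum(c(1, diff(dead) != 1)))
  for (run in runs) {
    after <- living[living > max(run)]
    if (!length(after)) next # terminal death
    reborn_row <- min(after)
    cand <- which(seq_len(nrow(s)) >= reborn_row & !is.na(s$dbh_cm) &
                    s$status %in% LIVING_STATUSES)
    if (!length(cand)) {
      psp_stop(sprintf(
        "tree '%s': re-born in %d but no subsequent diameter measurement",
        s$tree_id[1], s$campaign_year[reborn_row]), "psp_correction_error")
    }
    src <- min(cand)
    s$dbh_cm[run] <- s$dbh_cm[src]
    s$hom_m[run] <- s$hom_m[src]
    s$status[run] <- "alive"
    s$mortality_code[run] <- NA_character_
    s$method[run] <- "reborn_backfill"
    s$provenance[run] <- "reborn_backfill"
  }
  s
}

#' Detect hom raises in a series
#'
#' One taper event per increase of the height of measurement between
#' successive measured campaigns. The taper ratio — diameter at the raise
#' campaign measured at the raised hom over the diameter at the previous
#' campaign measured at the original hom — is defined only when the two
#' flanking measurements are at consecutive campaigns; a raise inside a
#' measurement gap yields `ratio = NA` and is resolved by [fill_gaps()].
#'
#' @param series A tree series.
#' @return Tibble of events: `raise_campaign`, `hom_old`, `hom_new`,
#'   `dbh_before`, `dbh_at`, `ratio`.
#' @export
detect_hom_raises <- function(series) {
  s <- dplyr::arrange(series, .data$campaign_year)
  meas <- which(!is.na(s$dbh_cm) & !is.na(s$hom_m) &
                  s$status %in% LIVING_STATUSES)
  ev <- list()
  if (length(meas) >= 2) {
    for (k in 2:length(meas)) {
      i <- meas[k]; j <- meas[k - 1]
      if (s$hom_m[i] > s$hom_m[j]) {
        adjacent <- (i - j) == 1
        ev[[length(ev) + 1]] <- tibble::tibble(
          raise_campaign = s$campaign_year[i],
          hom_old = s$hom_m[j], hom_new = s$hom_m[i],
          dbh_before = s$dbh_cm[j], dbh_at = s$dbh_cm[i],
          ratio = if (adjacent) s$dbh_cm[i] / s$dbh_cm[j] else NA_real_)
      }
    }
  }
  if (!length(ev)) {
    return(tibble::tibble(raise_campaign = integer(0), hom_old = numeric(0),
                          hom_new = numeric(0), dbh_before = numeric(0),
                          dbh_at = numeric(0), ratio = numeric(0)))
  }
  dplyr::bind_rows(ev)
}

#' Convert raised-hom measurements to original-hom equivalents
#'
#' From the raise campaign onward, measured diameters are divided by the
#' taper ratio; successive raises chain, so the divisor is the product of
#' the ratios of all raises at or before the campaign. At the raise campaign
#' itself the converted value equals the previous campaign's value exactly
#' (a consequence of the ratio's definition), which keeps the equivalent
#' series continuous. An event with an undefined ratio (raise inside a gap)
#' breaks the chain and is left to [fill_gaps()].
#'
#' @param series A tree series.
#' @param events Output of [detect_hom_raises()].
#' @return Series with converted values (`provenance = "taper_converted"`,
#'   `hom_m` reset to the hom the values are now equivalent to).
#' @export
apply_taper_correction <- function(series, events = detect_hom_raises(series)) {
  s <- ensure_provenance(dplyr::arrange(series, .data$campaign_year))
  if (any(!is.na(events$ratio) & events$ratio <= 0)) {
    psp_stop("taper ratio must be positive", "psp_correction_error")
  }
  if (any(!is.na(events$ratio) & events$ratio > 1.5)) {
    warning("taper ratio above the 1.5 sanity bound; applied as measured",
            call. = FALSE)
  }
  meas <- which(!is.na(s$dbh_cm) & !is.na(s$hom_m) &
                  s$status %in% LIVING_STATUSES)
  if (length(meas) < 2) return(s)
  raw_hom <- s$hom_m # compare recorded homs, not already-converted ones
  div <- 1
  equiv_hom <- raw_hom[meas[1]]
  for (k in 2:length(meas)) {
    i <- meas[k]; j <- meas[k - 1]
    if (raw_hom[i] > raw_hom[j]) {
      ratio <- events$ratio[match(s$campaign_year[i], events$raise_campaign)]
      if (is.null(ratio)) ratio <- NA_real_
      if (length(ratio) && !is.na(ratio)) {
        div <- div * ratio
      } else {
        # raise inside a gap: conversion restarts at the new hom
        div <- 1
        equiv_hom <- raw_hom[i]
      }
    } else if (raw_hom[i] < raw_hom[j]) {
      div <- 1
      equiv_hom <- raw_hom[i]
    }
    if (div != 1) {
      s$dbh_cm[i] <- round_half_up(s$dbh_cm[i] / div, 0.1)
      s$provenance[i] <- "taper_converted"
    }
    s$hom_m[i] <- equiv_hom
  }
  s
}

#' Fill measurement gaps in a series
#'
#' For each maximal run of missing values between valid measurements
#' \eqn{d_a} (time a) and \eqn{d_b} (time b), the filling rule depends on
#' the sign of the increment: positive — linear interpolation in decimal
#' time; negative with a hom raise inside the gap — the taper-ratio
#' procedure between the two valid measurements at different homs (the
#' ratio then also converts every later raised-hom value); negative without
#' a raise — the last valid value is carried forward (including to b);
#' zero — constant fill. Leading and trailing missing runs have no flanking
#' pair and are left unfilled (`provenance = "unfilled"`).
#'
#' @param series A tree series (re-born intervals already resolved;
#'   adjacent-raise conversions already applied).
#' @return A hole-free series between the first and last valid measurement.
#' @export
fill_gaps <- function(series) {
  s <- ensure_provenance(dplyr::arrange(series, .data$campaign_year))
  tt <- decimal_year(s$census_date)
  # scan stops at a terminal death record
  dead <- which(!is.na(s$status) & s$status == "dead")
  last_row <- if (length(dead)) min(dead) - 1 else nrow(s)
  scope <- seq_len(last_row)
  valid <- scope[!is.na(s$dbh_cm[scope])]
  if (length(valid) == 0) return(s)
  in_hom <- s$hom_m # homs as given on input (raise comparisons use these)
  gap_div <- 1
  frame_hom <- NA_real_ # hom the gap-taper-converted values are expressed at
  for (k in seq_along(valid)) {
    b <- valid[k]
    if (gap_div != 1) {
      s$dbh_cm[b] <- round_half_up(s$dbh_cm[b] / gap_div, 0.1)
      s$provenance[b] <- "taper_converted"
      s$hom_m[b] <- frame_hom
    }
    if (k == 1) next
    a <- valid[k - 1]
    gap <- setdiff(seq(a, b), c(a, b))
    if (!length(gap)) next
    v_a <- s$dbh_cm[a]
    v_b <- s$dbh_cm[b]
    raised <- !is.na(in_hom[a]) && !is.na(in_hom[b]) &&
      in_hom[b] > in_hom[a]
    if (v_b > v_a) {
      f <- (tt[gap] - tt[a]) / (tt[b] - tt[a])
      s$dbh_cm[gap] <- round_half_up(v_a + f * (v_b - v_a), 0.1)
      s$provenance[gap] <- "interpolated"
    } else if (v_b < v_a && raised) {
      ratio <- v_b / v_a
      if (ratio <= 0) psp_stop("taper ratio must be positive",
                               "psp_correction_error")
      gap_div <- gap_div * ratio
      if (is.na(frame_hom)) frame_hom <- s$hom_m[a]
      s$dbh_cm[b] <- v_a
      s$provenance[b] <- "taper_converted"
      s$hom_m[b] <- frame_hom
      s$dbh_cm[gap] <- v_a
      s$provenance[gap] <- "interpolated"
    } else if (v_b < v_a) {
      # negative increment, no raise: report the last valid value
      s$dbh_cm[gap] <- v_a
      s$provenance[gap] <- "carried_forward"
      s$dbh_cm[b] <- v_a
      s$provenance[b] <- "carried_forward"
    } else {
      s$dbh_cm[gap] <- v_a
      s$provenance[gap] <- "interpolated"
    }
    s$status[gap] <- "alive"
    s$hom_m[gap] <- s$hom_m[a]
  }
  lead <- scope[scope < min(valid) & is.na(s$dbh_cm[scope])]
  trail <- scope[scope > max(valid) & is.na(s$dbh_cm[scope])]
  s$provenance[c(lead, trail)] <- "unfilled"
  s
}

recompute_status <- function(series, recruit_threshold = 10) {
  s <- series
  liv <- s$status %in% c(LIVING_STATUSES, "missing") | is.na(s$status)
  dead <- !is.na(s$status) & s$status == "dead"
  recruited_at <- which(!is.na(s$dbh_cm) & s$dbh_cm >= recruit_threshold &
                          !dead)
  first_rec <- if (length(recruited_at)) min(recruited_at) else Inf
  s$status[liv & seq_len(nrow(s)) < first_rec & !is.na(s$dbh_cm)] <-
    "not_yet_recruited"
  s$status[liv & seq_len(nrow(s)) >= first_rec & !is.na(s$dbh_cm)] <- "alive"
  s
}

#' Correct one tree's diameter series
#'
#' The full deterministic pipeline: manual overrides, re-born back-fill,
#' taper-ratio conversion of hom raises (sequentially chained), and
#' increment-sign-dependent gap filling; statuses are then recomputed
#' against the database recruitment threshold. The output carries a
#' `provenance` column; `provenance == "raw"` if and only if the value
#' equals the raw measured dbh. Running the pipeline on an
#' already-corrected series (recognized by its provenance column) returns
#' it unchanged: corrected values are original-hom equivalents, so hom
#' raises must not be re-detected against the raw hom record.
#'
#' @param series A tree series from [tree_series()] (or any tibble with the
#'   measures columns plus `census_date`, one row per campaign).
#' @param overrides Optional manual-override table (`tree_id`,
#'   `campaign_year`, `dbh_cm`, `note`).
#' @param recruit_threshold Database recruitment threshold in cm (default 10).
#' @return The corrected series.
#' @export
correct_tree <- function(series, overrides = NULL, recruit_threshold = 10) {
  if ("provenance" %in% names(series) && is.null(overrides)) {
    return(recompute_status(series, recruit_threshold))
  }
  s <- dplyr::arrange(series, .data$campaign_year)
  s$provenance <- NULL
  s <- ensure_provenance(s)
  s <- apply_overrides(s, overrides)
  s <- backfill_reborn(s)
  s <- apply_taper_correction(s, detect_hom_raises(s))
  s <- fill_gaps(s)
  recompute_status(s, recruit_threshold)
}

#' Correct every tree of an archive
#'
#' Applies [correct_tree()] tree by tree and returns a corrected archive:
#' same ten-file schema with a `provenance` column in `measures`, corrected
#' `dbh_cm` values (raw girths are kept untouched) and recomputed statuses.
#'
#' @param archive A raw `census_archive`.
#' @param overrides Optional manual-override table.
#' @param recruit_threshold Database recruitment threshold in cm.
#' @return A corrected `census_archive`.
#' @export
correct_archive <- function(archive, overrides = NULL,
                            recruit_threshold = 10) {
  ms <- archive$measures
  if (!nrow(ms)) {
    out <- archive
    attr(out, "corrected") <- TRUE
    out$measures$provenance <- character(0)
    return(out)
  }
  pieces <- split(ms, ms$tree_id)
  corrected <- lapply(pieces, function(piece) {
    s <- expand_series_grid(piece, archive$inventories)
    s <- correct_tree(s, overrides, recruit_threshold)
    s$census_date <- NULL
    s
  })
  out_ms <- dplyr::bind_rows(corrected) |>
    dplyr::arrange(.data$tree_id, .data$campaign_year)
  # derived values surface in the method column too (manual overrides keep
  # the field method)
  derived <- c("taper_converted", "interpolated", "carried_forward",
               "reborn_backfill")
  out_ms$method <- ifelse(out_ms$provenance %in% derived, out_ms$provenance,
                          out_ms$method)
  arc <- census_archive(tree = archive$tree, taxonomy = archive$taxonomy,
                        vernacular = archive$vernacular,
                        trees_context = archive$trees_context,
                        measures = out_ms, inventories = archive$inventories,
                        observation_codes = archive$observation_codes,
                        mortality_codes = archive$mortality_codes,
                        plots = archive$plots, subplots = archive$subplots,
                        corrected = TRUE)
  arc
}
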