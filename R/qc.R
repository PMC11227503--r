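# Post-campaign anomaly screening: each campaign is compared with the
# previous inventory campaign, reproducing the three check families used
# after every field campaign: (1) living-tree inconsistencies (excessive
# growth or decline, re-born trees), (2) unauthorized or doubtful values
# (under-threshold recruits, diameter increase despite a hom raise),
# (3) missing data.

#' Quality-control thresholds
#'
#' Annualized diameter-increment limits for living trees and the database
#' recruitment threshold. The defaults are the operational values: growth
#' above +2 cm/yr or below -0.6 cm/yr is anomalous; recruits must enter at
#' 10 cm dbh or more. Comparisons are strict (`>`, `<`).
#'
#' @param max_growth_cm_per_yr Upper increment limit (default 2).
#' @param min_growth_cm_per_yr Lower increment limit (default -0.6).
#' @param recruit_min_dbh_cm Database recruitment threshold (default 10).
#' @return A named list of thresholds.
#' @export
qc_thresholds <- function(max_growth_cm_per_yr = 2,
                          min_growth_cm_per_yr = -0.6,
                          recruit_min_dbh_cm = 10) {
  if (!(max_growth_cm_per_yr > 0 && min_growth_cm_per_yr < 0)) {
    psp_stop("max_growth must be > 0 > min_growth", "psp_domain_error")
  }
  list(max_growth_cm_per_yr = max_growth_cm_per_yr,
       min_growth_cm_per_yr = min_growth_cm_per_yr,
       recruit_min_dbh_cm = recruit_min_dbh_cm)
}

qc_severity <- function(rule_id) {
  dplyr::case_when(
    rule_id %in% c("REBORN", "UNAUTHORIZED_VALUE", "RECRUIT_UNDER_10") ~ "block",
    TRUE ~ "review"
  )
}

empty_flags <- function() {
  tibble::tibble(tree_id = character(0), campaign_year = integer(0),
                 rule_id = character(0), severity = character(0),
                 detail = character(0))
}

# all flags for all campaigns, vectorized; screening never modifies the archive
qc_flags_all <- function(archive, thresholds = qc_thresholds()) {
  ms <- archive$measures
  inv <- dplyr::arrange(archive$inventories, .data$campaign_year)
  if (!nrow(ms) || !nrow(inv)) return(empty_flags())
  years <- inv$campaign_year
  tvec <- decimal_year(inv$census_date)
  prev_of <- stats::setNames(c(NA, years[-length(years)]), years)
  time_of <- stats::setNames(tvec, years)

  living <- c("alive", "not_yet_recruited")
  m <- ms |>
    dplyr::select("tree_id", "campaign_year", "dbh_cm", "hom_m", "status") |>
    dplyr::arrange(.data$tree_id, .data$campaign_year)
  m$prev_year <- unname(prev_of[as.character(m$campaign_year)])

  # self-join each record to the tree's record at the previous campaign
  prev <- m |>
    dplyr::select("tree_id", prev_year = "campaign_year",
                  dbh_prev = "dbh_cm", hom_prev = "hom_m",
                  status_prev = "status")
  pair <- dplyr::left_join(m, prev, by = c("tree_id", "prev_year"))
  first_year <- m |>
    dplyr::group_by(.data$tree_id) |>
    dplyr::summarise(first_campaign = min(.data$campaign_year),
                     .groups = "drop")
  pair <- dplyr::left_join(pair, first_year, by = "tree_id")
  dt <- unname(time_of[as.character(pair$campaign_year)] -
                 time_of[as.character(pair$prev_year)])

  flags <- list()
  emit <- function(sel, rule, detail) {
    if (!any(sel)) return()
    flags[[length(flags) + 1]] <<- tibble::tibble(
      tree_id = pair$tree_id[sel],
      campaign_year = pair$campaign_year[sel],
      rule_id = rule, severity = qc_severity(rule), detail = detail[sel])
  }

  both_living <- pair$status %in% living & pair$status_prev %in% living
  both_meas <- !is.na(pair$dbh_cm) & !is.na(pair$dbh_prev)
  same_hom <- !is.na(pair$hom_m) & !is.na(pair$hom_prev) &
    pair$hom_m == pair$hom_prev
  inc <- (pair$dbh_cm - pair$dbh_prev) / dt

  # (1) increment checks between measurements at the same hom: increments
  # across a hom change are not comparable and are handled by the raise rule
  sel <- both_living & both_meas & same_hom & !is.na(inc) &
    inc > thresholds$max_growth_cm_per_yr
  emit(sel, "EXCESS_GROWTH",
       sprintf("dbh %.1f -> %.1f over %.2f yr (%.2f cm/yr > %.2f)",
               pair$dbh_prev, pair$dbh_cm, dt, inc,
               thresholds$max_growth_cm_per_yr))
  sel <- both_living & both_meas & same_hom & !is.na(inc) &
    inc < thresholds$min_growth_cm_per_yr
  emit(sel, "EXCESS_DECLINE",
       sprintf("dbh %.1f -> %.1f over %.2f yr (%.2f cm/yr < %.2f)",
               pair$dbh_prev, pair$dbh_cm, dt, inc,
               thresholds$min_growth_cm_per_yr))

  # (1) re-born: previously considered dead, now recorded living
  sel <- pair$status %in% living & !is.na(pair$status_prev) &
    pair$status_prev == "dead"
  emit(sel, "REBORN",
       sprintf("recorded dead in %d but living in %d", pair$prev_year,
               pair$campaign_year))

  # (2) recruits entering the database below 10 cm dbh
  sel <- pair$campaign_year == pair$first_campaign & pair$status == "alive" &
    !is.na(pair$dbh_cm) & pair$dbh_cm < thresholds$recruit_min_dbh_cm
  emit(sel, "RECRUIT_UNDER_10",
       sprintf("recruit entering at %.1f cm dbh (< %.1f)", pair$dbh_cm,
               thresholds$recruit_min_dbh_cm))

  # (2) doubtful: diameter increases although the hom was raised
  sel <- both_living & both_meas & !is.na(pair$hom_m) & !is.na(pair$hom_prev) &
    pair$hom_m > pair$hom_prev & pair$dbh_cm > pair$dbh_prev
  emit(sel, "HOM_RAISE_INCREASE",
       sprintf("dbh %.1f -> %.1f while hom raised %.2f -> %.2f m",
               pair$dbh_prev, pair$dbh_cm, pair$hom_prev, pair$hom_m))

  # (2) unauthorized values
  sel <- pair$status %in% living & !is.na(pair$dbh_cm) & pair$dbh_cm <= 0
  emit(sel, "UNAUTHORIZED_VALUE",
       sprintf("non-positive dbh %.1f for a living tree", pair$dbh_cm))
  sel <- !is.na(pair$hom_m) & pair$hom_m < 1.5
  emit(sel, "UNAUTHORIZED_VALUE",
       sprintf("hom %.2f m below the 1.50 m minimum", pair$hom_m))

  # (3) missing data: a living record with no measurement, or a living tree
  # absent from the campaign that follows one where it was recorded living
  sel <- pair$status %in% living & is.na(pair$dbh_cm)
  emit(sel, "MISSING_DATA",
       rep("living record with no diameter measurement", nrow(pair)))
  present <- paste0(m$tree_id, "@", m$campaign_year)
  cand <- m[m$status %in% living & !is.na(m$campaign_year), ]
  nxt <- stats::setNames(c(years[-1], NA), years)
  cand$next_year <- unname(nxt[as.character(cand$campaign_year)])
  cand <- cand[!is.na(cand$next_year), ]
  gone <- !paste0(cand$tree_id, "@", cand$next_year) %in% present
  if (any(gone)) {
    flags[[length(flags) + 1]] <- tibble::tibble(
      tree_id = cand$tree_id[gone],
      campaign_year = as.integer(cand$next_year[gone]),
      rule_id = "MISSING_DATA", severity = "review",
      detail = sprintf("tree recorded living in %d has no record in %d",
                       cand$campaign_year[gone], cand$next_year[gone]))
  }

  out <- if (length(flags)) dplyr::bind_rows(flags) else empty_flags()
  # deterministic ordering: campaign, plot, subplot, tree number, rule
  out |>
    tidyr::separate_wider_delim("tree_id", "_",
                                names = c("p", "s", "n"),
                                cols_remove = FALSE, too_few = "align_start") |>
    dplyr::arrange(.data$campaign_year, .data$p, .data$s, .data$n,
                   .data$rule_id) |>
    dplyr::select("tree_id", "campaign_year", "rule_id", "severity", "detail")
}

#' Screen one campaign against its predecessor
#'
#' Runs the post-campaign checks for `campaign_year`, comparing every tree's
#' record with the previous inventory campaign: excessive annualized growth
#' or decline (decimal-year interval), re-born trees, under-threshold
#' recruits, diameter increases despite a hom raise, unauthorized values and
#' missing data. For the first campaign only the single-campaign rules run.
#'
#' @param archive A `census_archive` (raw; screening precedes correction).
#' @param campaign_year A campaign present in the archive.
#' @param thresholds See [qc_thresholds()].
#' @return Tibble of flags: `tree_id`, `campaign_year`, `rule_id`,
#'   `severity` (`block`/`review`), `detail`.
#' @export
screen_campaign <- function(archive, campaign_year,
                            thresholds = qc_thresholds()) {
  if (!campaign_year %in% archive$inventories$campaign_year) {
    psp_stop(sprintf("campaign %s is not in the archive", campaign_year),
             "psp_domain_error")
  }
  qc_flags_all(archive, thresholds) |>
    dplyr::filter(.data$campaign_year == !!as.integer(campaign_year))
}

#' Screen every campaign of an archive
#'
#' [screen_campaign()] applied over all campaigns in chronological order,
#' with deterministic row ordering (campaign, plot, subplot, tree number,
#' rule). Screening is read-only.
#'
#' @inheritParams screen_campaign
#' @return Tibble of flags (possibly zero rows).
#' @export
screen_archive <- function(archive, thresholds = qc_thresholds()) {
  qc_flags_all(archive, thresholds)
}
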