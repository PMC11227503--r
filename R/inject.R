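# QC test harness: deterministic injection of known anomalies into a clean
# synthetic archive. Each injection perturbs the series as a persistent
# level shift (all subsequent campaigns move together), so exactly one
# campaign's increment violates the rule being planted and neighbouring
# intervals stay clean.

eligible_pairs <- function(archive) {
  inv <- dplyr::arrange(archive$inventories, .data$campaign_year)
  years <- inv$campaign_year
  tvec <- decimal_year(inv$census_date)
  ms <- archive$measures |>
    dplyr::arrange(.data$tree_id, .data$campaign_year)
  ms$k <- match(ms$campaign_year, years)
  prev <- ms |>
    dplyr::transmute(.data$tree_id, k = .data$k + 1L,
                     dbh_prev = .data$dbh_cm, hom_prev = .data$hom_m,
                     status_prev = .data$status)
  pair <- dplyr::inner_join(ms, prev, by = c("tree_id", "k"))
  pair$dt <- tvec[pair$k] - tvec[pair$k - 1]
  pair[pair$status %in% c("alive", "not_yet_recruited") &
         pair$status_prev %in% c("alive", "not_yet_recruited") &
         !is.na(pair$dbh_cm) & !is.na(pair$dbh_prev) &
         !is.na(pair$hom_m) & !is.na(pair$hom_prev) &
         pair$hom_m == pair$hom_prev, , drop = FALSE]
}

shift_from <- function(measures, tree_id, campaign_year, bump) {
  sel <- measures$tree_id == tree_id &
    measures$campaign_year >= campaign_year & !is.na(measures$dbh_cm)
  measures$dbh_cm[sel] <- round_half_up(measures$dbh_cm[sel] + bump, 0.1)
  measures$girth_cm[sel] <- dbh_to_gbh(measures$dbh_cm[sel])
  measures
}

#' Inject known anomalies into an archive
#'
#' Plants the requested number of each anomaly family — growth spikes
#' beyond +2 cm/yr, declines beyond -0.6 cm/yr, recruits entering below
#' 10 cm dbh, and diameter increases concurrent with a hom raise — and logs
#' every injection. Each tree receives at most one injection. A shortfall
#' (not enough eligible trees) is reported in the returned log attribute.
#'
#' @param archive A raw `census_archive` (a clean simulated one, for a
#'   round-trip with [screen_archive()]).
#' @param n_growth,n_decline,n_recruit_under,n_hom_increase Counts per rule.
#' @param seed Integer seed controlling the random placement.
#' @return List with `archive` (modified copy) and `log`, a tibble
#'   `tree_id`, `campaign_year`, `rule_id`.
#' @export
inject_anomalies <- function(archive, n_growth = 0, n_decline = 0,
                             n_recruit_under = 0, n_hom_increase = 0,
                             seed = 1L) {
  set.seed(seed)
  ms <- archive$measures
  log <- list()
  used_trees <- character(0)
  shortfall <- character(0)

  pairs <- eligible_pairs(archive)
  first_year <- min(archive$inventories$campaign_year)

  draw_pairs <- function(n, extra_filter = TRUE) {
    cand <- pairs[extra_filter & !pairs$tree_id %in% used_trees, ,
                  drop = FALSE]
    cand <- cand[!duplicated(cand$tree_id), , drop = FALSE]
    if (nrow(cand) < n) return(NULL)
    cand[sample.int(nrow(cand), n), , drop = FALSE]
  }

  if (n_growth > 0) {
    pick <- draw_pairs(n_growth)
    if (is.null(pick)) shortfall <- c(shortfall, "EXCESS_GROWTH") else {
      for (j in seq_len(nrow(pick))) {
        bump <- 3 * pick$dt[j] - (pick$dbh_cm[j] - pick$dbh_prev[j])
        ms <- shift_from(ms, pick$tree_id[j], pick$campaign_year[j], bump)
        log[[length(log) + 1]] <- tibble::tibble(
          tree_id = pick$tree_id[j], campaign_year = pick$campaign_year[j],
          rule_id = "EXCESS_GROWTH")
      }
      used_trees <- c(used_trees, pick$tree_id)
    }
  }

  if (n_decline > 0) {
    pick <- draw_pairs(n_decline, pairs$dbh_prev >= 15)
    if (is.null(pick)) shortfall <- c(shortfall, "EXCESS_DECLINE") else {
      for (j in seq_len(nrow(pick))) {
        bump <- -1.5 * pick$dt[j] - (pick$dbh_cm[j] - pick$dbh_prev[j])
        ms <- shift_from(ms, pick$tree_id[j], pick$campaign_year[j], bump)
        log[[length(log) + 1]] <- tibble::tibble(
          tree_id = pick$tree_id[j], campaign_year = pick$campaign_year[j],
          rule_id = "EXCESS_DECLINE")
      }
      used_trees <- c(used_trees, pick$tree_id)
    }
  }

  if (n_hom_increase > 0) {
    pick <- draw_pairs(n_hom_increase, pairs$hom_m == 1.5)
    if (is.null(pick)) shortfall <- c(shortfall, "HOM_RAISE_INCREASE") else {
      for (j in seq_len(nrow(pick))) {
        # raise the hom from this campaign on; force a (modest) increase
        sel <- ms$tree_id == pick$tree_id[j] &
          ms$campaign_year >= pick$campaign_year[j] & !is.na(ms$hom_m)
        ms$hom_m[sel] <- 4.5
        if (pick$dbh_cm[j] <= pick$dbh_prev[j]) {
          bump <- pick$dbh_prev[j] - pick$dbh_cm[j] + 0.3
          ms <- shift_from(ms, pick$tree_id[j], pick$campaign_year[j], bump)
        }
        log[[length(log) + 1]] <- tibble::tibble(
          tree_id = pick$tree_id[j], campaign_year = pick$campaign_year[j],
          rule_id = "HOM_RAISE_INCREASE")
      }
      used_trees <- c(used_trees, pick$tree_id)
    }
  }

  if (n_recruit_under > 0) {
    # recruits: first record after the first campaign, next increment small
    firsts <- ms |>
      dplyr::filter(!.data$tree_id %in% used_trees) |>
      dplyr::group_by(.data$tree_id) |>
      dplyr::arrange(.data$campaign_year, .by_group = TRUE) |>
      dplyr::summarise(first_campaign = dplyr::first(.data$campaign_year),
                       d1 = dplyr::first(.data$dbh_cm),
                       d2 = dplyr::nth(.data$dbh_cm, 2),
                       .groups = "drop") |>
      dplyr::filter(.data$first_campaign > first_year, !is.na(.data$d1),
                    !is.na(.data$d2), .data$d2 < 11.5)
    if (nrow(firsts) < n_recruit_under) {
      shortfall <- c(shortfall, "RECRUIT_UNDER_10")
    } else {
      pick <- firsts[sample.int(nrow(firsts), n_recruit_under), ]
      for (j in seq_len(nrow(pick))) {
        sel <- ms$tree_id == pick$tree_id[j] &
          ms$campaign_year == pick$first_campaign[j]
        ms$dbh_cm[sel] <- 9.8
        ms$girth_cm[sel] <- dbh_to_gbh(9.8)
        ms$status[sel] <- "alive"
        log[[length(log) + 1]] <- tibble::tibble(
          tree_id = pick$tree_id[j],
          campaign_year = pick$first_campaign[j],
          rule_id = "RECRUIT_UNDER_10")
      }
      used_trees <- c(used_trees, pick$tree_id)
    }
  }

  out <- archive
  out$measures <- ms
  log_tbl <- if (length(log)) dplyr::bind_rows(log) else
    tibble::tibble(tree_id = character(0), campaign_year = integer(0),
                   rule_id = character(0))
  attr(log_tbl, "shortfall") <- shortfall
  list(archive = out, log = log_tbl)
}
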