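# Plot-level forest dynamics: stem density N (ha^-1), basal area G
# (m^2 ha^-1), and annualized mortality and recruitment rates (% yr^-1)
# per plot or subplot over the campaign sequence.
#
# Annualization uses the survival-fraction power form (the
# exponential-equivalent per-capita rate), correct across multi-year census
# gaps; the simple D/(N0*dt) estimator is available for comparison.

#' Database recruitment campaign of a corrected series
#'
#' A tree is recruited in the database at the first campaign at which its
#' dbh reaches the threshold (10 cm by default); trees measured in the
#' field from 30 cm gbh (9.5 cm dbh) are present but unrecruited below it.
#'
#' @param series A corrected, hole-free tree series (tibble with
#'   `campaign_year`, `dbh_cm`).
#' @param threshold Recruitment threshold in cm dbh.
#' @return The recruitment campaign year, or `NA` if never reached.
#' @export
recruitment_campaign <- function(series, threshold = 10) {
  s <- dplyr::arrange(series, .data$campaign_year)
  hit <- which(!is.na(s$dbh_cm) & s$dbh_cm >= threshold)
  if (!length(hit)) return(NA_integer_)
  as.integer(s$campaign_year[min(hit)])
}

# per-tree demography summary: recruitment campaign, death campaign, unit
tree_demography <- function(archive, threshold = 10) {
  ms <- archive$measures
  tr <- archive$tree
  demo <- ms |>
    dplyr::group_by(.data$tree_id) |>
    dplyr::summarise(
      recruit_campaign = {
        ok <- !is.na(.data$dbh_cm) & .data$dbh_cm >= threshold &
          .data$status != "dead"
        if (any(ok)) min(.data$campaign_year[ok]) else NA_integer_
      },
      death_campaign = {
        d <- .data$status == "dead"
        if (any(d, na.rm = TRUE)) min(.data$campaign_year[d], na.rm = TRUE)
        else NA_integer_
      },
      .groups = "drop")
  dplyr::left_join(demo, tr[c("tree_id", "plot_no", "subplot_no")],
                   by = "tree_id")
}

unit_area_ha <- function(archive, level) {
  if (level == "plot") {
    tibble::tibble(plot_no = archive$plots$plot_no,
                   area_ha = archive$plots$area_ha)
  } else {
    tibble::tibble(plot_no = archive$subplots$plot_no,
                   subplot_no = archive$subplots$subplot_no,
                   area_ha = archive$subplots$area_ha)
  }
}

#' Stand state (N, G) of a unit at a campaign
#'
#' N is the number of alive, recruited trees per hectare; G is the sum of
#' cross-sectional areas at breast height per hectare,
#' \eqn{G = \sum \pi (d/200)^2 / A} with d in cm and A in ha, giving
#' m^2 ha^-1. A tree counts from its recruitment campaign (first campaign
#' with dbh at or above the threshold) until its death record.
#'
#' @param archive A corrected `census_archive`.
#' @param plot_no Plot number of the unit.
#' @param subplot_no Subplot number, or `NULL` for the whole 4-ha plot.
#' @param campaign_year Campaign to evaluate.
#' @param threshold Recruitment threshold in cm dbh (default 10; 9.5
#'   reproduces the field-threshold variant).
#' @return One-row tibble: unit columns, `campaign_year`, `N_per_ha`,
#'   `G_m2_per_ha`.
#' @export
stand_state <- function(archive, plot_no, subplot_no = NULL, campaign_year,
                        threshold = 10) {
  level <- if (is.null(subplot_no)) "plot" else "subplot"
  tab <- dynamics_table(archive, level = level, threshold = threshold)
  row <- tab[tab$plot_no == plot_no & tab$campaign_year == campaign_year, ]
  if (level == "subplot") row <- row[row$subplot_no == subplot_no, ]
  if (!nrow(row)) {
    psp_stop("unknown unit or campaign", "psp_domain_error")
  }
  row[c(names(row)[names(row) %in% c("plot_no", "subplot_no")],
        "campaign_year", "N_per_ha", "G_m2_per_ha")]
}

annualize <- function(frac, dt, estimator) {
  if (estimator == "power") (1 - frac^(1 / dt)) * 100 else NA_real_
}

#' Demographic rates of a unit over one census interval
#'
#' With \eqn{N_0} alive recruited trees at campaign a, S survivors at b,
#' and R trees recruited in (a, b] and alive at b (\eqn{N_b = S + R}):
#' mortality \eqn{= (1 - (S/N_0)^{1/\Delta t}) \times 100} and recruitment
#' \eqn{= (1 - ((N_b - R)/N_b)^{1/\Delta t}) \times 100}, both in % per
#' year with \eqn{\Delta t} the decimal-year census interval. The simple
#' estimators \eqn{D/(N_0 \Delta t)} and \eqn{R/(N_b \Delta t)} are
#' available via `estimator = "simple"`. Rates are undefined (NA) when the
#' corresponding denominator is zero. Trees that would be recruited and die
#' within the same interval never enter the recruited-alive population at a
#' census and count in neither R nor D.
#'
#' @inheritParams stand_state
#' @param campaign_a,campaign_b Two consecutive campaigns of the archive.
#' @param estimator `"power"` (default) or `"simple"`.
#' @return One-row tibble with the interval, counts and rates.
#' @export
demographic_rates <- function(archive, plot_no, subplot_no = NULL,
                              campaign_a, campaign_b, threshold = 10,
                              estimator = c("power", "simple")) {
  estimator <- match.arg(estimator)
  inv_years <- sort(archive$inventories$campaign_year)
  ib <- match(campaign_b, inv_years)
  if (is.na(ib) || ib < 2 || inv_years[ib - 1] != campaign_a) {
    psp_stop("campaigns must be consecutive in the archive",
             "psp_domain_error")
  }
  level <- if (is.null(subplot_no)) "plot" else "subplot"
  tab <- dynamics_table(archive, level = level, threshold = threshold,
                        estimator = estimator)
  row <- tab[tab$plot_no == plot_no & tab$campaign_year == campaign_b, ]
  if (level == "subplot") row <- row[row$subplot_no == subplot_no, ]
  if (!nrow(row)) {
    psp_stop("unknown unit or interval", "psp_domain_error")
  }
  cols <- c(names(row)[names(row) %in% c("plot_no", "subplot_no")],
            "campaign_year", "interval_years", "n_initial", "n_final",
            "n_deaths", "n_recruits", "mortality_pct_yr",
            "recruitment_pct_yr")
  out <- row[cols]
  out$campaign_a <- as.integer(campaign_a)
  out
}

#' Forest-dynamics table over all campaigns
#'
#' Chronological stand states and interval demographic rates per unit:
#' stem density, basal area, annualized mortality and recruitment with
#' event counts. Rates at a campaign refer to the interval ending there;
#' the first campaign has none.
#'
#' @param archive A corrected `census_archive` (any hole-free archive
#'   works; demographic counts do not depend on gap-filled diameters).
#' @param level `"plot"` (4-ha) or `"subplot"` (1-ha).
#' @param threshold Recruitment threshold in cm dbh.
#' @param estimator `"power"` (default) or `"simple"` annualization.
#' @return Tibble with one row per unit and campaign: `plot_no`
#'   (`subplot_no`), `campaign_year`, `N_per_ha`, `G_m2_per_ha`,
#'   `interval_years`, `n_initial`, `n_final`, `n_deaths`, `n_recruits`,
#'   `mortality_pct_yr`, `recruitment_pct_yr`.
#' @export
dynamics_table <- function(archive, level = c("plot", "subplot"),
                           threshold = 10,
                           estimator = c("power", "simple")) {
  level <- match.arg(level)
  estimator <- match.arg(estimator)
  inv <- dplyr::arrange(archive$inventories, .data$campaign_year)
  years <- inv$campaign_year
  times <- decimal_year(inv$census_date)
  demo <- tree_demography(archive, threshold)
  units <- unit_area_ha(archive, level)
  keys <- if (level == "plot") "plot_no" else c("plot_no", "subplot_no")

  ms <- archive$measures |>
    dplyr::select("tree_id", "campaign_year", "dbh_cm") |>
    dplyr::inner_join(demo, by = "tree_id")

  per_campaign <- vector("list", length(years))
  for (k in seq_along(years)) {
    y <- years[k]
    standing <- demo[!is.na(demo$recruit_campaign) &
                       demo$recruit_campaign <= y &
                       (is.na(demo$death_campaign) | demo$death_campaign > y), ]
    mrows <- ms[ms$campaign_year == y &
                  ms$tree_id %in% standing$tree_id, , drop = FALSE]
    st <- mrows |>
      dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
      dplyr::summarise(n_standing = dplyr::n(),
                       ba_m2 = sum(pi * (.data$dbh_cm / 200)^2, na.rm = TRUE),
                       .groups = "drop")
    prev <- if (k > 1) years[k - 1] else NA_integer_
    ev <- demo |>
      dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
      dplyr::summarise(
        n_deaths = if (is.na(prev)) NA_integer_ else
          sum(!is.na(.data$death_campaign) & .data$death_campaign == y &
                !is.na(.data$recruit_campaign) & .data$recruit_campaign <= prev),
        n_recruits = if (is.na(prev)) NA_integer_ else
          sum(!is.na(.data$recruit_campaign) & .data$recruit_campaign == y &
                (is.na(.data$death_campaign) | .data$death_campaign > y)),
        .groups = "drop")
    st <- dplyr::full_join(st, ev, by = keys)
    st$campaign_year <- y
    per_campaign[[k]] <- st
  }
  out <- dplyr::bind_rows(per_campaign) |>
    dplyr::right_join(tidyr::crossing(units[keys],
                                      campaign_year = years), by = c(keys, "campaign_year")) |>
    dplyr::left_join(units, by = keys) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(keys, "campaign_year"))))
  out$n_standing[is.na(out$n_standing)] <- 0L
  out$ba_m2[is.na(out$ba_m2)] <- 0
  out$N_per_ha <- out$n_standing / out$area_ha
  out$G_m2_per_ha <- out$ba_m2 / out$area_ha

  # interval rates
  out <- out |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::arrange(.data$campaign_year, .by_group = TRUE) |>
    dplyr::mutate(n_initial = dplyr::lag(.data$n_standing),
                  n_final = .data$n_standing) |>
    dplyr::ungroup()
  # interval length: decimal years between this campaign and the previous one
  idx <- match(out$campaign_year, years)
  out$interval_years <- ifelse(idx > 1, times[idx] - times[pmax(idx - 1, 1)],
                               NA_real_)
  surv <- out$n_initial - out$n_deaths
  prev_pop <- out$n_final - out$n_recruits
  if (estimator == "power") {
    out$mortality_pct_yr <- ifelse(
      !is.na(out$n_initial) & out$n_initial > 0,
      (1 - (surv / out$n_initial)^(1 / out$interval_years)) * 100, NA_real_)
    out$recruitment_pct_yr <- ifelse(
      !is.na(out$n_final) & out$n_final > 0,
      (1 - (prev_pop / out$n_final)^(1 / out$interval_years)) * 100, NA_real_)
  } else {
    out$mortality_pct_yr <- ifelse(
      !is.na(out$n_initial) & out$n_initial > 0,
      out$n_deaths / (out$n_initial * out$interval_years) * 100, NA_real_)
    out$recruitment_pct_yr <- ifelse(
      !is.na(out$n_final) & out$n_final > 0,
      out$n_recruits / (out$n_final * out$interval_years) * 100, NA_real_)
  }
  out[c(keys, "campaign_year", "N_per_ha", "G_m2_per_ha", "interval_years",
        "n_initial", "n_final", "n_deaths", "n_recruits",
        "mortality_pct_yr", "recruitment_pct_yr")]
}

#' Four-panel dynamics figure
#'
#' Stem density, basal area, mortality and recruitment trajectories per
#' unit, faceted, mirroring the classic presentation of long-term plot
#' monitoring.
#'
#' @param dyn Output of [dynamics_table()].
#' @return A ggplot object.
#' @export
plot_dynamics <- function(dyn) {
  keys <- intersect(c("plot_no", "subplot_no"), names(dyn))
  dyn$unit <- do.call(paste, c(dyn[keys], sep = "_"))
  long <- dyn |>
    dplyr::select("unit", "campaign_year", "N_per_ha", "G_m2_per_ha",
                  "mortality_pct_yr", "recruitment_pct_yr") |>
    tidyr::pivot_longer(-c("unit", "campaign_year"), names_to = "panel") |>
    dplyr::mutate(panel = factor(.data$panel,
                                 levels = c("N_per_ha", "G_m2_per_ha",
                                            "mortality_pct_yr",
                                            "recruitment_pct_yr"),
                                 labels = c("N (ha^-1)", "G (m2 ha^-1)",
                                            "mortality (% yr^-1)",
                                            "recruitment (% yr^-1)")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$campaign_year, y = .data$value,
                                     colour = .data$unit)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "campaign year", y = NULL, colour = "unit") +
    ggplot2::theme_minimal()
}
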