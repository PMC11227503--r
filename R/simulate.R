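# Synthetic PSP census generator: an individual-based stand simulator
# (lognormal annual diameter growth, Bernoulli mortality with cause
# assignment, Poisson recruitment entering at the 30 cm gbh field
# threshold) behind an observation layer that emulates the census process —
# girth measurement with noise, 0.5 cm field rounding, hom raises with
# multiplicative taper, missing records, false-dead (re-born) episodes and
# the campaign calendar with its skipped years. Every divergence between
# truth and emitted observation is logged, so the ground truth is an oracle
# for every downstream module.

#' Simulation configuration
#'
#' Defaults describe an intact-forest control stand: three 4-ha control
#' plots (12 ha), initial density a little above 500 stems per hectare at
#' 10 cm dbh (a reverse-J size structure from a truncated exponential),
#' growth averaging 2 mm/yr, and mortality and recruitment both near
#' 1 %/yr — the regime of undisturbed tropical moist forest. Observation
#' defaults: 0.1 cm girth noise, 1% missing records, no false-dead
#' episodes (switch `p_false_dead` on to exercise the re-born path).
#'
#' @param seed Integer RNG seed; the simulation is fully deterministic
#'   given the seed.
#' @param plot_nos Plot numbers in `c(11:16, 21:24)`.
#' @param treatments Treatment per plot (`"control"`, `"logging"`,
#'   `"logging_thinning"`); metadata only, except that
#'   `disturbance_events` model the removal pulses.
#' @param campaign_years Census calendar (default: annual 1982-2022 minus
#'   the six skipped years).
#' @param initial_density_per_ha Initial stems/ha at >= 10 cm dbh.
#' @param init_dbh_scale_cm Scale of the truncated-exponential initial
#'   size distribution (dbh = 10 + Exp(scale)).
#' @param growth_mean_cm_yr,growth_sd_cm_yr Mean and sd of the lognormal
#'   annual dbh increment.
#' @param mortality_pct_yr,recruitment_pct_yr Demographic rates in % per
#'   year (recruitment is the entry stream at the field threshold,
#'   proportional to the standing >= 10 cm population).
#' @param mortality_cause_probs Named probabilities over the three causes.
#' @param p_hom_raise_per_yr Annual probability that a living tree's hom is
#'   raised (once, to 4.50 m).
#' @param taper_factor_range Range of the multiplicative girth reduction at
#'   the raised hom.
#' @param measurement_sd_cm Gaussian noise sd on the measured girth (cm).
#' @param p_missing_record Probability a living tree's record lacks its
#'   measurement in a campaign.
#' @param p_false_dead Per-campaign probability of starting a false-dead
#'   (re-born) episode of 1-2 campaigns.
#' @param recruit_entry_dbh_range True dbh range at which recruits enter.
#' @param disturbance_events Optional tibble `year`,
#'   `fraction_basal_area_removed`: stems are removed with probability
#'   proportional to basal-area share until the target fraction is reached
#'   (a stylized logging pulse, not a logging model).
#' @return A validated `psp_sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       plot_nos = c(11L, 14L, 21L),
                       treatments = rep("control", length(plot_nos)),
                       campaign_years = default_campaign_years(),
                       initial_density_per_ha = 520,
                       init_dbh_scale_cm = 13,
                       growth_mean_cm_yr = 0.2,
                       growth_sd_cm_yr = 0.15,
                       mortality_pct_yr = 1,
                       recruitment_pct_yr = 1,
                       mortality_cause_probs = c(standing_death = 0.5,
                                                 primary_treefall = 0.3,
                                                 secondary_treefall = 0.2),
                       p_hom_raise_per_yr = 0.005,
                       taper_factor_range = c(0.85, 0.98),
                       measurement_sd_cm = 0.1,
                       p_missing_record = 0.01,
                       p_false_dead = 0,
                       recruit_entry_dbh_range = c(9.5, 10),
                       disturbance_events = NULL) {
  cfg <- list(seed = as.integer(seed), plot_nos = as.integer(plot_nos),
              treatments = treatments,
              campaign_years = as.integer(campaign_years),
              initial_density_per_ha = initial_density_per_ha,
              init_dbh_scale_cm = init_dbh_scale_cm,
              growth_mean_cm_yr = growth_mean_cm_yr,
              growth_sd_cm_yr = growth_sd_cm_yr,
              mortality_pct_yr = mortality_pct_yr,
              recruitment_pct_yr = recruitment_pct_yr,
              mortality_cause_probs = mortality_cause_probs,
              p_hom_raise_per_yr = p_hom_raise_per_yr,
              taper_factor_range = taper_factor_range,
              measurement_sd_cm = measurement_sd_cm,
              p_missing_record = p_missing_record,
              p_false_dead = p_false_dead,
              recruit_entry_dbh_range = recruit_entry_dbh_range,
              disturbance_events = disturbance_events)
  validate_sim_config(cfg)
  structure(cfg, class = "psp_sim_config")
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$p_hom_raise_per_yr, cfg$p_missing_record, cfg$p_false_dead,
             cfg$mortality_pct_yr / 100, cfg$recruitment_pct_yr / 100)
  if (any(probs < 0 | probs > 1)) {
    psp_stop("probabilities/rates must lie in [0,1] (rates in [0,100] %/yr)",
             "psp_config_error")
  }
  if (cfg$initial_density_per_ha <= 0) {
    psp_stop("initial density must be positive", "psp_config_error")
  }
  if (any(diff(cfg$campaign_years) <= 0)) {
    psp_stop("campaign years must be strictly increasing", "psp_config_error")
  }
  if (!all(cfg$plot_nos %in% valid_plot_nos())) {
    psp_stop("plot numbers must lie in {11..16, 21..24}", "psp_config_error")
  }
  if (length(cfg$treatments) != length(cfg$plot_nos)) {
    psp_stop("one treatment per plot is required", "psp_config_error")
  }
  tf <- cfg$taper_factor_range
  if (length(tf) != 2 || tf[1] <= 0 || tf[2] < tf[1] || tf[2] > 1.5) {
    psp_stop("taper_factor_range must be within (0, 1.5]", "psp_config_error")
  }
  abs(sum(cfg$mortality_cause_probs) - 1) < 1e-9 ||
    psp_stop("mortality cause probabilities must sum to 1", "psp_config_error")
  invisible(cfg)
}

# subplot spatial frames within the 200 m plot: 1 = SW, 2 = SE, 3 = NW, 4 = NE
subplot_origin <- function(subplot_no) {
  cbind(x = c(0, 100, 0, 100)[subplot_no], y = c(0, 0, 100, 100)[subplot_no])
}

simulate_taxonomy <- function() {
  fx <- load_valuable_species_fixture()
  valuable <- tibble::tibble(
    id_taxonomy = seq_len(36),
    sci_name_1991 = fx$species,
    sci_name_2010 = ifelse(is.na(fx$valid_name), fx$species, fx$valid_name),
    sci_name_2011 = ifelse(is.na(fx$valid_name), fx$species, fx$valid_name),
    valuable_code = fx$code,
    valuable_category = fx$category)
  others <- tibble::tibble(
    id_taxonomy = 36 + seq_len(20),
    sci_name_1991 = sprintf("Indet morphospecies %02d", seq_len(20)),
    sci_name_2010 = sprintf("Indet morphospecies %02d", seq_len(20)),
    sci_name_2011 = sprintf("Indet morphospecies %02d", seq_len(20)),
    valuable_code = NA_character_,
    valuable_category = "C")
  dplyr::bind_rows(valuable, others)
}

simulate_vernacular <- function() {
  fx <- load_valuable_species_fixture()
  tibble::tibble(id_vernacular = seq_len(36),
                 vernacular_name = fx$commercial_name,
                 issongo_name = fx$issongo_name,
                 id_taxonomy = seq_len(36))
}

#' Simulate a census archive with ground truth
#'
#' Runs the stand simulator and its observation layer and assembles the
#' ten-file archive plus an exhaustive ground-truth log. Deterministic
#' given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list with `archive` (a raw `census_archive`) and `truth`, a
#'   list of tibbles: `trees` (per-tree true death year/cause, hom-raise
#'   year and taper factor, entry and recruitment campaigns),
#'   `trajectories` (true dbh per observed tree and year), `false_dead`,
#'   `missing` (campaigns whose record lacks its measurement) and
#'   `removals` (disturbance removals).
#' @export
simulate_archive <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  cy <- config$campaign_years
  years <- seq(min(cy), max(cy))
  ny <- length(years)
  nc <- length(cy)
  camp_idx <- match(cy, years)

  plots <- config$plot_nos
  grid <- expand.grid(subplot_no = 1:4, plot_no = plots)[2:1]
  n_sub <- nrow(grid)
  n0 <- round(config$initial_density_per_ha)
  # stationary in-transit pool below the 10 cm database threshold: the
  # recruitment stream enters at the field threshold and takes
  # (10 - mean entry)/growth years to cross, so at equilibrium that band
  # holds inflow x transit-time trees (triangular density, thicker near 10)
  entry_lo <- config$recruit_entry_dbh_range[1]
  entry_mid <- mean(config$recruit_entry_dbh_range)
  transit_yr <- max(0, (10 - entry_mid) / config$growth_mean_cm_yr)
  n_pipe <- round(config$recruitment_pct_yr / 100 * n0 * transit_yr)
  n_init <- (n0 + n_pipe) * n_sub

  m <- config$growth_mean_cm_yr
  s <- config$growth_sd_cm_yr
  sdlog <- sqrt(log(1 + (s / m)^2))
  meanlog <- log(m) - sdlog^2 / 2

  cap <- n_init +
    ceiling(4 * config$recruitment_pct_yr / 100 * n_init * ny) + 100
  sub <- integer(cap); xs <- numeric(cap); ys <- numeric(cap)
  dbh <- rep(NA_real_, cap); alive <- logical(cap)
  birth_year <- rep(NA_integer_, cap)
  death_year <- rep(NA_integer_, cap); cause <- rep(NA_character_, cap)
  raise_year <- rep(NA_integer_, cap); taper <- rep(1, cap)
  traj <- matrix(NA_real_, cap, ny)
  n_used <- n_init

  grow_cap <- function(extra) {
    add <- max(extra, cap)
    sub <<- c(sub, integer(add)); xs <<- c(xs, numeric(add))
    ys <<- c(ys, numeric(add)); dbh <<- c(dbh, rep(NA_real_, add))
    alive <<- c(alive, logical(add))
    birth_year <<- c(birth_year, rep(NA_integer_, add))
    death_year <<- c(death_year, rep(NA_integer_, add))
    cause <<- c(cause, rep(NA_character_, add))
    raise_year <<- c(raise_year, rep(NA_integer_, add))
    taper <<- c(taper, rep(1, add))
    traj <<- rbind(traj, matrix(NA_real_, add, ny))
    cap <<- cap + add
  }

  init_idx <- seq_len(n_init)
  sub[init_idx] <- rep(seq_len(n_sub), each = n0 + n_pipe)
  off <- subplot_origin(grid$subplot_no[sub[init_idx]])
  xs[init_idx] <- round(off[, 1] + stats::runif(n_init, 0, 100), 1)
  ys[init_idx] <- round(off[, 2] + stats::runif(n_init, 0, 100), 1)
  main <- rep(c(TRUE, FALSE), times = c(n0, n_pipe))
  is_main <- rep(main, n_sub)
  dbh[init_idx[is_main]] <-
    10 + stats::rexp(sum(is_main), 1 / config$init_dbh_scale_cm)
  if (any(!is_main)) {
    dbh[init_idx[!is_main]] <-
      entry_lo + (10 - entry_lo) * sqrt(stats::runif(sum(!is_main)))
  }
  alive[init_idx] <- TRUE
  birth_year[init_idx] <- years[1]
  traj[init_idx, 1] <- dbh[init_idx]

  removals <- list()
  dist_years <- if (is.null(config$disturbance_events)) integer(0) else
    config$disturbance_events$year

  for (t in 2:ny) {
    y <- years[t]
    idx <- which(alive)
    dbh[idx] <- dbh[idx] + stats::rlnorm(length(idx), meanlog, sdlog)

    if (y %in% dist_years) {
      frac <- config$disturbance_events$fraction_basal_area_removed[
        match(y, config$disturbance_events$year)]
      cand <- which(alive & dbh >= 10)
      if (length(cand)) {
        w <- dbh[cand]^2
        ord <- cand[sample.int(length(cand), prob = w)]
        k <- min(which(cumsum(dbh[ord]^2) >= frac * sum(w)))
        rem <- ord[seq_len(k)]
        alive[rem] <- FALSE
        death_year[rem] <- y
        cause[rem] <- "primary_treefall"
        removals[[length(removals) + 1]] <-
          tibble::tibble(sim_index = rem, year = y)
      }
    }

    idx <- which(alive)
    die <- stats::runif(length(idx)) < config$mortality_pct_yr / 100
    if (any(die)) {
      dd <- idx[die]
      alive[dd] <- FALSE
      death_year[dd] <- y
      cause[dd] <- sample(names(config$mortality_cause_probs), length(dd),
                          replace = TRUE, prob = config$mortality_cause_probs)
    }

    idx <- which(alive & is.na(raise_year))
    up <- stats::runif(length(idx)) < config$p_hom_raise_per_yr
    if (any(up)) {
      rr <- idx[up]
      raise_year[rr] <- y
      taper[rr] <- stats::runif(length(rr), config$taper_factor_range[1],
                                config$taper_factor_range[2])
    }

    n_ge10 <- tabulate(sub[alive & !is.na(dbh) & dbh >= 10], nbins = n_sub)
    n_new <- stats::rpois(n_sub, config$recruitment_pct_yr / 100 * n_ge10)
    tot_new <- sum(n_new)
    if (tot_new > 0) {
      if (n_used + tot_new > cap) grow_cap(tot_new)
      new_idx <- n_used + seq_len(tot_new)
      n_used <- n_used + tot_new
      sub[new_idx] <- rep(seq_len(n_sub), n_new)
      off <- subplot_origin(grid$subplot_no[sub[new_idx]])
      xs[new_idx] <- round(off[, 1] + stats::runif(tot_new, 0, 100), 1)
      ys[new_idx] <- round(off[, 2] + stats::runif(tot_new, 0, 100), 1)
      dbh[new_idx] <- stats::runif(tot_new, config$recruit_entry_dbh_range[1],
                                   config$recruit_entry_dbh_range[2])
      alive[new_idx] <- TRUE
      birth_year[new_idx] <- y
    }
    traj[which(alive), t] <- dbh[alive]
  }

  use <- seq_len(n_used)
  TT <- traj[use, camp_idx, drop = FALSE]
  mult <- matrix(1, n_used, nc)
  raised <- which(!is.na(raise_year[use]))
  for (i in raised) {
    mult[i, cy >= raise_year[i]] <- taper[i]
  }
  g_true <- TT * pi * mult
  noise <- matrix(stats::rnorm(n_used * nc, 0, config$measurement_sd_cm),
                  n_used, nc)
  g_obs <- round_half_up(pmax(g_true + noise, 0), 0.5)
  d_obs <- round_half_up(g_obs / pi, 0.1)
  hom_mat <- matrix(1.5, n_used, nc)
  hom_mat[mult < 1] <- 4.5

  seen <- !is.na(g_obs) & g_obs >= 30
  entry_k <- ifelse(rowSums(seen) > 0, max.col(seen, "first"), NA_integer_)
  dc_k <- rep(NA_integer_, n_used)
  has_death <- !is.na(death_year[use])
  dc_k[has_death] <- vapply(which(has_death), function(i) {
    k <- which(cy >= death_year[i])
    if (length(k)) min(k) else NA_integer_
  }, integer(1))
  archived <- !is.na(entry_k) & (is.na(dc_k) | entry_k < dc_k)

  live_mat <- matrix(FALSE, n_used, nc)
  for (i in which(archived)) {
    last <- if (is.na(dc_k[i])) nc else dc_k[i] - 1
    live_mat[i, entry_k[i]:last] <- TRUE
  }
  dead_mat <- matrix(FALSE, n_used, nc)
  dr <- which(archived & !is.na(dc_k))
  dead_mat[cbind(dr, dc_k[dr])] <- TRUE

  miss_mat <- matrix(stats::runif(n_used * nc) < config$p_missing_record,
                     n_used, nc)
  miss_mat <- miss_mat & live_mat
  miss_mat[cbind(seq_len(n_used), pmin(entry_k, nc, na.rm = TRUE))] <- FALSE

  fd_mat <- matrix(FALSE, n_used, nc)
  if (config$p_false_dead > 0) {
    fd_draw <- matrix(stats::runif(n_used * nc) < config$p_false_dead,
                      n_used, nc)
    for (i in which(archived)) {
      last_live <- max(which(live_mat[i, ]))
      elig <- which(fd_draw[i, ] & live_mat[i, ])
      elig <- elig[elig > entry_k[i] & elig < last_live]
      if (length(elig)) {
        start <- elig[1]
        dur <- sample(1:2, 1)
        end <- min(start + dur - 1, last_live - 1)
        fd_mat[i, start:end] <- TRUE
      }
    }
  }

  measured_ok <- live_mat & !miss_mat & !fd_mat & !is.na(d_obs) & d_obs >= 10
  rec_k <- ifelse(rowSums(measured_ok) > 0, max.col(measured_ok, "first"),
                  NA_integer_)

  # tree numbering within subplots, by entry order then creation order
  arc_idx <- which(archived)
  ord <- arc_idx[order(sub[arc_idx], entry_k[arc_idx], arc_idx)]
  tree_no <- integer(n_used)
  tree_no[ord] <- stats::ave(seq_along(ord), sub[ord], FUN = seq_along)
  tid <- rep(NA_character_, n_used)
  tid[arc_idx] <- make_tree_id(grid$plot_no[sub[arc_idx]],
                               grid$subplot_no[sub[arc_idx]],
                               tree_no[arc_idx])

  species <- sample(56, n_used, replace = TRUE,
                    prob = c(rep(0.15 / 36, 36), rep(0.85 / 20, 20)))

  cells <- which(live_mat | dead_mat, arr.ind = TRUE)
  i <- cells[, 1]; k <- cells[, 2]
  is_dead <- dead_mat[cells]
  is_fd <- fd_mat[cells]
  is_miss <- miss_mat[cells]
  no_val <- is_dead | is_fd | is_miss
  recd <- !is.na(rec_k[i]) & k >= rec_k[i]
  status <- ifelse(is_dead | is_fd, "dead",
                   ifelse(recd, "alive", "not_yet_recruited"))
  mcode <- ifelse(is_dead, cause[use][i],
                  ifelse(is_fd, "standing_death", NA_character_))
  measures <- tibble::tibble(
    tree_id = tid[i],
    campaign_year = cy[k],
    girth_cm = ifelse(no_val, NA_real_, g_obs[cells]),
    dbh_cm = ifelse(no_val, NA_real_, d_obs[cells]),
    hom_m = ifelse(is_dead | is_fd, NA_real_, hom_mat[cells]),
    method = ifelse(no_val, NA_character_, "tape"),
    status = status,
    mortality_code = mcode,
    observation_codes = ifelse(!no_val & hom_mat[cells] > 1.5,
                               "SHAPE_IRREGULAR", NA_character_)
  ) |>
    dplyr::arrange(.data$tree_id, .data$campaign_year)

  tree <- tibble::tibble(
    tree_id = tid[arc_idx],
    plot_no = grid$plot_no[sub[arc_idx]],
    subplot_no = grid$subplot_no[sub[arc_idx]],
    tree_no = tree_no[arc_idx],
    x_m = xs[arc_idx], y_m = ys[arc_idx],
    id_taxonomy = species[arc_idx],
    vernacular_name = NA_character_
  ) |> dplyr::arrange(.data$tree_id)
  vern <- simulate_vernacular()
  tree$vernacular_name <- vern$issongo_name[match(tree$id_taxonomy,
                                                  vern$id_taxonomy)]

  trees_context <- tibble::tibble(plot_no = plots,
                                  treatment = config$treatments,
                                  block = block_for_plot(plots),
                                  area_ha = 4)
  geom <- lapply(seq_along(plots), function(j) {
    plot_geometry(plots[j], config$treatments[j],
                  ref_lon = 17.50 + 0.01 * j, ref_lat = 3.45)
  })
  plots_tbl <- dplyr::bind_rows(lapply(geom, `[[`, "plots"))
  subplots_tbl <- dplyr::bind_rows(lapply(geom, `[[`, "subplots"))

  archive <- census_archive(
    tree = tree, taxonomy = simulate_taxonomy(), vernacular = vern,
    trees_context = trees_context, measures = measures,
    inventories = campaign_calendar(cy),
    observation_codes = default_observation_codes(),
    mortality_codes = default_mortality_codes(),
    plots = plots_tbl, subplots = subplots_tbl)

  truth_trees <- tibble::tibble(
    sim_index = use,
    tree_id = tid[use],
    plot_no = grid$plot_no[sub[use]],
    subplot_no = grid$subplot_no[sub[use]],
    birth_year = birth_year[use],
    death_year = death_year[use],
    death_cause = cause[use],
    hom_raise_year = raise_year[use],
    taper_factor = ifelse(is.na(raise_year[use]), NA_real_, taper[use]),
    entry_campaign = ifelse(is.na(entry_k), NA_integer_, cy[entry_k]),
    recruit_campaign = ifelse(is.na(rec_k), NA_integer_, cy[rec_k]))
  traj_long <- NULL
  obs_rows <- which(archived)
  if (length(obs_rows)) {
    tl <- which(!is.na(traj[obs_rows, , drop = FALSE]), arr.ind = TRUE)
    traj_long <- tibble::tibble(tree_id = tid[obs_rows][tl[, 1]],
                                year = years[tl[, 2]],
                                dbh_true = traj[obs_rows, ,
                                                drop = FALSE][tl])
  } else {
    traj_long <- tibble::tibble(tree_id = character(0), year = integer(0),
                                dbh_true = numeric(0))
  }
  fd_cells <- which(fd_mat, arr.ind = TRUE)
  miss_cells <- which(miss_mat, arr.ind = TRUE)
  rem <- if (length(removals)) dplyr::bind_rows(removals) else
    tibble::tibble(sim_index = integer(0), year = integer(0))
  rem$tree_id <- tid[rem$sim_index]
  truth <- structure(list(
    trees = truth_trees,
    trajectories = traj_long,
    false_dead = tibble::tibble(tree_id = tid[fd_cells[, 1]],
                                campaign_year = cy[fd_cells[, 2]]),
    missing = tibble::tibble(tree_id = tid[miss_cells[, 1]],
                             campaign_year = cy[miss_cells[, 2]]),
    removals = rem[c("tree_id", "year")]
  ), class = "psp_truth")
  list(archive = archive, truth = truth)
}
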