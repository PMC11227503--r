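# helper: an archive with n0 trees of given dbh in subplot 1, with chosen
# deaths and recruits across two campaigns
h_two_campaign <- function(n0, years = c(2001, 2002), d0 = 20,
                           n_dead = 0, n_recruit = 0) {
  ids <- make_tree_id(11, 1, seq_len(n0 + n_recruit))
  rows <- list()
  for (i in seq_len(n0)) {
    dead <- i <= n_dead
    rows[[i]] <- h_measures(tibble::tibble(
      tree_id = ids[i], campaign_year = years,
      dbh_cm = c(d0, if (dead) NA else d0 + 0.2),
      status = c("alive", if (dead) "dead" else "alive"),
      mortality_code = c(NA, if (dead) "standing_death" else NA)))
  }
  for (j in seq_len(n_recruit)) {
    rows[[n0 + j]] <- h_measures(tibble::tibble(
      tree_id = ids[n0 + j], campaign_year = years[2], dbh_cm = 10.4))
  }
  h_archive(dplyr::bind_rows(rows), years = years, corrected = FALSE)
}

test_that("the recruitment campaign is the first with dbh at the threshold", {
  s <- h_series(2000:2003, dbh = c(9.5, 9.8, 10.2, 10.5))
  expect_equal(recruitment_campaign(s), 2002L)
  expect_equal(recruitment_campaign(h_series(2000, dbh = 15)), 2000L)
  expect_true(is.na(recruitment_campaign(h_series(2000:2001,
                                                  dbh = c(9.5, 9.9)))))
})

test_that("stand state gives N and G in per-hectare units", {
  ms <- h_measures(tibble::tibble(tree_id = "11_1_0001",
                                  campaign_year = 2000, dbh_cm = 50))
  arc <- h_archive(ms, years = 2000)
  st <- stand_state(arc, plot_no = 11, subplot_no = 1, campaign_year = 2000)
  expect_equal(st$N_per_ha, 1)
  expect_equal(st$G_m2_per_ha, pi * 0.25^2, tolerance = 1e-9)
  # at the plot scale the same tree spreads over 4 ha
  stp <- stand_state(arc, plot_no = 11, campaign_year = 2000)
  expect_equal(stp$N_per_ha, 0.25)

  # threshold rule: 9.5 cm stays out at the 10 cm threshold
  ms2 <- h_measures(tibble::tibble(
    tree_id = c("11_1_0001", "11_1_0002"), campaign_year = 2000,
    dbh_cm = c(10, 9.5), status = c("alive", "not_yet_recruited")))
  st2 <- stand_state(h_archive(ms2, years = 2000), 11, 1, 2000)
  expect_equal(st2$N_per_ha, 1)
  st95 <- stand_state(h_archive(ms2, years = 2000), 11, 1, 2000,
                      threshold = 9.5)
  expect_equal(st95$N_per_ha, 2)

  expect_error(stand_state(h_archive(ms2, years = 2000), 12, 1, 2000),
               class = "psp_domain_error")
})

test_that("demographic rates match the closed-form power annualization", {
  # 100 trees, 1 death, 1 yr: mortality 1.0 %/yr exactly
  arc <- h_two_campaign(100, n_dead = 1)
  r <- demographic_rates(arc, plot_no = 11, subplot_no = 1,
                         campaign_a = 2001, campaign_b = 2002)
  expect_equal(r$n_deaths, 1)
  expect_equal(r$mortality_pct_yr, 1, tolerance = 1e-9)
  expect_equal(r$recruitment_pct_yr, 0)

  # 2 deaths over a two-year gap (non-leap dates): 1 - 0.98^(1/2)
  arc2 <- h_two_campaign(100, years = c(2001, 2003), n_dead = 2)
  r2 <- demographic_rates(arc2, plot_no = 11, subplot_no = 1,
                          campaign_a = 2001, campaign_b = 2003)
  expect_equal(r2$mortality_pct_yr, (1 - 0.98^(1 / 2)) * 100,
               tolerance = 1e-9)

  # 10 recruits among 110 at b over 1 yr: (1 - 100/110) * 100
  arc3 <- h_two_campaign(100, n_recruit = 10)
  r3 <- demographic_rates(arc3, plot_no = 11, subplot_no = 1,
                          campaign_a = 2001, campaign_b = 2002)
  expect_equal(r3$n_recruits, 10)
  expect_equal(r3$recruitment_pct_yr, (1 - 100 / 110) * 100,
               tolerance = 1e-9)
  expect_equal(r3$mortality_pct_yr, 0)

  # simple estimator agrees at dt = 1 for mortality
  r1s <- demographic_rates(arc, 11, 1, 2001, 2002, estimator = "simple")
  expect_equal(r1s$mortality_pct_yr, 1, tolerance = 1e-9)

  expect_error(demographic_rates(arc, 11, 1, 2001, 2005),
               class = "psp_domain_error")
})

test_that("zero-denominator rates are missing, not zero", {
  arc <- h_two_campaign(1, n_dead = 1)
  dyn <- dynamics_table(arc, level = "subplot")
  row <- dyn[dyn$subplot_no == 1 & dyn$campaign_year == 2002, ]
  expect_equal(row$mortality_pct_yr, 100) # all died
  expect_true(is.na(row$recruitment_pct_yr)) # nobody left at b
})

test_that("plot-level N and G are the area-weighted means of the subplots", {
  sim <- simulate_archive(sim_config(seed = 61, plot_nos = 11L,
                                     initial_density_per_ha = 80))
  dyn_p <- dynamics_table(sim$archive, level = "plot")
  dyn_s <- dynamics_table(sim$archive, level = "subplot")
  agg <- dyn_s |>
    dplyr::group_by(plot_no, campaign_year) |>
    dplyr::summarise(N = mean(N_per_ha), G = mean(G_m2_per_ha),
                     .groups = "drop")
  j <- dplyr::inner_join(dyn_p, agg, by = c("plot_no", "campaign_year"))
  expect_equal(j$N_per_ha, j$N, tolerance = 1e-9)
  expect_equal(j$G_m2_per_ha, j$G, tolerance = 1e-9)
})

test_that("G is order-invariant and scales quadratically with diameter", {
  ms <- h_measures(tibble::tibble(
    tree_id = make_tree_id(11, 1, 1:3), campaign_year = 2000,
    dbh_cm = c(20, 35, 50)))
  arc <- h_archive(ms, years = 2000)
  g1 <- stand_state(arc, 11, 1, 2000)$G_m2_per_ha
  ms2 <- ms[3:1, ]
  arc2 <- h_archive(ms2, trees = arc$tree, years = 2000)
  expect_equal(stand_state(arc2, 11, 1, 2000)$G_m2_per_ha, g1)
  ms4 <- dplyr::mutate(ms, dbh_cm = dbh_cm * 2,
                       girth_cm = dbh_to_gbh(dbh_cm * 2))
  arc4 <- h_archive(ms4, trees = arc$tree, years = 2000)
  expect_equal(stand_state(arc4, 11, 1, 2000)$G_m2_per_ha, 4 * g1,
               tolerance = 1e-9)
})

test_that("an event-free stand has constant N and zero rates", {
  sim <- simulate_archive(sim_config(seed = 71, plot_nos = 11L,
                                     initial_density_per_ha = 50,
                                     mortality_pct_yr = 0,
                                     recruitment_pct_yr = 0,
                                     measurement_sd_cm = 0,
                                     p_missing_record = 0,
                                     p_hom_raise_per_yr = 0))
  dyn <- dynamics_table(sim$archive, level = "plot")
  expect_equal(unique(dyn$N_per_ha), dyn$N_per_ha[1])
  expect_true(all(dyn$mortality_pct_yr[-1] == 0))
  expect_true(all(dyn$recruitment_pct_yr[-1] == 0))
  expect_true(all(diff(dyn$G_m2_per_ha) >= 0))
})

test_that("a simulated logging pulse shows up as a mortality spike of the removed fraction", {
  ev <- tibble::tibble(year = 1986, fraction_basal_area_removed = 0.3)
  sim <- simulate_archive(sim_config(seed = 81, plot_nos = 12L,
                                     treatments = "logging",
                                     initial_density_per_ha = 150,
                                     disturbance_events = ev))
  dyn <- dynamics_table(sim$archive, level = "plot")
  n_before <- dyn$n_initial[dyn$campaign_year == 1986]
  removed <- sum(!is.na(sim$truth$removals$tree_id))
  spike <- dyn$mortality_pct_yr[dyn$campaign_year == 1986]
  expect_gt(spike, 5)
  expect_equal(spike, 100 * removed / n_before, tolerance = 0.25)
  # removing by basal-area share removes fewer stems than basal-area fraction
  expect_lt(removed / n_before, 0.3)
})
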