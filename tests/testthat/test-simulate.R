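test_that("simulation is deterministic given the seed", {
  cfg <- sim_config(seed = 5, plot_nos = 11L, initial_density_per_ha = 40)
  a <- simulate_archive(cfg)
  b <- simulate_archive(cfg)
  expect_true(isTRUE(archive_equal(a$archive, b$archive)))
  expect_identical(a$truth$trees, b$truth$trees)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_archive(a$archive, d1); write_archive(b$archive, d2)
  expect_identical(dir_bytes(d1), dir_bytes(d2))
  # a different seed gives a different stand
  c2 <- simulate_archive(sim_config(seed = 6, plot_nos = 11L,
                                    initial_density_per_ha = 40))
  expect_false(isTRUE(archive_equal(a$archive, c2$archive)))
})

test_that("a process-free stand stays alive with monotone series", {
  sim <- simulate_archive(sim_config(seed = 8, plot_nos = 11L,
                                     initial_density_per_ha = 30,
                                     mortality_pct_yr = 0,
                                     recruitment_pct_yr = 0,
                                     measurement_sd_cm = 0,
                                     p_missing_record = 0,
                                     p_hom_raise_per_yr = 0))
  ms <- sim$archive$measures
  expect_true(all(ms$status %in% c("alive", "not_yet_recruited")))
  mono <- ms |>
    dplyr::group_by(tree_id) |>
    dplyr::summarise(ok = all(diff(dbh_cm) >= 0), .groups = "drop")
  expect_true(all(mono$ok))
  # every tree persists to the last campaign
  last <- ms |>
    dplyr::group_by(tree_id) |>
    dplyr::summarise(last = max(campaign_year), .groups = "drop")
  expect_true(all(last$last == 2022))
})

test_that("emitted clean archives pass validation", {
  sim <- simulate_archive(sim_config(seed = 9, plot_nos = c(11L, 21L),
                                     initial_density_per_ha = 40))
  expect_equal(nrow(validate_archive(sim$archive)), 0)
  expect_equal(sort(unique(sim$archive$tree$plot_no)), c(11L, 21L))
  expect_equal(nrow(sim$archive$plots), 2)
  expect_equal(nrow(sim$archive$subplots), 8)
})

test_that("false-dead episodes appear as dead-then-alive patterns matching the log", {
  sim <- simulate_archive(sim_config(seed = 10, plot_nos = 11L,
                                     initial_density_per_ha = 60,
                                     p_false_dead = 0.01))
  fd <- sim$truth$false_dead
  expect_gt(nrow(fd), 0)
  ms <- sim$archive$measures
  # every logged episode is recorded dead and later seen living again
  for (i in seq_len(min(nrow(fd), 25))) {
    rows <- ms[ms$tree_id == fd$tree_id[i], ]
    expect_equal(rows$status[rows$campaign_year == fd$campaign_year[i]],
                 "dead")
    expect_true(any(rows$campaign_year > fd$campaign_year[i] &
                      rows$status %in% c("alive", "not_yet_recruited")))
  }
  # conversely, every dead-then-living pattern in the archive is logged
  reborn <- ms |>
    dplyr::group_by(tree_id) |>
    dplyr::summarise(pattern = any(status == "dead" &
                                     dplyr::lead(status, default = "dead") !=
                                       "dead"), .groups = "drop")
  expect_setequal(reborn$tree_id[reborn$pattern], unique(fd$tree_id))
})

test_that("realized demographic frequencies converge to the configured rates", {
  sim <- simulate_archive(sim_config(seed = 14, plot_nos = 11L,
                                     initial_density_per_ha = 300,
                                     mortality_pct_yr = 2))
  tr <- sim$truth$trees
  # person-years: from birth to death (or end of simulation)
  last <- 2022
  span <- ifelse(is.na(tr$death_year), last - tr$birth_year,
                 tr$death_year - tr$birth_year)
  deaths <- sum(!is.na(tr$death_year))
  phat <- deaths / sum(span)
  se <- sqrt(phat * (1 - phat) / sum(span))
  expect_lt(abs(phat - 0.02), 4 * se)
})

test_that("true taper factors are recoverable from noise-free observations", {
  sim <- simulate_archive(sim_config(seed = 15, plot_nos = 11L,
                                     initial_density_per_ha = 80,
                                     measurement_sd_cm = 0,
                                     p_missing_record = 0,
                                     p_hom_raise_per_yr = 0.04))
  tr <- sim$truth$trees
  raised <- tr[!is.na(tr$hom_raise_year) & !is.na(tr$tree_id), ]
  traj <- sim$truth$trajectories
  checked <- 0
  for (i in seq_len(nrow(raised))) {
    s <- tree_series(sim$archive, raised$tree_id[i])
    ev <- detect_hom_raises(s)
    ev <- ev[!is.na(ev$ratio), ]
    if (!nrow(ev)) next
    # the measured ratio is the true taper factor times the true growth
    # over the flanking interval; with zero noise only the two rounded
    # readings separate them
    tt <- traj[traj$tree_id == raised$tree_id[i], ]
    yb <- ev$raise_campaign[1]
    ya <- max(s$campaign_year[s$campaign_year < yb &
                                !is.na(s$dbh_cm)])
    d_a <- tt$dbh_true[tt$year == ya]
    d_b <- tt$dbh_true[tt$year == yb]
    expected <- raised$taper_factor[i] * d_b / d_a
    expect_lt(abs(ev$ratio[1] - expected), 0.3 / d_a)
    checked <- checked + 1
  }
  expect_gt(checked, 5)
})

test_that("injection honours counts, logs placements, and reports shortfalls", {
  sim <- simulate_archive(sim_config(seed = 16, plot_nos = 11L,
                                     initial_density_per_ha = 50,
                                     measurement_sd_cm = 0,
                                     p_missing_record = 0,
                                     p_hom_raise_per_yr = 0))
  inj0 <- inject_anomalies(sim$archive, seed = 1)
  expect_equal(nrow(inj0$log), 0)
  expect_true(isTRUE(archive_equal(inj0$archive, sim$archive)))

  inj <- inject_anomalies(sim$archive, n_growth = 5, n_decline = 5,
                          n_recruit_under = 3, n_hom_increase = 4, seed = 2)
  expect_equal(table(inj$log$rule_id)[["EXCESS_GROWTH"]], 5)
  expect_equal(nrow(inj$log), 17)
  fl <- screen_archive(inj$archive)
  # an injected decline is flagged as a decline, never as growth
  dec <- inj$log[inj$log$rule_id == "EXCESS_DECLINE", ]
  hit <- fl[fl$tree_id %in% dec$tree_id & fl$campaign_year %in%
              dec$campaign_year, ]
  expect_true(all(hit$rule_id == "EXCESS_DECLINE"))

  # impossible request: more recruits than exist
  inj2 <- inject_anomalies(sim$archive, n_recruit_under = 10000, seed = 3)
  expect_true("RECRUIT_UNDER_10" %in% attr(inj2$log, "shortfall"))
})
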