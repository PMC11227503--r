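test_that("hom raises are detected with flanking-measurement ratios", {
  s <- h_series(2000:2003, dbh = c(30, 31, 28, 28.5),
                hom = c(1.5, 1.5, 3.5, 3.5))
  ev <- detect_hom_raises(s)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$raise_campaign, 2002L)
  expect_equal(ev$ratio, 28 / 31, tolerance = 1e-12)

  expect_equal(nrow(detect_hom_raises(h_series(2000:2003,
                                               dbh = c(30, 30.5, 31, 31.2)))),
               0)

  # raise across a measurement gap has an undefined ratio
  s2 <- h_series(2000:2002, dbh = c(31, NA, 28), hom = c(1.5, 1.5, 4.5))
  ev2 <- detect_hom_raises(s2)
  expect_true(is.na(ev2$ratio))
})

test_that("taper conversion divides by the ratio and chains across raises", {
  s <- h_series(2000:2003, dbh = c(30, 31, 28, 28.4),
                hom = c(1.5, 1.5, 4.5, 4.5))
  out <- apply_taper_correction(s)
  # at the raise campaign the converted value equals the previous value
  expect_equal(out$dbh_cm[3], 31)
  expect_equal(out$dbh_cm[4], 31.4) # 28.4 / (28/31) = 31.44 -> 31.4
  expect_equal(out$provenance[3:4], rep("taper_converted", 2))
  expect_equal(out$hom_m, rep(1.5, 4))
  expect_equal(out$dbh_cm[1:2], c(30, 31)) # pre-raise values untouched

  # ratio exactly 1 leaves the series unchanged
  s1 <- h_series(2000:2003, dbh = c(30, 31, 31, 31.2),
                 hom = c(1.5, 1.5, 4.5, 4.5))
  expect_equal(apply_taper_correction(s1)$dbh_cm, s1$dbh_cm)

  # two successive raises: the final-segment divisor is the ratio product
  s2 <- h_series(2000:2005, dbh = c(30, 31, 28, 28.5, 26, 26.3),
                 hom = c(1.5, 1.5, 3.5, 3.5, 4.5, 4.5))
  out2 <- apply_taper_correction(s2)
  r1 <- 28 / 31; r2 <- 26 / 28.5
  expect_equal(out2$dbh_cm[5], round_half_up(26 / (r1 * r2), 0.1))
  expect_equal(out2$dbh_cm[6], round_half_up(26.3 / (r1 * r2), 0.1))
  # and it matches composing two single-raise corrections by hand
  step1 <- c(30, 31, 28 / r1, 28.5 / r1, 26 / r1, 26.3 / r1)
  expect_equal(out2$dbh_cm, round_half_up(c(step1[1:4],
                                            step1[5:6] / r2), 0.1),
               tolerance = 0.051) # intermediate rounding differs at most a step
})

test_that("gap filling follows the increment-sign rules", {
  # positive increment: linear interpolation in decimal time
  s <- h_series(2000:2002, dbh = c(10, NA, 12))
  out <- fill_gaps(s)
  expect_equal(out$dbh_cm[2], 11)
  expect_equal(out$provenance[2], "interpolated")

  # negative increment without raise: the last valid value is reported
  s2 <- h_series(2000:2002, dbh = c(30, NA, 29))
  out2 <- fill_gaps(s2)
  expect_equal(out2$dbh_cm, c(30, 30, 30))
  expect_equal(out2$provenance[2:3], rep("carried_forward", 2))

  # negative increment with a raise inside the gap: taper procedure between
  # the valid measurements at different homs, propagated onward
  s3 <- h_series(2000:2003, dbh = c(31, NA, 28, 27.5),
                 hom = c(1.5, 1.5, 4.5, 4.5))
  out3 <- fill_gaps(s3)
  expect_equal(out3$dbh_cm[1:3], c(31, 31, 31))
  expect_equal(out3$dbh_cm[4], round_half_up(27.5 / (28 / 31), 0.1)) # 30.4
  expect_equal(out3$hom_m, rep(1.5, 4))

  # equal flanking values: constant fill
  s4 <- h_series(2000:2002, dbh = c(20, NA, 20))
  expect_equal(fill_gaps(s4)$dbh_cm, c(20, 20, 20))

  # leading missing values have no flanking pair and stay unfilled
  s5 <- h_series(2000:2002, dbh = c(NA, 20, 20.3))
  out5 <- fill_gaps(s5)
  expect_true(is.na(out5$dbh_cm[1]))
  expect_equal(out5$provenance[1], "unfilled")
})

test_that("re-born trees are back-filled from the re-born diameter", {
  s <- h_series(2000:2003, dbh = c(30, NA, NA, 31),
                status = c("alive", "dead", "dead", "alive"))
  out <- backfill_reborn(s)
  expect_equal(out$dbh_cm, c(30, 31, 31, 31))
  expect_equal(out$status, rep("alive", 4))
  expect_equal(out$provenance[2:3], rep("reborn_backfill", 2))
  expect_true(all(is.na(out$mortality_code)))

  # no dead interval: identity
  s2 <- h_series(2000:2002, dbh = c(30, 30.2, 30.5))
  expect_equal(backfill_reborn(s2)$dbh_cm, s2$dbh_cm)

  # two separate dead intervals, each back-filled from its own re-born value
  s3 <- h_series(2000:2004, dbh = c(30, NA, 31, NA, 33),
                 status = c("alive", "dead", "alive", "dead", "alive"))
  out3 <- backfill_reborn(s3)
  expect_equal(out3$dbh_cm, c(30, 31, 31, 33, 33))

  # a terminal death is not a re-born tree
  s4 <- h_series(2000:2002, dbh = c(30, 30.2, NA),
                 status = c("alive", "alive", "dead"))
  expect_equal(backfill_reborn(s4)$status[3], "dead")

  # re-born with no subsequent measurement anywhere is an error
  s5 <- h_series(2000:2002, dbh = c(30, NA, NA),
                 status = c("alive", "dead", "alive"))
  expect_error(backfill_reborn(s5), class = "psp_correction_error")
})

test_that("the full pipeline orders overrides, re-born, taper and gap filling", {
  # clean series: provenance all raw
  s <- h_series(2000:2003, dbh = c(20, 20.3, 20.5, 20.9))
  out <- correct_tree(s)
  expect_equal(out$provenance, rep("raw", 4))
  expect_equal(out$dbh_cm, s$dbh_cm)

  # an override replaces an outlier, then interpolation crosses the gap
  s2 <- h_series(2000:2003, dbh = c(30, 35, NA, 33))
  ov <- tibble::tibble(tree_id = "11_1_0001", campaign_year = 2001L,
                       dbh_cm = 31, note = "outlier recheck")
  out2 <- correct_tree(s2, overrides = ov)
  expect_equal(out2$dbh_cm, c(30, 31, 32, 33))
  expect_equal(out2$provenance,
               c("raw", "manual_override", "interpolated", "raw"))
})

test_that("the correction pipeline is idempotent and deterministic", {
  sim <- simulate_archive(sim_config(seed = 31, plot_nos = 11L,
                                     initial_density_per_ha = 50,
                                     p_missing_record = 0.05,
                                     p_hom_raise_per_yr = 0.02,
                                     p_false_dead = 0.01))
  corr <- correct_archive(sim$archive)
  twice <- correct_archive(corr)
  expect_equal(as.data.frame(twice$measures), as.data.frame(corr$measures))

  # row order of the input does not matter
  shuffled <- sim$archive
  set.seed(2)
  shuffled$measures <- shuffled$measures[sample.int(nrow(shuffled$measures)), ]
  corr2 <- correct_archive(shuffled)
  expect_equal(as.data.frame(corr2$measures), as.data.frame(corr$measures))
})

test_that("corrected series are closer to the true trajectories than raw ones", {
  sim <- simulate_archive(sim_config(seed = 41, plot_nos = 11L,
                                     initial_density_per_ha = 60,
                                     measurement_sd_cm = 0,
                                     p_missing_record = 0.03,
                                     p_hom_raise_per_yr = 0.05,
                                     p_false_dead = 0))
  corr <- correct_archive(sim$archive)
  truth <- sim$truth$trajectories
  raw <- sim$archive$measures |>
    dplyr::inner_join(truth, by = c("tree_id", "campaign_year" = "year"))
  cor_ms <- corr$measures |>
    dplyr::inner_join(truth, by = c("tree_id", "campaign_year" = "year"))
  mae_raw <- mean(abs(raw$dbh_cm - raw$dbh_true), na.rm = TRUE)
  mae_cor <- mean(abs(cor_ms$dbh_cm - cor_ms$dbh_true), na.rm = TRUE)
  expect_lte(mae_cor, mae_raw)
  # and the hom-raised subset specifically improves
  raised <- sim$truth$trees$tree_id[!is.na(sim$truth$trees$hom_raise_year)]
  mae_raw_r <- mean(abs(raw$dbh_cm - raw$dbh_true)[raw$tree_id %in% raised],
                    na.rm = TRUE)
  mae_cor_r <- mean(abs(cor_ms$dbh_cm - cor_ms$dbh_true)[
    cor_ms$tree_id %in% raised], na.rm = TRUE)
  expect_lt(mae_cor_r, mae_raw_r)
})

test_that("taper continuity holds at every defined raise in simulated series", {
  sim <- simulate_archive(sim_config(seed = 51, plot_nos = 11L,
                                     initial_density_per_ha = 40,
                                     p_hom_raise_per_yr = 0.05,
                                     p_missing_record = 0))
  corr <- correct_archive(sim$archive)
  raised <- sim$truth$trees[!is.na(sim$truth$trees$hom_raise_year), ]
  checked <- 0
  for (i in seq_len(nrow(raised))) {
    tid <- raised$tree_id[i]
    if (is.na(tid)) next
    s <- corr$measures[corr$measures$tree_id == tid, ]
    k <- which(s$provenance == "taper_converted")
    if (!length(k) || min(k) == 1) next
    expect_equal(s$dbh_cm[min(k)], s$dbh_cm[min(k) - 1])
    checked <- checked + 1
  }
  expect_gt(checked, 0)
})
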