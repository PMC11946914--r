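test_that("daily_tsm and weighted_mean_se match the stated formulas", {
  expect_equal(daily_tsm(36, 30), 6)
  expect_equal(daily_tsm(30, 36), -6)
  expect_equal(daily_tsm(33, 33), 0)

  wm <- weighted_mean_se(c(10, 20), c(1, 2))
  expect_equal(wm$mean, 12)                     # (10 + 20/4) / (1 + 1/4)
  expect_equal(wm$se, sqrt(1 / 1.25), tolerance = 1e-12)
  expect_equal(weighted_mean_se(c(3, 5, 7), c(2, 2, 2))$mean, 5)
  one <- weighted_mean_se(4, 0.3)
  expect_equal(one$mean, 4)
  expect_equal(one$se, 0.3)
  expect_error(weighted_mean_se(numeric(0), numeric(0)), "empty")
  expect_error(weighted_mean_se(1:2, c(1, -1)), "positive")
})

test_that("exceedance_probability is the capped normal CDF", {
  expect_equal(exceedance_probability(36, 36, 0.8), 0.5)
  # normal CDF oracle at +3 sigma
  expect_equal(exceedance_probability(36 + 3 * 0.8, 36, 0.8),
               pnorm(3), tolerance = 1e-9)
  expect_equal(round(exceedance_probability(39, 36, 1), 5), 0.99865)
  # SEs above the cap behave exactly like the cap
  expect_equal(exceedance_probability(35, 36, 2, sigma_policy(cap = 1)),
               exceedance_probability(35, 36, 1, sigma_policy(cap = 1)))
  # biological-range mode caps at bio_cap
  pol <- sigma_policy("biological_range", bio_cap = 2)
  expect_equal(exceedance_probability(35, 36, 5, pol), pnorm(-0.5))
  # capped-sigma dominance: for daily_max < ctmax_day capping never raises p
  expect_lte(exceedance_probability(34, 36, 1, sigma_policy(cap = 1)),
             exceedance_probability(34, 36, 3, sigma_policy("none")))
  expect_error(sigma_policy(cap = -1), "caps")
  expect_error(exceedance_probability(35, 36, 0), "positive")
})

test_that("overheating_days applies the binomial formulas", {
  expect_equal(overheating_days(rep(0, 910))$n, 0)
  expect_equal(overheating_days(rep(0, 910))$se, 0)
  od <- overheating_days(rep(0.5, 910))
  expect_equal(od$n, 455)
  expect_equal(od$se, sqrt(910 * 0.25), tolerance = 1e-12)
  expect_equal(round(od$se, 3), 15.083)
  full <- overheating_days(rep(1, 910))
  expect_equal(full$n, 910)
  expect_equal(full$se, 0)
  expect_error(overheating_days(c(0.5, 1.2)), "outside")
})

test_that("binary_risk implements both decision rules", {
  dm <- rep(30, 10); cm <- dm + 5
  expect_equal(binary_risk(dm, cm), 0L)
  cm2 <- cm; dm2 <- dm; dm2[4] <- cm2[4] + 0.1
  expect_equal(binary_risk(dm2, cm2), 1L)
  expect_equal(binary_risk(variant = "ci", n = 0.4, se = 0.63), 0L)
  expect_equal(binary_risk(variant = "ci", n = 5, se = 1), 1L)
  expect_error(binary_risk(1:3, 1:2), "misaligned")
})

test_that("tsm_summary assembles metrics and honours variants", {
  n <- 910L
  dm <- rep(30, n); cm <- rep(36, n); se <- rep(0.8, n)
  yr <- rep(1:10, each = 91)
  out <- tsm_summary(dm, cm, se, yr)
  expect_equal(out$tsm_mean, 6)
  expect_equal(out$p_bar, pnorm(-6 / 0.8), tolerance = 1e-12)
  expect_equal(out$n_days_total, 910L)
  expect_equal(out$risk_binary, 0L)

  # one synthetic heat-wave day crossing CT_max by 2 degC
  dm2 <- dm; dm2[500] <- 38
  out2 <- tsm_summary(dm2, cm, se, yr)
  expect_equal(out2$risk_binary, 1L)
  p_hot <- pnorm(2 / 0.8)
  expect_equal(out2$n_overheat_days,
               (909 * pnorm(-7.5) + p_hot) / 910 * 910, tolerance = 1e-9)

  # equal SEs: weighted TSM equals the arithmetic mean of daily TSMs
  set.seed(3)
  dm3 <- rnorm(n, 30, 2)
  out3 <- tsm_summary(dm3, cm, se, yr)
  expect_equal(out3$tsm_mean, mean(36 - dm3), tolerance = 1e-10)

  # annual_max variant: TSM at each year's hottest day
  out4 <- tsm_summary(dm3, cm, se, yr, tsm_variant = "annual_max")
  oracle <- mean(vapply(split(seq_len(n), yr), function(i)
    36 - max(dm3[i]), numeric(1)))
  expect_equal(out4$tsm_mean, oracle, tolerance = 1e-10)
  expect_lt(out4$tsm_mean, out3$tsm_mean)

  # trimmed variant drops the temperature tails
  out5 <- tsm_summary(dm3, cm, se, yr, trim = TRUE)
  expect_lt(out5$n_days_total, n)
  expect_error(tsm_summary(dm, cm[1:10], se, yr), "misaligned")
})

test_that("metrics are monotone in temperatures and CT_max", {
  set.seed(8)
  n <- 910L
  dm <- rnorm(n, 32, 2); cm <- rep(36, n); se <- rep(0.9, n)
  p0 <- overheating_days(exceedance_probability(dm, cm, se))$n
  p_up <- overheating_days(exceedance_probability(dm + 1, cm, se))$n
  p_ct <- overheating_days(exceedance_probability(dm, cm + 1, se))$n
  expect_gt(p_up, p0)
  expect_lt(p_ct, p0)
})

test_that("assess_vulnerability joins occurrences, exposure and plasticity", {
  cells <- data.frame(cell_id = cell_id_of(c(0, 10), c(0, 0)),
                      lat = c(0.5, 10.5), lon = c(0.5, 0.5))
  temps <- simulate_operative_temps(cells, 2005:2008, "terrestrial", 0,
                                    seed = 5L)
  ex <- build_exposure(temps)
  plast <- data.frame(species = c("a", "b"), intercept = c(31, 28),
                      slope_arr = c(0.134, 0.134),
                      var_intercept = 1e-4, var_slope = 1e-6,
                      cov_int_slope = 0, residual_tau2 = 0,
                      t_min = 10, t_max = 40, n = 3)
  occ <- data.frame(species = c("a", "a", "b"),
                    cell_id = cells$cell_id[c(1, 2, 1)])
  v <- assess_vulnerability(ex, plast, occ)
  expect_equal(nrow(v), 3L)
  expect_equal(unique(v$n_days_total), 3L * 91L)
  expect_true(all(v$p_bar >= 0 & v$p_bar <= 1))
  expect_equal(v$n_overheat_days, v$p_bar * v$n_days_total)
  # the lower-CT_max species is more exposed in the same cell
  va <- v[v$species == "a" & v$cell_id == cells$cell_id[1], ]
  vb <- v[v$species == "b" & v$cell_id == cells$cell_id[1], ]
  expect_gt(vb$n_overheat_days, va$n_overheat_days)
  expect_lt(vb$tsm_mean, va$tsm_mean)

  expect_error(assess_vulnerability(ex, plast,
                                    data.frame(species = "zz", cell_id = 1)),
               "no plasticity model")
  expect_error(assess_vulnerability(ex, plast,
                                    data.frame(species = "a", cell_id = 999)),
               "without exposure")
})
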