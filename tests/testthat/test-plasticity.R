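test_that("fit_species_plasticity reproduces exact lines and weighted fits", {
  pts <- data.frame(t_acc_ref = c(20, 25, 30), ctmax_hat = c(35, 36, 37),
                    ctmax_se = 0.5, species = "x")
  m <- fit_species_plasticity(pts)
  expect_equal(m$slope_arr, 0.2, tolerance = 1e-12)
  expect_equal(m$intercept, 31, tolerance = 1e-12)

  # equal SEs == ordinary least squares
  set.seed(4)
  pts2 <- data.frame(t_acc_ref = c(18, 22, 27, 31),
                     ctmax_hat = 30 + 0.15 * c(18, 22, 27, 31) + rnorm(4, 0, 0.3),
                     ctmax_se = 0.7)
  m2 <- fit_species_plasticity(pts2, species = "y")
  ols <- stats::lm(ctmax_hat ~ t_acc_ref, data = pts2)
  expect_equal(unname(c(m2$intercept, m2$slope_arr)),
               unname(stats::coef(ols)), tolerance = 1e-10)

  # down-weighting an outlier moves the fit toward the trusted points
  pts3 <- data.frame(t_acc_ref = c(20, 25, 30), ctmax_hat = c(35, 36, 45),
                     ctmax_se = c(0.5, 0.5, 0.5))
  pts3d <- pts3; pts3d$ctmax_se[3] <- 5
  m_eq <- fit_species_plasticity(pts3)
  m_dw <- fit_species_plasticity(pts3d)
  line2 <- stats::lm(ctmax_hat ~ t_acc_ref, data = pts3[1:2, ])
  slope2 <- stats::coef(line2)[2]
  expect_lt(abs(m_dw$slope_arr - slope2), abs(m_eq$slope_arr - slope2))

  expect_error(fit_species_plasticity(
    data.frame(t_acc_ref = c(20, 20), ctmax_hat = c(35, 36), ctmax_se = 1)),
    "unidentifiable")
})

test_that("predict_ctmax propagates coefficient uncertainty correctly", {
  pts <- data.frame(t_acc_ref = c(20, 25, 30), ctmax_hat = c(35, 36, 37),
                    ctmax_se = 0.5, species = "x")
  m <- fit_species_plasticity(pts)
  pr <- predict_ctmax(m, 27)
  expect_equal(pr$ctmax, 36.4, tolerance = 1e-10)   # exact line
  expect_false(pr$extrapolated)
  expect_true(predict_ctmax(m, 35)$extrapolated)

  # hat-matrix property: prediction SE is minimized near the weighted mean
  grid <- predict_ctmax(m, seq(15, 35, by = 0.5))
  tbar <- 25  # equal weights
  expect_lt(abs(grid$t_acc[which.min(grid$se)] - tbar), 1)

  # slope-0 model predicts a constant
  m0 <- m; m0$slope_arr <- 0
  expect_equal(predict_ctmax(m0, 10)$ctmax, predict_ctmax(m0, 40)$ctmax)
})

test_that("project_daily_ctmax follows the trailing-week rolling mean", {
  m <- structure(list(species = "x", intercept = 31, slope_arr = 0.2,
                      coef_cov = diag(c(1e-4, 1e-6)), residual_tau2 = 0,
                      t_range = c(15, 35), n = 3),
                 class = "plasticity_model")
  # constant series: flat CT_max
  ex <- data.frame(day_index = 8:20, week_mean = 25, week_max = 25,
                   daily_max = 25)
  out <- project_daily_ctmax(m, ex)
  expect_true(all(out$ctmax_day == 31 + 0.2 * 25))

  # step series ramps over exactly the window length
  x <- c(rep(20, 30), rep(30, 30))
  st <- trailing_week_stats(x, 8:60)
  ex2 <- data.frame(day_index = 8:60, week_mean = st$week_mean,
                    week_max = st$week_max, daily_max = x[8:60])
  out2 <- project_daily_ctmax(m, ex2)
  # oracle: rolling mean of the step
  roll <- vapply(8:60, function(d) mean(x[(d - 7):(d - 1)]), numeric(1))
  expect_equal(out2$ctmax_day, 31 + 0.2 * roll, tolerance = 1e-12)
  pre <- out2$ctmax_day[ex2$day_index <= 30]
  post <- out2$ctmax_day[ex2$day_index >= 38]  # window saturated
  expect_true(all(pre == pre[1]))
  expect_true(all(post == post[1]))
  expect_gt(post[1], pre[1])

  # linearity: a +4 degC shift moves CT_max by slope * 4 after saturation
  m134 <- m; m134$slope_arr <- 0.134
  out_a <- project_daily_ctmax(m134, ex2)
  ex3 <- ex2; ex3$week_mean <- ex3$week_mean + 4; ex3$daily_max <- ex3$daily_max + 4
  out_b <- project_daily_ctmax(m134, ex3)
  expect_equal(out_b$ctmax_day - out_a$ctmax_day,
               rep(0.536, nrow(ex2)), tolerance = 1e-12)

  # missing history days are dropped with a warning
  ex4 <- rbind(data.frame(day_index = 1, week_mean = NA, week_max = NA,
                          daily_max = 20), ex2)
  expect_warning(out4 <- project_daily_ctmax(m, ex4), "dropped")
  expect_equal(nrow(out4), nrow(ex2))
})

test_that("daily CT_max is monotone in the trailing-week mean for ARR >= 0", {
  m <- structure(list(species = "x", intercept = 31, slope_arr = 0.134,
                      coef_cov = diag(c(1e-4, 1e-6)), residual_tau2 = 0,
                      t_range = c(10, 40), n = 3),
                 class = "plasticity_model")
  t_grid <- seq(10, 40, by = 0.25)
  pred <- predict_ctmax(m, t_grid)$ctmax
  expect_true(all(diff(pred) >= 0))
})
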