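# generate a labelled study (true labels, no waveforms) and its model tables
study_tables <- function(seed, n_birds = 17, response = true_response_model()) {
  sched <- generate_schedules(n_birds, seed = seed)
  ds <- generate_dataset(sched, response = response, seed = seed,
                         waveforms = FALSE)
  m <- ds$meta[, .(burst_id, bird_id, site_id, day, hour, minute, time,
                   jdate, temp_c, display)]
  bt <- apply_study_window(m, ds$schedules)
  hp <- hourly_proportions(bt)
  daily <- build_daily_table(hp, qualify_days(hp), bt, ds$temperature)
  list(ds = ds, bt = bt, daily = daily)
}

null_response <- function(intercept = -0.3)
  true_response_model(intercept = intercept,
                      f_temp = list(x = c(0, 40), y = c(0, 0)),
                      f_hour = list(x = c(0, 24), y = c(0, 0)),
                      f_date = list(x = c(91, 151), y = c(0, 0)),
                      bird_sd = 0)

test_that("null truth is recovered as flat partial effects with edf near 1", {
  st <- study_tables(seed = 41, n_birds = 10, response = null_response())
  fit <- fit_hourly_model(st$bt)
  pe <- partial_effects(fit)
  expect_lt(max(abs(pe$effect)), 0.25)
  expect_true(all(fit$edf[fit$terms] < 2))
  # bands cover zero over at least 90% of grid points
  expect_gt(mean(pe$lower <= 0 & pe$upper >= 0), 0.9)
})

test_that("hourly model recovers the true temperature and hour shapes", {
  st <- study_tables(seed = 42)
  fit <- fit_hourly_model(st$bt)
  expect_s3_class(fit, "lekaccel_fit")
  expect_true(all(fit$edf[fit$terms] <= 3 + 1e-6))  # k = 4 bound
  pe <- partial_effects(fit, "s(temp_c)")
  truth <- st$ds$truth$functions$f_temp
  tv <- approx(truth$x, truth$y, pe$x, rule = 2)$y
  expect_gt(cor(pe$effect, tv), 0.9)
  # declines over the steep 8-20 C stretch
  lowr <- pe[x >= 8 & x <= 20]
  expect_lt(lowr$effect[nrow(lowr)], lowr$effect[1])
  # morning effect exceeds midday effect
  ph <- partial_effects(fit, "s(time)")
  expect_gt(mean(ph[x >= 5 & x <= 7, effect]),
            mean(ph[x >= 12 & x <= 16, effect]))
  expect_error(partial_effects(fit, "s(wind)"), "unknown term")
})

test_that("daily model recovers a decreasing temperature effect", {
  st <- study_tables(seed = 43)
  fit <- fit_daily_model(st$daily)
  pe <- partial_effects(fit, "s(daytime_mean_temp)")
  expect_lt(pe$effect[nrow(pe)], pe$effect[1])
  expect_true(all(pe$lower <= pe$effect & pe$effect <= pe$upper))
  expect_lt(fit$random_intercept_variance, 0.05)
  expect_error(fit_daily_model(st$daily[1:5]), "nrow")
})

test_that("single-bird input drops the random effect with a warning", {
  st <- study_tables(seed = 44, n_birds = 6)
  one <- st$bt[bird_id == st$bt$bird_id[1]]
  expect_warning(fit <- fit_hourly_model(one), "single bird")
  expect_false("s(bird_id)" %in% rownames(fit$s_table))
})

test_that("in-sample deviance is monotone in basis dimension", {
  st <- study_tables(seed = 45, n_birds = 8)
  dev <- sapply(c(3, 4, 5), function(k)
    deviance(fit_hourly_model(st$bt, k = k, method = "GCV.Cp")$gam))
  expect_true(all(diff(dev) <= 1e-6))
})

test_that("fitted probabilities follow a monotone injected effect", {
  st <- study_tables(seed = 46, n_birds = 8,
                     response = true_response_model(
                       intercept = 0,
                       f_temp = list(x = c(0, 40), y = c(2, -2)),
                       f_hour = list(x = c(0, 24), y = c(0, 0)),
                       f_date = list(x = c(91, 151), y = c(0, 0)),
                       bird_sd = 0))
  fit <- fit_hourly_model(st$bt)
  pe <- partial_effects(fit, "s(temp_c)")
  expect_lt(cor(pe$x, pe$effect), -0.95)  # essentially linear decreasing
})

test_that("partial-effect export round-trips losslessly", {
  st <- study_tables(seed = 47, n_birds = 6)
  pe <- partial_effects(fit_daily_model(st$daily), grid_size = 25)
  f <- withr::local_tempfile(fileext = ".csv")
  fwrite(pe, f)
  back <- fread(f)
  expect_equal(back$effect, pe$effect, tolerance = 1e-12)
  expect_equal(back$lower, pe$lower, tolerance = 1e-12)
})

test_that("CV error metrics match their definitions in limiting cases", {
  # noiseless gaussian: activity is an exact linear function of temperature
  set.seed(48)
  daily <- data.table(bird_id = rep(sprintf("b%d", 1:5), each = 20),
                      jdate = rep(101:120, 5),
                      daytime_mean_temp = runif(100, 10, 26))
  daily[, display_activity := 0.9 - 0.02 * daytime_mean_temp +
          rnorm(.N, 0, 0.002)]
  cvd <- cv_predictive_error("daily", daily, k = 10, seed = 1)
  expect_equal(cvd$metric, "nrmse")
  expect_lt(cvd$mean, 0.05)

  # pure-noise binary response: error rate ~ majority baseline 100*min(p,1-p)
  set.seed(49)
  n <- 3000
  bt <- data.table(bird_id = rep(sprintf("b%d", 1:6), length.out = n),
                   temp_c = runif(n, 5, 30), time = runif(n, 5, 21),
                   jdate = sample(100:140, n, TRUE),
                   display = rbinom(n, 1, 0.3))
  cvh <- cv_predictive_error("hourly", bt, k = 5, seed = 2)
  expect_equal(cvh$metric, "error_rate")
  expect_equal(cvh$mean, 30, tolerance = 0.12)
  expect_true(cvh$sd >= 0)
})

test_that("CV folds depend only on the seeded index, not row order", {
  st <- study_tables(seed = 50, n_birds = 8)
  a <- cv_predictive_error("daily", st$daily, k = 5, seed = 9)
  b <- cv_predictive_error("daily", st$daily, k = 5, seed = 9)
  expect_identical(a$per_fold, b$per_fold)
  shuf <- st$daily[sample(.N)]
  c2 <- cv_predictive_error("daily", shuf, k = 5, seed = 9)
  expect_equal(c2$mean, a$mean, tolerance = 0.5)  # fold-sampling noise only
})
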