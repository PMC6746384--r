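test_that("display bursts reproduce the video-validated signature", {
  sig <- default_signatures()$display
  b <- generate_bursts("display", sig, n = 6000, seed = 11)
  pm <- b[, .(sway = mean(sway_g), surge = mean(surge_g),
              heave = mean(heave_g)), by = burst_id]
  expect_lt(abs(mean(pm$heave) - 0.60), 0.01)
  expect_lt(abs(mean(pm$sway) - (-0.03)), 0.01)
  expect_lt(abs(mean(pm$surge) - 0.81), 0.01)
  expect_lt(abs(sd(pm$heave) - 0.10), 0.015)
  expect_lt(abs(sd(pm$sway) - 0.03), 0.005)
  expect_lt(abs(sd(pm$surge) - 0.09), 0.015)
})

test_that("per-class empirical means converge to the signature as n grows", {
  for (cl in c("rest", "alert")) {
    sig <- default_signatures()[[cl]]
    err <- sapply(c(200, 5000), function(n) {
      b <- generate_bursts(cl, sig, n = n, seed = 7)
      pm <- b[, .(mean(sway_g), mean(surge_g), mean(heave_g)), by = burst_id]
      max(abs(colMeans(as.matrix(pm[, -1])) - sig$static_mean))
    })
    expect_lt(err[2], err[1])            # standard-error scaling
    expect_lt(err[2], 0.01)
  }
})

test_that("degenerate signatures and error cases behave", {
  sig <- class_signature(c(0, 0, 1), c(0, 0, 0), c(0, 0, 0))
  b <- generate_burst("rest", sig, n_samples = 10, seed = 1)
  expect_equal(b$heave_g, rep(1, 10))
  expect_equal(b$sway_g, rep(0, 10))
  expect_error(generate_burst("swim", sig), "unknown behaviour class")
  expect_error(generate_burst("rest", sig, n_samples = 0), "n_samples")
  expect_error(class_signature(c(0, 0, 7), c(0, 0, 0), c(0, 0, 0)), "6 g")
  expect_error(class_signature(c(0, 0, 1), c(-1, 0, 0), c(0, 0, 0)), "sds")
})

test_that("flight bursts only rarely approach 3 g and never exceed 6 g", {
  b <- generate_bursts("flight", default_signatures()$flight, n = 2000,
                       seed = 13)
  nr <- sqrt(b$sway_g^2 + b$surge_g^2 + b$heave_g^2)
  expect_gt(max(nr), 2)       # some samples approach 3 g
  expect_lt(mean(nr > 3), 0.01)
  expect_true(all(nr <= 6 * sqrt(3) + 1e-12))
  expect_true(all(abs(c(b$sway_g, b$surge_g, b$heave_g)) <= 6))
})

test_that("schedules match the tracking-duration distribution", {
  durs <- unlist(lapply(1:50, function(s) generate_schedules(17, seed = s)$duration))
  expect_true(all(durs >= 2 & durs <= 25))
  expect_equal(mean(durs), 12.8, tolerance = 0.06)  # relative tol ~ +-0.7 d
  s1 <- generate_schedules(17, seed = 99)
  expect_identical(s1, generate_schedules(17, seed = 99))  # determinism
  expect_false(identical(s1$start_day, generate_schedules(17, seed = 100)$start_day))
  one <- generate_schedules(1, seed = 3)
  expect_equal(nrow(one), 1L)
  expect_true(one$duration >= 2 && one$duration <= 25)
  expect_true(all(s1$start_day + s1$duration - 1L <= 151L))
  expect_true(all(s1$burst_interval %in% c(10L, 20L)))
})

test_that("temperature model hits the calibrated study targets", {
  env <- environment_model()
  temps <- generate_temperature(env, 93:140, paste0("site", 1:5), seed = 21)
  day <- temps[hour >= 5 & hour < 21]
  expect_equal(mean(day$temp_c), 18, tolerance = 0.03)
  daily_means <- day[, .(m = mean(temp_c)), by = .(site_id, day)]$m
  expect_gt(diff(range(daily_means)), 12)   # wide span of daily conditions
  expect_true(all(daily_means > 5 & daily_means < 35))

  # degenerate: no trend, no cycle, no noise -> constant at the daytime mean
  env0 <- environment_model(seasonal_slope = 0, diurnal_amplitude = 0,
                            site_offset_sd = 0, daily_weather_sd = 0,
                            hourly_noise_sd = 0)
  t0 <- generate_temperature(env0, 100:102, "s1", seed = 1)
  expect_equal(t0$temp_c, rep(18, nrow(t0)))
})

test_that("daylight predictor correlations match the printed diagnostics", {
  sched <- generate_schedules(17, seed = 31)
  ds <- generate_dataset(sched, seed = 31, waveforms = FALSE)
  day <- ds$meta[hour >= 5 & hour < 21]
  expect_equal(cor(day$temp_c, day$time), 0.51, tolerance = 0.12)
  expect_lt(abs(cor(day$time, day$jdate)), 0.1)
  expect_lt(abs(cor(day$temp_c, day$jdate) - 0.16), 0.2)
})

test_that("default study prevalence is calibrated to 41.5% of daylight bursts", {
  sched <- generate_schedules(17, seed = 5)
  ds <- generate_dataset(sched, seed = 5, waveforms = FALSE)
  day <- ds$meta[hour >= 5 & hour < 21]
  expect_equal(mean(day$display), 0.415, tolerance = 0.1)  # ~ +-4pp absolute
})

test_that("prevalence is monotone in the intercept and null model is flat", {
  sched <- generate_schedules(6, seed = 2)
  prev <- sapply(c(-1, 0, 1), function(b0) {
    resp <- true_response_model(intercept = b0)
    ds <- generate_dataset(sched, response = resp, seed = 2, waveforms = FALSE)
    mean(ds$meta$display)
  })
  expect_true(all(diff(prev) > 0))

  null_resp <- true_response_model(
    intercept = 0.4,
    f_temp = list(x = c(0, 40), y = c(0, 0)),
    f_hour = list(x = c(0, 24), y = c(0, 0)),
    f_date = list(x = c(91, 151), y = c(0, 0)),
    bird_sd = 0)
  ds <- generate_dataset(sched, response = null_resp, seed = 2,
                         waveforms = FALSE)
  expect_equal(unique(ds$meta$p_true), plogis(0.4))
  expect_equal(mean(ds$meta$display), plogis(0.4), tolerance = 0.02)
})

test_that("complete 10-min days carry exactly 96 daylight bursts; labels are one-to-one", {
  sched <- data.table(bird_id = "b1", site_id = "site1", start_day = 100L,
                      duration = 3L, burst_interval = 10L)
  ds <- generate_dataset(sched, seed = 8, missingness = 0)
  per_day <- ds$meta[hour >= 5 & hour < 21, .N, by = day]
  expect_equal(per_day$N, rep(96L, 3))
  expect_equal(nrow(ds$meta) * 10L, nrow(ds$bursts))
  expect_identical(sort(unique(ds$bursts$burst_id)), sort(ds$meta$burst_id))
  expect_true(all(ds$meta$class %in% behaviour_classes))

  # determinism contract
  ds2 <- generate_dataset(sched, seed = 8, missingness = 0)
  expect_identical(ds$meta, ds2$meta)
  expect_identical(ds$bursts, ds2$bursts)
})

test_that("incomplete signature sets are rejected", {
  sched <- generate_schedules(2, seed = 1)
  expect_error(generate_dataset(sched, signatures = list()), "missing signatures")
})
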