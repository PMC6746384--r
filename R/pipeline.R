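# End-to-end orchestration: simulate -> features -> classify -> aggregate
# -> model -> project, with one top-level seed fanned out to per-stage
# substreams and a run manifest reconciling every stage's row counts.

#' Run the full pipeline
#'
#' Executes every stage on one output directory. Identical config + seed
#' reproduce identical outputs; each stochastic stage draws its seed from
#' the top-level seed via [substream_seed()].
#'
#' @param config nested list as [default_config()] (validated first)
#' @param out_dir output directory (created if needed); `NULL` keeps
#'   everything in memory
#' @return list with `manifest` and the stage outputs (`dataset`,
#'   `features`, `cv_reports`, `best_family`, `labels`, `burst_table`,
#'   `daily_table`, `hourly_fit`, `daily_fit`, `cv_error_hourly`,
#'   `cv_error_daily`, `scenarios`, `correlations`)
#' @export
run_all <- function(config = default_config(), out_dir = NULL) {
  config <- validate_config(config)
  seed <- config$seed
  t0 <- Sys.time()
  manifest <- list(config = config, seed = seed,
                   started = format(t0, "%Y-%m-%dT%H:%M:%S"), stages = list())
  note <- function(stage, n_in, n_out)
    manifest$stages[[stage]] <<- list(n_in = n_in, n_out = n_out)

  # -- simulate ------------------------------------------------------------
  sched <- generate_schedules(config$simulate$n_birds,
                              seed = substream_seed(seed, "schedules"))
  ds <- generate_dataset(sched, environment_model(), true_response_model(),
                         default_signatures(),
                         seed = substream_seed(seed, "simulate"),
                         missingness = config$simulate$missingness)
  note("simulate", config$simulate$n_birds, nrow(ds$meta))

  # -- features ------------------------------------------------------------
  feats <- extract_features_all(ds$bursts, window_s = config$label_window_s)
  note("features", nrow(ds$meta), nrow(feats))

  # -- classify ------------------------------------------------------------
  labeled <- make_training_subset(feats, ds$meta[, .(burst_id, class)],
                                  fraction = config$training_fraction,
                                  seed = substream_seed(seed, "subset"))
  reports <- train_and_cv(labeled, config$classifier$families,
                          k = config$cv_folds,
                          seed = substream_seed(seed, "cv"))
  best <- select_best(reports)
  final <- train_model(best, feature_matrix(labeled$features), labeled$label,
                       seed = substream_seed(seed, "final_model"))
  labels <- classify_remaining(final, feats, labeled,
                               threshold = config$classifier$threshold)
  note("classify", nrow(feats), nrow(labels))

  # -- aggregate -----------------------------------------------------------
  meta_lab <- labels[, .(burst_id, display)][
    ds$meta[, .(burst_id, bird_id, site_id, day, hour, minute, time, jdate)],
    on = "burst_id"]
  meta_lab <- align_temperature(meta_lab, ds$temperature)
  bt <- apply_study_window(meta_lab, ds$schedules,
                           daylight = config$daylight_window,
                           post_tag_days = config$post_tag_exclusion_days)
  hp <- hourly_proportions(bt)
  qd <- qualify_days(hp, min_bursts = config$min_bursts_per_hour,
                     min_hours = config$min_hours_per_day)
  daily <- build_daily_table(hp, qd, bt, ds$temperature,
                             daylight = config$daylight_window)
  note("aggregate", nrow(meta_lab), nrow(daily))
  cors <- predictor_correlations(bt, daily)

  # -- model ---------------------------------------------------------------
  hf <- fit_hourly_model(bt, k = config$smooth_basis_k)
  df <- fit_daily_model(daily, k = config$smooth_basis_k)
  cvh <- cv_predictive_error("hourly", bt, k = config$cv_folds,
                             seed = substream_seed(seed, "cv_hourly"),
                             basis_k = config$smooth_basis_k)
  cvd <- cv_predictive_error("daily", daily, k = config$cv_folds,
                             seed = substream_seed(seed, "cv_daily"),
                             basis_k = config$smooth_basis_k)
  note("model", nrow(bt) + nrow(daily), 2L)

  # -- project -------------------------------------------------------------
  sc <- suppressWarnings(project(df, daily, deltas = config$scenario_deltas))
  note("project", nrow(daily), nrow(sc))

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  out <- list(manifest = manifest, dataset = ds, features = feats,
              cv_reports = reports, best_family = best, labels = labels,
              burst_table = bt, daily_table = daily, hourly_fit = hf,
              daily_fit = df, cv_error_hourly = cvh, cv_error_daily = cvd,
              scenarios = sc, correlations = cors)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_bursts(ds$meta, ds$bursts, file.path(out_dir, "bursts.csv"))
    write_temperature(ds$temperature, file.path(out_dir, "temperature.csv"))
    write_labels(ds$meta[, .(burst_id, class)],
                 file.path(out_dir, "true_labels.csv"))
    write_labels(labels, file.path(out_dir, "predicted_labels.csv"))
    fwrite(feats, file.path(out_dir, "features.csv"))
    fwrite(bt, file.path(out_dir, "burst_table.csv"))
    fwrite(daily, file.path(out_dir, "daily_table.csv"))
    fwrite(sc, file.path(out_dir, "scenarios.csv"))
    fwrite(partial_effects(hf), file.path(out_dir, "partial_effects_hourly.csv"))
    fwrite(partial_effects(df), file.path(out_dir, "partial_effects_daily.csv"))
    jsonlite::write_json(
      list(truth = list(intercept = ds$truth$intercept,
                        bird_sd = ds$truth$bird_sd,
                        f_temp = ds$truth$functions$f_temp,
                        f_hour = ds$truth$functions$f_hour,
                        f_date = ds$truth$functions$f_date),
           cv_reports = lapply(reports, function(r)
             r[c("family", "precision", "recall")]),
           best_family = best,
           correlations = as.list(cors),
           cv_error_hourly = cvh[c("metric", "mean", "sd")],
           cv_error_daily = cvd[c("metric", "mean", "sd")],
           edf_hourly = as.list(hf$edf), edf_daily = as.list(df$edf)),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  out
}
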