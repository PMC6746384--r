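# Study-design temporal filters and the two modelling tables.
#
# Hour-of-day is the integer clock hour of the burst start; the daylight
# window [5, 21) is half-open, giving exactly 16 daylight hours. Daily
# display activity is the unweighted mean of hourly display proportions so
# unevenly sampled hours do not bias the daily average.

#' Apply the study observation window
#'
#' Drops bursts from the first `post_tag_days` days after tagging (so
#' behaviour has normalised) and bursts outside the [5:00, 21:00) daylight
#' window. Counts removed by each rule are attached as attributes and
#' logged.
#'
#' @param meta burst-level table with `bird_id`, `day`, `hour`
#' @param schedules table with `bird_id`, `start_day`
#' @param daylight integer `c(start, end)` clock hours, default `c(5, 21)`
#' @param post_tag_days days excluded after tagging start (default 2)
#' @return filtered copy of `meta` with attributes `n_removed_post_tag` and
#'   `n_removed_night`
#' @export
apply_study_window <- function(meta, schedules, daylight = c(5L, 21L),
                               post_tag_days = 2L) {
  meta <- as.data.table(meta)
  schedules <- as.data.table(schedules)
  if (length(setdiff(meta$bird_id, schedules$bird_id)))
    stop("burst(s) from bird(s) with no schedule: ",
         paste(setdiff(meta$bird_id, schedules$bird_id), collapse = ", "))
  m <- schedules[, .(bird_id, start_day)][meta, on = "bird_id"]
  keep_tag <- m$day >= m$start_day + post_tag_days
  keep_light <- m$hour >= daylight[1] & m$hour < daylight[2]
  out <- m[keep_tag & keep_light][, start_day := NULL]
  setattr(out, "n_removed_post_tag", sum(!keep_tag))
  setattr(out, "n_removed_night", sum(keep_tag & !keep_light))
  log_stage("filter", "post-tag removed %d, night removed %d, retained %d",
            sum(!keep_tag), sum(keep_tag & !keep_light), nrow(out))
  out[]
}

#' Hourly display proportions per bird-day-hour cell
#'
#' Cells with no bursts are absent, not zero.
#'
#' @param records filtered burst table with `bird_id`, `day`, `hour`,
#'   `display` (0/1)
#' @return `data.table` with `bird_id`, `day`, `hour`, `n_bursts`,
#'   `n_display`, `prop`
#' @export
hourly_proportions <- function(records) {
  r <- as.data.table(records)
  out <- r[, .(n_bursts = .N, n_display = sum(display)),
           by = .(bird_id, day, hour)]
  out[, prop := n_display / n_bursts]
  setorder(out, bird_id, day, hour)
  out[]
}

#' Qualify bird-days for the daily model
#'
#' A bird-day qualifies iff at least `min_hours` distinct daylight hours
#' each contain at least `min_bursts` bursts (study rule: >= 2 bursts/hour
#' for >= 11 of the 16 daylight hours).
#'
#' @param hourly from [hourly_proportions()]
#' @param min_bursts per-hour burst minimum (default 2)
#' @param min_hours minimum qualifying hours (default 11)
#' @return `data.table` of qualifying `bird_id`, `day` pairs with
#'   `n_hours_ok`
#' @export
qualify_days <- function(hourly, min_bursts = 2L, min_hours = 11L) {
  h <- as.data.table(hourly)
  q <- h[, .(n_hours_ok = sum(n_bursts >= min_bursts)), by = .(bird_id, day)]
  q[n_hours_ok >= min_hours][]
}

#' Build the daily modelling table
#'
#' For each qualifying bird-day: `display_activity` is the unweighted mean
#' of the day's hourly proportions (every daylight hour with >= 1 burst
#' contributes equally), and `daytime_mean_temp` is the mean of the site's
#' hourly readings over the full [5, 21) daylight window for that day,
#' using all temperature data regardless of burst coverage.
#'
#' @param hourly from [hourly_proportions()]
#' @param qualified from [qualify_days()]
#' @param meta burst table carrying `bird_id` -> `site_id`
#' @param temps temperature table (`site_id`, `day`, `hour`, `temp_c`)
#' @param daylight daylight window, default `c(5, 21)`
#' @return `data.table` with `bird_id`, `day`, `jdate`, `display_activity`,
#'   `daytime_mean_temp`, `n_hours_used`
#' @export
build_daily_table <- function(hourly, qualified, meta, temps,
                              daylight = c(5L, 21L)) {
  stopifnot(nrow(qualified) >= 1L)
  h <- as.data.table(hourly)[as.data.table(qualified)[, .(bird_id, day)],
                             on = c("bird_id", "day")]
  act <- h[, .(display_activity = mean(prop), n_hours_used = .N),
           by = .(bird_id, day)]
  site_of <- unique(as.data.table(meta)[, .(bird_id, site_id)])
  daytemp <- as.data.table(temps)[hour >= daylight[1] & hour < daylight[2],
                                  .(daytime_mean_temp = mean(temp_c)),
                                  by = .(site_id, day)]
  out <- act[site_of, on = "bird_id", nomatch = NULL]
  out <- daytemp[out, on = c("site_id", "day")]
  if (anyNA(out$daytime_mean_temp))
    stop("missing daytime temperatures for some qualifying bird-days")
  out[, jdate := day]
  setorder(out, bird_id, day)
  out[, .(bird_id, site_id, day, jdate, display_activity, daytime_mean_temp,
          n_hours_used)]
}

#' Predictor-correlation diagnostics
#'
#' The multi-collinearity checks performed before modelling: burst-level
#' temperature vs time of day, temperature vs Julian date, time vs Julian
#' date, and daily mean temperature vs Julian date.
#'
#' @param burst_table burst-level table with `temp_c`, `time`, `jdate`
#' @param daily_table optional daily table with `daytime_mean_temp`, `jdate`
#' @return named numeric vector of Pearson correlations
#' @export
predictor_correlations <- function(burst_table, daily_table = NULL) {
  b <- as.data.table(burst_table)
  out <- c(temp_vs_time = cor(b$temp_c, b$time),
           temp_vs_date = cor(b$temp_c, b$jdate),
           time_vs_date = cor(b$time, b$jdate))
  if (!is.null(daily_table)) {
    d <- as.data.table(daily_table)
    out <- c(out, daily_temp_vs_date = cor(d$daytime_mean_temp, d$jdate))
  }
  log_stage("diagnostics", paste(sprintf("%s=%.2f", names(out), out),
                                 collapse = " "))
  out
}
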