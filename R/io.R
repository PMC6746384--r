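# File formats, configuration and input validation.
#
# All tables travel as plain CSV. Timestamps are local solar time written as
# ISO-8601 (no time zone arithmetic); the calendar year is a fixed non-leap
# year so Julian date is simply day-of-year (Jan 1 = 1).

.lekaccel_year <- 2014L  # non-leap reference year for timestamps

# day-of-year + hour + minute -> ISO-8601 string (vectorised)
format_timestamp <- function(day, hour, minute = 0L) {
  origin <- as.Date(sprintf("%d-01-01", .lekaccel_year))
  format(as.POSIXct(as.Date(day - 1L, origin = origin), tz = "UTC") +
           hour * 3600 + minute * 60, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

# ISO-8601 string -> list(day, hour, minute)
parse_timestamp <- function(ts) {
  t <- as.POSIXct(ts, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  if (anyNA(t)) stop("malformed timestamp(s): ",
                     paste(head(ts[is.na(t)], 3L), collapse = ", "))
  list(day = as.integer(strftime(t, "%j", tz = "UTC")),
       hour = as.integer(strftime(t, "%H", tz = "UTC")),
       minute = as.integer(strftime(t, "%M", tz = "UTC")))
}

#' Default pipeline configuration
#'
#' Every study constant lives here rather than in code: the daylight window
#' (5:00-21:00, half-open so it spans exactly 16 hours), the 2-day
#' post-tagging exclusion, the 10% training fraction, the 7-s labelling
#' window, 10-fold cross-validation, spline basis dimension k = 4, the
#' >= 2 bursts/hour for >= 11 of 16 daylight hours day-qualification rule,
#' and the +1..+7 degC warming scenarios.
#'
#' @return nested named list
#' @export
default_config <- function() {
  list(
    seed = 1L,
    daylight_window = c(5L, 21L),
    post_tag_exclusion_days = 2L,
    label_window_s = 7L,
    training_fraction = 0.10,
    cv_folds = 10L,
    smooth_basis_k = 4L,
    min_bursts_per_hour = 2L,
    min_hours_per_day = 11L,
    scenario_deltas = 1:7,
    out_of_range_policy = "reject",   # or "clip"
    simulate = list(n_birds = 17L, missingness = 0.4),
    classifier = list(
      families = c("random_forest", "decision_tree", "knn", "linear_svm"),
      random_forest = list(ntree = 500L, min_node = 1L, max_depth = 30L,
                           sample_frac = 1.0),
      decision_tree = list(min_node = 5L, max_depth = 30L),
      knn = list(k = 5L),
      linear_svm = list(lambda = 1e-3),
      threshold = 0.5,
      group_folds_by_bird = FALSE
    )
  )
}

#' Read a pipeline configuration file
#'
#' YAML key-value file; keys absent from the file keep their defaults.
#' Unknown top-level keys are an error (fail fast before any stage runs).
#'
#' @param path YAML file, or `NULL` for pure defaults
#' @return nested named list as [default_config()]
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  bad <- setdiff(names(user), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  validate_config(modifyList(cfg, user))
}

#' Validate a pipeline configuration
#'
#' @param cfg nested list as returned by [default_config()]
#' @return `cfg`, invisibly usable; stops with a named error on violation
#' @export
validate_config <- function(cfg) {
  req <- names(default_config())
  miss <- setdiff(req, names(cfg))
  if (length(miss)) stop("missing config key(s): ", paste(miss, collapse = ", "))
  if (diff(cfg$daylight_window) != 16L)
    stop("daylight_window must span 16 hours")
  if (cfg$training_fraction <= 0 || cfg$training_fraction > 1)
    stop("training_fraction must be in (0, 1]")
  stopifnot(cfg$cv_folds >= 2L, cfg$smooth_basis_k >= 3L,
            cfg$min_bursts_per_hour >= 1L, cfg$min_hours_per_day >= 1L,
            cfg$post_tag_exclusion_days >= 0L)
  cfg
}

#' Write accelerometer bursts to CSV
#'
#' Long format: one row per sample, columns `bird_id`, `site_id`,
#' `timestamp` (ISO-8601), `sample_index` (0-9), `sway_g`, `surge_g`,
#' `heave_g`.
#'
#' @param meta burst-level table with `burst_id`, `bird_id`, `site_id`,
#'   `day`, `hour`, `minute`
#' @param bursts long per-sample table keyed by `burst_id`
#' @param path output CSV path
#' @export
write_bursts <- function(meta, bursts, path) {
  out <- as.data.table(bursts)[
    as.data.table(meta)[, .(burst_id, bird_id, site_id, day, hour, minute)],
    on = "burst_id"]
  out[, timestamp := format_timestamp(day, hour, minute)]
  setorder(out, bird_id, timestamp, sample_index)
  fwrite(out[, .(bird_id, site_id, timestamp, sample_index,
                 sway_g, surge_g, heave_g)], path)
  invisible(path)
}

#' Read accelerometer bursts from CSV
#'
#' Groups rows into bursts by (bird, timestamp); grouping is insensitive to
#' row order in the file. Bursts with fewer than `min_samples` samples, a
#' non-contiguous `sample_index`, or (under the "reject" policy)
#' accelerations outside the +/- 6 g sensor range are rejected with a
#' warning naming the burst; the remaining bursts load.
#'
#' @param path CSV written by [write_bursts()]
#' @param min_samples minimum samples per burst (default 7, the labelling
#'   window)
#' @param out_of_range one of "reject" (drop the burst) or "clip"
#' @return list with `meta` (burst-level: `burst_id`, `bird_id`, `site_id`,
#'   `day`, `hour`, `minute`, `time`, `jdate`, `n_samples`) and `bursts`
#'   (long per-sample table), plus `rejected` (burst ids with reasons)
#' @export
read_bursts <- function(path, min_samples = 7L,
                        out_of_range = c("reject", "clip")) {
  out_of_range <- match.arg(out_of_range)
  need <- c("bird_id", "site_id", "timestamp", "sample_index",
            "sway_g", "surge_g", "heave_g")
  dt <- fread(path, colClasses = list(character = c("bird_id", "site_id",
                                                    "timestamp")))
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("bursts CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  dt[, row_nr := .I + 1L]  # physical line number incl. header
  setorder(dt, bird_id, timestamp, sample_index)
  dt[, burst_id := paste(bird_id, timestamp, sep = "|")]

  bad <- dt[, {
    n <- .N
    contiguous <- identical(as.integer(sample_index), seq_len(n) - 1L)
    reason <- if (n < min_samples) sprintf("only %d samples", n)
      else if (!contiguous) "non-contiguous sample_index"
      else NA_character_
    .(reason = reason, line = row_nr[1L])
  }, by = burst_id][!is.na(reason)]

  vals <- c(dt$sway_g, dt$surge_g, dt$heave_g)
  if (any(abs(vals) > 6)) {
    if (out_of_range == "clip") {
      for (cc in c("sway_g", "surge_g", "heave_g"))
        dt[, (cc) := pmin(pmax(get(cc), -6), 6)]
      warning("acceleration values outside +/- 6 g clipped")
    } else {
      oob <- dt[abs(sway_g) > 6 | abs(surge_g) > 6 | abs(heave_g) > 6,
                .(reason = "acceleration outside +/- 6 g", line = row_nr[1L]),
                by = burst_id]
      bad <- unique(rbind(bad, oob), by = "burst_id")
    }
  }
  if (nrow(bad))
    warning(sprintf("rejected %d burst(s); first: %s (line %d, %s)",
                    nrow(bad), bad$burst_id[1L], bad$line[1L], bad$reason[1L]))
  dt <- dt[!burst_id %in% bad$burst_id]

  ts <- parse_timestamp(dt$timestamp)
  dt[, `:=`(day = ts$day, hour = ts$hour, minute = ts$minute)]
  meta <- dt[, .(bird_id = bird_id[1L], site_id = site_id[1L],
                 day = day[1L], hour = hour[1L], minute = minute[1L],
                 n_samples = .N), by = burst_id]
  meta[, `:=`(time = hour + minute / 60, jdate = day)]
  bursts <- dt[, .(burst_id, sample_index, sway_g, surge_g, heave_g)]
  setkey(bursts, burst_id, sample_index)
  list(meta = meta[], bursts = bursts[],
       rejected = bad[, .(burst_id, reason, line)])
}

#' Write / read a temperature series CSV
#'
#' Columns `site_id`, `timestamp` (ISO-8601, one reading per hour),
#' `temp_c`.
#'
#' @param temps table with `site_id`, `day`, `hour`, `temp_c`
#' @param path CSV path
#' @export
write_temperature <- function(temps, path) {
  out <- as.data.table(temps)[, .(site_id, timestamp = format_timestamp(day, hour),
                                  temp_c)]
  fwrite(out, path)
  invisible(path)
}

#' @rdname write_temperature
#' @return `read_temperature`: `data.table` with `site_id`, `day`, `hour`,
#'   `temp_c`; stops if timestamps are not strictly increasing within a
#'   site, warns on gaps
#' @export
read_temperature <- function(path) {
  dt <- fread(path, colClasses = list(character = c("site_id", "timestamp")))
  miss <- setdiff(c("site_id", "timestamp", "temp_c"), names(dt))
  if (length(miss)) stop("temperature CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  ts <- parse_timestamp(dt$timestamp)
  dt[, `:=`(day = ts$day, hour = ts$hour)]
  setorder(dt, site_id, day, hour)
  key <- dt[, day * 24L + hour]
  if (any(dt[, .(dup = anyDuplicated(day * 24L + hour) > 0L), by = site_id]$dup))
    stop("temperature timestamps not strictly increasing (duplicates) within a site")
  gaps <- dt[, .(gap = any(diff(day * 24L + hour) > 1L)), by = site_id]
  if (any(gaps$gap))
    warning("temperature series has gaps at site(s): ",
            paste(gaps[gap == TRUE, site_id], collapse = ", "))
  dt[, .(site_id, day, hour, temp_c)]
}

#' Write / read a labels CSV (burst key + behaviour class)
#'
#' @param labels table with `burst_id` and `class` (or predicted columns)
#' @param path CSV path
#' @export
write_labels <- function(labels, path) {
  fwrite(as.data.table(labels), path)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  dt <- fread(path, colClasses = list(character = "burst_id"))
  if (!"burst_id" %in% names(dt)) stop("labels CSV missing column: burst_id")
  dt
}

#' Attach hourly temperature to bursts
#'
#' Each burst gets its site's reading for the clock hour containing the
#' burst start; no interpolation. Bursts whose site/hour has no reading are
#' flagged (`temp_missing`), not silently dropped or interpolated.
#'
#' @param meta burst-level table with `site_id`, `day`, `hour`
#' @param temps temperature table with `site_id`, `day`, `hour`, `temp_c`
#' @return `meta` with `temp_c` and logical `temp_missing` columns
#' @export
align_temperature <- function(meta, temps) {
  meta <- as.data.table(meta)
  temps <- as.data.table(temps)
  if (length(setdiff(meta$site_id, temps$site_id)))
    stop("site(s) without any temperature series: ",
         paste(setdiff(meta$site_id, temps$site_id), collapse = ", "))
  out <- temps[, .(site_id, day, hour, temp_c)][meta, on = c("site_id", "day", "hour")]
  out[, temp_missing := is.na(temp_c)]
  if (any(out$temp_missing))
    warning(sum(out$temp_missing), " burst(s) have no temperature reading for their hour")
  out[]
}
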