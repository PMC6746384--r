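# Per-burst summary-statistic features for behaviour classification.
#
# All statistics are computed on the first `window_s` samples (default 7,
# matching the manual labelling window). Conventions, fixed once and used
# everywhere: sd and covariance use the n-1 denominator; skewness is the
# bias-uncorrected third standardised moment; kurtosis is excess (normal ->
# 0); quantiles interpolate linearly between order statistics (R type 7);
# zero-variance axes yield skewness = kurtosis = Pearson r = 0 so constant
# (resting) bursts never produce undefined features.

.axes <- c("sway", "surge", "heave")
.axis_cols <- c("sway_g", "surge_g", "heave_g")

#' Names of the burst feature vector, in pipeline order
#'
#' Per axis: mean, sd, skewness, kurtosis, min, max, q25, q50, q75; per axis
#' pair: covariance, Pearson r, mean absolute difference; plus per-sample
#' vector-norm mean and sd, and ODBA.
#' @return character vector of 39 feature names
#' @export
feature_names <- function() {
  per_axis <- as.vector(t(outer(.axes,
    c("mean", "sd", "skew", "kurt", "min", "max", "q25", "q50", "q75"),
    paste, sep = "_")))
  pairs <- c("sway_surge", "sway_heave", "surge_heave")
  c(per_axis,
    as.vector(t(outer(pairs, c("cov", "cor", "mad"), paste, sep = "_"))),
    "norm_mean", "norm_sd", "odba")
}

# moments of the columns of an n-burst x window matrix, vectorised over rows
row_stats <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  d <- m - mu
  m2 <- rowMeans(d^2)                      # population variance
  s <- sqrt(rowSums(d^2) / (n - 1))        # sample sd
  skew <- ifelse(m2 > 0, rowMeans(d^3) / m2^1.5, 0)
  kurt <- ifelse(m2 > 0, rowMeans(d^4) / m2^2 - 3, 0)
  srt <- t(apply(m, 1L, sort))
  q <- function(p) {                       # type-7 quantile on sorted rows
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    srt[, lo] + (h - lo) * (srt[, hi] - srt[, lo])
  }
  list(mean = mu, sd = s, skew = skew, kurt = kurt,
       min = srt[, 1L], max = srt[, n],
       q25 = q(0.25), q50 = q(0.5), q75 = q(0.75), dev = d)
}

#' Extract classifier features for every burst
#'
#' Vectorised over bursts; see [extract_features()] for the single-burst
#' contract and [feature_names()] for the exact roster.
#'
#' @param bursts long per-sample table with `burst_id`, `sample_index`,
#'   `sway_g`, `surge_g`, `heave_g`
#' @param window_s number of leading samples used (default 7)
#' @return `data.table`: `burst_id` plus one column per feature
#' @export
extract_features_all <- function(bursts, window_s = 7L) {
  b <- as.data.table(bursts)[sample_index < window_s]
  counts <- b[, .N, by = burst_id]
  if (any(counts$N < window_s))
    stop(sum(counts$N < window_s), " burst(s) have fewer than ", window_s,
         " samples")
  setorder(b, burst_id, sample_index)
  ids <- unique(b$burst_id)
  mats <- lapply(.axis_cols, function(cc)
    matrix(b[[cc]], ncol = window_s, byrow = TRUE))
  st <- lapply(mats, row_stats)

  out <- data.table(burst_id = ids)
  for (i in seq_along(.axes))
    for (nm in c("mean", "sd", "skew", "kurt", "min", "max", "q25", "q50", "q75"))
      out[, (paste(.axes[i], nm, sep = "_")) := st[[i]][[nm]]]

  pair_idx <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  pair_nms <- c("sway_surge", "sway_heave", "surge_heave")
  n <- window_s
  for (k in seq_along(pair_idx)) {
    i <- pair_idx[[k]][1]; j <- pair_idx[[k]][2]
    cv <- rowSums(st[[i]]$dev * st[[j]]$dev) / (n - 1)
    denom <- st[[i]]$sd * st[[j]]$sd
    out[, (paste0(pair_nms[k], "_cov")) := cv]
    out[, (paste0(pair_nms[k], "_cor")) := ifelse(denom > 0, cv / denom, 0)]
    out[, (paste0(pair_nms[k], "_mad")) := rowMeans(abs(mats[[i]] - mats[[j]]))]
  }

  nrm <- sqrt(mats[[1]]^2 + mats[[2]]^2 + mats[[3]]^2)
  out[, norm_mean := rowMeans(nrm)]
  out[, norm_sd := sqrt(rowSums((nrm - rowMeans(nrm))^2) / (n - 1))]
  out[, odba := rowMeans(abs(st[[1]]$dev) + abs(st[[2]]$dev) + abs(st[[3]]$dev))]
  setcolorder(out, c("burst_id", feature_names()))
  out[]
}

#' Extract the feature vector of a single burst
#'
#' @param burst per-sample table for one burst (`sample_index`, `sway_g`,
#'   `surge_g`, `heave_g`)
#' @param window_s number of leading samples used (default 7)
#' @return named numeric vector in [feature_names()] order
#' @export
extract_features <- function(burst, window_s = 7L) {
  burst <- as.data.table(burst)
  if (!"burst_id" %in% names(burst)) burst[, burst_id := "b1"]
  ft <- extract_features_all(burst, window_s = window_s)
  unlist(ft[1L, feature_names(), with = FALSE])
}

#' Overall dynamic body acceleration of a burst
#'
#' Static component per axis is the mean over the window; ODBA is the mean
#' over samples of the summed absolute dynamic components.
#'
#' @inheritParams extract_features
#' @return ODBA in g
#' @export
odba <- function(burst, window_s = 7L) {
  burst <- as.data.table(burst)[sample_index < window_s]
  if (nrow(burst) < window_s) stop("burst has fewer than ", window_s, " samples")
  dev <- lapply(.axis_cols, function(cc) burst[[cc]] - mean(burst[[cc]]))
  mean(abs(dev[[1]]) + abs(dev[[2]]) + abs(dev[[3]]))
}
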