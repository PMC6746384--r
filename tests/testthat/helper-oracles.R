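# Independent brute-force oracles and small fixtures, coded directly from
# textbook definitions with plain loops -- deliberately sharing no code with
# the package internals.

library(data.table)

# ---- feature oracle ------------------------------------------------------

oracle_quantile <- function(x, p) {
  # linear interpolation between order statistics (R type 7), by hand
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
}

oracle_axis_stats <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  d <- x - mu
  m2 <- sum(d^2) / n
  s <- sqrt(sum(d^2) / (n - 1))
  list(mean = mu, sd = s,
       skew = if (m2 > 0) (sum(d^3) / n) / m2^1.5 else 0,
       kurt = if (m2 > 0) (sum(d^4) / n) / m2^2 - 3 else 0,
       min = min(x), max = max(x),
       q25 = oracle_quantile(x, 0.25), q50 = oracle_quantile(x, 0.50),
       q75 = oracle_quantile(x, 0.75))
}

# feature vector of one burst (matrix window x 3, cols sway/surge/heave)
oracle_features <- function(m) {
  n <- nrow(m)
  out <- c()
  ax <- c("sway", "surge", "heave")
  st <- list()
  for (i in 1:3) {
    st[[i]] <- oracle_axis_stats(m[, i])
    v <- unlist(st[[i]])
    names(v) <- paste(ax[i], names(st[[i]]), sep = "_")
    out <- c(out, v)
  }
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  pnm <- c("sway_surge", "sway_heave", "surge_heave")
  for (k in 1:3) {
    a <- m[, pairs[[k]][1]]; b <- m[, pairs[[k]][2]]
    cv <- sum((a - mean(a)) * (b - mean(b))) / (n - 1)
    sa <- st[[pairs[[k]][1]]]$sd; sb <- st[[pairs[[k]][2]]]$sd
    r <- if (sa > 0 && sb > 0) cv / (sa * sb) else 0
    v <- c(cv, r, mean(abs(a - b)))
    names(v) <- paste(pnm[k], c("cov", "cor", "mad"), sep = "_")
    out <- c(out, v)
  }
  nr <- sqrt(m[, 1]^2 + m[, 2]^2 + m[, 3]^2)
  dsum <- 0
  for (i in 1:n)
    dsum <- dsum + sum(abs(m[i, ] - colMeans(m)))
  out <- c(out, norm_mean = mean(nr),
           norm_sd = sqrt(sum((nr - mean(nr))^2) / (n - 1)),
           odba = dsum / n)
  out
}

# ---- tiny burst fixture --------------------------------------------------

# per-sample table for one burst from explicit axis vectors
burst_from_vectors <- function(sway, surge, heave, id = "b1") {
  data.table(burst_id = id, sample_index = seq_along(sway) - 1L,
             sway_g = sway, surge_g = surge, heave_g = heave)
}

# a small complete study used by io/aggregation tests (3 birds, no gaps)
tiny_study <- function(seed = 42L, missingness = 0, n_birds = 3L) {
  sched <- generate_schedules(n_birds, seed = seed)
  sched$duration <- pmin(sched$duration, 6L)  # keep it small
  generate_dataset(sched, environment_model(), true_response_model(),
                   default_signatures(), seed = seed,
                   missingness = missingness)
}

# ---- aggregation recount oracle (plain loops) ----------------------------

oracle_daily_records <- function(bt, min_bursts = 2, min_hours = 11) {
  bt <- as.data.frame(bt)
  keys <- unique(bt[, c("bird_id", "day")])
  res <- list()
  for (i in seq_len(nrow(keys))) {
    sub <- bt[bt$bird_id == keys$bird_id[i] & bt$day == keys$day[i], ]
    hrs <- sort(unique(sub$hour))
    ok_hours <- 0
    props <- c()
    for (h in hrs) {
      cell <- sub[sub$hour == h, ]
      if (nrow(cell) >= min_bursts) ok_hours <- ok_hours + 1
      props <- c(props, mean(cell$display))
    }
    if (ok_hours >= min_hours)
      res[[length(res) + 1]] <- data.frame(bird_id = keys$bird_id[i],
                                           day = keys$day[i],
                                           activity = mean(props))
  }
  if (!length(res)) return(NULL)
  do.call(rbind, res)
}
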