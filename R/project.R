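# Warming-scenario projection from the fitted daily model.

#' Project display activity under uniform warming
#'
#' For each temperature increment, every observed bird-day is predicted
#' twice from the daily model — at its observed mean daytime temperature
#' and at that temperature plus the increment — holding Julian date fixed
#' and the bird random intercept at its population level (0). The decrease
#' is the mean difference in predicted activity, reported both in absolute
#' percentage points and as a relative percent of the baseline; a pointwise
#' 95% interval comes from the coefficient covariance. Temperatures pushed
#' beyond the fitted range are extrapolated, with a warning flag.
#'
#' @param fit a daily `lekaccel_fit` from [fit_daily_model()]
#' @param daily_table the table the model was fitted to (or any table with
#'   `daytime_mean_temp`, `jdate`, `bird_id`)
#' @param deltas non-negative temperature increments in degC (default 1-7)
#' @return `data.table` with one row per delta: `delta_c`, `baseline`,
#'   `shifted`, `decrease_points`, `decrease_relative_pct`, `ci_lower`,
#'   `ci_upper` (points), `extrapolated`
#' @export
project <- function(fit, daily_table, deltas = 1:7) {
  stopifnot(inherits(fit, "lekaccel_fit"), fit$family_kind == "daily",
            all(deltas >= 0))
  dt <- as.data.table(daily_table)
  dt$bird_id <- factor(dt$bird_id, levels = levels(fit$data$bird_id))
  tmax <- max(fit$data$daytime_mean_temp)

  lp_mat <- function(d) {
    nd <- copy(dt)
    nd[, daytime_mean_temp := daytime_mean_temp + d]
    nd$bird_id <- levels(fit$data$bird_id)[1L]  # placeholder; column zeroed below
    X <- predict(fit$gam, newdata = nd, type = "lpmatrix")
    X[, grepl("bird_id", colnames(X))] <- 0     # population level
    X
  }
  X0 <- lp_mat(0)
  beta <- coef(fit$gam)
  V <- vcov(fit$gam)
  base_pred <- drop(X0 %*% beta)  # identity link: linear predictor = response

  out <- lapply(deltas, function(d) {
    X1 <- lp_mat(d)
    a <- colMeans(X0 - X1)        # mean decrease is linear in coefficients
    dec <- sum(a * beta)
    se <- sqrt(drop(t(a) %*% V %*% a))
    shifted <- drop(X1 %*% beta)
    data.table(delta_c = d,
               baseline = mean(base_pred),
               shifted = mean(shifted),
               decrease_points = 100 * dec,
               decrease_relative_pct = 100 * dec / mean(base_pred),
               ci_lower = 100 * (dec - 1.96 * se),
               ci_upper = 100 * (dec + 1.96 * se),
               extrapolated = max(dt$daytime_mean_temp + d) > tmax)
  })
  res <- rbindlist(out)
  if (any(res$extrapolated))
    warning("deltas ", paste(res[extrapolated == TRUE, delta_c], collapse = ", "),
            " push temperatures beyond the fitted range (extrapolation)")
  res[]
}
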