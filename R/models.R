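# Smooth additive mixed models of display behaviour.
#
# Both models are penalized-regression-spline GAMMs fitted with mgcv: the
# bird random intercept enters as a ridge-penalized group-intercept smooth
# (bs = "re"), the standard equivalence to a Gaussian random intercept.
# Smoothing parameters are selected by REML by default (GCV available).
# Basis dimension k = 4 on every covariate smooth guards against
# overfitting, mirroring the study design.

#' Fit the burst-level (hourly) display-probability model
#'
#' Binomial GAMM with logit link relating per-burst display occurrence
#' (0/1) to smooth effects of hourly temperature, continuous time of day
#' and Julian date, plus a bird random intercept.
#'
#' @param burst_table table with `display`, `temp_c`, `time`, `jdate`,
#'   `bird_id`
#' @param k basis dimension for each covariate smooth (default 4)
#' @param method smoothing-parameter criterion, `"REML"` (default) or
#'   `"GCV.Cp"`
#' @return a `lekaccel_fit`: the mgcv fit plus `family_kind`, per-term edf
#'   and the random-intercept variance
#' @export
fit_hourly_model <- function(burst_table, k = 4L, method = "REML") {
  bt <- as.data.table(burst_table)
  stopifnot(all(c("display", "temp_c", "time", "jdate", "bird_id") %in% names(bt)))
  bt <- bt[, .(display, temp_c, time, jdate,
               bird_id = factor(bird_id))]
  for (v in c("temp_c", "time", "jdate"))
    if (length(unique(bt[[v]])) < k) stop("degenerate covariate: ", v)
  fit_gamm(display ~ s(temp_c, k = k) + s(time, k = k) + s(jdate, k = k),
           bt, stats::binomial(), method, "hourly")
}

#' Fit the day-level display-activity model
#'
#' Gaussian GAMM (identity link) relating daily display activity to smooth
#' effects of mean daytime temperature and Julian date, plus a bird random
#' intercept.
#'
#' @param daily_table table with `display_activity`, `daytime_mean_temp`,
#'   `jdate`, `bird_id`
#' @inheritParams fit_hourly_model
#' @export
fit_daily_model <- function(daily_table, k = 4L, method = "REML") {
  dt <- as.data.table(daily_table)
  stopifnot(nrow(dt) >= 10L,
            all(c("display_activity", "daytime_mean_temp", "jdate",
                  "bird_id") %in% names(dt)))
  dt <- dt[, .(display_activity, daytime_mean_temp, jdate,
               bird_id = factor(bird_id))]
  fit_gamm(display_activity ~ s(daytime_mean_temp, k = k) + s(jdate, k = k),
           dt, stats::gaussian(), method, "daily")
}

fit_gamm <- function(fixed, data, family, method, kind) {
  if (nlevels(data$bird_id) >= 2L) {
    formula <- stats::update(fixed, . ~ . + s(bird_id, bs = "re"))
  } else {
    warning("single bird: random intercept dropped")
    formula <- fixed
  }
  g <- mgcv::gam(formula, family = family, data = data, method = method)
  if (!g$converged) warning("GAMM did not converge; inspect mgcv diagnostics")
  sm <- summary(g)
  terms <- rownames(sm$s.table)
  cov_terms <- terms[terms != "s(bird_id)"]
  re_var <- if ("s(bird_id)" %in% terms) {
    tryCatch({
      utils::capture.output(vc <- mgcv::gam.vcomp(g, rescale = TRUE))
      sdv <- if (is.matrix(vc)) vc["s(bird_id)", "std.dev"] else vc["s(bird_id)"]
      unname(sdv^2)
    }, error = function(e) NA_real_)
  } else NA_real_
  structure(list(gam = g, family_kind = kind,
                 formula = formula, method = method,
                 edf = stats::setNames(sm$s.table[, "edf"], terms),
                 s_table = sm$s.table,
                 terms = cov_terms,
                 random_intercept_variance = re_var,
                 data = data),
            class = "lekaccel_fit")
}

#' @export
print.lekaccel_fit <- function(x, ...) {
  cat(sprintf("lekaccel %s GAMM (%s)\n", x$family_kind, x$method))
  print(round(x$s_table, 3))
  if (!is.na(x$random_intercept_variance))
    cat(sprintf("bird random-intercept variance: %.4f\n",
                x$random_intercept_variance))
  invisible(x)
}

#' Extract centred partial-effect curves with 95% bands
#'
#' Each smooth covariate term is evaluated on a grid spanning its observed
#' range, on the linear-predictor scale, with pointwise 95% confidence
#' bands from the coefficient covariance (other terms and the random
#' intercept do not contribute).
#'
#' @param fit a `lekaccel_fit`
#' @param terms term names as in `fit$terms` (default: all covariate
#'   smooths)
#' @param grid_size points per curve (default 100)
#' @return `data.table` with `term`, `x`, `effect`, `lower`, `upper`
#' @export
partial_effects <- function(fit, terms = fit$terms, grid_size = 100L) {
  stopifnot(inherits(fit, "lekaccel_fit"))
  bad <- setdiff(terms, fit$terms)
  if (length(bad)) stop("unknown term(s): ", paste(bad, collapse = ", "))
  data <- fit$data
  out <- lapply(terms, function(tm) {
    v <- gsub("^s\\(|\\)$", "", tm)
    xg <- seq(min(data[[v]]), max(data[[v]]), length.out = grid_size)
    nd <- data[rep(1L, grid_size)]
    nd[[v]] <- xg
    pr <- predict(fit$gam, newdata = nd, type = "terms", se.fit = TRUE)
    col <- which(colnames(pr$fit) == tm)
    data.table(term = tm, x = xg, effect = pr$fit[, col],
               lower = pr$fit[, col] - 1.96 * pr$se.fit[, col],
               upper = pr$fit[, col] + 1.96 * pr$se.fit[, col])
  })
  rbindlist(out)
}

#' Cross-validated predictive error of a GAMM
#'
#' Rows are split into `k` random near-equal folds; the model is refitted
#' on k-1 folds (smoothing parameters re-estimated per fold) and predicts
#' the held-out fold. For the binomial (hourly) model the metric is the
#' percentage of misclassifications at a 0.5 threshold; for the Gaussian
#' (daily) model it is the RMSE divided by the observed response range
#' (NRMSE). A fold whose refit fails is skipped and reported.
#'
#' @param kind `"hourly"` or `"daily"`
#' @param table the corresponding modelling table
#' @param k number of folds (study value 10)
#' @param seed integer seed for fold assignment
#' @param basis_k smooth basis dimension passed to the fit
#' @return list with `metric`, `mean`, `sd`, `per_fold`
#' @export
cv_predictive_error <- function(kind = c("hourly", "daily"), table, k = 10L,
                                seed = 1L, basis_k = 4L) {
  kind <- match.arg(kind)
  tb <- as.data.table(table)
  stopifnot(nrow(tb) >= k)
  fold <- with_seed(substream_seed(seed, "gamm_cv"),
                    function() sample(rep_len(seq_len(k), nrow(tb))))
  fitter <- if (kind == "hourly") fit_hourly_model else fit_daily_model
  resp <- if (kind == "hourly") "display" else "display_activity"
  vals <- rep(NA_real_, k)
  for (f in seq_len(k)) {
    fit_f <- tryCatch(fitter(tb[fold != f], k = basis_k),
                      error = function(e) {
                        warning("fold ", f, " refit failed: ",
                                conditionMessage(e))
                        NULL
                      })
    if (is.null(fit_f)) next
    nd <- tb[fold == f]
    nd$bird_id <- factor(nd$bird_id, levels = levels(fit_f$data$bird_id))
    pr <- predict_response(fit_f, nd)
    obs <- nd[[resp]]
    vals[f] <- if (kind == "hourly") {
      100 * mean((pr >= 0.5) != (obs == 1L))
    } else {
      sqrt(mean((pr - obs)^2)) / diff(range(tb[[resp]]))
    }
  }
  list(metric = if (kind == "hourly") "error_rate" else "nrmse",
       mean = mean(vals, na.rm = TRUE), sd = sd(vals, na.rm = TRUE),
       per_fold = vals)
}

# response-scale predictions; unseen birds predicted at the population level
predict_response <- function(fit, newdata) {
  nd <- as.data.table(newdata)
  has_re <- "s(bird_id)" %in% rownames(fit$s_table)
  if (has_re) {
    known <- nd$bird_id %in% levels(fit$data$bird_id) & !is.na(nd$bird_id)
    nd$bird_id <- factor(ifelse(known, as.character(nd$bird_id),
                                levels(fit$data$bird_id)[1L]),
                         levels = levels(fit$data$bird_id))
    pr <- predict(fit$gam, newdata = nd, type = "link")
    if (any(!known)) {
      pr0 <- predict(fit$gam, newdata = nd, type = "link",
                     exclude = "s(bird_id)")
      pr[!known] <- pr0[!known]
    }
  } else {
    pr <- predict(fit$gam, newdata = nd, type = "link")
  }
  fit$gam$family$linkinv(as.numeric(pr))
}
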