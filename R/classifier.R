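# Behaviour classification: train candidate model families on a small
# labelled subset, pick the best by cross-validated precision/recall for
# the display class, and label the remaining bursts.
#
# Four of the classic biologging model families are provided: random
# forest (bagged CART with per-node feature subsampling; the deployed
# model), a single decision tree, k-nearest neighbours and a linear
# support vector machine (squared hinge, L2, BFGS). Labels are binary
# throughout: display vs everything else.

.family_order <- c("random_forest", "decision_tree", "knn", "linear_svm")

#' Draw the manually-labelled training subset
#'
#' Uniform sample without replacement of `round(fraction * N)` bursts with
#' their true labels collapsed to binary display / non-display, emulating
#' the study's manual classification of 10% of sequences.
#'
#' @param features table from [extract_features_all()] (`burst_id` +
#'   feature columns)
#' @param labels table with `burst_id` and `class`
#' @param fraction sampling fraction in (0, 1] (default 0.10)
#' @param seed integer seed
#' @return list with `features` (sampled rows), `label` (integer 0/1
#'   display), `burst_id`
#' @export
make_training_subset <- function(features, labels, fraction = 0.10, seed = 1L) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  features <- as.data.table(features)
  labels <- as.data.table(labels)
  stopifnot(nrow(features) >= 1L, !anyDuplicated(features$burst_id))
  n <- max(1L, round(fraction * nrow(features)))
  idx <- with_seed(seed, function() sample(nrow(features), n))
  ft <- features[sort(idx)]
  lab <- labels[ft, on = "burst_id"]
  stopifnot(!anyNA(lab$class))
  list(features = ft, label = as.integer(lab$class == "display"),
       burst_id = ft$burst_id)
}

feature_matrix <- function(features) {
  as.matrix(as.data.table(features)[, feature_names(), with = FALSE])
}

#' Train one classifier family
#'
#' @param family one of `"random_forest"`, `"decision_tree"`, `"knn"`,
#'   `"linear_svm"`
#' @param X numeric feature matrix (rows = bursts)
#' @param y integer 0/1 labels (1 = display)
#' @param params family hyperparameters (see [default_config()]
#'   `$classifier`); unspecified entries use the config defaults
#' @param seed integer seed (tree growing and bagging are stochastic)
#' @return a `lekaccel_model` object
#' @export
train_model <- function(family, X, y, params = list(), seed = 1L) {
  family <- match.arg(family, .family_order)
  p <- modifyList(default_config()$classifier[[family]], params)
  y <- as.integer(y)
  stopifnot(all(y %in% 0:1), nrow(X) == length(y))
  fit <- switch(family,
    random_forest = with_seed(seed, function() {
      mtry <- max(1L, floor(sqrt(ncol(X))))
      .cart_forest(X, y, p$ntree, mtry, p$min_node, p$max_depth, p$sample_frac)
    }),
    decision_tree = with_seed(seed, function() {
      list(.cart_grow(X, y, ncol(X), p$min_node, p$max_depth))
    }),
    knn = {
      mu <- colMeans(X); sg <- apply(X, 2L, sd); sg[sg == 0] <- 1
      list(X = scale(X, mu, sg), y = y, k = p$k, mu = mu, sg = sg)
    },
    linear_svm = {
      mu <- colMeans(X); sg <- apply(X, 2L, sd); sg[sg == 0] <- 1
      Xs <- scale(X, mu, sg)
      ys <- 2 * y - 1
      lam <- p$lambda
      obj <- function(w) {
        f <- drop(Xs %*% w[-1L]) + w[1L]
        m <- pmax(0, 1 - ys * f)
        mean(m^2) + lam * sum(w[-1L]^2)
      }
      grd <- function(w) {
        f <- drop(Xs %*% w[-1L]) + w[1L]
        m <- pmax(0, 1 - ys * f)
        g <- -2 * ys * m / length(ys)
        c(sum(g), drop(crossprod(Xs, g)) + 2 * lam * w[-1L])
      }
      w <- stats::optim(numeric(ncol(Xs) + 1L), obj, grd, method = "BFGS",
                        control = list(maxit = 200L))$par
      list(w = w, mu = mu, sg = sg)
    })
  structure(list(family = family, fit = fit, params = p,
                 n_features = ncol(X)),
            class = "lekaccel_model")
}

#' Predict display scores for new bursts
#'
#' @param object a `lekaccel_model`
#' @param X feature matrix with the training schema
#' @param ... unused
#' @return numeric display scores in `[0, 1]` (vote fractions or a
#'   margin squashed through the logistic for the SVM)
#' @export
predict.lekaccel_model <- function(object, X, ...) {
  if (ncol(X) != object$n_features) stop("feature schema mismatch: got ",
                                         ncol(X), " features, model expects ",
                                         object$n_features)
  switch(object$family,
    random_forest = ,
    decision_tree = .cart_predict(object$fit, X),
    knn = {
      f <- object$fit
      Xs <- scale(X, f$mu, f$sg)
      d2 <- outer(rowSums(Xs^2), rowSums(f$X^2), "+") - 2 * Xs %*% t(f$X)
      apply(d2, 1L, function(r) mean(f$y[order(r)[seq_len(f$k)]]))
    },
    linear_svm = {
      f <- object$fit
      invlogit(drop(scale(X, f$mu, f$sg) %*% f$w[-1L]) + f$w[1L])
    })
}

pooled_confusion <- function(truth, pred) {
  c(tp = sum(pred == 1L & truth == 1L), fp = sum(pred == 1L & truth == 0L),
    fn = sum(pred == 0L & truth == 1L), tn = sum(pred == 0L & truth == 0L))
}

precision_recall <- function(cm) {
  c(precision = unname(cm["tp"] / max(1L, cm["tp"] + cm["fp"])),
    recall = unname(cm["tp"] / max(1L, cm["tp"] + cm["fn"])))
}

#' Cross-validate candidate classifier families
#'
#' Rows are split into `k` near-equal random folds; each fold is predicted
#' by a model trained on the other k-1, and fold confusion matrices are
#' pooled into a single display precision and recall per family. A fold
#' whose training part contains a single class is reported and the family
#' skipped.
#'
#' @param labeled from [make_training_subset()]
#' @param families subset of the four family names
#' @param k number of folds (study value 10)
#' @param seed integer seed for fold assignment and tree growing
#' @param params optional per-family hyperparameter overrides
#' @return list of `cv_report` objects (family, pooled confusion,
#'   `precision`, `recall`, per-fold matrices, seed)
#' @export
train_and_cv <- function(labeled, families = .family_order, k = 10L,
                         seed = 1L, params = list()) {
  stopifnot(k >= 2L)
  X <- feature_matrix(labeled$features)
  y <- labeled$label
  n <- nrow(X)
  fold <- with_seed(substream_seed(seed, "folds"),
                    function() sample(rep_len(seq_len(k), n)))
  if (min(table(fold)) < 1L) stop("empty fold; reduce k")
  lapply(families, function(fam) {
    per_fold <- vector("list", k)
    ok <- TRUE
    pred_all <- integer(n)
    for (f in seq_len(k)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2L) {
        warning("fold ", f, " has a single training class; skipping ", fam)
        ok <- FALSE
        break
      }
      m <- train_model(fam, X[tr, , drop = FALSE], y[tr],
                       params = params[[fam]] %||% list(),
                       seed = substream_seed(seed, paste0(fam, "_fold", f)))
      pr <- as.integer(predict(m, X[!tr, , drop = FALSE]) >= 0.5)
      pred_all[!tr] <- pr
      per_fold[[f]] <- pooled_confusion(y[!tr], pr)
    }
    if (!ok) return(NULL)
    cm <- Reduce(`+`, per_fold)
    structure(c(list(family = fam, confusion = cm,
                     per_fold = per_fold, k = k, seed = seed),
                as.list(precision_recall(cm))),
              class = "cv_report")
  }) -> reports
  reports[!vapply(reports, is.null, logical(1))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select the best classifier family from CV reports
#'
#' Maximises the display-class F1 score (harmonic mean of pooled precision
#' and recall); ties break by precision, then by the fixed family order.
#'
#' @param reports list of `cv_report`s from [train_and_cv()]
#' @return the winning family name
#' @export
select_best <- function(reports) {
  if (!length(reports)) stop("no CV reports to select from")
  f1 <- vapply(reports, function(r) {
    if (r$precision + r$recall == 0) 0 else
      2 * r$precision * r$recall / (r$precision + r$recall)
  }, numeric(1))
  prec <- vapply(reports, `[[`, numeric(1), "precision")
  fams <- vapply(reports, `[[`, character(1), "family")
  ord <- order(-f1, -prec, match(fams, .family_order))
  fams[ord[1L]]
}

#' Classify the remaining (unlabelled) bursts
#'
#' Training bursts keep their given labels; every other burst receives the
#' model's thresholded prediction.
#'
#' @param model a trained `lekaccel_model` (fit on the full labelled subset)
#' @param features full feature table (`burst_id` + feature columns)
#' @param labeled the training subset from [make_training_subset()]
#' @param threshold display-score threshold (default 0.5)
#' @return `data.table` with `burst_id`, `display` (0/1), `score`,
#'   `source` ("manual" or the model family)
#' @export
classify_remaining <- function(model, features, labeled, threshold = 0.5) {
  features <- as.data.table(features)
  rest <- features[!burst_id %in% labeled$burst_id]
  out <- data.table(burst_id = labeled$burst_id,
                    display = labeled$label,
                    score = as.numeric(labeled$label), source = "manual")
  if (nrow(rest)) {
    sc <- predict(model, feature_matrix(rest))
    out <- rbind(out, data.table(burst_id = rest$burst_id,
                                 display = as.integer(sc >= threshold),
                                 score = sc, source = model$family))
  }
  setkey(out, burst_id)
  out[]
}
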