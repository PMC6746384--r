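# Two well-separated Gaussian clouds in feature space, as a table with the
# standard feature schema (only three informative columns vary).
separable_set <- function(n = 120, gap = 6, seed = 1) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  ft <- as.data.table(matrix(rnorm(n * length(feature_names()), 0, 0.1),
                             nrow = n))
  setnames(ft, feature_names())
  # shift a handful of features so the classes are separable for every
  # family, including distance-based kNN in the 39-dimensional space
  for (cc in c("sway_mean", "surge_mean", "heave_mean", "surge_q50",
               "heave_q50", "norm_mean", "odba", "heave_sd"))
    ft[, (cc) := get(cc) + gap * y]
  ft[, burst_id := sprintf("b%03d", seq_len(n))]
  list(features = ft, label = as.integer(y), burst_id = ft$burst_id)
}

test_that("training-subset sampling honours size, seed and bounds", {
  ds <- tiny_study(seed = 9)
  ft <- extract_features_all(ds$bursts)
  labs <- ds$meta[, .(burst_id, class)]
  sub <- make_training_subset(ft, labs, fraction = 0.10, seed = 1)
  expect_equal(length(sub$label), round(0.10 * nrow(ft)))
  expect_setequal(unique(sub$label), 0:1)
  all_sub <- make_training_subset(ft, labs, fraction = 1, seed = 1)
  expect_equal(length(all_sub$label), nrow(ft))               # identity
  sub2 <- make_training_subset(ft, labs, fraction = 0.10, seed = 2)
  expect_equal(length(sub2$label), length(sub$label))
  expect_false(setequal(sub$burst_id, sub2$burst_id))         # seed matters
  expect_error(make_training_subset(ft, labs, fraction = 0), "fraction")
  expect_error(make_training_subset(ft, labs, fraction = 1.2), "fraction")
})

test_that("all four families separate well-separated classes perfectly", {
  lab <- separable_set()
  reps <- train_and_cv(lab, k = 5, seed = 3)
  expect_equal(length(reps), 4L)
  for (r in reps) {
    expect_equal(r$precision, 1.0)
    expect_equal(r$recall, 1.0)
    expect_equal(sum(r$confusion), length(lab$label))
  }
})

test_that("pooled precision/recall match the count definitions", {
  pr <- lekaccel:::precision_recall(c(tp = 9, fp = 1, fn = 0, tn = 5))
  expect_equal(unname(pr["precision"]), 0.9)
  expect_equal(unname(pr["recall"]), 1.0)
  cm <- lekaccel:::pooled_confusion(c(1, 1, 0, 0, 1), c(1, 0, 0, 1, 1))
  expect_equal(unname(cm), c(2, 1, 1, 1))
})

test_that("select_best maximises F1 with documented tie-breaks", {
  rep_of <- function(fam, p, r)
    structure(list(family = fam, precision = p, recall = r), class = "cv_report")
  expect_equal(select_best(list(rep_of("knn", 0.9, 0.9),
                                rep_of("linear_svm", 0.99, 0.98))),
               "linear_svm")                                   # dominance
  expect_equal(select_best(list(rep_of("knn", 0.95, 0.95))), "knn")
  # equal F1, precision breaks the tie
  expect_equal(select_best(list(rep_of("knn", 0.90, 0.80),
                                rep_of("decision_tree", 0.80, 0.90))), "knn")
  # full tie -> fixed family order
  expect_equal(select_best(list(rep_of("knn", 0.9, 0.9),
                                rep_of("random_forest", 0.9, 0.9))),
               "random_forest")
  expect_error(select_best(list()), "no CV reports")
})

test_that("classify_remaining keeps manual labels and fills the rest", {
  lab <- separable_set(n = 80)
  X <- lekaccel:::feature_matrix(lab$features)
  m <- train_model("random_forest", X, lab$label, params = list(ntree = 100L),
                   seed = 4)
  # resubstitution sanity
  agree <- mean((predict(m, X) >= 0.5) == (lab$label == 1))
  expect_gte(agree, 0.95)

  more <- separable_set(n = 40, seed = 9)
  more$features[, burst_id := paste0("x", burst_id)]
  allft <- rbind(lab$features, more$features)
  out <- classify_remaining(m, allft, lab)
  expect_equal(nrow(out), 120L)
  expect_equal(out[.(lab$burst_id), display, on = "burst_id"], lab$label)
  expect_equal(mean(out[.(paste0("x", more$burst_id)), display,
                        on = "burst_id"] == more$label), 1.0)
  # empty remainder
  out0 <- classify_remaining(m, lab$features, lab)
  expect_identical(sort(out0$burst_id), sort(lab$burst_id))
  expect_true(all(out0$source == "manual"))
  # schema mismatch
  expect_error(predict(m, X[, 1:10]), "schema mismatch")
})

test_that("CV performance is non-decreasing as class separation grows", {
  f1_at_gap <- function(gap) {
    # two informative, genuinely overlapping features; the rest pure noise
    set.seed(11)
    n <- 200L
    y <- rep(0:1, each = n / 2)
    ft <- as.data.table(matrix(rnorm(n * length(feature_names()), 0, 0.1),
                               nrow = n))
    setnames(ft, feature_names())
    ft[, heave_mean := rnorm(n, gap * y, 1)]
    ft[, surge_mean := rnorm(n, gap * y, 1)]
    ft[, burst_id := sprintf("b%03d", seq_len(n))]
    lab <- list(features = ft, label = as.integer(y), burst_id = ft$burst_id)
    r <- train_and_cv(lab, families = "random_forest", k = 5, seed = 13,
                      params = list(random_forest = list(ntree = 150L)))[[1]]
    2 * r$precision * r$recall / (r$precision + r$recall)
  }
  f1 <- vapply(c(0.5, 2, 6), f1_at_gap, numeric(1))
  expect_true(all(diff(f1) >= -0.02))  # non-decreasing up to fold noise
  expect_gt(f1[3], f1[1])
})

test_that("single-class folds are reported and the family skipped", {
  lab <- separable_set(n = 20)
  lab$label <- rep(0L, 20)
  lab$label[1] <- 1L
  expect_warning(reps <- train_and_cv(lab, families = "linear_svm", k = 10,
                                      seed = 1),
                 "single training class")
  expect_equal(length(reps), 0L)
})
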