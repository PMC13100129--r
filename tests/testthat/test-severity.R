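test_that("raw 0-4 scores merge into severity categories", {
  expect_equal(as.character(merge_scores(c(0, 1, 2, 3, 4))),
               c("Mild", "Mild", "Moderate", "Severe", "Severe"))
  expect_true(is.ordered(merge_scores(2)))
  expect_error(merge_scores(5), "0..4")
  expect_error(merge_scores(-1), "0..4")
})

test_that("score-distribution counts merge to the three severity groups", {
  counts <- c(355, 1070, 1380, 1196, 72)  # videos per raw score 0..4
  scores <- rep(0:4, times = counts)
  merged <- table(merge_scores(scores))
  expect_equal(as.integer(merged), c(1425, 1380, 1268))
  expect_equal(round(100 * merged[["Mild"]] / sum(merged), 1), 35.0)
})

test_that("majority vote picks the modal rating, ties to the lower score", {
  expect_equal(majority_vote(c(2, 2, 3)), 2L)
  expect_equal(majority_vote(1), 1L)
  expect_equal(majority_vote(c(1, 2)), 1L)
  expect_equal(majority_vote(c(4, 4, 0, 0, 3)), 0L)
  expect_error(majority_vote(integer(0)), "no ratings")
})

test_that("cumulative probabilities difference into valid class probabilities", {
  p <- fingertap:::.ordinal_combine(0.9, 0.2)
  expect_equal(unname(p[1, ]), c(0.1, 0.7, 0.2))
  expect_equal(unname(fingertap:::.ordinal_combine(0, 0)[1, ]), c(1, 0, 0))
  # monotonicity violation: middle clipped to zero, renormalized
  p <- fingertap:::.ordinal_combine(0.3, 0.6)
  expect_equal(unname(p[1, ]), c(0.7, 0, 0.6) / 1.3)
  expect_equal(SEVERITY_LEVELS[which.max(p[1, ])], "Mild")
  # property: rows always sum to one
  set.seed(3)
  q <- matrix(runif(400), 200, 2)
  expect_equal(rowSums(fingertap:::.ordinal_combine(q[, 1], q[, 2])),
               rep(1, 200))
})

test_that("metrics are perfect on perfect predictions", {
  y <- rep(SEVERITY_LEVELS, times = c(5, 5, 5))
  m <- compute_metrics(y, y)
  expect_equal(m$accuracy, 100)
  expect_equal(m$balanced_accuracy, 100)
  expect_equal(m$macro_precision, 100)
  expect_equal(m$macro_f1, 100)
  expect_equal(sum(diag(m$confusion)), 15)
})

test_that("a constant predictor pins down the metric conventions", {
  # majority prevalence 34.84 %: the printed baseline row follows exactly
  n <- 4073L
  n_mild <- 1419L  # 1419 / 4073 = 34.84 %
  y_true <- c(rep("Mild", n_mild), rep("Moderate", 1380),
              rep("Severe", n - n_mild - 1380))
  m <- compute_metrics(y_true, rep("Mild", n))
  expect_equal(m$accuracy, 34.84, tolerance = 0.005)
  expect_equal(m$balanced_accuracy, 100 / 3, tolerance = 1e-8)
  expect_equal(m$macro_precision, 11.61, tolerance = 0.005)
  expect_equal(m$macro_f1, 17.23, tolerance = 0.005)
})

test_that("balanced accuracy of any constant predictor is 1/K", {
  set.seed(14)
  for (k in 2:3) {
    y <- sample(SEVERITY_LEVELS[1:k], 60, replace = TRUE)
    for (cls in unique(y)) {
      m <- compute_metrics(y, rep(cls, 60))
      expect_equal(m$balanced_accuracy, 100 / length(unique(y)),
                   tolerance = 1e-8)
    }
  }
})

test_that("metrics agree with a brute-force confusion tally under fuzzing", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(3:40, 1)
    y <- sample(SEVERITY_LEVELS, n, replace = TRUE)
    p <- sample(SEVERITY_LEVELS, n, replace = TRUE)
    m <- compute_metrics(y, p)
    expect_equal(m$accuracy, 100 * mean(y == p))
    lv <- SEVERITY_LEVELS[SEVERITY_LEVELS %in% y]
    rec <- vapply(lv, function(c) mean(p[y == c] == c), numeric(1))
    prec <- vapply(lv, function(c) {
      if (sum(p == c) == 0) 0 else sum(y == c & p == c) / sum(p == c)
    }, numeric(1))
    f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
    expect_equal(m$balanced_accuracy, 100 * mean(rec))
    expect_equal(m$macro_precision, 100 * mean(prec))
    expect_equal(m$macro_f1, 100 * mean(f1))
    expect_equal(rowSums(m$confusion)[lv], table(y)[lv], ignore_attr = TRUE)
  }
})

test_that("length mismatches and empty inputs are rejected", {
  expect_error(compute_metrics(c("Mild", "Mild"), "Mild"), "mismatch")
  expect_error(compute_metrics(character(0), character(0)), "empty")
})

test_that("ordinal classification separates a separable training set", {
  set.seed(31)
  n <- 40
  X <- rbind(matrix(rnorm(n * 2, 0), n, 2),
             matrix(rnorm(n * 2, 4), n, 2),
             matrix(rnorm(n * 2, 8), n, 2))
  colnames(X) <- c("f1", "f2")
  y <- rep(SEVERITY_LEVELS, each = n)
  res <- ordinal_fit_predict(X, y, X, learner = "logistic")
  expect_gt(mean(res$labels == y), 0.95)
  expect_equal(rowSums(res$probs), rep(1, nrow(X)))
  expect_false(any(res$degenerate))
})

test_that("one-sided binary tasks degrade gracefully and are flagged", {
  X <- matrix(rnorm(20), 10, 2)
  colnames(X) <- c("f1", "f2")
  y <- rep(c("Mild", "Moderate"), each = 5)  # no Severe in training
  res <- ordinal_fit_predict(X, y, X, learner = "logistic")
  expect_true(res$degenerate[2])
  expect_equal(rowSums(res$probs), rep(1, 10))
  expect_true(all(res$labels %in% c("Mild", "Moderate")))
})

test_that("LOSO never trains on the held-out subject", {
  ds <- simulate_cohort(n_subjects = 9, recordings_per_subject = 2,
                        profiles = class_profiles("well_separated"),
                        seed = 5)
  res <- loso_evaluate(ds, learner = "logistic", seed = 5)
  for (fold in res$folds) {
    expect_false(fold$test_subject %in% fold$train_subjects)
  }
  expect_setequal(vapply(res$folds, `[[`, "", "test_subject"),
                  unique(ds$subject_ids))
  # every recording received a prediction from a model never shown it
  expect_false(anyNA(res$predictions$predicted))
})

test_that("LOSO works with two subjects and predicts across subjects", {
  set.seed(8)
  X <- matrix(rnorm(24), 12, 2, dimnames = list(NULL, c("f1", "f2")))
  X[7:12, ] <- X[7:12, ] + 5
  ds <- severity_dataset(X, rep(c("Mild", "Severe"), each = 6),
                         rep(c("A", "B"), each = 6))
  res <- loso_evaluate(ds, learner = "logistic", seed = 1)
  expect_equal(nrow(res$predictions), 12)
  expect_false(anyNA(res$predictions$predicted))
  expect_error(loso_evaluate(
    severity_dataset(X, rep("Mild", 12), rep("A", 12))), "2 subjects")
})

test_that("a well-separated simulated cohort is classified almost perfectly", {
  ds <- simulate_cohort(n_subjects = 15, recordings_per_subject = 2,
                        profiles = class_profiles("well_separated"),
                        seed = 42)
  res <- loso_evaluate(ds, learner = "gbt", seed = 42)
  expect_gte(res$metrics$balanced_accuracy, 90)
  # reproducibility for a fixed seed
  res2 <- loso_evaluate(ds, learner = "gbt", seed = 42)
  expect_equal(res$metrics$balanced_accuracy, res2$metrics$balanced_accuracy)
  expect_equal(res$predictions, res2$predictions)
})

test_that("inner-loop tuning keeps folds grouped by subject", {
  ds <- simulate_cohort(n_subjects = 9, recordings_per_subject = 2,
                        profiles = class_profiles("well_separated"),
                        seed = 3)
  set.seed(1)
  fold <- fingertap:::.subject_folds(ds$subject_ids, ds$y, 3)
  per_rec <- fold[ds$subject_ids]
  expect_equal(as.integer(tapply(per_rec, ds$subject_ids,
                                 function(f) length(unique(f)))),
               rep(1L, 9))
  expect_setequal(unique(per_rec), 1:3)
})
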