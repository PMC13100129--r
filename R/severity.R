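# Severity-label preparation, multi-class and ordinal classification,
# leave-one-subject-out evaluation, and the evaluation metrics.

#' Ordered severity levels
#' @export
SEVERITY_LEVELS <- c("Mild", "Moderate", "Severe")

severity_factor <- function(x) {
  factor(as.character(x), levels = SEVERITY_LEVELS, ordered = TRUE)
}

#' Merge raw 0-4 scores into severity categories
#'
#' Scores 0-1 become `Mild`, 2 becomes `Moderate`, 3-4 become `Severe`
#' (merging mitigates class imbalance of the raw scale).
#'
#' @param score integer vector with values in 0..4.
#' @return Ordered factor `Mild < Moderate < Severe`.
#' @export
merge_scores <- function(score) {
  s <- suppressWarnings(as.integer(score))
  if (anyNA(s) || any(s != score) || any(s < 0L | s > 4L))
    stop("scores must be integers in 0..4")
  severity_factor(c("Mild", "Mild", "Moderate", "Severe", "Severe")[s + 1L])
}

#' Majority vote over multiple ratings
#'
#' Returns the most frequent rating; ties are broken deterministically
#' toward the lower (less severe) score.
#'
#' @param ratings integer vector of 0..4 ratings, length >= 1.
#' @return A single integer rating.
#' @export
majority_vote <- function(ratings) {
  r <- suppressWarnings(as.integer(ratings))
  if (length(r) == 0L) stop("no ratings given")
  if (anyNA(r) || any(r < 0L | r > 4L))
    stop("ratings must be integers in 0..4")
  tab <- table(r)
  winners <- as.integer(names(tab)[tab == max(tab)])
  min(winners)
}

#' Bundle features, labels and subject identifiers
#'
#' @param X recordings x features numeric matrix/data.frame.
#' @param y severity labels (coerced to the ordered `Mild < Moderate <
#'   Severe` factor).
#' @param subject_ids character vector, one per recording.
#' @param raw_scores optional original 0-4 scores.
#' @return An object of class `severity_dataset`.
#' @export
severity_dataset <- function(X, y, subject_ids, raw_scores = NULL) {
  X <- as.matrix(X)
  y <- severity_factor(y)
  if (anyNA(y)) stop("labels must be Mild/Moderate/Severe")
  subject_ids <- as.character(subject_ids)
  if (nrow(X) != length(y) || nrow(X) != length(subject_ids))
    stop("X, y and subject_ids must have equal lengths")
  structure(list(X = X, y = y, subject_ids = subject_ids,
                 raw_scores = raw_scores),
            class = "severity_dataset")
}

#' @export
print.severity_dataset <- function(x, ...) {
  cat("<severity_dataset>", nrow(x$X), "recordings,",
      length(unique(x$subject_ids)), "subjects\n")
  print(table(x$y))
  invisible(x)
}

# ---- base learners ---------------------------------------------------------
# One interface over three probabilistic classifiers: multinomial/binomial
# logistic regression, random forest, gradient-boosted trees.

.default_params <- function(learner) {
  switch(learner,
         logistic = list(decay = 0),
         rf = list(ntree = 300L, nodesize = 1L),
         gbt = list(nrounds = 60L, eta = 0.15, max_depth = 3L,
                    subsample = 1),
         stop("unknown learner: ", learner))
}

.sample_params <- function(learner, p) {
  switch(learner,
         logistic = list(decay = 10^runif(1, -4, 0)),
         rf = list(ntree = sample(c(200L, 400L), 1L),
                   mtry = sample.int(p, 1L),
                   nodesize = sample(c(1L, 3L, 5L), 1L)),
         gbt = list(nrounds = sample(30:150, 1L),
                    eta = 10^runif(1, -1.5, -0.3),
                    max_depth = sample(2:6, 1L),
                    subsample = runif(1, 0.6, 1)))
}

# Fit a probabilistic classifier; y a factor (2 or 3 levels). Training sets
# containing a single class yield a flagged constant-probability model.
.fit_classifier <- function(learner, X, y, params = NULL) {
  X <- as.matrix(X)
  y <- droplevels(factor(y))
  lv <- levels(y)
  if (is.null(params)) params <- .default_params(learner)
  if (length(lv) < 2L) {
    return(structure(list(constant = lv, levels = lv), class = "ft_constant"))
  }
  model <- switch(learner,
    logistic = {
      df <- data.frame(X)
      df$.y <- y
      if (length(lv) == 2L) {
        suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
      } else {
        o <- utils::capture.output(
          m <- nnet::multinom(.y ~ ., data = df, trace = FALSE, maxit = 300,
                              decay = params$decay))
        m
      }
    },
    rf = {
      mtry <- params$mtry
      if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
      randomForest::randomForest(x = X, y = y, ntree = params$ntree,
                                 mtry = min(mtry, ncol(X)),
                                 nodesize = params$nodesize)
    },
    gbt = xgboost::xgboost(X, y, nrounds = params$nrounds,
                           learning_rate = params$eta,
                           max_depth = params$max_depth,
                           subsample = params$subsample,
                           nthreads = 1, verbosity = 0))
  structure(list(model = model, learner = learner, levels = lv,
                 features = colnames(X)),
            class = "ft_classifier")
}

.predict_prob <- function(fit, X) {
  X <- as.matrix(X)
  if (inherits(fit, "ft_constant")) {
    out <- matrix(1, nrow(X), 1L, dimnames = list(NULL, fit$levels))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  lv <- fit$levels
  pr <- switch(fit$learner,
    logistic = {
      if (length(lv) == 2L) {
        # constant or collinear feature columns make the fit rank-deficient;
        # predictions remain well-defined for our in-range feature space
        p2 <- suppressWarnings(stats::predict(fit$model,
                                              newdata = data.frame(X),
                                              type = "response"))
        cbind(1 - p2, p2)
      } else {
        p <- stats::predict(fit$model, newdata = data.frame(X),
                            type = "probs")
        if (is.null(dim(p))) p <- matrix(p, nrow = nrow(X), byrow = FALSE)
        p
      }
    },
    rf = stats::predict(fit$model, X, type = "prob"),
    gbt = {
      p <- stats::predict(fit$model, X, type = "response")
      # binary models return P(second level)
      if (length(lv) == 2L) cbind(1 - p, p) else p
    })
  pr <- as.matrix(pr)
  colnames(pr) <- lv
  pr
}

# ---- classification schemes ------------------------------------------------

#' Multi-class severity classification
#'
#' Fits one multi-class probabilistic classifier and predicts the class
#' with the highest probability (ties toward the less severe label).
#'
#' @param X_train,y_train training features and labels.
#' @param X_test features to predict.
#' @param learner `"logistic"`, `"rf"` or `"gbt"` (gradient-boosted trees).
#' @param params optional learner hyperparameters.
#' @return list with `labels` (ordered factor) and `probs`
#'   (rows sum to 1, columns `Mild`, `Moderate`, `Severe`).
#' @export
multiclass_fit_predict <- function(X_train, y_train, X_test,
                                   learner = "gbt", params = NULL) {
  y_train <- severity_factor(y_train)
  fit <- .fit_classifier(learner, X_train, y_train, params)
  pr <- .predict_prob(fit, X_test)
  probs <- matrix(0, nrow(as.matrix(X_test)), 3L,
                  dimnames = list(NULL, SEVERITY_LEVELS))
  probs[, colnames(pr)] <- pr
  labels <- severity_factor(SEVERITY_LEVELS[apply(probs, 1L, which.max)])
  list(labels = labels, probs = probs)
}

# Difference the cumulative probabilities q1 = P(y > Mild),
# q2 = P(y > Moderate) into class probabilities; a negative middle
# (monotonicity violation) is clipped to 0 and the triple renormalized.
.ordinal_combine <- function(q1, q2) {
  probs <- cbind(Mild = 1 - q1, Moderate = pmax(q1 - q2, 0), Severe = q2)
  probs / rowSums(probs)
}

#' Ordinal severity classification (cumulative binary decomposition)
#'
#' Decomposes the 3-level ordinal problem into two cumulative binary
#' tasks: q1 = P(y > Mild) and q2 = P(y > Moderate). Class probabilities
#' are the differences `(1 - q1, q1 - q2, q2)`; a negative middle
#' probability (monotonicity violation, q2 > q1) is clipped to 0 and the
#' triple renormalized. Prediction is the argmax, ties toward the less
#' severe label. A binary task whose training labels are one-sided returns
#' its degenerate constant probability and flags the result.
#'
#' @inheritParams multiclass_fit_predict
#' @return list with `labels`, `probs` (rows sum to 1) and `degenerate`
#'   (logical flag per binary task).
#' @export
ordinal_fit_predict <- function(X_train, y_train, X_test,
                                learner = "gbt", params = NULL) {
  y_train <- severity_factor(y_train)
  if (nlevels(droplevels(y_train)) < 2L)
    stop("training data must contain at least 2 classes")
  gt_mild <- factor(ifelse(y_train > "Mild", "yes", "no"),
                    levels = c("no", "yes"))
  gt_mod <- factor(ifelse(y_train > "Moderate", "yes", "no"),
                   levels = c("no", "yes"))
  f1 <- .fit_classifier(learner, X_train, gt_mild, params)
  f2 <- .fit_classifier(learner, X_train, gt_mod, params)
  yes_prob <- function(fit) {
    pr <- .predict_prob(fit, X_test)
    if ("yes" %in% colnames(pr)) unname(pr[, "yes"]) else rep(0, nrow(pr))
  }
  probs <- .ordinal_combine(yes_prob(f1), yes_prob(f2))
  labels <- severity_factor(SEVERITY_LEVELS[apply(probs, 1L, which.max)])
  list(labels = labels, probs = probs,
       degenerate = c(inherits(f1, "ft_constant"),
                      inherits(f2, "ft_constant")))
}

#' Classification metrics for severity prediction
#'
#' Computes, as percentages: accuracy; balanced accuracy (mean per-class
#' recall over the classes present in the true labels); macro precision
#' (precision of a class never predicted is defined as 0); and macro F1
#' using the standard harmonic-mean form `2PR/(P+R)` (0 when P + R = 0).
#' Macro averages run over the classes present in the true labels.
#'
#' @param y_true,y_pred label vectors of equal length (coerced to the
#'   severity factor when their values allow it).
#' @return An object of class `metrics_report`: `accuracy`,
#'   `balanced_accuracy`, `macro_precision`, `macro_f1`, `per_class`
#'   (precision/recall/F1 per label) and `confusion` (true x predicted
#'   counts).
#' @export
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) == 0L) stop("empty label vectors")
  vals <- unique(c(as.character(y_true), as.character(y_pred)))
  lv <- if (all(vals %in% SEVERITY_LEVELS)) SEVERITY_LEVELS else sort(vals)
  yt <- factor(as.character(y_true), levels = lv)
  yp <- factor(as.character(y_pred), levels = lv)
  cm <- table(true = yt, predicted = yp)
  support <- rowSums(cm)
  predicted_n <- colSums(cm)
  tp <- diag(cm)
  recall <- ifelse(support > 0, tp / support, NA_real_)
  precision <- ifelse(predicted_n > 0, tp / predicted_n, 0)
  f1 <- ifelse(precision + recall > 0 & !is.na(recall),
               2 * precision * recall / (precision + recall), 0)
  present <- support > 0
  per_class <- data.frame(class = lv, support = as.integer(support),
                          precision = 100 * precision,
                          recall = 100 * recall, f1 = 100 * f1)
  structure(list(
    accuracy = 100 * sum(tp) / sum(cm),
    balanced_accuracy = 100 * mean(recall[present]),
    macro_precision = 100 * mean(precision[present]),
    macro_f1 = 100 * mean(f1[present]),
    per_class = per_class, confusion = cm),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  cat(sprintf("  accuracy          %6.2f %%\n", x$accuracy))
  cat(sprintf("  balanced accuracy %6.2f %%\n", x$balanced_accuracy))
  cat(sprintf("  macro precision   %6.2f %%\n", x$macro_precision))
  cat(sprintf("  macro F1          %6.2f %%\n", x$macro_f1))
  cat("  confusion (true x predicted):\n")
  print(x$confusion)
  invisible(x)
}

# grouped, label-stratified fold assignment at the subject level: each
# subject gets one fold; subjects are shuffled within their majority class
# and dealt round-robin so folds have similar class composition.
.subject_folds <- function(subject_ids, y, k) {
  subjects <- unique(subject_ids)
  subj_class <- vapply(subjects, function(s) {
    names(which.max(table(y[subject_ids == s])))
  }, character(1))
  fold <- setNames(integer(length(subjects)), subjects)
  i <- 0L
  for (cl in unique(subj_class)) {
    ss <- sample(subjects[subj_class == cl])
    for (s in ss) {
      fold[s] <- (i %% k) + 1L
      i <- i + 1L
    }
  }
  fold
}

.inner_tune <- function(X, y, subject_ids, learner, scheme, inner_folds,
                        tuning_budget) {
  if (tuning_budget <= 0L) return(NULL)
  k <- min(inner_folds, length(unique(subject_ids)))
  if (k < 2L) return(NULL)
  fold <- .subject_folds(subject_ids, y, k)
  candidates <- c(list(.default_params(learner)),
                  replicate(tuning_budget - 1L,
                            .sample_params(learner, ncol(X)),
                            simplify = FALSE))
  best <- NULL
  best_score <- -Inf
  for (params in candidates) {
    yp <- factor(rep(NA_character_, length(y)), levels = SEVERITY_LEVELS)
    for (f in seq_len(k)) {
      test <- fold[subject_ids] == f
      if (!any(test) || all(test)) next
      res <- tryCatch({
        if (scheme == "ordinal")
          ordinal_fit_predict(X[!test, , drop = FALSE], y[!test],
                              X[test, , drop = FALSE], learner, params)
        else
          multiclass_fit_predict(X[!test, , drop = FALSE], y[!test],
                                 X[test, , drop = FALSE], learner, params)
      }, error = function(e) NULL)
      if (!is.null(res)) yp[test] <- as.character(res$labels)
    }
    ok <- !is.na(yp)
    if (!any(ok)) next
    score <- compute_metrics(y[ok], yp[ok])$balanced_accuracy
    if (score > best_score) {
      best_score <- score
      best <- params
    }
  }
  best
}

#' Leave-one-subject-out evaluation
#'
#' Outer loop: all recordings of one subject are held out in turn; the
#' model never sees its own subject during training. Optional inner loop:
#' hyperparameters are tuned by grouped, label-stratified k-fold
#' cross-validation on the remaining subjects (a bounded random search of
#' `tuning_budget` candidate settings, scored by balanced accuracy).
#' Metrics pool the predictions of all outer folds. Fully reproducible for
#' a fixed `seed`.
#'
#' @param data a [severity_dataset()].
#' @param learner `"logistic"`, `"rf"` or `"gbt"`.
#' @param scheme `"multiclass"` or `"ordinal"`.
#' @param inner_folds inner CV folds (default 5).
#' @param tuning_budget number of hyperparameter candidates to try per
#'   outer fold; 0 (default) uses the learner's default settings.
#' @param seed integer seed for all stochastic components.
#' @return An object of class `loso_result`: `metrics`
#'   (a [compute_metrics()] report), `predictions` (per-recording table
#'   with class probabilities), and `folds` (per-fold test subject and
#'   training subjects, for structural leakage checks).
#' @export
loso_evaluate <- function(data, learner = "gbt",
                          scheme = c("multiclass", "ordinal"),
                          inner_folds = 5L, tuning_budget = 0L, seed = 1L) {
  stopifnot(inherits(data, "severity_dataset"))
  scheme <- match.arg(scheme)
  subjects <- unique(data$subject_ids)
  if (length(subjects) < 2L) stop("need at least 2 subjects for LOSO")
  if (nlevels(droplevels(data$y)) < 2L) stop("need at least 2 classes")
  set.seed(seed)
  n <- nrow(data$X)
  pred <- factor(rep(NA_character_, n), levels = SEVERITY_LEVELS,
                 ordered = TRUE)
  probs <- matrix(NA_real_, n, 3L, dimnames = list(NULL, SEVERITY_LEVELS))
  folds <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    s <- subjects[i]
    test <- data$subject_ids == s
    Xtr <- data$X[!test, , drop = FALSE]
    ytr <- data$y[!test]
    params <- .inner_tune(Xtr, ytr, data$subject_ids[!test], learner,
                          scheme, inner_folds, tuning_budget)
    res <- if (scheme == "ordinal")
      ordinal_fit_predict(Xtr, ytr, data$X[test, , drop = FALSE],
                          learner, params)
    else
      multiclass_fit_predict(Xtr, ytr, data$X[test, , drop = FALSE],
                             learner, params)
    pred[test] <- res$labels
    probs[test, ] <- res$probs
    folds[[i]] <- list(test_subject = s,
                       train_subjects = unique(data$subject_ids[!test]))
  }
  predictions <- data.frame(recording = seq_len(n),
                            subject_id = data$subject_ids,
                            true = data$y, predicted = pred,
                            p_mild = probs[, 1L], p_moderate = probs[, 2L],
                            p_severe = probs[, 3L])
  structure(list(metrics = compute_metrics(data$y, pred),
                 predictions = predictions, folds = folds,
                 learner = learner, scheme = scheme, seed = seed),
            class = "loso_result")
}

#' @export
print.loso_result <- function(x, ...) {
  cat("<loso_result>", x$learner, "/", x$scheme, "\n")
  print(x$metrics)
  invisible(x)
}
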