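# Supervised label transfer: per-omics classifiers trained on the discovered
# G1/G2 subtypes. Features are ranked by the one-way ANOVA F statistic and
# pruned by backward elimination under repeated stratified 10-fold
# cross-validation; gradient-boosted trees instead rely on their internal
# split-gain selection. The best model per omics layer (by cross-validated
# AUC) transfers labels to cohorts carrying only that layer.

CLASSIFIER_ALGORITHMS <- c("logistic", "naive_bayes", "svm_linear", "xgboost")

#' Per-feature one-way ANOVA F statistics
#'
#' F statistic of the between- versus within-group mean squares for each
#' feature (row), used as the feature-importance ranking for backward
#' elimination.
#'
#' @param m An `OmicsMatrix`.
#' @param labels Class labels, one per sample of `m` (named vectors are
#'   matched to `m`'s samples by name).
#' @return Named numeric vector of F statistics (one per feature); features
#'   with zero within-group variance and zero between-group spread get 0,
#'   zero within- but positive between-group spread get `Inf`.
#' @export
anova_f_scores <- function(m, labels) {
  y <- resolve_labels(labels, colnames(m))
  g <- factor(y)
  counts <- table(g)
  if (any(counts < 2)) stopf("every class needs at least 2 samples")
  k <- nlevels(g)
  n <- length(y)
  vals <- unclass(m)
  grand <- rowMeans(vals)
  ssb <- numeric(nrow(vals))
  ssw <- numeric(nrow(vals))
  for (lev in levels(g)) {
    xi <- vals[, g == lev, drop = FALSE]
    mi <- rowMeans(xi)
    ssb <- ssb + ncol(xi) * (mi - grand)^2
    ssw <- ssw + rowSums((xi - mi)^2)
  }
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  f[ssw == 0 & ssb == 0] <- 0
  f[ssw == 0 & ssb > 0] <- Inf
  stats::setNames(f, rownames(vals))
}

# Accept labels as a SubtypeAssignment, a named vector, or a plain vector in
# sample order.
resolve_labels <- function(labels, ids) {
  if (inherits(labels, "SubtypeAssignment")) labels <- labels$labels
  if (!is.null(names(labels))) {
    idx <- match(ids, names(labels))
    if (anyNA(idx)) {
      stopf("labels missing for sample(s): %s",
            paste(utils::head(ids[is.na(idx)], 5), collapse = ", "))
    }
    labels <- labels[idx]
  } else if (length(labels) != length(ids)) {
    stopf("labels length (%d) does not match sample count (%d)",
          length(labels), length(ids))
  }
  as.character(labels)
}

# Fit one binary classifier on a samples-x-features matrix. `positive` is the
# class whose score should be large. Returns an object understood by
# predict_classifier().
fit_classifier <- function(x, y, algorithm, positive, seed = 1) {
  y <- factor(y)
  if (nlevels(y) != 2) stopf("binary classification requires 2 classes")
  fit <- with_seed(seed, switch(
    algorithm,
    svm_linear = e1071::svm(x, y, kernel = "linear", cost = 1,
                            scale = FALSE),
    naive_bayes = e1071::naiveBayes(x, y),
    logistic = {
      df <- data.frame(.y = as.integer(y == positive), x, check.names = FALSE)
      suppressWarnings(stats::glm(.y ~ ., data = df,
                                  family = stats::binomial()))
    },
    xgboost = xgboost::xgb.train(
      params = list(max_depth = 3, eta = 0.1,
                    objective = "binary:logistic", nthread = 1),
      data = xgboost::xgb.DMatrix(x, label = as.integer(y == positive),
                                  nthread = 1),
      nrounds = 100, verbose = 0),
    stopf("unknown algorithm '%s'", algorithm)))
  list(algorithm = algorithm, fit = fit, positive = positive,
       levels = levels(y), features = colnames(x))
}

# Predict classes and positive-class scores for new samples (rows).
predict_classifier <- function(clf, x) {
  x <- x[, clf$features, drop = FALSE]
  other <- setdiff(clf$levels, clf$positive)
  score <- switch(
    clf$algorithm,
    svm_linear = {
      pr <- stats::predict(clf$fit, x, decision.values = TRUE)
      dv <- drop(attr(pr, "decision.values"))
      # decision values are oriented "first/second" of the colname
      if (startsWith(colnames(attr(pr, "decision.values"))[1],
                     clf$positive)) dv else -dv
    },
    naive_bayes = {
      post <- stats::predict(clf$fit, as.data.frame(x), type = "raw")
      post[, clf$positive]
    },
    logistic = {
      df <- as.data.frame(x)
      suppressWarnings(
        stats::predict(clf$fit, newdata = df, type = "response"))
    },
    xgboost = stats::predict(clf$fit,
                             xgboost::xgb.DMatrix(x, nthread = 1)))
  class_ <- ifelse(score >= classifier_threshold(clf$algorithm),
                   clf$positive, other)
  list(class = stats::setNames(class_, rownames(x)),
       score = stats::setNames(as.numeric(score), rownames(x)))
}

classifier_threshold <- function(algorithm) {
  if (algorithm == "svm_linear") 0 else 0.5
}

#' ROC area under the curve
#'
#' Mann-Whitney rank formulation: the probability that a random positive
#' outranks a random negative, ties receiving half credit.
#'
#' @param scores Numeric prediction scores, higher = more positive.
#' @param truth Binary ground truth (logical, 0/1, or a 2-level factor whose
#'   second level is positive).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, truth) {
  if (is.factor(truth)) truth <- truth == levels(truth)[2]
  truth <- as.logical(truth)
  n_pos <- sum(truth)
  n_neg <- sum(!truth)
  if (n_pos == 0 || n_neg == 0) stopf("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[truth]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Seeded stratified fold assignment: within each class, shuffled indices are
# dealt out cyclically so every fold sees both classes.
stratified_folds <- function(y, folds, seed) {
  fold_of <- integer(length(y))
  with_seed(seed, {
    for (lev in unique(y)) {
      idx <- sample(which(y == lev))
      fold_of[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold_of
}

# Mean accuracy and AUC of `algorithm` on feature columns `feats` under
# repeated stratified k-fold CV.
cv_performance <- function(x, y, feats, algorithm, positive, folds, repeats,
                           seed) {
  accs <- c()
  aucs <- c()
  for (rep_i in seq_len(repeats)) {
    fold_of <- stratified_folds(y, folds, derive_seed(seed,
                                                      paste0("rep", rep_i)))
    for (f in seq_len(folds)) {
      test <- fold_of == f
      if (!any(test) || length(unique(y[!test])) < 2) next
      clf <- fit_classifier(x[!test, feats, drop = FALSE], y[!test],
                            algorithm, positive,
                            seed = derive_seed(seed, sprintf("f%d_%d",
                                                             rep_i, f)))
      pr <- predict_classifier(clf, x[test, feats, drop = FALSE])
      accs <- c(accs, mean(pr$class == y[test]))
      if (length(unique(y[test])) == 2) {
        aucs <- c(aucs, roc_auc(pr$score, y[test] == positive))
      }
    }
  }
  c(accuracy = mean(accs), auc = if (length(aucs)) mean(aucs) else NA_real_)
}

#' Backward feature elimination under repeated cross-validation
#'
#' Ranks features by [anova_f_scores()], starts from the top `start_m`, and
#' repeatedly drops the lowest-ranked feature, recording the mean accuracy
#' (and AUC) of `algorithm` over `repeats` runs of stratified `folds`-fold
#' cross-validation at every set size. Returns the feature set with the
#' highest mean accuracy; ties favour fewer features.
#'
#' @param m An `OmicsMatrix` (training cohort).
#' @param labels G1/G2 labels (a `SubtypeAssignment` or vector).
#' @param algorithm One of `"logistic"`, `"naive_bayes"`, `"svm_linear"`.
#' @param folds,repeats Cross-validation geometry (defaults 10 and 10).
#' @param start_m Size of the initial F-ranked feature pool (default 100).
#' @param seed Integer seed for fold assignment and fits.
#' @param positive Label treated as the positive class (default `"G1"`).
#' @return List with `features` (selected ids, F-rank order), `trace` (data
#'   frame: `n_features`, `cv_accuracy`, `cv_auc`), `f_scores`.
#' @export
backward_elimination_cv <- function(m, labels, algorithm,
                                    folds = 10, repeats = 10,
                                    start_m = 100, seed = 1,
                                    positive = "G1") {
  if (algorithm == "xgboost") {
    stopf("gradient-boosted trees use internal feature selection, %s",
          "not backward elimination")
  }
  y <- resolve_labels(labels, colnames(m))
  if (ncol(m) < folds) stopf("need at least as many samples as folds")
  f <- anova_f_scores(m, y)
  ranked <- names(sort(f, decreasing = TRUE))
  pool <- utils::head(ranked, start_m)
  x <- t(unclass(m))
  trace <- data.frame(n_features = integer(), cv_accuracy = numeric(),
                      cv_auc = numeric())
  for (size in rev(seq_along(pool))) {
    perf <- cv_performance(x, y, pool[seq_len(size)], algorithm, positive,
                           folds, repeats, derive_seed(seed, "cv"))
    trace <- rbind(trace,
                   data.frame(n_features = size,
                              cv_accuracy = perf[["accuracy"]],
                              cv_auc = perf[["auc"]]))
  }
  trace <- trace[order(trace$n_features), ]
  rownames(trace) <- NULL
  # highest accuracy; among ties the smallest set
  best_size <- trace$n_features[trace$cv_accuracy == max(trace$cv_accuracy)]
  best_size <- min(best_size)
  list(features = pool[seq_len(best_size)], trace = trace, f_scores = f)
}

#' Train a final classifier on the full training cohort
#'
#' Fits `algorithm` on all training samples using `features`. For
#' gradient-boosted trees (`"xgboost"`), `features` is the candidate pool and
#' the reported `selected_features` are those with nonzero split-gain
#' importance; other algorithms use `features` as-is.
#'
#' @inheritParams backward_elimination_cv
#' @param features Feature ids to train on.
#' @param cv_stats Optional named vector with `accuracy` and `auc` from
#'   cross-validation, stored on the model for model selection.
#' @return List of class `TrainedClassifier`: `algorithm`, `omics_kind`,
#'   `selected_features`, `classifier`, `training_auc`, `cv_mean_accuracy`,
#'   `cv_mean_auc`, `seed`.
#' @export
train_final <- function(m, labels, algorithm, features, seed = 1,
                        positive = "G1", cv_stats = NULL) {
  y <- resolve_labels(labels, colnames(m))
  if (length(unique(y)) < 2) stopf("training labels contain a single class")
  missing <- setdiff(features, rownames(m))
  if (length(missing)) {
    stopf("feature(s) absent from the matrix: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  }
  x <- t(unclass(m)[features, , drop = FALSE])
  clf <- fit_classifier(x, y, algorithm, positive, seed = seed)
  selected <- features
  if (algorithm == "xgboost") {
    imp <- xgboost::xgb.importance(model = clf$fit)
    selected <- imp$Feature[imp$Gain > 0]
    if (!length(selected)) selected <- features
  }
  pr <- predict_classifier(clf, x)
  structure(list(algorithm = algorithm, omics_kind = omics_kind(m),
                 selected_features = selected, classifier = clf,
                 training_auc = roc_auc(pr$score, y == positive),
                 cv_mean_accuracy = if (!is.null(cv_stats))
                   unname(cv_stats[["accuracy"]]) else NA_real_,
                 cv_mean_auc = if (!is.null(cv_stats))
                   unname(cv_stats[["auc"]]) else NA_real_,
                 positive = positive, seed = as.integer(seed)),
            class = "TrainedClassifier")
}

#' Pick the best classifier per omics layer
#'
#' Argmax of cross-validated mean AUC within each omics kind; ties are broken
#' by cross-validated accuracy, then by algorithm simplicity (logistic <
#' naive Bayes < linear SVM < gradient-boosted trees).
#'
#' @param candidates List of `TrainedClassifier` objects.
#' @return Named list, one winning `TrainedClassifier` per omics kind.
#' @export
select_best_model <- function(candidates) {
  if (!length(candidates)) stopf("no candidate models supplied")
  kinds <- vapply(candidates, function(c) c$omics_kind, "")
  out <- list()
  for (kind in unique(kinds)) {
    cs <- candidates[kinds == kind]
    auc <- vapply(cs, function(c) c$cv_mean_auc, 0)
    acc <- vapply(cs, function(c) c$cv_mean_accuracy, 0)
    simplicity <- match(vapply(cs, function(c) c$algorithm, ""),
                        CLASSIFIER_ALGORITHMS)
    ord <- order(-auc, -acc, simplicity)
    out[[kind]] <- cs[[ord[1]]]
  }
  out
}

#' Transfer subtype labels to a single-omics cohort
#'
#' Predicts G1/G2 for every sample of `cohort` with a trained classifier and,
#' when survival data are supplied, validates the transferred labels
#' prognostically with a two-group log-rank test and Harrell's C-index on
#' each endpoint. The cohort must be normalized the same way as the training
#' data (z-score by gene) and must contain every model feature.
#'
#' @param model A `TrainedClassifier`.
#' @param cohort An `OmicsMatrix` of the matching omics kind.
#' @param surv Optional [survival_table()] for the cohort samples.
#' @return List with `labels` (named character vector), and when `surv` is
#'   given: `logrank_efs`, `logrank_os`, `concordance_efs`,
#'   `concordance_os`.
#' @export
transfer_labels <- function(model, cohort, surv = NULL) {
  feats <- model$classifier$features  # full training columns, superset of
  present <- feats %in% rownames(cohort)  # the reported selected_features
  if (mean(present) < 0.9) {
    stopf("cohort carries only %.0f%% of the %d model features; refusing %s",
          100 * mean(present), length(feats), "to predict")
  }
  if (!all(present)) {
    stopf("model feature(s) missing from the cohort: %s",
          paste(utils::head(feats[!present], 5), collapse = ", "))
  }
  x <- t(unclass(cohort)[feats, , drop = FALSE])
  pr <- predict_classifier(model$classifier, x)
  out <- list(labels = pr$class, scores = pr$score)
  if (!is.null(surv)) {
    cl <- align_survival(surv, colnames(cohort))
    if (length(unique(pr$class)) == 2) {
      risk <- as.integer(pr$class == model$positive)
      out$logrank_efs <- logrank_two_group(pr$class, cl$efs_time,
                                           cl$efs_event)
      out$logrank_os <- logrank_two_group(pr$class, cl$os_time, cl$os_event)
      out$concordance_efs <- concordance_index(risk, cl$efs_time,
                                               cl$efs_event)
      out$concordance_os <- concordance_index(risk, cl$os_time, cl$os_event)
    } else {
      warnf("all samples predicted as one class; no prognostic validation")
    }
  }
  out
}
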