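# Supervised label transfer: ANOVA F ranking, backward elimination under
# repeated CV, final model fitting, AUC, model choice and cohort transfer.

labelled_omics <- function(n_feat, n_samp, informative = 1, shift = 3,
                           seed = 1, kind = "expression") {
  withr::with_seed(seed, {
    y <- rep(c("G1", "G2"), length.out = n_samp)
    vals <- matrix(rnorm(n_feat * n_samp), n_feat, n_samp,
                   dimnames = list(sprintf("f%d", seq_len(n_feat)),
                                   sprintf("s%d", seq_len(n_samp))))
    for (i in seq_len(informative)) {
      vals[i, ] <- vals[i, ] + ifelse(y == "G1", shift / 2, -shift / 2)
    }
    list(m = omics_matrix(vals, omics_kind = kind), y = y)
  })
}

test_that("ANOVA F is zero for equal means and matches aov on a toy", {
  # duplicate each G1 column into G2: identical class means, F exactly 0
  d <- labelled_omics(3, 40, informative = 0, seed = 91)
  vals <- unclass(d$m)
  vals[, d$y == "G2"] <- vals[, d$y == "G1"]
  f0 <- anova_f_scores(omics_matrix(vals), d$y)
  expect_true(all(abs(f0) < 1e-20))

  # two classes (1,1) vs (3,3) with tiny jitter: compare against stats::aov
  vals <- matrix(c(1.01, 0.99, 3.02, 2.98), 1, 4,
                 dimnames = list("f1", sprintf("s%d", 1:4)))
  y <- c("G1", "G1", "G2", "G2")
  f1 <- anova_f_scores(omics_matrix(vals), y)[["f1"]]
  ref <- summary(stats::aov(vals[1, ] ~ factor(y)))[[1]][["F value"]][1]
  expect_equal(f1, ref, tolerance = 1e-10)

  # location invariance
  shifted <- omics_matrix(vals + 1000)
  expect_equal(anova_f_scores(shifted, y)[["f1"]], f1, tolerance = 1e-6)

  expect_error(anova_f_scores(d$m, c("G1", rep("G2", 39))),
               "at least 2 samples")
})

test_that("backward elimination keeps a perfectly separating feature", {
  d <- labelled_omics(50, 60, informative = 1, shift = 8, seed = 92)
  be <- backward_elimination_cv(d$m, d$y, "svm_linear", folds = 5,
                                repeats = 2, start_m = 10, seed = 11)
  expect_true("f1" %in% be$features)
  expect_gte(max(be$trace$cv_accuracy), 0.95)
  # determinism
  be2 <- backward_elimination_cv(d$m, d$y, "svm_linear", folds = 5,
                                 repeats = 2, start_m = 10, seed = 11)
  expect_identical(be$features, be2$features)
  expect_identical(be$trace, be2$trace)
})

test_that("permuted labels yield chance-level cross-validated accuracy", {
  d <- labelled_omics(30, 80, informative = 0, seed = 93)
  y_perm <- withr::with_seed(94, sample(d$y))
  be <- backward_elimination_cv(d$m, y_perm, "logistic", folds = 5,
                                repeats = 2, start_m = 8, seed = 12)
  expect_lt(max(be$trace$cv_accuracy), 0.72)
  expect_gt(max(be$trace$cv_accuracy), 0.38)
})

test_that("every classifier family trains and predicts on separable data", {
  d <- labelled_omics(10, 50, informative = 2, shift = 8, seed = 95)
  for (algo in c("logistic", "naive_bayes", "svm_linear", "xgboost")) {
    fit <- train_final(d$m, d$y, algo, sprintf("f%d", 1:10), seed = 13)
    expect_s3_class(fit, "TrainedClassifier")
    pr <- prognae:::predict_classifier(fit$classifier, t(unclass(d$m)))
    expect_gte(mean(pr$class == d$y), 0.95)
    expect_gte(fit$training_auc, 0.99)
  }
})

test_that("gradient-boosted trees surface the informative feature", {
  d <- labelled_omics(20, 120, informative = 1, shift = 4, seed = 96)
  fit <- train_final(d$m, d$y, "xgboost", sprintf("f%d", 1:20), seed = 14)
  imp <- xgboost::xgb.importance(model = fit$classifier$fit)
  expect_identical(imp$Feature[1], "f1")
  expect_true("f1" %in% fit$selected_features)
})

test_that("serialized models reproduce identical predictions", {
  d <- labelled_omics(8, 40, informative = 1, shift = 5, seed = 97)
  fit <- train_final(d$m, d$y, "svm_linear", sprintf("f%d", 1:8), seed = 15)
  x <- t(unclass(d$m))
  before <- prognae:::predict_classifier(fit$classifier, x)
  path <- withr::local_tempfile(fileext = ".rds")
  saveRDS(fit, path)
  after <- prognae:::predict_classifier(readRDS(path)$classifier, x)
  expect_identical(before$class, after$class)
  expect_equal(before$score, after$score)
})

test_that("AUC follows Mann-Whitney pair counting, ties included", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
  withr::with_seed(98, {
    for (r in 1:25) {
      n <- sample(5:12, 1)
      scores <- sample(1:4, n, replace = TRUE)   # plenty of ties
      truth <- rbinom(n, 1, 0.5)
      if (length(unique(truth)) < 2) next
      expect_equal(roc_auc(scores, truth), brute_auc(scores, truth))
    }
    # complement property without ties
    scores <- rnorm(30)
    truth <- rbinom(30, 1, 0.5)
    expect_equal(roc_auc(scores, truth) + roc_auc(-scores, truth), 1)
  })
})

fake_model <- function(auc, acc, algo, kind = "expression") {
  structure(list(algorithm = algo, omics_kind = kind,
                 cv_mean_auc = auc, cv_mean_accuracy = acc),
            class = "TrainedClassifier")
}

test_that("model selection maximizes AUC with documented tie-breaks", {
  single <- fake_model(0.8, 0.7, "logistic")
  expect_identical(select_best_model(list(single))$expression$cv_mean_auc,
                   0.8)
  pair <- list(fake_model(0.9, 0.6, "svm_linear"),
               fake_model(0.7, 0.9, "logistic"))
  expect_identical(select_best_model(pair)$expression$cv_mean_auc, 0.9)
  # AUC tie -> higher accuracy wins
  tie <- list(fake_model(0.8, 0.6, "svm_linear"),
              fake_model(0.8, 0.75, "naive_bayes"))
  expect_identical(select_best_model(tie)$expression$algorithm,
                   "naive_bayes")
  # full tie -> simpler algorithm
  tie2 <- list(fake_model(0.8, 0.7, "svm_linear"),
               fake_model(0.8, 0.7, "logistic"))
  expect_identical(select_best_model(tie2)$expression$algorithm, "logistic")
  expect_error(select_best_model(list()), "no candidate")
})

test_that("transfer reproduces training labels and guards feature overlap", {
  d <- labelled_omics(12, 60, informative = 2, shift = 8, seed = 99)
  fit <- train_final(d$m, d$y, "svm_linear", sprintf("f%d", 1:12), seed = 16)
  tr <- transfer_labels(fit, d$m)
  expect_identical(unname(tr$labels), d$y)

  half <- omics_matrix(unclass(d$m)[1:6, , drop = FALSE])
  expect_error(transfer_labels(fit, half), "refusing")
  near <- omics_matrix(unclass(d$m)[1:11, , drop = FALSE])
  expect_error(transfer_labels(fit, near), "missing from the cohort")
})

test_that("transferred labels validate prognostically on a fresh cohort", {
  d <- labelled_omics(15, 100, informative = 3, shift = 5, seed = 101)
  fit <- train_final(d$m, d$y, "svm_linear", sprintf("f%d", 1:15), seed = 17)
  fresh <- labelled_omics(15, 80, informative = 3, shift = 5, seed = 102)
  surv <- withr::with_seed(103, {
    rate <- ifelse(fresh$y == "G1", 0.4, 0.1)
    t_ev <- rexp(80, rate)
    t_c <- rexp(80, 0.08)
    survival_table(data.frame(
      sample_id = sample_ids(fresh$m),
      efs_time = pmin(t_ev, t_c), efs_event = as.integer(t_ev <= t_c),
      os_time = pmin(t_ev, t_c), os_event = as.integer(t_ev <= t_c)))
  })
  tr <- transfer_labels(fit, fresh$m, surv)
  expect_gte(mean(tr$labels == fresh$y), 0.9)
  expect_lt(tr$logrank_efs$p_value, 0.01)
  expect_gt(tr$concordance_efs$c_index, 0.6)
})
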