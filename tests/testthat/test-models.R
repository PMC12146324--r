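test_that("the registry covers the benchmark's classifier families", {
  reg <- list_classifiers()
  expect_true(all(c("random_forest", "gradient_boosting", "xgboost",
                    "decision_tree", "mlp", "svm_linear", "svm_radial",
                    "naive_bayes", "qda", "adaboost", "knn",
                    "logistic_regression", "gaussian_process") %in%
                    reg$name))
  expect_error(classifier_spec("nonexistent"), "unknown classifier")
})

test_that("train/evaluate learns a separable problem and memorizes with 1-NN", {
  frame <- toy_frame(n = 60, sep = 3)
  ev <- train_evaluate(frame, frame, "knn", seed = 1)
  # knn backend uses k = 5 but perfect separation still memorizes
  expect_gt(ev$metrics$acc, 0.95)
  ev2 <- train_evaluate(frame, frame, "decision_tree", seed = 1)
  expect_gt(ev2$metrics$auc, 0.9)
  expect_error(train_evaluate(frame, frame, "no_such_model"),
               "unknown classifier")
})

test_that("label-shuffled validation gives chance-level AUC", {
  frame <- toy_frame(n = 100, sep = 2, seed = 13)
  shuffled <- frame
  withr::with_seed(14, shuffled$label <- sample(shuffled$label))
  ev <- train_evaluate(frame, shuffled, "logistic_regression", seed = 14)
  expect_gt(ev$metrics$auc, 0.35)
  expect_lt(ev$metrics$auc, 0.65)
})

test_that("model persistence round-trips with identical predictions", {
  frame <- toy_frame(n = 60, sep = 2, seed = 15)
  for (name in c("random_forest", "xgboost", "mlp", "adaboost")) {
    ev <- train_evaluate(frame[1:40, ], frame[41:60, ], name, seed = 15)
    path <- withr::local_tempfile(fileext = ".rds")
    save_model(ev$model, path)
    back <- load_model(path)
    expect_identical(predict(back, frame[41:60, ]),
                     predict(ev$model, frame[41:60, ]))
  }
  # mismatching feature names are refused
  ev <- train_evaluate(frame[1:40, ], frame[41:60, ], "decision_tree")
  bad <- frame[41:60, ]
  names(bad)[3] <- "renamed"
  expect_error(predict(ev$model, bad), "feature name mismatch")
})

test_that("every registry classifier trains and scores on a small problem", {
  frame <- toy_frame(n = 50, p = 3, sep = 2.5, seed = 16)
  for (name in list_classifiers()$name) {
    ev <- train_evaluate(frame[1:34, ], frame[35:50, ], name, seed = 16)
    expect_true(is.finite(ev$metrics$auc), info = name)
    expect_gt(ev$metrics$auc, 0.7)  # strongly separable toy problem
    expect_true(all(ev$scores$score >= 0 & ev$scores$score <= 1),
                info = name)
  }
})

test_that("five-fold CV partitions correctly and is seed-deterministic", {
  frame <- toy_frame(n = 100, sep = 2, seed = 17)
  cv <- five_fold_cv(frame, "logistic_regression", seed = 17)
  expect_equal(nrow(cv$folds), 5)
  # folds disjoint, exhaustive, balanced for N = 100 with 50/50 classes
  expect_equal(unname(table(cv$fold_id)), rep(20L, 5), ignore_attr = TRUE)
  for (f in 1:5) {
    expect_equal(sum(frame$label[cv$fold_id == f] == "CYTOPLASM"), 10)
  }
  # mean equals the arithmetic mean of folds
  expect_equal(cv$mean$auc, mean(cv$folds$auc))
  cv2 <- five_fold_cv(frame, "logistic_regression", seed = 17)
  expect_identical(cv$folds, cv2$folds)
  # only 3 cytoplasm members: stratified 5-fold is impossible
  few_pos <- frame[c(which(frame$label == "CYTOPLASM")[1:3],
                     which(frame$label == "NUCLEUS")), ]
  expect_error(five_fold_cv(few_pos, "knn", seed = 1), "stratification")
})

test_that("CV AUC is consistent with hold-out AUC on planted-signal data", {
  cfg <- synthetic_config(n_sequences = 600, length_range = c(200, 600),
                          seed = 42)
  sim <- simulate_dataset(cfg)
  labelled <- assign_labels(
    sim$cnrci[sim$cnrci$cell_line == "SIM.CL01", ], quiet = TRUE)
  feats <- featurize(sim$sequences, "composition")
  frame <- dplyr::inner_join(
    tibble::tibble(id = labelled$gene_id, label = labelled$label),
    feats, by = "id")
  sp <- stratified_split(frame, 0.2, seed = 42)
  train <- frame[frame$id %in% sp$train, ]
  valid <- frame[frame$id %in% sp$validation, ]
  cv <- five_fold_cv(train, "gradient_boosting", seed = 42)
  ev <- train_evaluate(train, valid, "gradient_boosting", seed = 42)
  expect_lt(abs(cv$mean$auc - ev$metrics$auc), 0.05)
})

test_that("best-model selection follows AUC, MCC and registry-order tie-breaks", {
  one <- tibble::tibble(classifier = "knn", auc = 0.7, mcc = 0.2)
  expect_equal(select_best(one)$classifier, "knn")
  two <- tibble::tibble(classifier = c("knn", "mlp"), auc = c(0.70, 0.72),
                        mcc = c(0.5, 0.1))
  expect_equal(select_best(two)$classifier, "mlp")
  # randomized lists match a brute-force argmax with the stated tie-break
  reg <- list_classifiers()$name
  withr::with_seed(18, {
    for (rep in 1:20) {
      cand <- tibble::tibble(
        classifier = sample(reg, 6),
        auc = sample(seq(0.6, 0.8, 0.05), 6, replace = TRUE),
        mcc = sample(seq(0, 0.4, 0.1), 6, replace = TRUE))
      got <- select_best(cand)
      ord <- order(-cand$auc, -cand$mcc, match(cand$classifier, reg))
      expect_equal(got$classifier, cand$classifier[ord[1]])
    }
  })
})

test_that("tidiers and autoplot provide the broom-style surface", {
  frame <- toy_frame(n = 60, sep = 2, seed = 19)
  cv <- five_fold_cv(frame, "decision_tree", seed = 19)
  td <- tidy(cv)
  expect_setequal(unique(td$metric),
                  c("sens", "spec", "prec", "acc", "mcc", "f1", "auc"))
  expect_equal(nrow(td), 35)
  gl <- glance(cv)
  expect_equal(gl$folds, 5)
  ev <- train_evaluate(frame[1:40, ], frame[41:60, ], "decision_tree")
  expect_equal(nrow(tidy(ev)), 20)
  expect_s3_class(autoplot(cv), "ggplot")
  expect_s3_class(autoplot(ev), "ggplot")
})
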