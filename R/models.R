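# AdaBoost.M1 with depth-1 rpart stumps; h in {-1, +1}, score = sigmoid of
# the additive margin
fit_adaboost <- function(X, y01, n_rounds = 50L) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  ysign <- ifelse(y01 == 1, 1, -1)
  df <- as.data.frame(X)
  stumps <- vector("list", n_rounds)
  alphas <- numeric(n_rounds)
  used <- 0L
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(y ~ ., data = cbind(df, y = factor(y01)), weights = w,
                        method = "class",
                        control = rpart::rpart.control(maxdepth = 1,
                                                       cp = -1, xval = 0,
                                                       minsplit = 2))
    pred <- ifelse(predict(fit, df, type = "class") == "1", 1, -1)
    err <- sum(w * (pred != ysign))
    if (err <= 0) {
      # perfect weak learner: keep it with a capped weight and stop
      used <- m
      stumps[[m]] <- fit
      alphas[m] <- 10
      break
    }
    if (err >= 0.5) break
    alpha <- 0.5 * log((1 - err) / err)
    used <- m
    stumps[[m]] <- fit
    alphas[m] <- alpha
    w <- w * exp(-alpha * ysign * pred)
    w <- w / sum(w)
  }
  list(stumps = stumps[seq_len(used)], alphas = alphas[seq_len(used)])
}

predict_adaboost <- function(model, X) {
  df <- as.data.frame(X)
  if (length(model$stumps) == 0) return(rep(0.5, nrow(df)))
  margin <- rowSums(vapply(seq_along(model$stumps), function(m) {
    pred <- ifelse(predict(model$stumps[[m]], df, type = "class") == "1",
                   1, -1)
    model$alphas[m] * pred
  }, numeric(nrow(df))))
  1 / (1 + exp(-2 * margin))
}

# drop columns whose within-class sd is ~0 in any class (needed by the
# Gaussian generative models)
nonconstant_within_class <- function(X, y01, tol = 1e-8) {
  ok <- rep(TRUE, ncol(X))
  for (cl in unique(y01)) {
    sds <- apply(X[y01 == cl, , drop = FALSE], 2, stats::sd)
    ok <- ok & sds > tol
  }
  which(ok)
}

# classifier registry: fit(X, y01, seed) -> model; score(model, X) -> P(pos)
backend_registry <- function() {
  list(
    logistic_regression = list(
      backend = "stats::glm",
      fit = function(X, y01, seed) {
        df <- as.data.frame(X)
        suppressWarnings(stats::glm(y ~ ., data = cbind(df, y = y01),
                                    family = stats::binomial()))
      },
      score = function(m, X) {
        suppressWarnings(
          unname(stats::predict(m, as.data.frame(X), type = "response")))
      }
    ),
    decision_tree = list(
      backend = "rpart::rpart",
      fit = function(X, y01, seed) {
        rpart::rpart(y ~ ., data = cbind(as.data.frame(X),
                                         y = factor(y01)),
                     method = "class")
      },
      score = function(m, X) {
        unname(predict(m, as.data.frame(X), type = "prob")[, "1"])
      }
    ),
    random_forest = list(
      backend = "ranger::ranger",
      fit = function(X, y01, seed) {
        ranger::ranger(x = as.data.frame(X), y = factor(y01),
                       probability = TRUE, num.trees = 500, seed = seed,
                       num.threads = 1)
      },
      score = function(m, X) {
        unname(predict(m, as.data.frame(X),
                       num.threads = 1)$predictions[, "1"])
      }
    ),
    gradient_boosting = list(
      # sklearn-GBM-style preset on the xgboost backend
      backend = "xgboost::xgb.train",
      fit = function(X, y01, seed) {
        xgboost::xgb.train(
          params = list(objective = "binary:logistic", eta = 0.1,
                        max_depth = 3, nthread = 1, seed = seed),
          data = xgboost::xgb.DMatrix(X, label = y01, nthread = 1),
          nrounds = 100, verbose = 0)
      },
      score = function(m, X) {
        unname(predict(m, xgboost::xgb.DMatrix(X, nthread = 1)))
      }
    ),
    xgboost = list(
      backend = "xgboost::xgb.train",
      fit = function(X, y01, seed) {
        xgboost::xgb.train(
          params = list(objective = "binary:logistic", eta = 0.3,
                        max_depth = 6, nthread = 1, seed = seed),
          data = xgboost::xgb.DMatrix(X, label = y01, nthread = 1),
          nrounds = 100, verbose = 0)
      },
      score = function(m, X) {
        unname(predict(m, xgboost::xgb.DMatrix(X, nthread = 1)))
      }
    ),
    mlp = list(
      backend = "nnet::nnet",
      fit = function(X, y01, seed) {
        with_seed(seed, nnet::nnet(x = X, y = y01, size = 16, decay = 0.01,
                                   maxit = 200, entropy = TRUE,
                                   MaxNWts = 1e6, trace = FALSE))
      },
      score = function(m, X) as.vector(predict(m, X))
    ),
    svm_linear = list(
      backend = "e1071::svm",
      fit = function(X, y01, seed) {
        with_seed(seed, e1071::svm(x = X, y = factor(y01), kernel = "linear",
                                   probability = TRUE))
      },
      score = function(m, X) {
        p <- predict(m, X, probability = TRUE)
        unname(attr(p, "probabilities")[, "1"])
      }
    ),
    svm_radial = list(
      backend = "e1071::svm",
      fit = function(X, y01, seed) {
        with_seed(seed, e1071::svm(x = X, y = factor(y01), kernel = "radial",
                                   probability = TRUE))
      },
      score = function(m, X) {
        p <- predict(m, X, probability = TRUE)
        unname(attr(p, "probabilities")[, "1"])
      }
    ),
    naive_bayes = list(
      backend = "e1071::naiveBayes",
      fit = function(X, y01, seed) {
        keep <- nonconstant_within_class(X, y01)
        list(keep = keep,
             nb = e1071::naiveBayes(X[, keep, drop = FALSE], factor(y01)))
      },
      score = function(m, X) {
        unname(predict(m$nb, X[, m$keep, drop = FALSE],
                       type = "raw")[, "1"])
      }
    ),
    qda = list(
      backend = "MASS::qda",
      fit = function(X, y01, seed) {
        keep <- nonconstant_within_class(X, y01)
        list(keep = keep,
             qda = MASS::qda(X[, keep, drop = FALSE], grouping = factor(y01)))
      },
      score = function(m, X) {
        unname(predict(m$qda, X[, m$keep, drop = FALSE])$posterior[, "1"])
      }
    ),
    adaboost = list(
      backend = "lnclocr (AdaBoost.M1, rpart stumps)",
      fit = function(X, y01, seed) fit_adaboost(X, y01),
      score = function(m, X) predict_adaboost(m, X)
    ),
    knn = list(
      backend = "class::knn",
      fit = function(X, y01, seed) list(X = X, y01 = y01, k = 5L,
                                        seed = seed),
      score = function(m, X) {
        pred <- with_seed(m$seed,
                          class::knn(m$X, X, factor(m$y01), k = m$k,
                                     prob = TRUE))
        p <- attr(pred, "prob")
        ifelse(pred == "1", p, 1 - p)
      }
    ),
    gaussian_process = list(
      backend = "kernlab::gausspr",
      fit = function(X, y01, seed) {
        with_seed(seed,
                  kernlab::gausspr(x = X, y = factor(y01), kernel = "rbfdot",
                                   prob.model = TRUE))
      },
      score = function(m, X) {
        unname(kernlab::predict(m, X, type = "probabilities")[, "1"])
      }
    )
  )
}

#' Classifier registry
#'
#' The evaluation harness trains classical classifiers from a fixed
#' registry covering the families of the benchmark: random forest,
#' gradient boosting and extreme gradient boosting (both on the xgboost
#' backend with different presets), decision tree, multilayer perceptron,
#' linear and radial support-vector machines, Gaussian naive Bayes,
#' quadratic discriminant analysis, AdaBoost (implemented in-package over
#' decision stumps), k-nearest neighbours, logistic regression and a
#' Gaussian process classifier.
#'
#' @return A tibble with columns `name` and `backend`.
#' @export
list_classifiers <- function() {
  reg <- backend_registry()
  tibble::tibble(name = names(reg),
                 backend = vapply(reg, `[[`, character(1), "backend"))
}

#' Construct a classifier specification
#'
#' @param name Registry key (see [list_classifiers()]).
#' @param ... Hyperparameter overrides (currently recorded, passed through
#'   to the backend where supported).
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(name, ...) {
  if (!name %in% names(backend_registry())) {
    stop("unknown classifier '", name, "'; see list_classifiers()",
         call. = FALSE)
  }
  structure(list(name = name, hyperparameters = list(...)),
            class = "classifier_spec")
}

as_spec <- function(spec) {
  if (inherits(spec, "classifier_spec")) spec else classifier_spec(spec)
}

# split a modelling frame into feature matrix + 0/1 response
frame_to_xy <- function(data, label_col, positive) {
  stopifnot(label_col %in% names(data))
  feat_cols <- setdiff(names(data), c("id", label_col, "cnrci", "cell_line",
                                      "split", "length"))
  X <- as.matrix(as.data.frame(data)[, feat_cols, drop = FALSE])
  storage.mode(X) <- "double"
  y01 <- as.integer(data[[label_col]] == positive)
  list(X = X, y01 = y01, features = feat_cols)
}

#' Train a classifier and evaluate it on a hold-out set
#'
#' Fits one registry classifier on the training frame (features are
#' standardized by training means and sds, stored in the model), scores
#' the validation frame, thresholds the positive-class score at 0.5 for
#' the confusion-matrix metrics and computes the full seven-metric set.
#' The positive class is cytoplasm.
#'
#' @param train,validation Data frames with a label column plus numeric
#'   descriptor columns (columns `id`, `cnrci`, `cell_line`, `split` are
#'   ignored as features).
#' @param spec A [classifier_spec()] or registry name.
#' @param seed Integer seed for stochastic backends.
#' @param label_col Name of the label column.
#' @param positive Positive-class label (default `"CYTOPLASM"`).
#' @param threshold Score threshold for label metrics.
#' @param families Optional descriptor family tag recorded in the model
#'   (used when predicting straight from sequences).
#' @return A list of class `lnclocr_eval`: `model` (an `lnclocr_model`),
#'   `metrics` (one-row tibble), `scores` (per-validation-row tibble).
#' @export
train_evaluate <- function(train, validation, spec = "random_forest",
                           seed = 42L, label_col = "label",
                           positive = "CYTOPLASM", threshold = 0.5,
                           families = NULL) {
  spec <- as_spec(spec)
  tr <- frame_to_xy(train, label_col, positive)
  va <- frame_to_xy(validation, label_col, positive)
  if (length(unique(tr$y01)) < 2) {
    stop("training set must contain both classes", call. = FALSE)
  }
  if (!identical(tr$features, va$features)) {
    stop("train/validation feature columns differ", call. = FALSE)
  }
  center <- colMeans(tr$X)
  scale_ <- apply(tr$X, 2, stats::sd)
  scale_[scale_ == 0] <- 1
  Xtr <- sweep(sweep(tr$X, 2, center), 2, scale_, "/")
  Xva <- sweep(sweep(va$X, 2, center), 2, scale_, "/")
  entry <- backend_registry()[[spec$name]]
  fit <- entry$fit(Xtr, tr$y01, seed)
  model <- structure(list(spec = spec, fit = fit, center = center,
                          scale = scale_, feature_names = tr$features,
                          threshold = threshold, positive = positive,
                          families = families, seed = seed,
                          version = as.character(utils::packageVersion("lnclocr"))),
                     class = "lnclocr_model")
  scores <- entry$score(fit, Xva)
  metrics <- metric_set(va$y01 == 1, scores, threshold)
  structure(list(model = model,
                 metrics = dplyr::bind_cols(
                   tibble::tibble(classifier = spec$name), metrics),
                 scores = tibble::tibble(
                   id = if ("id" %in% names(validation)) validation$id
                        else seq_along(scores),
                   score = scores,
                   label = ifelse(scores >= threshold, positive,
                                  setdiff(unique(train[[label_col]]),
                                          positive)[1]),
                   truth = validation[[label_col]])),
            class = "lnclocr_eval")
}

#' Predict localization for new data
#'
#' @param object An `lnclocr_model` (from [train_evaluate()] or
#'   [load_model()]).
#' @param newdata A data frame with the model's descriptor columns, or a
#'   sequence tibble (`id`, `seq`) if the model records its descriptor
#'   families (it is then featurized first). Prediction refuses feature
#'   name mismatches.
#' @param ... Unused.
#' @return A tibble with columns `id`, `score`, `label`.
#' @method predict lnclocr_model
#' @export
predict.lnclocr_model <- function(object, newdata, ...) {
  if ("seq" %in% names(newdata) &&
      !all(object$feature_names %in% names(newdata))) {
    if (is.null(object$families)) {
      stop("model does not record descriptor families; supply a feature ",
           "data frame instead of sequences", call. = FALSE)
    }
    newdata <- featurize(newdata, object$families)
  }
  missing <- setdiff(object$feature_names, names(newdata))
  if (length(missing)) {
    stop("feature name mismatch: model expects missing column(s) ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(as.data.frame(newdata)[, object$feature_names,
                                        drop = FALSE])
  storage.mode(X) <- "double"
  X <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  scores <- backend_registry()[[object$spec$name]]$score(object$fit, X)
  tibble::tibble(
    id = if ("id" %in% names(newdata)) newdata$id else seq_along(scores),
    score = scores,
    label = ifelse(scores >= object$threshold, object$positive,
                   if (object$positive == "CYTOPLASM") "NUCLEUS"
                   else "CYTOPLASM"))
}

#' Persist / restore a fitted model
#'
#' A model is stored as a single-file archive embedding the fitted
#' backend object, feature-name list, standardization constants,
#' descriptor-family configuration, decision threshold, seed and package
#' version; reloading gives bit-identical predictions.
#'
#' @param model An `lnclocr_model`.
#' @param path File path.
#' @return `path` (save) or the restored model (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "lnclocr_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "lnclocr_model")) {
    stop("not an lnclocr model file: ", path, call. = FALSE)
  }
  model
}

# seeded stratified fold assignment: vector of fold ids 1..k
stratified_folds <- function(y, k, seed) {
  tab <- table(y)
  if (any(tab < k)) {
    stop("stratification error: class(es) with fewer than ", k,
         " members: ", paste(names(tab)[tab < k], collapse = ", "),
         call. = FALSE)
  }
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in names(tab)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Stratified five-fold cross-validation
#'
#' Splits the data into five stratified folds (seeded), trains on four
#' and evaluates on the held-out fold, rotating; reports the per-fold
#' metric sets and their arithmetic mean. Folds are disjoint and
#' exhaustive, and identical seeds give identical folds and metrics.
#'
#' @param data Modelling frame (label column + descriptor columns).
#' @param spec Classifier spec or registry name.
#' @param seed Integer seed (controls folds and stochastic backends).
#' @param folds Number of folds (default 5).
#' @inheritParams train_evaluate
#' @return An `lnclocr_cv` object: list with `folds` (per-fold metric
#'   tibble), `mean` (one-row tibble), `spec`, `seed`.
#' @export
five_fold_cv <- function(data, spec = "random_forest", seed = 42L,
                         folds = 5L, label_col = "label",
                         positive = "CYTOPLASM", threshold = 0.5) {
  spec <- as_spec(spec)
  fold_id <- stratified_folds(data[[label_col]], folds, seed)
  per_fold <- lapply(seq_len(folds), function(f) {
    ev <- train_evaluate(data[fold_id != f, , drop = FALSE],
                         data[fold_id == f, , drop = FALSE],
                         spec, seed = seed, label_col = label_col,
                         positive = positive, threshold = threshold)
    dplyr::bind_cols(tibble::tibble(fold = f), ev$metrics)
  })
  fold_tbl <- dplyr::bind_rows(per_fold)
  mean_tbl <- fold_tbl |>
    dplyr::summarise(dplyr::across(c("sens", "spec", "prec", "acc",
                                     "mcc", "f1", "auc"), mean))
  structure(list(folds = fold_tbl,
                 mean = dplyr::bind_cols(
                   tibble::tibble(classifier = spec$name), mean_tbl),
                 spec = spec, seed = seed, fold_id = fold_id),
            class = "lnclocr_cv")
}

#' Select the best classifier by validation AUC
#'
#' Argmax over candidate metric rows by AUC, ties broken by higher MCC,
#' then by classifier registry order.
#'
#' @param results A tibble with columns `classifier`, `auc`, `mcc` (one
#'   row per candidate, as stacked from [train_evaluate()] metrics).
#' @return The winning row.
#' @export
select_best <- function(results) {
  stopifnot(nrow(results) >= 1,
            all(c("classifier", "auc", "mcc") %in% names(results)))
  reg_order <- match(results$classifier, names(backend_registry()))
  ord <- order(-results$auc, -results$mcc, reg_order)
  results[ord[1], , drop = FALSE]
}
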