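#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end workflow with the method's
#' stated defaults: length cap 10,000 nt, redundancy identity 0.90,
#' validation fraction 0.2, five CV folds, mRMR subset grid
#' `c(10, 50, 100, 500, 1000, 1500, 2000)`.
#'
#' @param fasta,cnrci Input paths (FASTA + CNRCI table), or `NULL` when
#'   `simulate` is given.
#' @param simulate Optional [synthetic_config()]; when set, inputs are
#'   simulated instead of read from disk.
#' @param cell_lines Optional cell-line selector.
#' @param families Descriptor families passed to [featurize()].
#' @param classifiers Registry names to train per cell line.
#' @param mrmr_k Number of features kept after mRMR ranking (`NULL` for
#'   no selection).
#' @param max_length,identity_threshold,test_fraction,cv_folds Dataset
#'   thresholds.
#' @param seed Master seed.
#' @param out_dir Optional output directory for TSV reports.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(fasta = NULL, cnrci = NULL, simulate = NULL,
                            cell_lines = NULL, families = "correlation",
                            classifiers = c("logistic_regression",
                                            "random_forest", "xgboost",
                                            "naive_bayes"),
                            mrmr_k = NULL, max_length = 10000L,
                            identity_threshold = 0.90, test_fraction = 0.2,
                            cv_folds = 5L, seed = 42L, out_dir = NULL) {
  if (is.null(simulate) && (is.null(fasta) || is.null(cnrci))) {
    stop("provide fasta + cnrci paths or a simulate config", call. = FALSE)
  }
  structure(list(fasta = fasta, cnrci = cnrci, simulate = simulate,
                 cell_lines = cell_lines, families = families,
                 classifiers = classifiers, mrmr_k = mrmr_k,
                 max_length = max_length,
                 identity_threshold = identity_threshold,
                 test_fraction = test_fraction, cv_folds = cv_folds,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full per-cell-line workflow
#'
#' One call reproduces the whole method for every requested cell line:
#' label by CNRCI sign, filter by length, reduce redundancy, stratified
#' split, featurize, (optionally) rank features with mRMR, five-fold CV
#' and hold-out evaluation for every registry classifier, best-model
#' selection, and a feature-CNRCI correlation report. Fully
#' deterministic given the config seed.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `lnclocr_report`: `manifest`, `metrics` (CV
#'   mean + validation rows per cell line x classifier), `best` (one row
#'   per cell line), `models` (named list of `lnclocr_model`), `ranked`
#'   (mRMR tibbles per cell line, if requested), `correlation`
#'   (feature-CNRCI profiles), `variability` (cross-cell-line ranges, if
#'   >= 2 cell lines), `config`, `config_hash`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- rlang::hash(config)
  if (!is.null(config$simulate)) {
    sim <- pipeline_stage("simulate", simulate_dataset(config$simulate))
    seqs <- sim$sequences
    cnrci <- sim$cnrci
  } else {
    seqs <- pipeline_stage("read-fasta", read_fasta(config$fasta))
    cnrci <- pipeline_stage("read-cnrci", read_cnrci_table(config$cnrci))
  }
  manifest <- pipeline_stage("dataset", build_cell_line_datasets(
    seqs, cnrci, cell_lines = config$cell_lines,
    max_length = config$max_length,
    identity_threshold = config$identity_threshold,
    test_fraction = config$test_fraction, seed = config$seed))
  features <- pipeline_stage("featurize", featurize(
    seqs[seqs$id %in% manifest$id, , drop = FALSE], config$families))
  metrics <- list()
  best <- list()
  models <- list()
  ranked <- list()
  corr <- list()
  for (cl in unique(manifest$cell_line)) {
    man <- manifest[manifest$cell_line == cl, , drop = FALSE]
    frame <- dplyr::inner_join(man, features, by = "id")
    feat_cols <- setdiff(names(features), "id")
    if (!is.null(config$mrmr_k)) {
      rk <- pipeline_stage("select-features", mrmr_rank(
        frame[frame$split == "TRAIN", feat_cols, drop = FALSE],
        frame$label[frame$split == "TRAIN"],
        k = min(config$mrmr_k, length(feat_cols))))
      ranked[[cl]] <- rk
      feat_cols <- rk$feature
      frame <- frame[, c("id", "cell_line", "length", "cnrci", "label",
                         "split", feat_cols)]
    }
    train <- frame[frame$split == "TRAIN", , drop = FALSE]
    valid <- frame[frame$split == "VALIDATION", , drop = FALSE]
    rows <- lapply(config$classifiers, function(name) {
      cv <- pipeline_stage(paste0("cv:", name), five_fold_cv(
        train, name, seed = config$seed, folds = config$cv_folds))
      ev <- pipeline_stage(paste0("evaluate:", name), train_evaluate(
        train, valid, name, seed = config$seed,
        families = config$families))
      models[[paste(cl, name, sep = "/")]] <<- ev$model
      dplyr::bind_rows(
        dplyr::bind_cols(tibble::tibble(cell_line = cl, phase = "cv"),
                         cv$mean),
        dplyr::bind_cols(tibble::tibble(cell_line = cl,
                                        phase = "validation"),
                         ev$metrics))
    })
    metrics[[cl]] <- dplyr::bind_rows(rows)
    val_rows <- metrics[[cl]][metrics[[cl]]$phase == "validation", ,
                              drop = FALSE]
    best[[cl]] <- select_best(val_rows)
    corr[[cl]] <- dplyr::bind_cols(
      tibble::tibble(cell_line = cl),
      feature_label_correlation(
        frame[, setdiff(names(frame),
                        c("id", "cell_line", "cnrci", "label", "split",
                          "length")),
              drop = FALSE],
        frame$cnrci))
  }
  report <- structure(list(
    manifest = manifest,
    metrics = dplyr::bind_rows(metrics),
    best = dplyr::bind_rows(best),
    models = models,
    ranked = ranked,
    correlation = dplyr::bind_rows(corr),
    variability = if (length(corr) >= 2) {
      cross_cell_line_variability(dplyr::bind_rows(corr))
    },
    config = config, config_hash = hash, seed = config$seed),
    class = "lnclocr_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- function(tbl) {
    tbl$config_hash <- report$config_hash
    tbl$seed <- report$seed
    tbl
  }
  readr::write_tsv(stamp(report$manifest),
                   file.path(out_dir, "manifest.tsv"))
  readr::write_tsv(stamp(report$metrics), file.path(out_dir, "metrics.tsv"))
  readr::write_tsv(stamp(report$best), file.path(out_dir, "best_models.tsv"))
  readr::write_tsv(stamp(report$correlation),
                   file.path(out_dir, "feature_cnrci_correlation.tsv"))
  if (!is.null(report$variability)) {
    readr::write_tsv(stamp(report$variability),
                     file.path(out_dir, "cross_cell_line_variability.tsv"))
  }
  for (key in names(report$models)) {
    safe <- gsub("[^A-Za-z0-9._-]", "_", key)
    save_model(report$models[[key]],
               file.path(out_dir, paste0("model_", safe, ".rds")))
  }
  invisible(out_dir)
}

#' @export
print.lnclocr_report <- function(x, ...) {
  cat("lnclocr pipeline report\n")
  cat("  cell lines:", paste(unique(x$manifest$cell_line), collapse = ", "),
      "\n")
  cat("  sequences in manifest:", nrow(x$manifest), "\n")
  cat("  config hash:", x$config_hash, " seed:", x$seed, "\n\n")
  cat("Best model per cell line (validation):\n")
  print(x$best, ...)
  invisible(x)
}
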