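#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cross-validation result
#'
#' @param x An `lnclocr_cv` from [five_fold_cv()].
#' @param ... Unused.
#' @return Per-fold metrics in long form: `fold`, `metric`, `value`.
#' @export
tidy.lnclocr_cv <- function(x, ...) {
  tidyr::pivot_longer(x$folds, -c("fold", "classifier"),
                      names_to = "metric", values_to = "value")
}

#' @rdname tidy.lnclocr_cv
#' @return For `glance()`: one row with the classifier, mean metrics and
#'   seed.
#' @export
glance.lnclocr_cv <- function(x, ...) {
  dplyr::bind_cols(x$mean, tibble::tibble(folds = max(x$folds$fold),
                                          seed = x$seed))
}

#' Tidy a hold-out evaluation
#'
#' @param x An `lnclocr_eval` from [train_evaluate()].
#' @param ... Unused.
#' @return For `tidy()`: per-sequence scores (`id`, `score`, `label`,
#'   `truth`); for `glance()`: the one-row metric set.
#' @export
tidy.lnclocr_eval <- function(x, ...) x$scores

#' @rdname tidy.lnclocr_eval
#' @export
glance.lnclocr_eval <- function(x, ...) x$metrics

#' Tidy an mRMR ranking
#'
#' @param x An `lnclocr_mrmr` from [mrmr_rank()].
#' @param ... Unused.
#' @return The ranking tibble (`rank`, `feature`, `relevance`, `f_stat`,
#'   `redundancy`, `score`).
#' @export
tidy.lnclocr_mrmr <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Plot per-fold cross-validation metrics
#'
#' @param object An `lnclocr_cv`.
#' @param ... Unused.
#' @return A ggplot: one point per fold and metric, with the fold mean.
#' @export
autoplot.lnclocr_cv <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 4, size = 3,
                          colour = "red") +
    ggplot2::labs(title = paste0("Five-fold CV: ", object$spec$name),
                  x = NULL, y = "metric value") +
    ggplot2::ylim(c(min(0, d$value), 1))
}

#' Plot the ROC curve of a hold-out evaluation
#'
#' @param object An `lnclocr_eval`.
#' @param ... Unused.
#' @return A ggplot of the empirical ROC curve.
#' @export
autoplot.lnclocr_eval <- function(object, ...) {
  sc <- object$scores
  pos <- sc$truth == object$model$positive
  ord <- order(-sc$score)
  d <- tibble::tibble(
    fpr = c(0, cumsum(!pos[ord]) / sum(!pos)),
    tpr = c(0, cumsum(pos[ord]) / sum(pos)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::labs(title = paste0("ROC: ", object$model$spec$name,
                                 " (AUC = ",
                                 sprintf("%.3f", object$metrics$auc), ")"),
                  x = "false positive rate", y = "true positive rate")
}

#' Plot the strongest feature-CNRCI correlations
#'
#' @param profile Output of [feature_label_correlation()] (optionally
#'   with a `cell_line` column, faceted if present).
#' @param top_n Number of features per direction.
#' @return A ggplot bar chart of the most positively and negatively
#'   correlated descriptors.
#' @export
plot_feature_correlation <- function(profile, top_n = 10L) {
  picked <- profile |>
    dplyr::arrange(dplyr::desc(abs(.data$r))) |>
    dplyr::slice_head(n = 2L * top_n)
  p <- ggplot2::ggplot(picked,
                       ggplot2::aes(x = stats::reorder(.data$feature,
                                                       .data$r),
                                    y = .data$r, fill = .data$r > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Pearson r with CNRCI",
                  title = "Descriptors most correlated with CNRCI")
  if ("cell_line" %in% names(picked)) {
    p <- p + ggplot2::facet_wrap(~cell_line)
  }
  p
}
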