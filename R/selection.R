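# one-way ANOVA F statistic of each feature column against a grouping
f_statistic <- function(X, y) {
  y <- as.factor(y)
  n <- nrow(X)
  g <- nlevels(y)
  grand <- colMeans(X)
  ss_between <- numeric(ncol(X))
  ss_within <- numeric(ncol(X))
  for (lev in levels(y)) {
    sub <- X[y == lev, , drop = FALSE]
    m <- colMeans(sub)
    ss_between <- ss_between + nrow(sub) * (m - grand)^2
    ss_within <- ss_within + colSums(sweep(sub, 2, m)^2)
  }
  safe_div(ss_between / (g - 1), ss_within / (n - g))
}

#' Minimum redundancy maximum relevance (mRMR) feature ranking
#'
#' Greedy forward selection of `k` features. Relevance of a feature is
#' its one-way ANOVA F statistic against the class; redundancy is the
#' mean absolute Pearson correlation with the already-selected features;
#' the selection criterion is relevance minus redundancy (`"difference"`,
#' the default) or relevance over redundancy (`"quotient"`). Because the
#' difference criterion needs both terms on a commensurate scale, the
#' relevance entering the criterion is the bounded variance-explained
#' form of the F statistic, `eta^2 = F(g-1) / (F(g-1) + n-g)` in `[0, 1]`
#' (monotone in F; the raw F is reported in the `f_stat` column). The
#' first pick is the most relevant feature; exact criterion ties are
#' broken lexicographically by descriptor name, so the ranking is
#' deterministic and a ranking of k' < k features is a prefix of the
#' ranking of k.
#'
#' @param X Feature data frame or matrix (numeric descriptor columns; an
#'   `id` column, if present, is ignored).
#' @param y Class labels, one per row of `X`.
#' @param k Number of features to rank (default: all).
#' @param variant `"difference"` or `"quotient"`.
#' @return An object of class `lnclocr_mrmr`: a tibble with columns
#'   `rank`, `feature`, `relevance` (eta-squared), `f_stat`, `redundancy`
#'   and `score`.
#' @export
mrmr_rank <- function(X, y, k = NULL, variant = c("difference", "quotient")) {
  variant <- match.arg(variant)
  X <- as.data.frame(X)
  if ("id" %in% names(X)) X$id <- NULL
  X <- as.matrix(X)
  stopifnot(is.numeric(X), nrow(X) == length(y))
  if (length(unique(y)) < 2) stop("constant-valued target", call. = FALSE)
  p <- ncol(X)
  n <- nrow(X)
  g <- length(unique(y))
  k <- k %||% p
  if (k > p) stop("k (", k, ") exceeds the number of features (", p, ")",
                  call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant feature column(s) carry no signal ",
            "and rank last")
  }
  fstat <- f_statistic(X, y)
  rel <- fstat * (g - 1) / (fstat * (g - 1) + n - g)
  nm <- colnames(X)
  # lexicographic tie-break: order candidates by name once, pick first max
  name_order <- order(nm)
  selected <- integer(0)
  red_sum <- numeric(p)
  rel_out <- red_out <- score_out <- numeric(k)
  for (step in seq_len(k)) {
    remaining <- setdiff(name_order, selected)
    red <- if (step == 1) numeric(length(remaining))
           else red_sum[remaining] / (step - 1)
    score <- if (variant == "difference") rel[remaining] - red
             else safe_div(rel[remaining], red + 1e-12)
    pick <- remaining[which.max(score)]
    i <- match(pick, remaining)
    selected <- c(selected, pick)
    rel_out[step] <- rel[pick]
    red_out[step] <- red[i]
    score_out[step] <- score[i]
    if (step < k) {
      r <- suppressWarnings(as.vector(stats::cor(X[, pick], X)))
      r[is.na(r)] <- 0
      red_sum <- red_sum + abs(r)
    }
  }
  structure(
    tibble::tibble(rank = seq_len(k), feature = nm[selected],
                   relevance = rel_out, f_stat = fstat[selected],
                   redundancy = red_out, score = score_out),
    class = c("lnclocr_mrmr", "tbl_df", "tbl", "data.frame"),
    variant = variant
  )
}

#' Default mRMR subset-size grid
#'
#' Subset sizes at which feature-selection impact is evaluated.
#' @return Integer vector `c(10, 50, 100, 500, 1000, 1500, 2000)`.
#' @export
mrmr_k_grid <- function() c(10L, 50L, 100L, 500L, 1000L, 1500L, 2000L)

#' Correlation of each feature with CNRCI
#'
#' Pearson correlation of every descriptor with the per-gene CNRCI
#' values. A positive correlation means higher feature values favour
#' cytoplasmic localization; negative favours nuclear. Constant
#' descriptors get r = 0 and are flagged.
#'
#' @param X Feature data frame/matrix (an `id` column is ignored).
#' @param cnrci Numeric CNRCI vector, one per row of `X`.
#' @return A tibble with columns `feature`, `r`, `constant`.
#' @export
feature_label_correlation <- function(X, cnrci) {
  X <- as.data.frame(X)
  if ("id" %in% names(X)) X$id <- NULL
  X <- as.matrix(X)
  if (nrow(X) != length(cnrci)) stop("length mismatch between features and ",
                                     "CNRCI values", call. = FALSE)
  stopifnot(nrow(X) >= 3, all(is.finite(cnrci)))
  r <- suppressWarnings(as.vector(stats::cor(X, cnrci)))
  constant <- is.na(r)
  r[constant] <- 0
  tibble::tibble(feature = colnames(X), r = r, constant = constant)
}

#' Cross-cell-line variability of feature-CNRCI correlations
#'
#' For each descriptor, the spread (max minus min) of its CNRCI
#' correlation across cell lines; large ranges mark features whose
#' association with localization is cell-line dependent.
#'
#' @param profiles A tibble with columns `cell_line`, `feature`, `r`
#'   (stack of [feature_label_correlation()] outputs).
#' @return A tibble with columns `feature`, `r_min`, `r_max`, `range`,
#'   sorted by decreasing range.
#' @export
cross_cell_line_variability <- function(profiles) {
  stopifnot(all(c("cell_line", "feature", "r") %in% names(profiles)))
  if (length(unique(profiles$cell_line)) < 2) {
    stop("need at least 2 cell lines", call. = FALSE)
  }
  profiles |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(r_min = min(.data$r), r_max = max(.data$r),
                     range = max(.data$r) - min(.data$r)) |>
    dplyr::arrange(dplyr::desc(range), .data$feature)
}
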