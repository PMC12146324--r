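#' Correlation-based sequence descriptors
#'
#' @description
#' Thirteen correlation-based descriptor families (1,100 named values in
#' total) that summarise how 12 standardized physicochemical properties
#' (see [load_property_table()]) covary along a sequence over short lags:
#'
#' * `auto_correlation()` — per-property lagged statistics of the property
#'   profile, under four schemes: plain autocovariance (`AC`; family `TAC`
#'   on trinucleotides), Moran (`MORAN`; `MAC`), Geary (`GEARY`; `GAC`)
#'   and normalized Moreau-Broto (`NMB`; `NMBAC`), each 12 x 2 = 24 values;
#' * `cross_correlation()` — lagged cross-covariance for the 12 x 11
#'   ordered property pairs on trinucleotides (`TCC`, 264 values);
#' * `auto_cross_correlation()` — auto + cross terms over all 12 x 12
#'   ordered pairs, on dinucleotides (`DACC`) and trinucleotides (`TACC`),
#'   288 values each;
#' * `pseudo_correlation()` — pseudo k-mer composition in parallel
#'   (Type-I; `PC_PDNC` 17, `PC_PTNC` 65) and serial (Type-II, one
#'   designated property; `SC_PDNC` 17, `SC_PTNC` 65) form.
#'
#' For a profile series X with N = L - k + 1 points, mean X-bar and lag d:
#' `AC = sum((X_i - Xbar)(X_{i+d} - Xbar)) / (N - d)`;
#' `MORAN = AC / s^2` with `s^2 = sum((X_i - Xbar)^2) / N`;
#' `GEARY = [sum((X_i - X_{i+d})^2) / (2(N - d))] / [sum((X_i - Xbar)^2) / (N - 1)]`;
#' `NMB = sum(X_i X_{i+d}) / (N - d)`.
#' Zero-variance (degenerate) profiles give 0 for the centred schemes so
#' homopolymer-rich inputs still featurize. Descriptors are computed on
#' the given strand only.
#'
#' @param seq Residue string over A/C/G/T.
#' @param table An `lnclocr_proptable` for the family's k.
#' @param max_lag Maximum lag (default 2, fixing the printed dimensions).
#' @name correlation
NULL

# profile matrix with the length precondition of correlation encoders
corr_profile <- function(seq, table, max_lag, encoder) {
  n <- nchar(seq) - table$k + 1L
  if (n <= max_lag + 1L) {
    stop("too short: ", encoder, " needs length > ",
         table$k + max_lag, " (got ", nchar(seq), ")", call. = FALSE)
  }
  property_profile(seq, table)
}

auto_corr_matrix <- function(X, scheme, max_lag) {
  n <- nrow(X)
  xbar <- colMeans(X)
  Xc <- sweep(X, 2, xbar)
  css <- colSums(Xc^2)
  out <- matrix(0, ncol(X), max_lag)
  for (d in seq_len(max_lag)) {
    lo <- 1:(n - d)
    hi <- (1 + d):n
    out[, d] <- switch(scheme,
      AC = colSums(Xc[lo, , drop = FALSE] * Xc[hi, , drop = FALSE]) / (n - d),
      MORAN = safe_div(
        colSums(Xc[lo, , drop = FALSE] * Xc[hi, , drop = FALSE]) / (n - d),
        css / n),
      GEARY = safe_div(
        colSums((X[lo, , drop = FALSE] - X[hi, , drop = FALSE])^2) /
          (2 * (n - d)),
        css / (n - 1)),
      NMB = colSums(X[lo, , drop = FALSE] * X[hi, , drop = FALSE]) / (n - d)
    )
  }
  out  # properties x lags
}

#' @rdname correlation
#' @param scheme Autocorrelation scheme: `"AC"`, `"MORAN"`, `"GEARY"` or
#'   `"NMB"`.
#' @param prefix Descriptor name prefix (defaults to the family
#'   abbreviation for the scheme and k).
#' @export
auto_correlation <- function(seq, table = default_property_table(2L),
                             scheme = c("AC", "MORAN", "GEARY", "NMB"),
                             max_lag = 2L, prefix = NULL) {
  scheme <- match.arg(scheme)
  if (is.null(prefix)) {
    prefix <- switch(scheme, AC = if (table$k == 3L) "TAC" else "DAC",
                     MORAN = "MAC", GEARY = "GAC", NMB = "NMBAC")
  }
  X <- corr_profile(seq, table, max_lag, paste0(prefix, " autocorrelation"))
  m <- auto_corr_matrix(X, scheme, max_lag)
  nm <- as.vector(t(outer(seq_len(ncol(X)), seq_len(max_lag),
                          function(c, d) paste0(prefix, "_p", c, "_lag", d))))
  stats::setNames(as.vector(t(m)), nm)
}

# lagged 12 x 12 cross-covariance matrices, one per lag
cross_cov_matrices <- function(X, max_lag) {
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  lapply(seq_len(max_lag), function(d) {
    crossprod(Xc[1:(n - d), , drop = FALSE],
              Xc[(1 + d):n, , drop = FALSE]) / (n - d)
  })
}

#' @rdname correlation
#' @export
cross_correlation <- function(seq, table = default_property_table(3L),
                              max_lag = 2L, prefix = "TCC") {
  X <- corr_profile(seq, table, max_lag, paste0(prefix, " cross-correlation"))
  covs <- cross_cov_matrices(X, max_lag)
  p <- ncol(X)
  out <- numeric(0)
  nm <- character(0)
  for (c1 in seq_len(p)) for (c2 in seq_len(p)) {
    if (c1 == c2) next
    for (d in seq_len(max_lag)) {
      out <- c(out, covs[[d]][c1, c2])
      nm <- c(nm, paste0(prefix, "_p", c1, "_p", c2, "_lag", d))
    }
  }
  stats::setNames(out, nm)
}

#' @rdname correlation
#' @export
auto_cross_correlation <- function(seq, table = default_property_table(2L),
                                   max_lag = 2L,
                                   prefix = if (table$k == 2L) "DACC"
                                            else "TACC") {
  X <- corr_profile(seq, table, max_lag,
                    paste0(prefix, " auto-cross correlation"))
  covs <- cross_cov_matrices(X, max_lag)
  p <- ncol(X)
  out <- numeric(0)
  nm <- character(0)
  for (c1 in seq_len(p)) for (c2 in seq_len(p)) {
    for (d in seq_len(max_lag)) {
      out <- c(out, covs[[d]][c1, c2])
      nm <- c(nm, if (c1 == c2) paste0(prefix, "_p", c1, "_lag", d)
                  else paste0(prefix, "_p", c1, "_p", c2, "_lag", d))
    }
  }
  stats::setNames(out, nm)
}

#' @rdname correlation
#' @param k k-mer size, 2 or 3.
#' @param mode `"PARALLEL"` (Type-I: correlation factors pool all 12
#'   properties) or `"SERIAL"` (Type-II: per-property factors for the
#'   designated properties).
#' @param lambda Number of correlation tiers (default 1).
#' @param weight Weight of the correlation factors (default 0.05).
#' @param n_props Number of designated properties for serial mode
#'   (default 1, property p1).
#' @export
pseudo_correlation <- function(seq, k = 2L, mode = c("PARALLEL", "SERIAL"),
                               lambda = 1L, weight = 0.05, n_props = 1L,
                               table = default_property_table(k)) {
  mode <- match.arg(mode)
  stopifnot(k %in% c(2L, 3L), lambda >= 1L, weight > 0, table$k == k)
  prefix <- paste0(if (mode == "PARALLEL") "PC_" else "SC_",
                   if (k == 2L) "PDNC" else "PTNC")
  if (nchar(seq) < k + lambda + 1L) {
    stop("too short: ", prefix, " (", mode, ", k = ", k,
         ") needs length >= ", k + lambda + 1L, call. = FALSE)
  }
  idx <- kmer_indices(seq_codes(seq), k)
  f <- tabulate(idx, 4L^k) / length(idx)
  if (mode == "PARALLEL") {
    fac <- theta_factors(idx, table, lambda)
    fac_names <- paste0(prefix, "_theta", seq_len(lambda))
  } else {
    vals <- table$values[idx, seq_len(n_props), drop = FALSE]
    n <- nrow(vals)
    fac <- numeric(0)
    fac_names <- character(0)
    for (j in seq_len(lambda)) {
      tau <- colSums(vals[1:(n - j), , drop = FALSE] *
                       vals[(1 + j):n, , drop = FALSE]) / (n - j)
      fac <- c(fac, tau)
      fac_names <- c(fac_names,
                     paste0(prefix, "_tau", (j - 1L) * n_props +
                              seq_len(n_props)))
    }
  }
  denom <- sum(f) + weight * sum(fac)
  stats::setNames(c(f, weight * fac) / denom,
                  c(paste0(prefix, "_", all_kmers(k)), fac_names))
}

#' Full correlation descriptor vector (1,100 values)
#'
#' Fixed-order concatenation of the 13 correlation families:
#' TCC (264) + DACC (288) + TACC (288) + TAC (24) + NMBAC (24) + MAC (24)
#' + GAC (24) + SC_PTNC (65) + SC_PDNC (17) + PC_PTNC (65) + PC_PDNC (17)
#' = 1,100. Together with [composition_features()] the full descriptor
#' bank has 1,223 values.
#'
#' @param seq Residue string over A/C/G/T.
#' @param tables List with `lnclocr_proptable` entries `k2` and `k3`.
#' @return Named numeric vector of length 1,100.
#' @export
correlation_features <- function(seq,
                                 tables = list(k2 = default_property_table(2L),
                                               k3 = default_property_table(3L))) {
  c(cross_correlation(seq, tables$k3),
    auto_cross_correlation(seq, tables$k2),
    auto_cross_correlation(seq, tables$k3),
    auto_correlation(seq, tables$k3, "AC", prefix = "TAC"),
    auto_correlation(seq, tables$k2, "NMB", prefix = "NMBAC"),
    auto_correlation(seq, tables$k2, "MORAN", prefix = "MAC"),
    auto_correlation(seq, tables$k2, "GEARY", prefix = "GAC"),
    pseudo_correlation(seq, k = 3L, mode = "SERIAL", table = tables$k3),
    pseudo_correlation(seq, k = 2L, mode = "SERIAL", table = tables$k2),
    pseudo_correlation(seq, k = 3L, mode = "PARALLEL", table = tables$k3),
    pseudo_correlation(seq, k = 2L, mode = "PARALLEL", table = tables$k2))
}
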