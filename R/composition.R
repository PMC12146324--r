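#' Composition-based sequence descriptors
#'
#' @description
#' Nine composition-based descriptor families summarising the nucleotide
#' content and arrangement of a sequence, 123 named values in total:
#'
#' * `dinucleotide_composition()` — frequencies of the 16 dinucleotides
#'   (prefix `DNC_`, dim 16);
#' * `rc_kmer_composition()` — dinucleotide frequencies pooled over
#'   reverse-complement equivalence classes (prefix `RCK_`, dim 10);
#' * `nucleotide_repeat_index()` — longest homopolymer run per base,
#'   normalized by length (prefix `NRI_`, dim 4);
#' * `entropy_features()` — Shannon entropy of the mononucleotide
#'   distribution plus its four per-base terms (prefix `ENT_`, dim 1 + 4);
#' * `distance_distribution()` — mean gap between consecutive occurrences
#'   of each base, normalized by length (prefix `DDN_`, dim 4);
#' * `pseudo_composition()` — Type-I (parallel-correlation) pseudo k-mer
#'   composition for k = 2 (prefix `PDNC_`, dim 19) and k = 3 (prefix
#'   `PKNC_`, dim 65).
#'
#' Each function returns a named numeric vector; [composition_features()]
#' concatenates all families in fixed order (16 + 10 + 4 + 1 + 4 + 4 +
#' 19 + 65 = 123).
#'
#' @param seq Residue string over A/C/G/T (see [normalize_sequence()]).
#' @name composition
NULL

check_len <- function(seq, min_len, encoder) {
  if (nchar(seq) < min_len) {
    stop("too short: ", encoder, " needs length >= ", min_len,
         " (got ", nchar(seq), ")", call. = FALSE)
  }
}

#' @rdname composition
#' @export
dinucleotide_composition <- function(seq) {
  check_len(seq, 2L, "dinucleotide composition")
  idx <- kmer_indices(seq_codes(seq), 2L)
  stats::setNames(tabulate(idx, 16L) / length(idx),
                  paste0("DNC_", all_kmers(2L)))
}

# reverse-complement equivalence classes of the 16 dinucleotides,
# keyed by lexicographically smallest member
RC_CLASSES <- list(
  AA = c("AA", "TT"), AC = c("AC", "GT"), AG = c("AG", "CT"), AT = "AT",
  CA = c("CA", "TG"), CC = c("CC", "GG"), CG = "CG", GA = c("GA", "TC"),
  GC = "GC", TA = "TA"
)

#' @rdname composition
#' @export
rc_kmer_composition <- function(seq) {
  check_len(seq, 2L, "reverse-complement k-mer composition")
  dnc <- dinucleotide_composition(seq)
  names(dnc) <- sub("^DNC_", "", names(dnc))
  vapply(RC_CLASSES, function(members) sum(dnc[members]), numeric(1)) |>
    stats::setNames(paste0("RCK_", names(RC_CLASSES)))
}

#' @rdname composition
#' @export
nucleotide_repeat_index <- function(seq) {
  check_len(seq, 1L, "nucleotide repeat index")
  runs <- rle(strsplit(seq, "", fixed = TRUE)[[1]])
  out <- stats::setNames(numeric(4), BASES)
  for (b in BASES) {
    hit <- runs$values == b
    if (any(hit)) out[b] <- max(runs$lengths[hit])
  }
  stats::setNames(out / nchar(seq), paste0("NRI_", BASES))
}

#' @rdname composition
#' @export
entropy_features <- function(seq) {
  check_len(seq, 1L, "entropy")
  codes <- seq_codes(seq)
  p <- tabulate(codes + 1L, 4L) / length(codes)
  terms <- ifelse(p > 0, -p * log2(p), 0)
  stats::setNames(c(sum(terms), terms),
                  c("ENT_seq", paste0("ENT_", BASES)))
}

#' @rdname composition
#' @export
distance_distribution <- function(seq) {
  check_len(seq, 1L, "distance distribution")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  out <- vapply(BASES, function(b) {
    pos <- which(chars == b)
    if (length(pos) < 2) 0 else mean(diff(pos)) / nchar(seq)
  }, numeric(1))
  stats::setNames(out, paste0("DDN_", BASES))
}

# Type-I sequence-order correlation factors theta_1..theta_lambda:
# theta_j = mean over positions of the mean squared difference of the
# standardized property values of k-mers j apart
theta_factors <- function(idx, table, lambda) {
  vals <- table$values[idx, , drop = FALSE]
  n <- nrow(vals)
  vapply(seq_len(lambda), function(j) {
    d <- vals[1:(n - j), , drop = FALSE] - vals[(1 + j):n, , drop = FALSE]
    mean(rowMeans(d^2))
  }, numeric(1))
}

#' @rdname composition
#' @param k k-mer size, 2 or 3.
#' @param lambda Number of sequence-order correlation factors (defaults:
#'   3 for k = 2, 1 for k = 3, fixing the family dimensions at 19 and 65).
#' @param weight Weight of the correlation factors (default 0.05).
#' @param table Property table for the chosen k (see
#'   [load_property_table()]).
#' @export
pseudo_composition <- function(seq, k = 2L, lambda = if (k == 2L) 3L else 1L,
                               weight = 0.05,
                               table = default_property_table(k)) {
  stopifnot(k %in% c(2L, 3L), lambda >= 1L, weight > 0, table$k == k)
  prefix <- if (k == 2L) "PDNC" else "PKNC"
  check_len(seq, k + lambda + 1L, paste0("pseudo composition (", prefix, ")"))
  idx <- kmer_indices(seq_codes(seq), k)
  f <- tabulate(idx, 4L^k) / length(idx)
  theta <- theta_factors(idx, table, lambda)
  denom <- sum(f) + weight * sum(theta)
  stats::setNames(c(f, weight * theta) / denom,
                  c(paste0(prefix, "_", all_kmers(k)),
                    paste0(prefix, "_theta", seq_len(lambda))))
}

#' Full composition descriptor vector (123 values)
#'
#' Fixed-order concatenation of all composition families; every valid
#' sequence yields exactly 123 named, finite values regardless of length.
#'
#' @inheritParams composition
#' @return Named numeric vector of length 123.
#' @export
composition_features <- function(seq) {
  c(dinucleotide_composition(seq),
    rc_kmer_composition(seq),
    nucleotide_repeat_index(seq),
    entropy_features(seq),
    distance_distribution(seq),
    pseudo_composition(seq, k = 2L),
    pseudo_composition(seq, k = 3L))
}
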