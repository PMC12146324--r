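#' Load a standardized k-mer physicochemical property table
#'
#' Correlation-based descriptors are driven by a table of 12 numbered
#' physicochemical properties (`p1`..`p12`) for every k-mer (k = 2 or 3).
#' The bundled dinucleotide table is a standard helical/thermodynamic
#' compilation (base-step geometry: twist, tilt, roll, shift, slide, rise;
#' nearest-neighbour enthalpy, entropy and free energy; melting
#' temperature; stacking energy; hydrophilicity); see
#' `system.file("extdata", "dinucleotide_property_names.tsv", package =
#' "lnclocr")` for the p-index mapping. The bundled trinucleotide table is
#' derived: each trinucleotide property is the mean of its two constituent
#' dinucleotide steps. Users can substitute their own tables via `path`
#' (delimited text, one row per k-mer, columns `kmer`, `p1`..`p12`).
#'
#' All properties are standardized per column to mean 0, sd 1 over the
#' 4^k k-mers, so descriptors are invariant to affine rescaling of the raw
#' property values.
#'
#' @param k k-mer size, 2 or 3.
#' @param path Optional path to a replacement property table.
#' @return An object of class `lnclocr_proptable`: a list with elements
#'   `k`, `properties` (p1..p12), `values` (standardized 4^k x 12 matrix,
#'   rownames = k-mers) and `raw`.
#' @export
load_property_table <- function(k = 2L, path = NULL) {
  stopifnot(k %in% c(2L, 3L))
  if (is.null(path)) {
    din_path <- system.file("extdata", "dinucleotide_properties.tsv",
                            package = "lnclocr", mustWork = TRUE)
    din <- utils::read.delim(din_path, stringsAsFactors = FALSE)
    raw <- as.matrix(din[, paste0("p", 1:12)])
    rownames(raw) <- din$kmer
    if (k == 3L) {
      tri <- all_kmers(3L)
      first <- substr(tri, 1, 2)
      second <- substr(tri, 2, 3)
      raw <- (raw[first, , drop = FALSE] + raw[second, , drop = FALSE]) / 2
      rownames(raw) <- tri
    }
  } else {
    tbl <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!"kmer" %in% names(tbl)) stop("property table needs a kmer column")
    props <- grep("^p[0-9]+$", names(tbl), value = TRUE)
    raw <- as.matrix(tbl[, props])
    rownames(raw) <- tbl$kmer
  }
  kmers <- all_kmers(k)
  if (!all(kmers %in% rownames(raw))) {
    stop("property table for k = ", k, " must cover all ", 4^k, " k-mers",
         call. = FALSE)
  }
  raw <- raw[kmers, , drop = FALSE]
  std <- scale(raw)
  attr(std, "scaled:center") <- NULL
  attr(std, "scaled:scale") <- NULL
  structure(list(k = k, properties = colnames(raw), values = std, raw = raw),
            class = "lnclocr_proptable")
}

# cache default tables for the life of the session
prop_cache <- new.env(parent = emptyenv())

default_property_table <- function(k) {
  key <- paste0("k", k)
  if (is.null(prop_cache[[key]])) {
    prop_cache[[key]] <- load_property_table(k)
  }
  prop_cache[[key]]
}

#' Standardized property profile of a sequence
#'
#' The shared kernel of all correlation descriptors: the series of
#' standardized property values at each of the L - k + 1 overlapping
#' k-mer positions of a sequence.
#'
#' @param seq Residue string over A/C/G/T.
#' @param table An `lnclocr_proptable` (default: bundled table for its k).
#' @param property Property index 1..12, or `NULL` for the full
#'   (L - k + 1) x 12 matrix.
#' @return Numeric vector (one property) or matrix (all properties).
#' @export
property_profile <- function(seq, table = default_property_table(2L),
                             property = NULL) {
  k <- table$k
  if (nchar(seq) < k) {
    stop("too short: property profile needs length >= ", k, call. = FALSE)
  }
  idx <- kmer_indices(seq_codes(seq), k)
  m <- table$values[idx, , drop = FALSE]
  rownames(m) <- NULL
  if (is.null(property)) m else m[, property]
}
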