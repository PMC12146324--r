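FAMILY_REGISTRY <- list(
  DNC = function(seq, tables) dinucleotide_composition(seq),
  RCK = function(seq, tables) rc_kmer_composition(seq),
  NRI = function(seq, tables) nucleotide_repeat_index(seq),
  ENT = function(seq, tables) entropy_features(seq),
  DDN = function(seq, tables) distance_distribution(seq),
  PDNC = function(seq, tables) pseudo_composition(seq, 2L, table = tables$k2),
  PKNC = function(seq, tables) pseudo_composition(seq, 3L, table = tables$k3),
  TCC = function(seq, tables) cross_correlation(seq, tables$k3),
  DACC = function(seq, tables) auto_cross_correlation(seq, tables$k2),
  TACC = function(seq, tables) auto_cross_correlation(seq, tables$k3),
  TAC = function(seq, tables) auto_correlation(seq, tables$k3, "AC",
                                               prefix = "TAC"),
  NMBAC = function(seq, tables) auto_correlation(seq, tables$k2, "NMB",
                                                 prefix = "NMBAC"),
  MAC = function(seq, tables) auto_correlation(seq, tables$k2, "MORAN",
                                               prefix = "MAC"),
  GAC = function(seq, tables) auto_correlation(seq, tables$k2, "GEARY",
                                               prefix = "GAC"),
  SC_PTNC = function(seq, tables) pseudo_correlation(seq, 3L, "SERIAL",
                                                     table = tables$k3),
  SC_PDNC = function(seq, tables) pseudo_correlation(seq, 2L, "SERIAL",
                                                     table = tables$k2),
  PC_PTNC = function(seq, tables) pseudo_correlation(seq, 3L, "PARALLEL",
                                                     table = tables$k3),
  PC_PDNC = function(seq, tables) pseudo_correlation(seq, 2L, "PARALLEL",
                                                     table = tables$k2)
)

COMPOSITION_FAMILIES <- c("DNC", "RCK", "NRI", "ENT", "DDN", "PDNC", "PKNC")
CORRELATION_FAMILIES <- c("TCC", "DACC", "TACC", "TAC", "NMBAC", "MAC",
                          "GAC", "SC_PTNC", "SC_PDNC", "PC_PTNC", "PC_PDNC")

resolve_families <- function(families) {
  out <- unlist(lapply(families, function(f) {
    switch(f,
           composition = COMPOSITION_FAMILIES,
           correlation = CORRELATION_FAMILIES,
           all = c(COMPOSITION_FAMILIES, CORRELATION_FAMILIES),
           f)
  }))
  unknown <- setdiff(out, names(FAMILY_REGISTRY))
  if (length(unknown)) {
    stop("unknown feature family: ", paste(unknown, collapse = ", "),
         "; see list_feature_families()", call. = FALSE)
  }
  unique(out)
}

#' List available descriptor families
#'
#' @return A tibble with the family code, group and dimension of each
#'   descriptor family.
#' @export
list_feature_families <- function() {
  tibble::tibble(
    family = c(COMPOSITION_FAMILIES, CORRELATION_FAMILIES),
    group = rep(c("composition", "correlation"),
                c(length(COMPOSITION_FAMILIES), length(CORRELATION_FAMILIES))),
    dim = c(16L, 10L, 4L, 5L, 4L, 19L, 65L,
            264L, 288L, 288L, 24L, 24L, 24L, 24L, 65L, 17L, 65L, 17L)
  )
}

#' Compute a named feature matrix for a sequence set
#'
#' Runs the selected descriptor families over every sequence and returns
#' one row per sequence with stable, namespaced descriptor columns.
#' `families` may mix the groups `"composition"` (123 descriptors),
#' `"correlation"` (1,100) and `"all"` (1,223) with individual family
#' codes (see [list_feature_families()]).
#'
#' @param seqs Sequence tibble with columns `id` and `seq` (as from
#'   [read_fasta()]), or a character vector of sequences.
#' @param families Character vector of family codes or groups.
#' @param tables List of property tables (`k2`, `k3`); defaults to the
#'   bundled tables.
#' @return A tibble: `id` column followed by one numeric column per
#'   descriptor, in fixed documented order.
#' @export
featurize <- function(seqs, families = "all",
                      tables = list(k2 = default_property_table(2L),
                                    k3 = default_property_table(3L))) {
  if (is.character(seqs)) {
    seqs <- tibble::tibble(id = paste0("seq", seq_along(seqs)), seq = seqs)
  }
  stopifnot(all(c("id", "seq") %in% names(seqs)))
  fams <- resolve_families(families)
  rows <- lapply(seq_len(nrow(seqs)), function(i) {
    vec <- tryCatch(
      unlist(lapply(fams, function(f)
        FAMILY_REGISTRY[[f]](seqs$seq[i], tables))),
      error = function(e) {
        stop("featurize failed for sequence '", seqs$id[i], "': ",
             conditionMessage(e), call. = FALSE)
      })
    vec
  })
  mat <- do.call(rbind, rows)
  dplyr::bind_cols(tibble::tibble(id = seqs$id),
                   tibble::as_tibble(mat))
}
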