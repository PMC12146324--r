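#' Normalize a raw nucleotide string
#'
#' Uppercases the input and maps RNA uracil (`U`) to `T`, yielding a DNA
#' alphabet string. Characters outside `A/C/G/T/U` are either rejected
#' (`policy = "strict"`, the default) or silently removed
#' (`policy = "drop-ambiguous"`).
#'
#' @param raw Character scalar, the raw residue string.
#' @param policy Ambiguity policy, `"strict"` or `"drop-ambiguous"`.
#' @return A character scalar over the `A/C/G/T` alphabet.
#' @examples
#' normalize_sequence("acgu")            # "ACGT"
#' normalize_sequence("ACGN", "drop-ambiguous")  # "ACG"
#' @export
normalize_sequence <- function(raw, policy = c("strict", "drop-ambiguous")) {
  policy <- match.arg(policy)
  stopifnot(is.character(raw), length(raw) == 1L, nzchar(raw))
  up <- chartr("u", "U", toupper(raw))
  up <- gsub("U", "T", up, fixed = TRUE)
  bad <- regmatches(up, gregexpr("[^ACGT]", up))[[1]]
  if (length(bad) > 0) {
    if (policy == "strict") {
      stop("invalid alphabet: sequence contains non-ACGTU character(s): ",
           paste(unique(bad), collapse = ", "), call. = FALSE)
    }
    up <- gsub("[^ACGT]", "", up)
  }
  up
}

#' Read lncRNA sequences from a FASTA file
#'
#' Parses a (multi-line) FASTA file, takes the first whitespace-delimited
#' header token as the sequence id, and normalizes every record with
#' [normalize_sequence()] (so RNA input is mapped U to T). Record order is
#' preserved; duplicate ids are an error.
#'
#' @param path Path to a FASTA file.
#' @inheritParams normalize_sequence
#' @return A tibble with columns `id`, `seq` and `length` (nt).
#' @export
read_fasta <- function(path, policy = c("strict", "drop-ambiguous")) {
  policy <- match.arg(policy)
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0) {
    stop("empty dataset: no FASTA records in ", path, call. = FALSE)
  }
  if (!startsWith(trimws(lines[nonempty[1]]), ">")) {
    stop("malformed FASTA at line ", nonempty[1],
         ": expected a '>' header before sequence data", call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    stop("empty dataset: no FASTA records in ", path, call. = FALSE)
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  residues <- vapply(as.character(set), normalize_sequence, character(1),
                     policy = policy, USE.NAMES = FALSE)
  tibble::tibble(id = ids, seq = residues, length = nchar(residues))
}

#' Write sequences to a FASTA file
#'
#' @param seqs A tibble with columns `id` and `seq` (as from [read_fasta()]).
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::DNAStringSet(stats::setNames(seqs$seq, seqs$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Cytoplasmic/nuclear relative concentration index
#'
#' CNRCI is the log2-transformed ratio of cytoplasmic to nuclear expression
#' (FPKM/RPKM) of one gene in one cell line. A positive value means the
#' transcript is relatively enriched in the cytoplasm, a negative value in
#' the nucleus. If either compartment has zero expression the ratio is
#' undefined and a non-finite value is returned; such records are dropped
#' downstream by [assign_labels()].
#'
#' @param cyt_fpkm,nuc_fpkm Non-negative expression values (vectorized).
#' @return Numeric vector of log2 ratios (may contain non-finite values).
#' @examples
#' compute_cnrci(4, 2)  # 1
#' @export
compute_cnrci <- function(cyt_fpkm, nuc_fpkm) {
  stopifnot(is.numeric(cyt_fpkm), is.numeric(nuc_fpkm),
            all(is.finite(cyt_fpkm)), all(is.finite(nuc_fpkm)))
  if (any(cyt_fpkm < 0) || any(nuc_fpkm < 0)) {
    stop("FPKM values must be non-negative", call. = FALSE)
  }
  out <- suppressWarnings(log2(cyt_fpkm / nuc_fpkm))
  out[cyt_fpkm == 0 | nuc_fpkm == 0] <- NaN
  out
}

#' Read a per-gene, per-cell-line CNRCI table
#'
#' Reads delimited text (TSV or CSV, autodetected) with header columns
#' `gene_id`, `cell_line` and either `cnrci` or the pair
#' `cyt_fpkm`/`nuc_fpkm` (from which CNRCI is computed via
#' [compute_cnrci()]).
#'
#' @param path Path to the table.
#' @return A tibble with columns `gene_id`, `cell_line`, `cnrci`.
#' @export
read_cnrci_table <- function(path) {
  stopifnot(file.exists(path))
  tbl <- readr::read_delim(path, delim = NULL, show_col_types = FALSE,
                           progress = FALSE)
  if (!all(c("gene_id", "cell_line") %in% names(tbl))) {
    stop("CNRCI table must have columns gene_id and cell_line", call. = FALSE)
  }
  if (!"cnrci" %in% names(tbl)) {
    if (!all(c("cyt_fpkm", "nuc_fpkm") %in% names(tbl))) {
      stop("CNRCI table needs a cnrci column or cyt_fpkm + nuc_fpkm columns",
           call. = FALSE)
    }
    tbl$cnrci <- compute_cnrci(tbl$cyt_fpkm, tbl$nuc_fpkm)
  }
  dplyr::select(tbl, "gene_id", "cell_line", "cnrci")
}

#' Assign localization labels from CNRCI sign
#'
#' Strictly positive CNRCI is labelled `CYTOPLASM`, strictly negative
#' `NUCLEUS`. Records with CNRCI exactly 0, missing or non-finite carry no
#' localization information and are dropped; the number of drops is
#' reported via the `n_dropped` attribute and a message.
#'
#' @param records A data frame with a `cnrci` column (any other columns,
#'   e.g. `gene_id` and `cell_line`, are carried through).
#' @param quiet Suppress the dropped-record message.
#' @return A tibble of the labelled records with an added `label` column
#'   and attribute `n_dropped`.
#' @export
assign_labels <- function(records, quiet = FALSE) {
  stopifnot("cnrci" %in% names(records))
  keep <- is.finite(records$cnrci) & records$cnrci != 0
  out <- tibble::as_tibble(records[keep, , drop = FALSE])
  out$label <- ifelse(out$cnrci > 0, "CYTOPLASM", "NUCLEUS")
  n_dropped <- sum(!keep)
  if (n_dropped > 0 && !quiet) {
    message(n_dropped, " record(s) dropped (CNRCI zero or non-finite)")
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Filter sequences by maximum length
#'
#' Keeps sequences of at most `max_length` nucleotides (inclusive); very
#' long lncRNAs are excluded because they mislead the downstream models.
#'
#' @param seqs Sequence tibble (`id`, `seq`, `length`).
#' @param max_length Maximum length in nt (default 10,000).
#' @param quiet Suppress the removed-record message.
#' @return The filtered tibble with attribute `n_removed`.
#' @export
filter_by_length <- function(seqs, max_length = 10000L, quiet = FALSE) {
  stopifnot(max_length >= 1)
  keep <- nchar(seqs$seq) <= max_length
  out <- tibble::as_tibble(seqs[keep, , drop = FALSE])
  n_removed <- sum(!keep)
  if (n_removed > 0 && !quiet) {
    message(n_removed, " sequence(s) removed (length > ", max_length, " nt)")
  }
  attr(out, "n_removed") <- n_removed
  out
}

# estimated identity between two sequences: containment of the shorter
# sequence's k-mer set in the longer one's
kmer_identity <- function(kmers_short, kmers_long) {
  if (length(kmers_short) == 0) return(0)
  sum(kmers_short %in% kmers_long) / length(kmers_short)
}

#' Greedy redundancy reduction of a sequence set
#'
#' Removes near-duplicate sequences with a greedy incremental clustering:
#' sequences are visited longest-first (ties broken by id) and each joins
#' the first existing cluster whose representative shares at least
#' `identity_threshold` of its k-mers (containment of the shorter
#' sequence's k-mer set, k = 12), otherwise it founds a new cluster. The
#' cluster founders are returned, in their original input order. The
#' operation is deterministic and idempotent.
#'
#' @param seqs Sequence tibble (`id`, `seq`).
#' @param identity_threshold Identity fraction in (0, 1); default 0.90.
#' @param k Word size for the k-mer identity estimate.
#' @return Tibble of representative sequences (a subset of the input rows),
#'   with attribute `cluster` mapping every input id to its representative.
#' @export
reduce_redundancy <- function(seqs, identity_threshold = 0.90, k = 12L) {
  stopifnot(identity_threshold > 0, identity_threshold < 1)
  n <- nrow(seqs)
  if (n == 0) return(seqs)
  ord <- order(-nchar(seqs$seq), seqs$id)
  km <- lapply(seqs$seq, function(s) {
    L <- nchar(s)
    if (L < k) return(s)
    unique(substring(s, 1:(L - k + 1L), k:L))
  })
  rep_idx <- integer(0)
  member_of <- integer(n)
  for (i in ord) {
    assigned <- FALSE
    for (r in rep_idx) {
      # representative is at least as long, so sequence i is the shorter
      if (kmer_identity(km[[i]], km[[r]]) >= identity_threshold) {
        member_of[i] <- r
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      rep_idx <- c(rep_idx, i)
      member_of[i] <- i
    }
  }
  keep <- sort(rep_idx)
  out <- tibble::as_tibble(seqs[keep, , drop = FALSE])
  attr(out, "cluster") <- stats::setNames(seqs$id[member_of], seqs$id)
  out
}

#' Stratified train/validation split
#'
#' Splits a labelled dataset into training and validation sets preserving
#' class proportions. The total validation size is
#' `ceiling(test_fraction * N)`; per-class validation counts follow
#' proportional allocation with largest-remainder rounding (remainder ties
#' broken by larger class, then class name). Membership is randomized by
#' `seed`; the sizes are seed-independent.
#'
#' @param dataset A data frame with columns `id` and `label`.
#' @param test_fraction Fraction held out for validation (default 0.2).
#' @param seed Integer seed controlling membership.
#' @return A list with character vectors `train` and `validation` of ids.
#' @export
stratified_split <- function(dataset, test_fraction = 0.2, seed = 42L) {
  stopifnot(all(c("id", "label") %in% names(dataset)),
            test_fraction > 0, test_fraction < 1)
  tab <- table(dataset$label)
  if (any(tab < 2)) {
    stop("stratification error: class(es) with fewer than 2 members: ",
         paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)
  }
  n <- nrow(dataset)
  n_val <- as.integer(ceiling(test_fraction * n))
  quota <- n_val * as.numeric(tab) / n
  base <- floor(quota)
  rem <- quota - base
  left <- n_val - sum(base)
  if (left > 0) {
    pick <- order(-rem, -as.numeric(tab), names(tab))[seq_len(left)]
    base[pick] <- base[pick] + 1
  }
  counts <- stats::setNames(as.integer(base), names(tab))
  val_ids <- with_seed(seed, {
    unlist(lapply(names(tab), function(cl) {
      ids <- dataset$id[dataset$label == cl]
      sample(ids, counts[[cl]])
    }), use.names = FALSE)
  })
  list(train = setdiff(dataset$id, val_ids), validation = val_ids)
}

#' Build per-cell-line labelled datasets
#'
#' End-to-end dataset construction: joins sequences with a CNRCI table,
#' labels by CNRCI sign, filters by length, removes redundancy (within
#' each cell line) and splits into train/validation.
#'
#' @param seqs Sequence tibble from [read_fasta()].
#' @param cnrci CNRCI tibble from [read_cnrci_table()] (columns `gene_id`,
#'   `cell_line`, `cnrci`).
#' @param cell_lines Optional character vector restricting the cell lines.
#' @param max_length Length filter threshold (nt).
#' @param identity_threshold Redundancy threshold.
#' @param test_fraction Validation fraction.
#' @param seed Split seed.
#' @return A dataset manifest tibble with columns `id`, `cell_line`,
#'   `length`, `cnrci`, `label`, `split`.
#' @export
build_cell_line_datasets <- function(seqs, cnrci, cell_lines = NULL,
                                     max_length = 10000L,
                                     identity_threshold = 0.90,
                                     test_fraction = 0.2, seed = 42L) {
  labelled <- assign_labels(cnrci, quiet = TRUE)
  if (!is.null(cell_lines)) {
    labelled <- labelled[labelled$cell_line %in% cell_lines, , drop = FALSE]
  }
  kept <- filter_by_length(seqs, max_length, quiet = TRUE)
  out <- lapply(split(labelled, labelled$cell_line), function(recs) {
    sub <- kept[kept$id %in% recs$gene_id, , drop = FALSE]
    if (nrow(sub) == 0) return(NULL)
    sub <- reduce_redundancy(sub, identity_threshold)
    recs <- recs[match(sub$id, recs$gene_id), , drop = FALSE]
    ds <- tibble::tibble(id = sub$id, cell_line = recs$cell_line[1],
                         length = sub$length, cnrci = recs$cnrci,
                         label = recs$label)
    sp <- stratified_split(ds, test_fraction, seed)
    ds$split <- ifelse(ds$id %in% sp$validation, "VALIDATION", "TRAIN")
    ds
  })
  dplyr::bind_rows(out)
}
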