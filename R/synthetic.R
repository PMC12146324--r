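#' Configuration for the synthetic lncRNA benchmark generator
#'
#' The generator emulates the inputs of the localization pipeline: a set
#' of transcript sequences plus a per-gene, per-cell-line CNRCI table,
#' with a planted, composition-borne localization signal. Sequences are
#' drawn from a class-tilted first-order (dinucleotide) Markov model:
#' the cytoplasm class is C/G-enriched with an extra boost of the CG
#' step, the nucleus class T-enriched with a boost of the TG step — so
#' both composition and correlation descriptor families carry class
#' signal. CNRCI is the planted effect `beta` times the standardized
#' CG-minus-TG dinucleotide frequency contrast plus Gaussian noise, with
#' the sign forced consistent with the latent class whenever the value
#' clears the noise scale.
#'
#' @param n_sequences Number of sequences (>= 20).
#' @param length_range Min/max sequence length in nt, within
#'   200-10,000.
#' @param effect_size Planted effect beta (>= 0); 0 gives a null dataset.
#' @param noise_sd CNRCI noise sd sigma (> 0), log2 units.
#' @param cg_bias,t_bias Mononucleotide probability tilts of the two
#'   classes (the per-class transition boosts scale with them).
#' @param p_cytoplasm Latent cytoplasm-class proportion (default 0.4,
#'   mirroring the nucleus-majority class balance of real per-cell-line
#'   datasets).
#' @param n_cell_lines Number of emitted cell-line tables.
#' @param flip_fraction Fraction of genes whose CNRCI sign flips in each
#'   additional cell line (emulating cross-cell-line variability).
#' @param seed Integer seed.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_sequences = 1000L,
                             length_range = c(200L, 2000L),
                             effect_size = 3, noise_sd = 0.5,
                             cg_bias = 0.15, t_bias = 0.15,
                             p_cytoplasm = 0.4, n_cell_lines = 2L,
                             flip_fraction = 0.1, seed = 42L) {
  stopifnot(n_sequences >= 20, length(length_range) == 2,
            length_range[1] >= 200, length_range[2] <= 10000,
            length_range[1] <= length_range[2],
            effect_size >= 0, noise_sd > 0,
            n_cell_lines >= 1, flip_fraction >= 0, flip_fraction <= 1,
            p_cytoplasm > 0, p_cytoplasm < 1)
  if (cg_bias < 0 || cg_bias > 0.25 || t_bias < 0 || t_bias > 0.25) {
    stop("invalid probability tilt: cg_bias and t_bias must lie in ",
         "[0, 0.25] so the tilted mononucleotide distribution stays valid",
         call. = FALSE)
  }
  structure(list(n_sequences = as.integer(n_sequences),
                 length_range = as.integer(length_range),
                 effect_size = effect_size, noise_sd = noise_sd,
                 cg_bias = cg_bias, t_bias = t_bias,
                 p_cytoplasm = p_cytoplasm,
                 n_cell_lines = as.integer(n_cell_lines),
                 flip_fraction = flip_fraction, seed = as.integer(seed)),
            class = "synthetic_config")
}

# class-specific transition matrix: tilted stationary distribution plus a
# multiplicative boost of one dinucleotide step
class_transition <- function(class, cg_bias, t_bias) {
  if (class == "CYTOPLASM") {
    p <- c(A = 0.25 - cg_bias / 2, C = 0.25 + cg_bias / 2,
           G = 0.25 + cg_bias / 2, T = 0.25 - cg_bias / 2)
    boost <- c(from = "C", to = "G")
    mult <- 1 + 4 * cg_bias
  } else {
    p <- c(A = 0.25 - t_bias / 3, C = 0.25 - t_bias / 3,
           G = 0.25 - t_bias / 3, T = 0.25 + t_bias)
    boost <- c(from = "T", to = "G")
    mult <- 1 + 4 * t_bias
  }
  tm <- matrix(rep(p, each = 4), 4, 4, dimnames = list(BASES, BASES))
  tm[boost["from"], boost["to"]] <- tm[boost["from"], boost["to"]] * mult
  tm / rowSums(tm)
}

sample_markov_seq <- function(len, p0, tm_cum) {
  u <- stats::runif(len)
  out <- integer(len)
  out[1] <- findInterval(u[1], p0) + 1L
  for (i in 2:len) {
    out[i] <- findInterval(u[i], tm_cum[out[i - 1L], ]) + 1L
  }
  paste(BASES[out], collapse = "")
}

dinu_freq <- function(seq, dinu) {
  idx <- kmer_indices(seq_codes(seq), 2L)
  sum(idx == match(dinu, all_kmers(2L))) / length(idx)
}

#' Simulate a labelled sequence dataset with planted localization signal
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `sequences` (tibble `id`, `seq`,
#'   `length`), `cnrci` (tibble `gene_id`, `cell_line`, `cnrci`, one row
#'   per gene x cell line) and `truth` (tibble `gene_id`, `class`,
#'   `f_cg`, `f_tg`). Identical configs (including seed) give identical
#'   output.
#' @export
simulate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    n <- config$n_sequences
    classes <- ifelse(stats::runif(n) < config$p_cytoplasm,
                      "CYTOPLASM", "NUCLEUS")
    lens <- sample(config$length_range[1]:config$length_range[2], n,
                   replace = TRUE)
    tms <- lapply(c(CYTOPLASM = "CYTOPLASM", NUCLEUS = "NUCLEUS"),
                  function(cl) {
                    tm <- class_transition(cl, config$cg_bias, config$t_bias)
                    list(p0 = cumsum(colMeans(tm))[1:3],
                         cum = t(apply(tm, 1, cumsum))[, 1:3, drop = FALSE])
                  })
    seqs <- vapply(seq_len(n), function(i) {
      m <- tms[[classes[i]]]
      sample_markov_seq(lens[i], m$p0, m$cum)
    }, character(1))
    ids <- sprintf("lnc%05d", seq_len(n))
    f_cg <- vapply(seqs, dinu_freq, numeric(1), dinu = "CG",
                   USE.NAMES = FALSE)
    f_tg <- vapply(seqs, dinu_freq, numeric(1), dinu = "TG",
                   USE.NAMES = FALSE)
    contrast <- f_cg - f_tg
    z <- as.vector(scale(contrast))
    cnrci <- config$effect_size * z + stats::rnorm(n, 0, config$noise_sd)
    # force sign-class consistency where the value clears the noise scale
    clear <- abs(cnrci) > config$noise_sd
    want <- ifelse(classes == "CYTOPLASM", 1, -1)
    cnrci[clear] <- abs(cnrci[clear]) * want[clear]
    cell_lines <- sprintf("SIM.CL%02d", seq_len(config$n_cell_lines))
    tables <- lapply(seq_along(cell_lines), function(j) {
      v <- cnrci
      if (j > 1 && config$flip_fraction > 0) {
        flip <- sample(n, round(config$flip_fraction * n))
        v[flip] <- -v[flip]
      }
      tibble::tibble(gene_id = ids, cell_line = cell_lines[j], cnrci = v)
    })
    list(sequences = tibble::tibble(id = ids, seq = seqs,
                                    length = nchar(seqs)),
         cnrci = dplyr::bind_rows(tables),
         truth = tibble::tibble(gene_id = ids, class = classes,
                                f_cg = f_cg, f_tg = f_tg))
  })
}

#' Write the canonical test fixture suite
#'
#' Writes the small plain-text fixtures used throughout the test suite:
#' a 3-sequence FASTA with hand-checkable descriptor values, a
#' 2-cell-line CNRCI table with boundary cases (zero, negative, missing),
#' a FASTA of mutated sequence families for redundancy reduction, and a
#' 1,000-sequence training fixture (FASTA + CNRCI table) generated with
#' the default config.
#'
#' @param out_dir Writable output directory (created if needed).
#' @param seed Seed for the training fixture.
#' @return Named character vector of the written paths, invisibly.
#' @export
make_fixture_suite <- function(out_dir, seed = 42L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    three = file.path(out_dir, "three_sequences.fasta"),
    cnrci = file.path(out_dir, "cnrci_boundary.tsv"),
    families = file.path(out_dir, "redundancy_families.fasta"),
    train_fa = file.path(out_dir, "training_1000.fasta"),
    train_cnrci = file.path(out_dir, "training_1000_cnrci.tsv"))
  writeLines(c(">s1 hand-checkable", "ACGT",
               ">s2", "AAAA",
               ">s3", "ACGTACGTACGTACGT"), paths["three"])
  readr::write_tsv(tibble::tibble(
    gene_id = c("s1", "s2", "s3", "s1", "s2", "s3"),
    cell_line = rep(c("CL1", "CL2"), each = 3),
    cnrci = c(1.5, -0.3, 0, -2.0, NA, 0.7)), paths["cnrci"])
  # one exact founder plus three single-point mutants per family: any two
  # members then share >= 1 - 24/389 ~ 0.94 of their 12-mers, safely above
  # the 0.90 clustering threshold, while unrelated 400-mers share none
  fam <- with_seed(seed, {
    founders <- replicate(5, paste(sample(BASES, 400, replace = TRUE),
                                   collapse = ""))
    recs <- lapply(seq_along(founders), function(f) {
      vapply(1:4, function(m) {
        if (m == 1) return(founders[f])
        chars <- strsplit(founders[f], "")[[1]]
        pos <- sample(length(chars), 1)
        chars[pos] <- sample(setdiff(BASES, chars[pos]), 1)
        paste(chars, collapse = "")
      }, character(1))
    })
    tibble::tibble(
      id = sprintf("fam%d_m%d", rep(1:5, each = 4), rep(1:4, 5)),
      seq = unlist(recs))
  })
  write_fasta(fam, paths["families"])
  sim <- simulate_dataset(synthetic_config(seed = seed))
  write_fasta(sim$sequences, paths["train_fa"])
  readr::write_tsv(sim$cnrci, paths["train_cnrci"])
  invisible(paths)
}
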