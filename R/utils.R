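BASES <- c("A", "C", "G", "T")

# all k-mers over ACGT in lexicographic order
all_kmers <- function(k) {
  grids <- rep(list(BASES), k)
  do.call(paste0, rev(expand.grid(rev(grids), stringsAsFactors = FALSE)))
}

# encode a residue string as integer codes 0..3 (A,C,G,T)
seq_codes <- function(seq) {
  match(strsplit(seq, "", fixed = TRUE)[[1]], BASES) - 1L
}

# 1-based lexicographic index of each overlapping k-mer
kmer_indices <- function(codes, k) {
  n <- length(codes) - k + 1L
  if (n < 1L) return(integer(0))
  idx <- integer(n)
  for (j in seq_len(k)) {
    idx <- idx * 4L + codes[j:(j + n - 1L)]
  }
  idx + 1L
}

# run expr with a temporary RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

safe_div <- function(num, den) {
  ifelse(den == 0, 0, num / den)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
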