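test_that("sequence normalization maps RNA to DNA and enforces the alphabet", {
  expect_equal(normalize_sequence("acgu"), "ACGT")
  expect_equal(normalize_sequence("AcGuU"), "ACGTT")
  expect_error(normalize_sequence("ACGN"), "invalid alphabet.*N")
  expect_equal(normalize_sequence("ACGN", policy = "drop-ambiguous"), "ACG")
})

test_that("FASTA reading normalizes, preserves order and rejects duplicates", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x some description", "ACGU"), path)
  got <- read_fasta(path)
  expect_equal(got$id, "x")
  expect_equal(got$seq, "ACGT")

  writeLines(c(">a", "AC", ">a", "GT"), path)
  expect_error(read_fasta(path), "duplicate")

  writeLines(character(0), path)
  expect_error(read_fasta(path), "empty")

  writeLines(c("ACGT", ">x", "ACGT"), path)
  expect_error(read_fasta(path), "line 1")
})

test_that("write/read FASTA round-trips 100 random records", {
  withr::with_seed(11, {
    seqs <- tibble::tibble(
      id = paste0("rec", 1:100),
      seq = vapply(1:100, function(i) rand_seq(sample(20:300, 1)),
                   character(1)))
  })
  seqs$length <- nchar(seqs$seq)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, path)
  back <- read_fasta(path)
  expect_identical(back$id, seqs$id)
  expect_identical(back$seq, seqs$seq)
})

test_that("CNRCI is the log2 expression ratio with a zero-exclusion policy", {
  expect_equal(compute_cnrci(4, 2), 1)
  expect_equal(compute_cnrci(1, 1), 0)
  expect_false(is.finite(compute_cnrci(2, 0)))
  expect_false(is.finite(compute_cnrci(0, 2)))
  expect_error(compute_cnrci(-1, 2), "non-negative")
  # vectorized
  expect_equal(compute_cnrci(c(4, 8), c(2, 2)), c(1, 2))
})

test_that("labels follow the strict CNRCI sign rule and drops are counted", {
  recs <- tibble::tibble(gene_id = paste0("g", 1:5),
                         cnrci = c(1.5, -0.3, 0, NA, Inf))
  out <- assign_labels(recs, quiet = TRUE)
  expect_equal(out$label, c("CYTOPLASM", "NUCLEUS"))
  expect_equal(attr(out, "n_dropped"), 3)
  expect_equal(nrow(out) + attr(out, "n_dropped"), nrow(recs))
})

test_that("length filter is inclusive at the boundary and never edits residues", {
  seqs <- tibble::tibble(id = c("a", "b", "c"),
                         seq = strrep("A", c(9999, 10000, 10001)))
  seqs$length <- nchar(seqs$seq)
  kept <- filter_by_length(seqs, quiet = TRUE)
  expect_equal(kept$id, c("a", "b"))
  expect_equal(attr(kept, "n_removed"), 1)

  withr::with_seed(3, {
    rnd <- tibble::tibble(id = paste0("s", 1:50),
                          seq = vapply(sample(50:400, 50, replace = TRUE),
                                       rand_seq, character(1)))
  })
  kept <- filter_by_length(rnd, max_length = 200, quiet = TRUE)
  expect_identical(kept, dplyr::as_tibble(rnd[nchar(rnd$seq) <= 200, ]),
                   ignore_attr = TRUE)
})

test_that("redundancy reduction collapses near-identical sequences", {
  withr::with_seed(5, s <- rand_seq(300))
  two <- tibble::tibble(id = c("a", "b"), seq = c(s, s))
  expect_equal(nrow(reduce_redundancy(two)), 1)

  withr::with_seed(6, {
    unrelated <- tibble::tibble(id = c("a", "b"),
                                seq = c(rand_seq(300), rand_seq(300)))
  })
  expect_equal(nrow(reduce_redundancy(unrelated)), 2)
})

test_that("mutated families cluster to their founders and reduction is idempotent", {
  dir <- withr::local_tempdir()
  paths <- make_fixture_suite(dir)
  fam <- read_fasta(paths[["families"]])
  expect_equal(nrow(fam), 20)
  reps <- reduce_redundancy(fam)
  expect_equal(nrow(reps), 5)
  # every member maps to a representative of its own family
  cluster <- attr(reps, "cluster")
  expect_true(all(sub("_m[0-9]+$", "", names(cluster)) ==
                    sub("_m[0-9]+$", "", cluster)))
  # brute-force pairwise identity confirms the clustering structure
  kmset <- function(s) unique(substring(s, 1:(nchar(s) - 11), 12:nchar(s)))
  ident <- function(a, b) mean(kmset(a) %in% kmset(b))
  same_family <- outer(fam$id, fam$id,
                       Vectorize(function(a, b)
                         sub("_m.*", "", a) == sub("_m.*", "", b)))
  pair_ident <- outer(fam$seq, fam$seq, Vectorize(ident))
  expect_true(all(pair_ident[same_family] >= 0.90))
  expect_true(all(pair_ident[!same_family] < 0.90))
  # idempotence
  expect_identical(reduce_redundancy(reps)$id, reps$id)
})

test_that("stratified split reproduces size arithmetic and is conserved", {
  ds <- tibble::tibble(id = paste0("g", 1:10),
                       label = rep(c("NUCLEUS", "CYTOPLASM"), each = 5))
  sp <- stratified_split(ds, 0.2, seed = 1)
  expect_equal(length(sp$validation), 2)
  lab <- ds$label[match(sp$validation, ds$id)]
  expect_equal(sort(table(lab)), sort(c(NUCLEUS = 1, CYTOPLASM = 1)),
               ignore_attr = TRUE)
  # conservation + determinism
  expect_setequal(c(sp$train, sp$validation), ds$id)
  sp2 <- stratified_split(ds, 0.2, seed = 1)
  expect_identical(sp, sp2)
  sp3 <- stratified_split(ds, 0.2, seed = 2)
  expect_equal(length(sp3$validation), length(sp$validation))
  expect_error(stratified_split(ds[c(1, 6:10), ], 0.2, 1), "stratification")
})

test_that("CNRCI table reader handles both direct and FPKM-pair input", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(gene_id = c("g1", "g2"),
                                  cell_line = "CL1",
                                  cyt_fpkm = c(4, 1), nuc_fpkm = c(2, 0)),
                   path)
  got <- read_cnrci_table(path)
  expect_equal(got$cnrci[1], 1)
  expect_false(is.finite(got$cnrci[2]))

  # csv with explicit cnrci column
  path2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(gene_id = "g1", cell_line = "CL1",
                                  cnrci = -0.3), path2)
  expect_equal(read_cnrci_table(path2)$cnrci, -0.3)
})

test_that("per-cell-line dataset assembly produces a consistent manifest", {
  cfg <- synthetic_config(n_sequences = 60, length_range = c(200, 400),
                          n_cell_lines = 2, seed = 9)
  sim <- simulate_dataset(cfg)
  manifest <- build_cell_line_datasets(sim$sequences, sim$cnrci, seed = 9)
  expect_setequal(unique(manifest$cell_line), c("SIM.CL01", "SIM.CL02"))
  expect_true(all(manifest$split %in% c("TRAIN", "VALIDATION")))
  expect_true(all((manifest$cnrci > 0) == (manifest$label == "CYTOPLASM")))
  for (cl in unique(manifest$cell_line)) {
    m <- manifest[manifest$cell_line == cl, ]
    expect_equal(sum(m$split == "VALIDATION"), ceiling(0.2 * nrow(m)))
  }
})
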