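test_that("property tables are complete and standardized", {
  for (k in c(2L, 3L)) {
    tbl <- load_property_table(k)
    expect_equal(nrow(tbl$values), 4^k)
    expect_equal(ncol(tbl$values), 12)
    expect_true(all(abs(colMeans(tbl$values)) < 1e-9))
    expect_true(all(abs(apply(tbl$values, 2, sd) - 1) < 1e-9))
  }
  # user-supplied replacement table round-trip
  path <- withr::local_tempfile(fileext = ".tsv")
  tbl <- load_property_table(2L)
  out <- data.frame(kmer = rownames(tbl$raw), tbl$raw)
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  again <- load_property_table(2L, path = path)
  expect_equal(again$values, tbl$values)
})

test_that("property profiles are table lookups of the right length", {
  tbl <- load_property_table(2L)
  prof <- property_profile("AAAA", tbl, property = 1)
  expect_length(prof, 3)
  expect_true(all(prof == tbl$values["AA", 1]))
  withr::with_seed(31, s <- rand_seq(100))
  m <- property_profile(s, tbl)
  expect_equal(dim(m), c(99, 12))
  # spot-check positions against direct lookup
  expect_equal(m[1, ], tbl$values[substr(s, 1, 2), ])
  expect_equal(m[50, ], tbl$values[substr(s, 50, 51), ])
  expect_error(property_profile("A", tbl), "too short")
})

test_that("autocorrelation schemes match brute-force loops and degenerate rules", {
  withr::with_seed(32, seqs <- replicate(5, rand_seq(300)))
  for (s in seqs) {
    for (k in c(2L, 3L)) {
      tbl <- load_property_table(k)
      for (scheme in c("AC", "MORAN", "GEARY", "NMB")) {
        expect_equal(unname(auto_correlation(s, tbl, scheme)),
                     oracle_auto(s, k, scheme), tolerance = 1e-12)
      }
    }
  }
  # homopolymer: degenerate variance; NMB is the squared standardized value
  tbl <- load_property_table(2L)
  homo <- strrep("A", 40)
  expect_true(all(auto_correlation(homo, tbl, "MORAN") == 0))
  expect_true(all(auto_correlation(homo, tbl, "GEARY") == 0))
  nmb <- auto_correlation(homo, tbl, "NMB")
  expect_equal(unname(nmb), rep(unname(tbl$values["AA", ])^2, each = 2),
               tolerance = 1e-12)
  mac <- auto_correlation(strrep("ACGT", 60), tbl, "MORAN")
  expect_length(mac, 24)
})

test_that("cross and auto-cross correlations match brute-force loops", {
  withr::with_seed(33, seqs <- replicate(4, rand_seq(sample(100:400, 1))))
  k2 <- load_property_table(2L)
  k3 <- load_property_table(3L)
  for (s in seqs) {
    tcc <- cross_correlation(s, k3)
    expect_length(tcc, 264)
    expect_equal(unname(tcc), oracle_cross(s), tolerance = 1e-12)
    dacc <- auto_cross_correlation(s, k2)
    tacc <- auto_cross_correlation(s, k3)
    expect_length(dacc, 288)
    expect_length(tacc, 288)
    expect_equal(unname(dacc), oracle_acc(s, 2), tolerance = 1e-12)
    expect_equal(unname(tacc), oracle_acc(s, 3), tolerance = 1e-12)
    # the auto terms of the ACC family equal plain autocovariance
    auto_part <- dacc[grep("^DACC_p[0-9]+_lag", names(dacc))]
    expect_equal(unname(auto_part),
                 unname(auto_correlation(s, k2, "AC", prefix = "DAC")),
                 tolerance = 1e-12)
    # ordered property pairs: reversed pair is a different descriptor
    expect_false(isTRUE(all.equal(tcc[["TCC_p1_p2_lag1"]],
                                  tcc[["TCC_p2_p1_lag1"]])))
  }
})

test_that("pseudo correlation modes hit their dimensions and oracles", {
  s <- "ACGTACGTACGTACGT"
  pc2 <- pseudo_correlation(s, 2, "PARALLEL")
  pc3 <- pseudo_correlation(s, 3, "PARALLEL")
  sc2 <- pseudo_correlation(s, 2, "SERIAL")
  sc3 <- pseudo_correlation(s, 3, "SERIAL")
  expect_length(pc2, 17)
  expect_length(pc3, 65)
  expect_length(sc2, 17)
  expect_length(sc3, 65)
  # frequency block sums to (sum f)/(sum f + w sum theta) <= 1
  expect_lte(sum(pc2[1:16]), 1)
  expect_lte(sum(sc3[1:64]), 1)
  expect_equal(unname(pc2), unname(oracle_pseudo(s, 2, 1)), tolerance = 1e-12)
  expect_equal(unname(sc2), unname(oracle_serial(s, 2)), tolerance = 1e-12)
  expect_equal(unname(sc3), unname(oracle_serial(s, 3)), tolerance = 1e-12)
  expect_error(pseudo_correlation("ACG", 2, "SERIAL"), "SC_PDNC")
})

test_that("the 1100-descriptor vector is the fixed-order family concatenation", {
  withr::with_seed(34, s <- rand_seq(500))
  v <- correlation_features(s)
  expect_length(v, 1100)
  expect_true(all(is.finite(v)))
  fams <- sub("_.*", "", sub("^(SC|PC)_", "\\1*", names(v)))
  runs <- rle(fams)
  expect_equal(runs$lengths,
               c(264, 288, 288, 24, 24, 24, 24, 65, 17, 65, 17))
  # combined with composition: the full 1223-descriptor bank
  expect_length(c(composition_features(s), v), 1223)
})

test_that("descriptors are invariant to affine property rescaling", {
  tbl <- load_property_table(2L)
  rescaled <- tbl
  rescaled$raw <- sweep(sweep(tbl$raw, 2, runif(12, 0.5, 3), "*"),
                        2, rnorm(12), "+")
  rescaled$values <- scale(rescaled$raw)
  attr(rescaled$values, "scaled:center") <- NULL
  attr(rescaled$values, "scaled:scale") <- NULL
  withr::with_seed(35, s <- rand_seq(200))
  for (scheme in c("MORAN", "GEARY")) {
    expect_equal(auto_correlation(s, rescaled, scheme),
                 auto_correlation(s, tbl, scheme), tolerance = 1e-10)
  }
})

test_that("no silent strand canonicalization happens", {
  s <- "AACCGGTTACGT"
  rc <- "ACGTAACCGGTT"  # reverse complement
  expect_false(isTRUE(all.equal(correlation_features(s),
                                correlation_features(rc),
                                check.attributes = FALSE)))
})
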