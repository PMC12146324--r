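# Independent brute-force oracles for every descriptor family. These are
# deliberately straight-line implementations of the defining formulas
# (substring scans, explicit per-descriptor sums, their own property
# standardization) sharing no kernels with the package internals.

ORACLE_BASES <- c("A", "C", "G", "T")

oracle_kmers <- function(k) {
  if (k == 1) return(ORACLE_BASES)
  sub <- oracle_kmers(k - 1)
  as.vector(t(outer(ORACLE_BASES, sub, paste0)))
}

rand_seq <- function(len) {
  paste(sample(ORACLE_BASES, len, replace = TRUE), collapse = "")
}

oracle_kmer_count <- function(seq, kmer) {
  k <- nchar(kmer)
  L <- nchar(seq)
  sum(vapply(1:(L - k + 1), function(i) substr(seq, i, i + k - 1) == kmer,
             logical(1)))
}

oracle_dnc <- function(seq) {
  L <- nchar(seq)
  vapply(oracle_kmers(2), function(d) oracle_kmer_count(seq, d) / (L - 1),
         numeric(1))
}

oracle_rck <- function(seq) {
  dnc <- oracle_dnc(seq)
  rc <- function(d) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste0(comp[substr(d, 2, 2)], comp[substr(d, 1, 1)])
  }
  canon <- vapply(names(dnc), function(d) min(d, rc(d)), character(1))
  classes <- sort(unique(canon))
  vapply(classes, function(cl) sum(dnc[canon == cl]), numeric(1))
}

oracle_nri <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  vapply(ORACLE_BASES, function(b) {
    best <- 0; run <- 0
    for (ch in chars) {
      run <- if (ch == b) run + 1 else 0
      best <- max(best, run)
    }
    best / length(chars)
  }, numeric(1))
}

oracle_ddn <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  vapply(ORACLE_BASES, function(b) {
    pos <- which(chars == b)
    if (length(pos) < 2) return(0)
    gaps <- pos[-1] - pos[-length(pos)]
    (sum(gaps) / length(gaps)) / length(chars)
  }, numeric(1))
}

oracle_entropy <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  p <- vapply(ORACLE_BASES, function(b) mean(chars == b), numeric(1))
  terms <- vapply(p, function(x) if (x > 0) -x * log2(x) else 0, numeric(1))
  c(sum(terms), terms)
}

# standardized property value lookup, standardization done here
oracle_std_table <- function(k) {
  tbl <- load_property_table(k)$raw
  apply(tbl, 2, function(x) (x - mean(x)) / sd(x))
}

oracle_profile <- function(seq, k, std) {
  L <- nchar(seq)
  words <- substring(seq, 1:(L - k + 1), k:L)
  std[words, , drop = FALSE]
}

oracle_pseudo <- function(seq, k, lambda, w = 0.05) {
  std <- oracle_std_table(k)
  L <- nchar(seq)
  words <- substring(seq, 1:(L - k + 1), k:L)
  f <- vapply(oracle_kmers(k), function(u) mean(words == u), numeric(1))
  n <- length(words)
  theta <- vapply(seq_len(lambda), function(j) {
    s <- 0
    for (i in 1:(n - j)) {
      s <- s + mean((std[words[i], ] - std[words[i + j], ])^2)
    }
    s / (n - j)
  }, numeric(1))
  c(f, w * theta) / (sum(f) + w * sum(theta))
}

oracle_auto <- function(seq, k, scheme, max_lag = 2) {
  X <- oracle_profile(seq, k, oracle_std_table(k))
  n <- nrow(X)
  out <- c()
  for (p in 1:12) {
    x <- X[, p]
    xb <- mean(x)
    for (d in 1:max_lag) {
      v <- switch(scheme,
        AC = sum((x[1:(n - d)] - xb) * (x[(1 + d):n] - xb)) / (n - d),
        MORAN = {
          s2 <- sum((x - xb)^2) / n
          if (s2 == 0) 0
          else (sum((x[1:(n - d)] - xb) * (x[(1 + d):n] - xb)) / (n - d)) / s2
        },
        GEARY = {
          den <- sum((x - xb)^2) / (n - 1)
          if (den == 0) 0
          else (sum((x[1:(n - d)] - x[(1 + d):n])^2) / (2 * (n - d))) / den
        },
        NMB = sum(x[1:(n - d)] * x[(1 + d):n]) / (n - d))
      out <- c(out, v)
    }
  }
  out
}

oracle_cross <- function(seq, k = 3, max_lag = 2) {
  X <- oracle_profile(seq, k, oracle_std_table(k))
  n <- nrow(X)
  out <- c()
  for (c1 in 1:12) for (c2 in 1:12) {
    if (c1 == c2) next
    for (d in 1:max_lag) {
      out <- c(out, sum((X[1:(n - d), c1] - mean(X[, c1])) *
                          (X[(1 + d):n, c2] - mean(X[, c2]))) / (n - d))
    }
  }
  out
}

oracle_acc <- function(seq, k, max_lag = 2) {
  X <- oracle_profile(seq, k, oracle_std_table(k))
  n <- nrow(X)
  out <- c()
  for (c1 in 1:12) for (c2 in 1:12) {
    for (d in 1:max_lag) {
      out <- c(out, sum((X[1:(n - d), c1] - mean(X[, c1])) *
                          (X[(1 + d):n, c2] - mean(X[, c2]))) / (n - d))
    }
  }
  out
}

oracle_serial <- function(seq, k, lambda = 1, w = 0.05, n_props = 1) {
  std <- oracle_std_table(k)
  L <- nchar(seq)
  words <- substring(seq, 1:(L - k + 1), k:L)
  f <- vapply(oracle_kmers(k), function(u) mean(words == u), numeric(1))
  n <- length(words)
  tau <- c()
  for (j in seq_len(lambda)) {
    for (p in seq_len(n_props)) {
      tau <- c(tau, sum(std[words[1:(n - j)], p] *
                          std[words[(1 + j):n], p]) / (n - j))
    }
  }
  c(f, w * tau) / (sum(f) + w * sum(tau))
}

# O(n^2) pair-counting AUC
oracle_auc <- function(labels, scores) {
  pos <- which(labels)
  neg <- which(!labels)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  tot / (length(pos) * length(neg))
}

# max elementwise deviation, relative for values of magnitude > 1
rel_err <- function(got, want) {
  max(abs(got - want) / pmax(abs(want), 1))
}

# small labelled modelling frame with separable classes
toy_frame <- function(n = 60, p = 4, sep = 2, seed = 7) {
  stopifnot(n %% 2 == 0)
  withr::with_seed(seed, {
    y <- rep(c("CYTOPLASM", "NUCLEUS"), n / 2)  # alternate so slices mix
    X <- matrix(rnorm(n * p), n, p)
    X[, 1] <- X[, 1] + ifelse(y == "CYTOPLASM", sep, -sep)
    colnames(X) <- paste0("f", seq_len(p))
    dplyr::bind_cols(tibble::tibble(id = paste0("g", seq_len(n)), label = y),
                     tibble::as_tibble(X))
  })
}

# shared default property tables for the oracle comparisons
default_tbl2 <- load_property_table(2L)
default_tbl3 <- load_property_table(3L)
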