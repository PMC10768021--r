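# Independent brute-force oracles and small fixture builders used across
# the suite.  These deliberately avoid the implementation's code paths.

AA20_TEST <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
               "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_seq <- function(n, alphabet = AA20_TEST) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Position-by-position check of every offset, independent of regex logic.
naive_scan <- function(sequence, positions) {
  chars <- strsplit(sequence, "")[[1]]
  k <- length(positions)
  n <- length(chars)
  starts <- integer(0)
  if (n >= k) {
    for (i in 1:(n - k + 1)) {
      ok <- TRUE
      for (j in seq_len(k)) {
        if (!chars[i + j - 1] %in% positions[[j]]) {
          ok <- FALSE
          break
        }
      }
      if (ok) starts <- c(starts, i)
    }
  }
  starts
}

# Random degenerate pattern spec of given length.
random_pattern_spec <- function(len) {
  paste(vapply(seq_len(len), function(i) {
    kind <- sample(c("fixed", "wild", "class"), 1, prob = c(0.4, 0.3, 0.3))
    switch(kind,
      fixed = sample(AA20_TEST, 1),
      wild = "x",
      class = paste0("[", paste(sample(AA20_TEST, sample(2:4, 1)),
                                collapse = ""), "]")
    )
  }, character(1)), collapse = "")
}

# Largest n with (EP)^n a contiguous substring, by exhaustive enumeration.
naive_ep_max <- function(s) {
  n <- nchar(s)
  best <- 0
  k <- 1
  repeat {
    unit <- paste(rep("EP", k), collapse = "")
    if (nchar(unit) > n) break
    if (grepl(unit, s, fixed = TRUE)) best <- k else break
    k <- k + 1
  }
  best
}

# Direct evaluation of the mean-centered hydrophobic moment of one window.
naive_moment <- function(window_chars, scale) {
  h <- unname(scale[window_chars])
  h[is.na(h)] <- 0
  hc <- h - mean(h)
  ang <- (100 * pi / 180) * (seq_along(h) - 1)
  sqrt(sum(hc * sin(ang))^2 + sum(hc * cos(ang))^2) / length(h)
}

# Minimal plus/minus-strand two-exon gene models built by hand.
toy_model <- function(strand = "+", cds_lens = c(100, 200), gap = 50,
                      gene_id = "toy") {
  k <- length(cds_lens)
  start <- 0
  iv <- matrix(0, nrow = k, ncol = 2)
  for (i in seq_len(k)) {
    iv[i, ] <- c(start, start + cds_lens[i])
    start <- start + cds_lens[i] + gap
  }
  if (strand == "-") {
    total <- iv[k, 2]
    iv <- cbind(total - iv[, 2], total - iv[, 1])
  }
  gene_model(gene_id, "chr", strand, exons = iv, cds = iv)
}

table1_path <- function() {
  system.file("extdata", "nurse_shark_tpm.tsv", package = "cd4lag3")
}
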