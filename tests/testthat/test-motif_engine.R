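test_that("compile_pattern builds position sets from the grammar", {
  p <- compile_pattern("Cx[CH]")
  expect_length(p$positions, 3L)
  expect_equal(p$positions[[1]], "C")
  expect_length(p$positions[[2]], 20L)
  expect_setequal(p$positions[[3]], c("C", "H"))
  expect_length(compile_pattern("[FY]xxL[DE]")$positions, 5L)
})

test_that("compile_pattern rejects malformed specs", {
  expect_error(compile_pattern("[FY"), "unbalanced")
  expect_error(compile_pattern("A[]C"), "empty residue class")
  expect_error(compile_pattern("Cz"), "illegal character")
  expect_error(compile_pattern(""), "non-empty")
  expect_error(compile_pattern("[FBY]"), "illegal residue")
})

test_that("scan_motif finds the printed worked examples", {
  hits <- scan_motif("RFSALE", "[FY]xxL[DE]")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 2L)
  expect_equal(hits$matched, "FSALE")
  expect_equal(nrow(scan_motif("EPEPEPEPEPEPEPEQL", "[FY]xxL[DE]")), 0L)
  expect_equal(nrow(scan_motif("", "[FY]xxL[DE]")), 0L)
})

test_that("scan_motif reports overlapping matches in ascending order", {
  hits <- scan_motif("CQCQC", "CxC")
  expect_equal(hits$start, c(1L, 3L))
  expect_equal(hits$matched, c("CQC", "CQC"))
})

test_that("X never satisfies a position class, wildcard included", {
  expect_equal(nrow(scan_motif("CXC", "CxC")), 0L)
  expect_equal(nrow(scan_motif("XQC", "xxC")), 0L)
})

test_that("scan_motif agrees with a naive position-by-position oracle", {
  set.seed(42)
  for (rep in 1:300) {
    spec <- random_pattern_spec(sample(2:6, 1))
    p <- compile_pattern(spec)
    s <- random_seq(sample(10:80, 1), alphabet = sample(AA20_TEST, 6))
    expect_identical(scan_motif(s, p)$start, naive_scan(s, p$positions),
                     info = paste(spec, s))
  }
})

test_that("widening a position class never removes a hit", {
  set.seed(7)
  for (rep in 1:50) {
    spec <- random_pattern_spec(4)
    p <- compile_pattern(spec)
    before <- scan_motif(s <- random_seq(60, sample(AA20_TEST, 8)), p)$start
    i <- sample(4, 1)
    p$positions[[i]] <- unique(c(p$positions[[i]], sample(AA20_TEST, 3)))
    after <- scan_motif(s, p)$start
    expect_true(all(before %in% after))
  }
})

test_that("kozak_verdict reproduces the two start-codon contexts", {
  expect_equal(kozak_verdict("cagATGt")$verdict, "unfavorable")
  expect_equal(kozak_verdict("cccATGg")$verdict, "favorable")
  expect_equal(kozak_verdict("aaaATGg")$verdict, "favorable")
  expect_error(kozak_verdict("cagTTGt"), "ATG")
  expect_error(kozak_verdict("ATG"), "7-character")
})

test_that("kozak_verdict depends only on the -3 and +4 positions", {
  set.seed(3)
  for (rep in 1:50) {
    m3 <- sample(c("a", "c", "g", "t"), 1)
    p4 <- sample(c("a", "c", "g", "t"), 1)
    mid <- paste(sample(c("a", "c", "g", "t"), 2, replace = TRUE),
                 collapse = "")
    v1 <- kozak_verdict(paste0(m3, mid, "ATG", p4))$verdict
    v2 <- kozak_verdict(paste0(m3, "gg", "ATG", p4))$verdict
    expect_equal(v1, v2)
  }
})

test_that("inhibitory motif classes follow the stated precedence", {
  expect_equal(classify_inhibitory_motif("FSALE"), "ITIM_like")
  expect_equal(classify_inhibitory_motif("VAYAQL"), "canonical_ITIM")
  expect_equal(classify_inhibitory_motif("AYKKM"), "YxxM")
  expect_equal(classify_inhibitory_motif("GGGGG"), "none")
  # canonical ITIM outranks a co-occurring ITIM-like motif, which
  # outranks YxxM
  expect_equal(classify_inhibitory_motif("FSALEGGVAYAQL"), "canonical_ITIM")
  expect_equal(classify_inhibitory_motif("YAAMGGFSALE"), "ITIM_like")
})

test_that("the shipped motif catalogue compiles and hits its exemplars", {
  cat <- motif_catalogue()
  expect_true(all(c("name", "pattern", "note") %in% names(cat)))
  for (i in seq_len(nrow(cat))) {
    expect_s3_class(compile_pattern(cat$pattern[i], name = cat$name[i]),
                    "motif_pattern")
  }
  pat <- cat$pattern[cat$name == "cd41_cterm"]
  expect_equal(nrow(scan_motif("PKPKAFYH", pat)), 1L)
  expect_equal(nrow(scan_motif("PQPRGFYR", pat)), 1L)
})
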