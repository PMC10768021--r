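test_that("identical (class, seed) pairs give byte-identical genes", {
  a <- generate_gene("CD4-1", 99)
  b <- generate_gene("CD4-1", 99)
  expect_identical(a$protein$sequence, b$protein$sequence)
  expect_identical(a$model$exons, b$model$exons)
  expect_identical(a$truth, b$truth)
  c <- generate_gene("CD4-1", 100)
  expect_false(identical(a$protein$sequence, c$protein$sequence))
})

test_that("the generator leaves the caller's RNG stream untouched", {
  set.seed(1234)
  before <- .Random.seed
  invisible(generate_gene("LAG-3", 5))
  expect_identical(.Random.seed, before)
  invisible(generate_cohort(classes = "CD4", n_per_class = 1, seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("every planted feature is re-detected at mutation rate 0", {
  co <- generate_cohort(classes = c("CD4", "CD4-1", "CD4-2", "LAG-3",
                                    "HYBRID", "FROG_LAG3", "SHARK_CD4"),
                        n_per_class = 4, seed = 29)
  for (i in seq_len(nrow(co$truth))) {
    tr <- co$truth[i, ]
    p <- co$proteins[[tr$gene_id]]
    m <- co$models[[tr$gene_id]]
    tm <- find_tm(p)
    expect_equal(unname(tm), c(tr$tm_start, tr$tm_end), info = tr$gene_id)
    prof <- profile_tail(p, tm = tm)
    expect_equal(prof$clasp, tr$clasp, info = tr$gene_id)
    expect_equal(prof$inhibitory, tr$inhibitory, info = tr$gene_id)
    expect_equal(prof$ep_repeat_n, tr$ep_repeat_n, info = tr$gene_id)
    expect_equal(prof$cd41_cterm_motif, tr$cd41_cterm, info = tr$gene_id)
    doms <- detect_domains(substr(p$sequence, 1, tm[1] - 1))
    expect_equal(architecture_string(doms)$string, tr$architecture,
                 info = tr$gene_id)
    ann <- annotate_intron_domains(intron_phases(m), doms)
    d1 <- ann$phase[!is.na(ann$within_domain) & ann$within_domain == "D1"]
    if (is.na(tr$d1_phase)) {
      expect_length(d1, 0L)
    } else {
      expect_equal(d1, tr$d1_phase, info = tr$gene_id)
    }
    m$tm_exon_index <- infer_tm_exon(m, tm)
    expect_equal(tail_structure(m)$tail_exon_count, tr$tail_exon_count,
                 info = tr$gene_id)
  }
})

test_that("a LAG-3 tail carries exactly one ITIM-like match, as planted", {
  for (s in 1:10) {
    g <- generate_gene("LAG-3", s)
    tail <- profile_tail(g$protein)$tail
    expect_equal(nrow(scan_motif(tail, "[FY]xxL[DE]")), 1L)
  }
})

test_that("mutation behaves as an i.i.d. substitution process", {
  s <- generate_gene("CD4", 2)$protein$sequence
  expect_identical(mutate_sequence(s, 0), s)
  m1 <- mutate_sequence(s, 0.2, seed = 5)
  m2 <- mutate_sequence(s, 0.2, seed = 5)
  expect_identical(m1, m2)
  expect_false(identical(m1, s))
  # protected spans survive heavy scrambling
  g <- generate_gene("LAG-3", 6)
  tail_start <- g$truth$tm_end + 1
  mut <- mutate_sequence(g$protein$sequence, 0.9, seed = 4,
                         protected = list(c(tail_start,
                                            nchar(g$protein$sequence))))
  prof <- profile_tail(mut, tm = c(g$truth$tm_start, g$truth$tm_end))
  expect_equal(prof$inhibitory, "ITIM_like")
  expect_equal(prof$ep_repeat_n, 7L)
})

test_that("expression rows show the class-typical thymus:spleen pattern", {
  co <- generate_cohort(classes = c("CD4", "LAG-3"), n_per_class = 40,
                        seed = 41)
  ratios <- co$expression[, "thymus"] / co$expression[, "spleen"]
  cd4_rows <- grepl("^CD4_", rownames(co$expression))
  expect_gt(median(ratios[cd4_rows]), 4)
  expect_lt(median(ratios[!cd4_rows]), 2)
  dom <- vapply(rownames(co$expression), function(g) {
    tissue_dominance(co$expression, g)$dominant
  }, logical(1))
  expect_gt(mean(dom[cd4_rows]), 0.6)
  expect_lt(mean(dom[!cd4_rows]), 0.05)
})

test_that("heavy mutation degrades label recovery (smoke)", {
  co0 <- generate_cohort(n_per_class = 5, mutation_rate = 0, seed = 51)
  co5 <- generate_cohort(n_per_class = 5, mutation_rate = 0.5, seed = 51)
  r0 <- label_recovery(classify_pipeline(co0$proteins, co0$models,
                                         co0$synteny, co0$expression),
                       co0$truth)
  r5 <- label_recovery(classify_pipeline(co5$proteins, co5$models,
                                         co5$synteny, co5$expression),
                       co5$truth)
  expect_equal(r0, 1)
  expect_lt(r5, 1)
})
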