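cd41_vector <- function() {
  feature_vector(clasp = "CxC", inhibitory = "none", cd41_cterm_motif = TRUE,
                 d1_intron_phase = "1", tail_exon_count = 2L,
                 architecture = "V-C2-V-C2", linker_cxxc = FALSE,
                 head_to_tail_role = "downstream", thymus_dominant = TRUE,
                 ep_repeat_n = 0L, acidic_fraction = 0.05)
}

lag3_vector <- function() {
  feature_vector(clasp = "none", inhibitory = "ITIM_like",
                 cd41_cterm_motif = FALSE, d1_intron_phase = "2",
                 tail_exon_count = 1L, architecture = "V-C2-V-C2",
                 linker_cxxc = FALSE, head_to_tail_role = "upstream",
                 thymus_dominant = FALSE, ep_repeat_n = 7L,
                 acidic_fraction = 8 / 17)
}

test_that("an all-unknown vector scores zero and stays AMBIGUOUS", {
  s <- score_features(feature_vector())
  expect_equal(s$cd4_score, 0)
  expect_equal(s$lag3_score, 0)
  expect_equal(assign_label(s, feature_vector()), "AMBIGUOUS")
})

test_that("canonical lineage vectors reach the documented scores", {
  s1 <- score_features(cd41_vector())
  expect_equal(s1$cd4_score, 10)  # 3 + 2 + 2 + 1 + 1 + 1
  expect_equal(s1$lag3_score, 0)
  expect_equal(assign_label(s1, cd41_vector()), "CD4-1")

  s2 <- score_features(lag3_vector())
  expect_gte(s2$lag3_score, 8)
  expect_equal(s2$cd4_score, 0)
  expect_equal(assign_label(s2, lag3_vector()), "LAG-3")
})

test_that("non-dominant expression is absent evidence, never negative", {
  with_flag <- lag3_vector()
  s1 <- score_features(with_flag)
  with_flag$thymus_dominant <- NA
  s2 <- score_features(with_flag)
  expect_equal(s1$lag3_score, s2$lag3_score)
  expect_equal(s1$cd4_score, s2$cd4_score)
})

test_that("the shark CD4 argument is recapitulated from its features", {
  shark <- feature_vector(clasp = "CxH", inhibitory = "none",
                          cd41_cterm_motif = FALSE,
                          d1_intron_phase = "absent",
                          tail_exon_count = 3L, architecture = "V-C2-V-C2",
                          linker_cxxc = FALSE,
                          head_to_tail_role = "downstream",
                          thymus_dominant = TRUE, ep_repeat_n = 0L,
                          acidic_fraction = 0)
  s <- score_features(shark)
  expect_equal(s$cd4_score, 7)
  expect_equal(assign_label(s, shark), "CD4")
})

test_that("frog-type LAG-3 is called from structure and synteny alone", {
  frog <- feature_vector(clasp = "none", inhibitory = "none",
                         cd41_cterm_motif = FALSE, d1_intron_phase = "2",
                         tail_exon_count = 1L, architecture = "V-C2-V-C2",
                         linker_cxxc = FALSE, head_to_tail_role = "upstream",
                         thymus_dominant = FALSE, ep_repeat_n = 0L,
                         acidic_fraction = 0)
  s <- score_features(frog)
  expect_equal(assign_label(s, frog), "LAG-3")
})

test_that("CD4-like gene structure with a LAG-3 tail is HYBRID", {
  hybrid <- feature_vector(clasp = "none", inhibitory = "ITIM_like",
                           cd41_cterm_motif = FALSE, d1_intron_phase = "1",
                           tail_exon_count = 1L,
                           architecture = "V-C2-V-C2", linker_cxxc = FALSE,
                           head_to_tail_role = "none",
                           thymus_dominant = FALSE, ep_repeat_n = 0L,
                           acidic_fraction = 0)
  expect_equal(assign_label(score_features(hybrid), hybrid), "HYBRID")
})

test_that("the CD4-1 / CD4-2 split needs a ray-finned-fish cue", {
  v <- cd41_vector()
  v$cd41_cterm_motif <- FALSE
  expect_equal(assign_label(score_features(v), v), "CD4")
  v$architecture <- "V-C2"
  expect_equal(assign_label(score_features(v), v), "CD4-2")
  v$architecture <- "V-C2-V-C2"
  v$linker_cxxc <- TRUE
  expect_equal(assign_label(score_features(v), v), "CD4-2")
})

test_that("adding concordant evidence never hurts the winning lineage", {
  base <- feature_vector(clasp = "CxC", tail_exon_count = 2L)
  s0 <- score_features(base)
  upgrades <- list(
    function(v) { v$d1_intron_phase <- "1"; v },
    function(v) { v$cd41_cterm_motif <- TRUE; v },
    function(v) { v$thymus_dominant <- TRUE; v },
    function(v) { v$head_to_tail_role <- "downstream"; v }
  )
  for (up in upgrades) {
    v <- up(base)
    s <- score_features(v)
    expect_gte(s$cd4_score, s0$cd4_score)
    expect_equal(s$lag3_score, s0$lag3_score)
    lbl <- assign_label(s, v)
    expect_true(lbl %in% c("CD4", "CD4-1", "CD4-2", "AMBIGUOUS"))
  }
})

test_that("classification is deterministic and label matches the scores", {
  co <- generate_cohort(classes = c("CD4", "LAG-3"), n_per_class = 3,
                        seed = 17)
  r1 <- classify_pipeline(co$proteins, co$models, co$synteny, co$expression)
  r2 <- classify_pipeline(co$proteins, co$models, co$synteny, co$expression)
  expect_identical(vapply(r1, `[[`, "", "label"),
                   vapply(r2, `[[`, "", "label"))
  for (r in r1) {
    s <- list(cd4_score = r$cd4_score, lag3_score = r$lag3_score)
    expect_equal(assign_label(s, do.call(feature_vector, r$features)),
                 r$label)
  }
})

test_that("FASTA-only input degrades to sequence features with unknowns", {
  co <- generate_cohort(classes = c("CD4-1", "LAG-3"), n_per_class = 2,
                        seed = 23)
  reps <- classify_pipeline(co$proteins)
  for (r in reps) {
    expect_true(is.na(r$features$d1_intron_phase))
    expect_true(is.na(r$features$tail_exon_count))
    expect_true(is.na(r$features$thymus_dominant))
  }
  # tail motifs alone still separate CD4-1 from LAG-3 in these fixtures
  labels <- vapply(reps, `[[`, "", "label")
  expect_true(all(labels[grepl("^CD41", names(labels))] %in%
                    c("CD4-1", "AMBIGUOUS")))
})

test_that("a failing record is reported in-line and the run continues", {
  recs <- list(protein_record("ok", generate_gene("CD4", 3)$protein$sequence),
               protein_record("no_tm", strrep("DKE", 40)))
  reps <- classify_pipeline(recs)
  expect_false(is.na(reps$ok$label))   # sequence-only CD4 stays evaluable
  expect_true(is.na(reps$ok$error))
  expect_true(is.na(reps$no_tm$label))
  expect_match(reps$no_tm$error, "no TM segment")
})
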