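test_that("read_fasta parses records, takes the first header token as id", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a some description", "RFSALE", ">b", "ACDEF", "GHIK"), f)
  recs <- read_fasta(f)
  expect_length(recs, 2L)
  expect_equal(names(recs), c("a", "b"))
  expect_equal(recs$a$sequence, "RFSALE")
  expect_equal(recs$b$sequence, "ACDEFGHIK")
})

test_that("read_fasta on an empty file returns an empty list", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), f)
  expect_length(read_fasta(f), 0L)
})

test_that("read_fasta rejects illegal residues, naming the line", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "RF SALE"), f)
  expect_error(read_fasta(f), "line 2")
  writeLines(c(">a", "RF-SALE"), f)
  expect_error(read_fasta(f), "illegal residue")
  writeLines(c("ACDEF", ">a", "ACDEF"), f)
  expect_error(read_fasta(f), "header")
})

test_that("gene_model enforces its interval invariants", {
  expect_error(
    gene_model("g", "chr", "+", exons = rbind(c(0, 100)),
               cds = rbind(c(50, 150))),
    "not contained in any exon"
  )
  expect_error(
    gene_model("g", "chr", "+", exons = rbind(c(0, 100), c(50, 200)),
               cds = rbind(c(0, 100))),
    "overlap|transcription order"
  )
  expect_warning(
    m <- gene_model("g", "chr", "+", exons = rbind(c(0, 100)),
                    cds = rbind(c(0, 100))),
    "cds_incomplete"
  )
  expect_true(m$cds_incomplete)
  clean <- gene_model("g", "chr", "+", exons = rbind(c(0, 99)),
                      cds = rbind(c(0, 99)))
  expect_false(clean$cds_incomplete)
})

test_that("read_gff3 converts 1-based closed disk coordinates", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t1\t400\t.\t+\t.\tID=gene:g1",
    "chr1\ttest\tmRNA\t1\t400\t.\t+\t.\tID=mrna:g1;Parent=gene:g1",
    "chr1\ttest\texon\t1\t100\t.\t+\t.\tParent=mrna:g1",
    "chr1\ttest\texon\t200\t400\t.\t+\t.\tParent=mrna:g1",
    "chr1\ttest\tCDS\t1\t99\t.\t+\t0\tParent=mrna:g1",
    "chr1\ttest\tCDS\t200\t400\t.\t+\t2\tParent=mrna:g1"
  ), f)
  models <- read_gff3(f)
  expect_length(models, 1L)
  m <- models$g1
  expect_equal(m$exons[1, ], c(start = 0, end = 100))
  expect_equal(m$exons[2, ], c(start = 199, end = 400))
})

test_that("read_gff3 reorders minus-strand features into transcription order", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t1\t400\t.\t-\t.\tID=gene:g1",
    "chr1\ttest\tmRNA\t1\t400\t.\t-\t.\tID=mrna:g1;Parent=gene:g1",
    "chr1\ttest\texon\t1\t100\t.\t-\t.\tParent=mrna:g1",
    "chr1\ttest\texon\t200\t400\t.\t-\t.\tParent=mrna:g1",
    "chr1\ttest\tCDS\t2\t100\t.\t-\t.\tParent=mrna:g1",
    "chr1\ttest\tCDS\t200\t400\t.\t-\t.\tParent=mrna:g1"
  ), f)
  m <- read_gff3(f)$g1
  # first listed exon is the 5'-most in transcription order (highest coords)
  expect_equal(m$exons[1, ], c(start = 199, end = 400))
  expect_equal(m$exons[2, ], c(start = 0, end = 100))
})

test_that("generated GFF3 round-trips through read_gff3 unchanged", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(classes = c("CD4", "LAG-3"), n_per_class = 2,
                        seed = 5, outdir = dir)
  back <- read_gff3(co$files$gff3)
  expect_setequal(names(back), names(co$models))
  for (id in names(co$models)) {
    expect_equal(back[[id]]$exons, co$models[[id]]$exons)
    expect_equal(back[[id]]$cds, co$models[[id]]$cds)
    expect_equal(back[[id]]$strand, co$models[[id]]$strand)
  }
})

test_that("evidence reports round-trip losslessly through JSON", {
  f <- withr::local_tempfile(fileext = ".json")
  write_report(list(), f)
  expect_length(read_report(f), 0L)

  co <- generate_cohort(classes = c("CD4-1", "LAG-3"), n_per_class = 1,
                        seed = 2)
  reps <- classify_pipeline(co$proteins, co$models, co$synteny,
                            co$expression)
  write_report(reps, f)
  back <- read_report(f)
  expect_length(back, length(reps))
  for (i in seq_along(reps)) {
    expect_equal(back[[i]]$gene_id, reps[[i]]$gene_id)
    expect_equal(back[[i]]$label, reps[[i]]$label)
    expect_equal(back[[i]]$features, unclass(reps[[i]]$features),
                 tolerance = 1e-12)
    expect_equal(back[[i]]$cd4_score, reps[[i]]$cd4_score)
    expect_equal(back[[i]]$lag3_score, reps[[i]]$lag3_score)
    expect_equal(back[[i]]$contributions$points,
                 reps[[i]]$contributions$points)
  }
})

test_that("CDS length stays divisible by 3 for clean generated models", {
  co <- generate_cohort(classes = c("CD4", "CD4-2", "LAG-3", "SHARK_CD4"),
                        n_per_class = 2, seed = 9)
  for (m in co$models) {
    expect_false(m$cds_incomplete)
    expect_equal(sum(m$cds[, 2] - m$cds[, 1]) %% 3, 0)
  }
})
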