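# Seeded generator of synthetic CD4/LAG-3 family genes.
#
# Every class template plants the features the classifier looks for:
# Ig-like domains with B/F cysteine pairs (spacing 45-65), WxC in C2
# domains, the six V-set start-consensus residues in V domains, a
# 19-residue hydrophobic TM, and a class-specific cytoplasmic tail.  Gene
# models place the D1-internal intron so the cumulative coding length is
# congruent 1 mod 3 for CD4-lineage templates and 2 mod 3 for LAG-3
# templates (at distinct positions), and split the tail over 1 (LAG-3),
# 2 (osteichthyan CD4) or 3 (shark CD4) coding exons.  Background filler
# is drawn from a reduced alphabet that cannot spell any catalogued motif,
# so at mutation rate 0 every planted feature is re-detected exactly.

SIM_CLASSES <- c("CD4", "CD4-1", "CD4-2", "LAG-3",
                 "HYBRID", "FROG_LAG3", "SHARK_CD4")

EXPECTED_LABELS <- c(
  "CD4" = "CD4", "CD4-1" = "CD4-1", "CD4-2" = "CD4-2", "LAG-3" = "LAG-3",
  "HYBRID" = "HYBRID", "FROG_LAG3" = "LAG-3", "SHARK_CD4" = "CD4"
)

# Filler alphabet: no C, W, F, Y, M, H, D, E or L, so no background run can
# complete a clasp, WxC, ITIM(-like), YxxM, EP or CD4-1 C-terminal motif.
FILLER_AA <- c("A", "G", "S", "T", "N", "Q", "K", "R", "P", "V", "I")

filler_str <- function(n) {
  if (n <= 0L) return("")
  paste(sample(FILLER_AA, n, replace = TRUE), collapse = "")
}

local_seed <- function(seed) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  invisible(function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
}

make_domain_block <- function(category) {
  spacing <- sample(45:65, 1L)
  n <- spacing + 18L  # cys_b at 16, cys_f at 16 + spacing, two trailing
  chars <- sample(FILLER_AA, n, replace = TRUE)
  if (category == "V") {
    chars[4L] <- sample(c("I", "V"), 1L)
    chars[5L] <- sample(c("F", "Y"), 1L)
    chars[9L] <- "G"
    chars[12L] <- sample(c("A", "V"), 1L)
    chars[14L] <- "L"
    chars[15L] <- "P"
  }
  chars[16L] <- "C"
  f <- 16L + spacing
  if (category == "C2") chars[f - 2L] <- "W"
  chars[f] <- "C"
  list(seq = paste(chars, collapse = ""), len = n,
       cys_b = 16L, cys_f = f)
}

sim_template <- function(class) {
  switch(class,
    "CD4" = list(arch = c("V", "C2", "V", "C2"), d1_phase = 1L,
                 tail_exons = 2L, linker_cxxc = FALSE, tail = "cd4"),
    "CD4-1" = list(arch = c("V", "C2", "V", "C2"), d1_phase = 1L,
                   tail_exons = 2L, linker_cxxc = FALSE, tail = "cd4_1"),
    "CD4-2" = list(arch = c("V", "C2"), d1_phase = 1L,
                   tail_exons = 2L, linker_cxxc = TRUE, tail = "cd4"),
    "LAG-3" = list(arch = c("V", "C2", "V", "C2"), d1_phase = 2L,
                   tail_exons = 1L, linker_cxxc = FALSE, tail = "lag3"),
    "HYBRID" = list(arch = c("V", "C2", "V", "C2"), d1_phase = 1L,
                    tail_exons = 1L, linker_cxxc = FALSE, tail = "hybrid"),
    "FROG_LAG3" = list(arch = c("V", "C2", "V", "C2"), d1_phase = 2L,
                       tail_exons = 1L, linker_cxxc = FALSE, tail = "frog"),
    "SHARK_CD4" = list(arch = c("V", "C2", "V", "C2"), d1_phase = NA_integer_,
                       tail_exons = 3L, linker_cxxc = FALSE, tail = "shark"),
    stop("unknown simulation class '", class, "'")
  )
}

# Amphipathic helix stretch of the CD4 membrane-proximal tail; avoids
# C/W/F/Y/M so no catalogued motif can form by accident.
AMPH_STRETCH <- "LKELAQKLAEK"
EP_STRETCH <- "EPEPEPEPEPEPEPEQL"

make_tail <- function(kind) {
  switch(kind,
    cd4 = paste0("KRK", AMPH_STRETCH, "TK", "Y", "CQC", filler_str(5L)),
    cd4_1 = paste0("KRK", AMPH_STRETCH, "TK", "Y", "CQC", filler_str(2L),
                   "PKPKAFYH", "K"),
    shark = paste0("KRK", filler_str(5L), AMPH_STRETCH, filler_str(8L),
                   "PTP", "Y", "CVH", filler_str(12L)),
    lag3 = paste0("KRR", filler_str(5L), "R", "FPALE", "T", EP_STRETCH),
    hybrid = paste0("KRR", filler_str(5L), "R", "FPALE", "T", filler_str(4L)),
    frog = paste0("KRR", filler_str(5L), "R", filler_str(6L), "T",
                  filler_str(4L)),
    stop("unknown tail kind '", kind, "'")
  )
}

#' Generate one synthetic CD4/LAG-3 family gene
#'
#' Builds a protein with planted class features, the matching gene model,
#' and a truth record listing every planted feature.  Identical
#' `(class, seed)` pairs yield byte-identical output; the caller's RNG
#' state is left untouched.
#'
#' @param class One of `r paste(SIM_CLASSES, collapse = ", ")`.
#' @param seed Integer seed.
#' @param gene_id Identifier (defaults to `<class>_s<seed>`).
#' @param seq_id,strand,offset Genomic placement of the gene model.
#' @return List with `protein` (a `protein_record`), `model` (a
#'   `gene_model`) and `truth` (a one-row data frame).
#' @export
generate_gene <- function(class, seed, gene_id = NULL, seq_id = "locus",
                          strand = "+", offset = 5000L) {
  class <- match.arg(class, SIM_CLASSES)
  if (is.null(gene_id)) gene_id <- paste0(gsub("-", "", class), "_s", seed)
  restore <- local_seed(seed)
  on.exit(restore())
  tpl <- sim_template(class)

  leader <- filler_str(18L)
  pos <- nchar(leader) + 1L
  parts <- list(leader)
  dom_start <- integer(0)
  dom_end <- integer(0)
  for (k in seq_along(tpl$arch)) {
    blk <- make_domain_block(tpl$arch[k])
    dom_start <- c(dom_start, pos)
    dom_end <- c(dom_end, pos + blk$len - 1L)
    parts <- c(parts, blk$seq)
    pos <- pos + blk$len
    if (k < length(tpl$arch)) {
      parts <- c(parts, filler_str(5L))
      pos <- pos + 5L
    }
  }
  # postlink ends in R so the planted TM is the unique hydropathy maximum
  postlink <- if (tpl$linker_cxxc) {
    paste0(filler_str(3L), "CQQC", filler_str(2L), "R")
  } else {
    paste0(filler_str(5L), "R")
  }
  parts <- c(parts, postlink)
  pos <- pos + nchar(postlink)
  tm_start <- pos
  tm_seq <- paste(sample(c("L", "I", "V", "A"), TM_WINDOW, replace = TRUE,
                         prob = c(0.4, 0.3, 0.2, 0.1)), collapse = "")
  parts <- c(parts, tm_seq)
  tm_end <- tm_start + TM_WINDOW - 1L
  pos <- tm_end + 1L
  tail_seq <- make_tail(tpl$tail)
  parts <- c(parts, tail_seq)
  sequence <- paste(unlist(parts), collapse = "")
  stopifnot(nchar(sequence) == tm_end + nchar(tail_seq))
  L <- nchar(sequence)

  # CDS breakpoints (coding-nucleotide offsets of the introns, ascending)
  breaks <- integer(0)
  d1_residue <- NA_integer_
  if (!is.na(tpl$d1_phase)) {
    d1_residue <- if (tpl$d1_phase == 1L) {
      dom_start[1] + 20L
    } else {
      dom_start[1] + 30L
    }
    breaks <- c(breaks, 3L * (d1_residue - 1L) + tpl$d1_phase)
  }
  for (k in seq_len(length(tpl$arch) - 1L)) {
    mid <- dom_end[k] + 3L  # inside the 5-residue inter-domain linker
    breaks <- c(breaks, 3L * (mid - 1L))  # phase 0 between domains
  }
  breaks <- c(breaks, 3L * (tm_start - 1L))       # ectodomain | TM exon
  breaks <- c(breaks, 3L * (tm_end + 2L))         # TM exon end (+2 residues)
  if (tpl$tail_exons == 2L) {
    breaks <- c(breaks, 3L * (tm_end + 2L + 6L) + 1L)
  } else if (tpl$tail_exons == 3L) {
    breaks <- c(breaks, 3L * (tm_end + 2L + 8L) + 1L,
                3L * (tm_end + 2L + 20L) + 2L)
  }
  breaks <- sort(unique(breaks))
  stopifnot(all(breaks > 0L), all(breaks < 3L * L))
  seg_lens <- diff(c(0L, breaks, 3L * L))
  intron_lens <- 150L + 37L * seq_len(length(seg_lens) - 1L)

  model <- layout_gene_model(gene_id, seq_id, strand, seg_lens, intron_lens,
                             offset)
  clasp_type <- switch(tpl$tail, cd4 = "CxC", cd4_1 = "CxC", shark = "CxH",
                       "none")
  inhib <- switch(tpl$tail, lag3 = "ITIM_like", hybrid = "ITIM_like", "none")
  truth <- data.frame(
    gene_id = gene_id, class = class,
    expected_label = unname(EXPECTED_LABELS[class]),
    d1_phase = tpl$d1_phase, d1_residue = d1_residue,
    d1_start = dom_start[1], d1_end = dom_end[1],
    tail_exon_count = tpl$tail_exons,
    tm_start = tm_start, tm_end = tm_end,
    clasp = clasp_type, inhibitory = inhib,
    architecture = architecture_string(tpl$arch)$string,
    linker_cxxc = tpl$linker_cxxc,
    ep_repeat_n = if (tpl$tail == "lag3") 7L else 0L,
    cd41_cterm = tpl$tail == "cd4_1",
    stringsAsFactors = FALSE
  )
  list(protein = protein_record(gene_id, sequence), model = model,
       truth = truth)
}

# Lay CDS segments (5'->3' transcription order) onto a genome strand.
layout_gene_model <- function(gene_id, seq_id, strand, seg_lens, intron_lens,
                              offset) {
  k <- length(seg_lens)
  rel <- matrix(0L, nrow = k, ncol = 2)
  at <- 0L
  for (i in seq_len(k)) {
    rel[i, ] <- c(at, at + seg_lens[i])
    at <- at + seg_lens[i] + if (i < k) intron_lens[i] else 0L
  }
  total <- rel[k, 2]
  genomic <- if (strand == "+") {
    cbind(offset + rel[, 1], offset + rel[, 2])
  } else {
    cbind(offset + total - rel[, 2], offset + total - rel[, 1])
  }
  gene_model(gene_id, seq_id, strand, exons = genomic, cds = genomic)
}

#' Point-mutate a protein sequence
#'
#' i.i.d. substitutions at the given per-residue rate, each to a uniformly
#' drawn different residue; spans listed in `protected` (1-based inclusive
#' `c(start, end)` pairs) are left untouched, which supports ablation
#' studies where planted features must survive background scrambling.
#'
#' @param sequence Sequence (string or `protein_record`).
#' @param rate Substitution probability in [0, 1).
#' @param seed Optional seed (caller RNG preserved when given).
#' @param protected List of `c(start, end)` spans to protect.
#' @return Mutated sequence string.
#' @export
mutate_sequence <- function(sequence, rate, seed = NULL, protected = NULL) {
  stopifnot(rate >= 0, rate < 1)
  sequence <- as_aa_sequence(sequence)
  if (rate == 0) return(sequence)
  if (!is.null(seed)) {
    restore <- local_seed(seed)
    on.exit(restore())
  }
  chars <- aa_chars(sequence)
  hit <- stats::runif(length(chars)) < rate
  if (!is.null(protected)) {
    for (span in protected) {
      hit[span[1]:span[2]] <- FALSE
    }
  }
  for (i in which(hit)) {
    chars[i] <- sample(setdiff(AA20, chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

#' Generate a full synthetic cohort
#'
#' One gene per (class, replicate) on its own locus, each with a tandem
#' anchor partner so the head-to-tail orientation is evaluable: CD4-class
#' genes get an upstream anchor (they are the downstream member), LAG-3
#' class genes a downstream anchor, and HYBRID genes one on each side
#' (the lungfish-type arrangement).  Locus strand is randomized.  The
#' expression table emulates thymus/spleen TPM rows: CD4-class genes at a
#' six-fold thymus:spleen ratio with lognormal noise (sigma 0.2), LAG-3
#' class genes around parity.  Protein sequences are then point-mutated at
#' `mutation_rate`; gene models, synteny and expression stay clean.
#'
#' @param classes Classes to simulate (subset of `SIM_CLASSES`).
#' @param n_per_class Replicates per class.
#' @param mutation_rate Per-residue substitution probability.
#' @param seed Integer seed; identical parameters give identical output.
#' @param outdir Optional directory; when given, writes `proteins.fasta`,
#'   `models.gff3`, `synteny.tsv`, `expression.tsv`, `truth.tsv`.
#' @return List with `proteins` (named list of `protein_record`),
#'   `models` (named list of `gene_model`), `synteny` (data frame),
#'   `expression` (matrix), `truth` (data frame) and `files`.
#' @export
generate_cohort <- function(classes = c("CD4", "CD4-1", "CD4-2", "LAG-3"),
                            n_per_class = 25L, mutation_rate = 0,
                            seed = 1L, outdir = NULL) {
  stopifnot(all(classes %in% SIM_CLASSES))
  restore <- local_seed(seed)
  on.exit(restore())
  plan <- expand.grid(rep = seq_len(n_per_class), class = classes,
                      stringsAsFactors = FALSE)
  n <- nrow(plan)
  strands <- sample(c("+", "-"), n, replace = TRUE)
  gene_seeds <- (as.integer(seed) + 1000003L * seq_len(n)) %% 2147483647L
  mut_seeds <- (as.integer(seed) + 2000003L * seq_len(n)) %% 2147483647L
  base_expr <- stats::rlnorm(n, meanlog = log(1.2), sdlog = 0.2)
  ratio_noise <- stats::rlnorm(n, meanlog = 0, sdlog = 0.2)
  gill_noise <- stats::rlnorm(n, meanlog = 0, sdlog = 0.3)

  proteins <- list()
  models <- list()
  syn_rows <- list()
  truth_rows <- list()
  expr <- matrix(NA_real_, nrow = n, ncol = 3,
                 dimnames = list(NULL, c("thymus", "spleen", "gill")))
  gene_ids <- character(n)
  for (i in seq_len(n)) {
    class <- plan$class[i]
    gid <- sprintf("%s_g%03d", gsub("-", "", class), i)
    locus <- sprintf("locus_%03d", i)
    g <- generate_gene(class, gene_seeds[i], gene_id = gid, seq_id = locus,
                       strand = strands[i], offset = 5000L)
    if (mutation_rate > 0) {
      g$protein <- protein_record(gid, mutate_sequence(
        g$protein, mutation_rate, seed = mut_seeds[i]))
    }
    gene_ids[i] <- gid
    proteins[[gid]] <- g$protein
    models[[gid]] <- g$model
    truth_rows[[i]] <- g$truth
    syn_rows[[length(syn_rows) + 1L]] <- locus_synteny_rows(
      g$model, class, locus)
    cd4_like <- class %in% c("CD4", "CD4-1", "CD4-2", "SHARK_CD4")
    ratio <- if (cd4_like) 6 * ratio_noise[i] else ratio_noise[i]
    expr[i, ] <- c(base_expr[i] * ratio, base_expr[i],
                   base_expr[i] * gill_noise[i])
  }
  rownames(expr) <- gene_ids
  synteny <- do.call(rbind, syn_rows)
  synteny <- synteny[order(synteny$seq_id, synteny$start), , drop = FALSE]
  rownames(synteny) <- NULL
  truth <- do.call(rbind, truth_rows)
  out <- list(proteins = proteins, models = models, synteny = synteny,
              expression = expr, truth = truth, files = NULL,
              params = list(classes = classes, n_per_class = n_per_class,
                            mutation_rate = mutation_rate, seed = seed))
  if (!is.null(outdir)) out$files <- write_cohort(out, outdir)
  out
}

locus_synteny_rows <- function(model, class, locus) {
  gs <- min(model$exons[, 1])
  ge <- max(model$exons[, 2])
  strand <- model$strand
  anchor <- function(name, side) {
    # side "up": transcriptionally upstream of the gene; "down": downstream
    left <- (side == "up") == (strand == "+")
    if (left) {
      data.frame(gene = name, seq_id = locus, start = gs - 2200L,
                 end = gs - 800L, strand = strand, stringsAsFactors = FALSE)
    } else {
      data.frame(gene = name, seq_id = locus, start = ge + 800L,
                 end = ge + 2200L, strand = strand, stringsAsFactors = FALSE)
    }
  }
  self <- data.frame(gene = model$gene_id, seq_id = locus, start = gs,
                     end = ge, strand = strand, stringsAsFactors = FALSE)
  rows <- list(self)
  if (class %in% c("CD4", "CD4-1", "CD4-2", "SHARK_CD4")) {
    rows <- c(rows, list(anchor(paste0("LAG3anchor_", locus), "up")))
  } else if (class %in% c("LAG-3", "FROG_LAG3")) {
    rows <- c(rows, list(anchor(paste0("CD4anchor_", locus), "down")))
  } else {  # HYBRID sits between the pair
    rows <- c(rows, list(anchor(paste0("LAG3anchor_", locus), "up"),
                         anchor(paste0("CD4anchor_", locus), "down")))
  }
  do.call(rbind, rows)
}

write_cohort <- function(cohort, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(outdir, "proteins.fasta")
  seqs <- Biostrings::AAStringSet(vapply(cohort$proteins, `[[`, character(1),
                                         "sequence"))
  names(seqs) <- names(cohort$proteins)
  Biostrings::writeXStringSet(seqs, fasta)
  gff3 <- file.path(outdir, "models.gff3")
  rtracklayer::export(models_to_granges(cohort$models), gff3, format = "gff3")
  syn <- file.path(outdir, "synteny.tsv")
  utils::write.table(cohort$synteny, syn, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  exprf <- file.path(outdir, "expression.tsv")
  utils::write.table(
    data.frame(gene = rownames(cohort$expression), cohort$expression,
               check.names = FALSE),
    exprf, sep = "\t", quote = FALSE, row.names = FALSE)
  truthf <- file.path(outdir, "truth.tsv")
  utils::write.table(cohort$truth, truthf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(fasta = fasta, gff3 = gff3, synteny = syn, expression = exprf,
       truth = truthf)
}

models_to_granges <- function(models) {
  rows <- list()
  for (m in models) {
    gs <- min(m$exons[, 1]) + 1L  # internal 0-based half-open -> GFF3 1-based
    ge <- max(m$exons[, 2])
    gid <- paste0("gene:", m$gene_id)
    mid <- paste0("mrna:", m$gene_id)
    add <- function(type, start, end, id = NA_character_,
                    parent = NA_character_, phase = NA_integer_) {
      rows[[length(rows) + 1L]] <<- data.frame(
        seq_id = m$seq_id, start = start, end = end, strand = m$strand,
        type = type, ID = id, Parent = parent, phase = phase,
        stringsAsFactors = FALSE)
    }
    add("gene", gs, ge, id = gid)
    add("mRNA", gs, ge, id = mid, parent = gid)
    for (j in order(m$exons[, 1])) {
      add("exon", m$exons[j, 1] + 1L, m$exons[j, 2], parent = mid)
    }
    # GFF3 phase: bases to trim from this CDS segment to reach a codon start
    lens <- m$cds[, 2] - m$cds[, 1]
    before <- c(0L, cumsum(lens))[seq_along(lens)]
    phases <- (3L - before %% 3L) %% 3L
    for (j in order(m$cds[, 1])) {
      add("CDS", m$cds[j, 1] + 1L, m$cds[j, 2], parent = mid,
          phase = phases[j])
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seq_id,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand
  )
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(df$Parent), "", df$Parent)
  S4Vectors::mcols(gr)$phase <- df$phase
  gr
}

#' Generate a synthetic qPCR quantity table
#'
#' Long-format target/housekeeping amounts per gene, tissue and replicate,
#' suitable for [qpcr_relative()]; the spleen rows serve as calibrator.
#'
#' @param genes Gene names.
#' @param tissues Tissue names (must include the intended calibrator).
#' @param n_replicates Replicates per gene and tissue.
#' @param seed Integer seed.
#' @return Data frame with columns `gene`, `tissue`, `replicate`,
#'   `target_amount`, `housekeeping_amount`.
#' @export
generate_qpcr <- function(genes = c("CD4", "LAG-3"),
                          tissues = c("spleen", "thymus", "gill"),
                          n_replicates = 4L, seed = 1L) {
  restore <- local_seed(seed)
  on.exit(restore())
  grid <- expand.grid(replicate = seq_len(n_replicates), tissue = tissues,
                      gene = genes, stringsAsFactors = FALSE)
  grid <- grid[, c("gene", "tissue", "replicate")]
  k <- nrow(grid)
  grid$target_amount <- stats::rlnorm(k, meanlog = log(5), sdlog = 0.5)
  grid$housekeeping_amount <- stats::rlnorm(k, meanlog = log(100),
                                            sdlog = 0.15)
  grid
}
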