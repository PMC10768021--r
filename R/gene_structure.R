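# Intron phase arithmetic and cytoplasmic-tail exon counting.
#
# Phase is defined on coding nucleotides only: an intron falling after
# `cds_offset` coding nucleotides has phase `cds_offset %% 3` (0 = between
# codons, 1/2 = inside the preceding codon) and sits in the codon of the
# 0-based protein residue `cds_offset %/% 3`.  Because gene models are
# normalized to transcription order at parse time, the same arithmetic
# serves both strands.

#' Intron phases of a gene model
#'
#' One record per junction between consecutive CDS intervals.
#'
#' @param model A `gene_model`.
#' @return Data frame with columns `index`, `cds_offset` (coding
#'   nucleotides 5' of the intron), `phase` (0/1/2), `protein_pos`
#'   (0-based residue whose codon contains or precedes the intron) and
#'   `within_domain` (`NA` until [annotate_intron_domains()] is applied).
#' @export
intron_phases <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  if (nrow(model$cds) == 0L) stop("gene model has no CDS")
  lens <- model$cds[, 2] - model$cds[, 1]
  k <- length(lens)
  if (k == 1L) {
    return(data.frame(index = integer(0), cds_offset = integer(0),
                      phase = integer(0), protein_pos = integer(0),
                      within_domain = character(0),
                      stringsAsFactors = FALSE))
  }
  offsets <- as.integer(cumsum(lens)[-k])
  data.frame(
    index = seq_len(k - 1L),
    cds_offset = offsets,
    phase = offsets %% 3L,
    protein_pos = offsets %/% 3L,
    within_domain = NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Label introns that fall inside Ig-like domains
#'
#' Sets `within_domain` for introns whose residue lies strictly inside a
#' domain's bounds; boundary residues are excluded, matching the notion of
#' an intron internal to the D1 coding sequence.
#'
#' @param introns Output of [intron_phases()].
#' @param domains Output of [detect_domains()] (columns `label`, `start`,
#'   `end`; 1-based residue bounds).
#' @return `introns` with `within_domain` filled in where applicable.
#' @export
annotate_intron_domains <- function(introns, domains) {
  if (nrow(introns) == 0L || is.null(domains) || nrow(domains) == 0L) {
    return(introns)
  }
  for (i in seq_len(nrow(introns))) {
    residue <- introns$protein_pos[i] + 1L  # 1-based residue index
    hit <- which(domains$start < residue & residue < domains$end)
    if (length(hit) > 0L) {
      introns$within_domain[i] <- domains$label[hit[1]]
    }
  }
  introns
}

#' Cytoplasmic-tail exon structure
#'
#' Counts the coding exons strictly behind the transmembrane-encoding exon.
#' Throughout jawed vertebrates the LAG-3 tail is encoded by a single such
#' exon, the osteichthyan CD4 tail by two, and the chondrichthyan CD4 tail
#' by three (the shark "extra exon"); `extra_exon` flags counts of three or
#' more.
#'
#' @param model A `gene_model` with `tm_exon_index` set (see
#'   [infer_tm_exon()]).
#' @return List with `tail_exon_count` and `extra_exon`.
#' @export
tail_structure <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  if (is.na(model$tm_exon_index)) {
    stop("gene_model '", model$gene_id, "': tm_exon_index not set; ",
         "supply it or locate the transmembrane exon first ",
         "(find_tm + infer_tm_exon)")
  }
  coding <- which(vapply(seq_len(nrow(model$exons)), function(i) {
    any(model$cds[, 1] < model$exons[i, 2] &
          model$cds[, 2] > model$exons[i, 1])
  }, logical(1)))
  n_tail <- sum(coding > model$tm_exon_index)
  list(tail_exon_count = as.integer(n_tail), extra_exon = n_tail >= 3L)
}

#' Locate the exon encoding a transmembrane span
#'
#' Maps the central residue of a transmembrane span (1-based protein
#' coordinates) to its coding-nucleotide offset and finds the exon whose
#' CDS covers it.  The midpoint is used because hydropathy-based TM
#' detection can shift the span bounds by a residue or two; the middle of
#' the span is insensitive to that slop.
#'
#' @param model A `gene_model`.
#' @param tm_span Length-2 vector `c(start, end)` of 1-based residue
#'   positions, e.g. from [find_tm()].
#' @return 1-based exon index (in transcription order).
#' @export
infer_tm_exon <- function(model, tm_span) {
  stopifnot(inherits(model, "gene_model"), length(tm_span) >= 2L)
  mid <- (as.integer(tm_span[1]) + as.integer(tm_span[2])) %/% 2L
  offset <- (mid - 1L) * 3L  # 0-based nt into the CDS
  lens <- model$cds[, 2] - model$cds[, 1]
  ends <- cumsum(lens)
  seg <- which(offset < ends)[1]
  if (is.na(seg)) {
    stop("TM residue ", mid, " beyond the CDS of '", model$gene_id, "'")
  }
  cds_iv <- model$cds[seg, , drop = FALSE]
  idx <- which(model$exons[, 1] <= cds_iv[1, 1] &
                 model$exons[, 2] >= cds_iv[1, 2])
  if (length(idx) == 0L) {
    stop("no exon contains CDS segment ", seg, " of '", model$gene_id, "'")
  }
  as.integer(idx[1])
}
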