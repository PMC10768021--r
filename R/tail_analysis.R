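# Transmembrane detection and cytoplasmic-tail feature extraction.

TM_WINDOW <- 19L
TM_MIN_MEAN <- 1.5

#' Locate the transmembrane segment
#'
#' Slides a 19-residue window over the sequence and reports the window with
#' the highest mean Kyte-Doolittle hydropathy, provided that mean is at
#' least 1.5; ties are broken toward the most C-terminal window (the tail
#' is defined downstream of the TM, so the later candidate is the
#' conservative choice).
#'
#' @param sequence Full-length mature sequence (string or `protein_record`).
#' @return Named integer vector `c(start, end)`, 1-based inclusive.
#' @export
find_tm <- function(sequence) {
  sequence <- as_aa_sequence(sequence)
  chars <- aa_chars(sequence)
  n <- length(chars)
  if (n < TM_WINDOW) stop("no TM segment: sequence shorter than ", TM_WINDOW)
  kd <- unname(KYTE_DOOLITTLE[chars])
  kd[is.na(kd)] <- 0
  cs <- c(0, cumsum(kd))
  means <- (cs[(TM_WINDOW + 1L):(n + 1L)] - cs[1:(n - TM_WINDOW + 1L)]) /
    TM_WINDOW
  best <- max(means)
  if (best < TM_MIN_MEAN) stop("no TM segment: max window hydropathy ",
                               round(best, 2), " < ", TM_MIN_MEAN)
  start <- max(which(means >= best - 1e-12))  # most C-terminal tie
  c(start = start, end = start + TM_WINDOW - 1L)
}

#' Zinc-clasp motif of a cytoplasmic tail
#'
#' Searches the tail for the LCK-binding clasp motif with precedence
#' CxC > CxH > CxF (histidine can substitute for cysteine in tetrahedral
#' zinc coordination; the CxF variant marks the sturgeon CD4-2f gene).
#' Also reports whether the motif is immediately preceded by a tyrosine, a
#' conserved feature of CD4 in primitive species.
#'
#' @param tail Tail sequence.
#' @return List with `type` (`"CxC"`, `"CxH"`, `"CxF"` or `"none"`),
#'   `position` (1-based start of the first match, or `NA`) and
#'   `preceding_tyr`.
#' @export
clasp_motif <- function(tail) {
  tail <- as_aa_sequence(tail)
  for (pat in list(.clasp_cxc, .clasp_cxh, .clasp_cxf)) {
    hits <- scan_motif(tail, pat)
    if (nrow(hits) > 0L) {
      pos <- hits$start[1]
      return(list(type = pat$name, position = pos,
                  preceding_tyr = pos > 1L &&
                    substr(tail, pos - 1L, pos - 1L) == "Y"))
    }
  }
  list(type = "none", position = NA_integer_, preceding_tyr = FALSE)
}

#' Maximal EP-repeat length
#'
#' Largest n such that (EP)^n occurs as a contiguous substring; the acidic
#' EP stretch at the end of the mammalian LAG-3 tail scores n = 7.
#'
#' @param tail Tail sequence.
#' @return Non-negative integer.
#' @examples
#' ep_repeat("EPEPEPEPEPEPEPEQL")  # 7
#' @export
ep_repeat <- function(tail) {
  tail <- as_aa_sequence(tail)
  m <- gregexpr("(?:EP)+", tail)[[1]]
  if (m[1] == -1L) return(0L)
  as.integer(max(attr(m, "match.length")) %/% 2L)
}

#' Acidic fraction of the tail end
#'
#' Fraction of D/E residues over the final `min(window, length)` residues.
#' The default window of 17 is the length of the human LAG-3 EP-repeat
#' stretch, the one concrete exemplar of the acidic C-terminus.
#'
#' @param tail Tail sequence (length >= 1).
#' @param window Window length, default 17.
#' @return Fraction in [0, 1].
#' @export
acidic_fraction <- function(tail, window = 17L) {
  tail <- as_aa_sequence(tail)
  n <- nchar(tail)
  if (n < 1L) stop("tail must be non-empty")
  w <- min(as.integer(window), n)
  seg <- aa_chars(substr(tail, n - w + 1L, n))
  sum(seg %in% c("D", "E")) / w
}

#' Amphipathic (hydrophobic-moment) score of a tail
#'
#' Maximum over all 11-residue windows of the hydrophobic moment of the
#' Eisenberg-scale hydrophobicity deviations at 100 degrees per residue
#' (one alpha-helical turn is ~3.6 residues), normalized by window length.
#' Centering on the window mean makes a homopolymer score exactly 0, so
#' the score measures periodic hydrophobic/hydrophilic alternation rather
#' than raw hydrophobicity.
#'
#' @param tail Tail sequence.
#' @return Non-negative score; 0 when the tail is shorter than 11 residues.
#' @export
amphipathic_score <- function(tail) {
  tail <- as_aa_sequence(tail)
  chars <- aa_chars(tail)
  n <- length(chars)
  w <- 11L
  if (n < w) return(0)
  h <- unname(EISENBERG[chars])
  h[is.na(h)] <- 0
  delta <- 100 * pi / 180
  angles <- delta * (0:(w - 1L))
  best <- 0
  for (i in 1:(n - w + 1L)) {
    hw <- h[i:(i + w - 1L)]
    hc <- hw - mean(hw)
    mu <- sqrt(sum(hc * sin(angles))^2 + sum(hc * cos(angles))^2) / w
    if (mu > best) best <- mu
  }
  best
}

#' Full cytoplasmic-tail feature profile
#'
#' Locates the transmembrane segment (unless a span is supplied), extracts
#' the tail downstream of it, and computes all tail features: clasp motif,
#' inhibitory-motif class, the CD4-1 C-terminal motif
#' P(K/Q)P(K/R)(A/G)FY(H/K/R) (searched only in the final 12 residues,
#' where it is length-conserved), EP-repeat, acidic fraction, amphipathic
#' score, and whether the tail starts with basic residues.
#'
#' @param sequence Full-length sequence (string or `protein_record`).
#' @param tail_exon_count Optional tail exon count carried through from
#'   [tail_structure()].
#' @param tm Optional precomputed TM span `c(start, end)`; when `NULL`,
#'   [find_tm()] is run.
#' @return Object of class `tail_profile`.
#' @export
profile_tail <- function(sequence, tail_exon_count = NA_integer_, tm = NULL) {
  sequence <- as_aa_sequence(sequence)
  if (is.null(tm)) tm <- find_tm(sequence)
  tail <- substr(sequence, tm[2] + 1L, nchar(sequence))
  if (!nzchar(tail)) stop("empty cytoplasmic tail downstream of TM span")
  clasp <- clasp_motif(tail)
  n <- nchar(tail)
  cterm <- substr(tail, max(1L, n - 11L), n)
  first5 <- aa_chars(substr(tail, 1L, min(5L, n)))
  structure(list(
    tm_span = c(start = unname(tm[1]), end = unname(tm[2])),
    tail = tail,
    clasp = clasp$type,
    clasp_pos = clasp$position,
    preceding_tyr = clasp$preceding_tyr,
    inhibitory = classify_inhibitory_motif(tail),
    fxxl_4mer = nrow(scan_motif(tail, .fxxl)) > 0L,
    cd41_cterm_motif = nrow(scan_motif(cterm, .cd41_cterm)) > 0L,
    ep_repeat_n = ep_repeat(tail),
    acidic_fraction = acidic_fraction(tail),
    amphipathic_score = amphipathic_score(tail),
    basic_start = any(first5 %in% c("K", "R")),
    tail_exon_count = as.integer(tail_exon_count)
  ), class = "tail_profile")
}

#' @export
print.tail_profile <- function(x, ...) {
  cat("<tail_profile> TM ", x$tm_span[1], "-", x$tm_span[2],
      ", tail ", nchar(x$tail), " aa, clasp ", x$clasp,
      ", inhibitory ", x$inhibitory, "\n", sep = "")
  invisible(x)
}
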