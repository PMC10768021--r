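# Ig-like domain detection in CD4/LAG-3 ectodomains.
#
# A candidate domain is a pair of cysteines (the B- and F-strand pair of an
# Ig-like fold) spaced 40-80 residues apart.  Candidates are resolved
# greedily left to right, ties broken by the smaller spacing, so detection
# is deterministic.  Category assignment:
#   * C2 when the F-strand cysteine carries the unusual WxC signature of
#     the family's D2/D4 domains (W two residues before the cysteine);
#   * V when at least 3 of 6 V-set start-consensus residues are present
#     ((I/V) at +3, (F/Y) at +4, G at +8, (A/V) at +11, L at +13, P at +14
#     relative to the reported domain start, which sits 15 residues before
#     the B-strand cysteine);
#   * degenerate otherwise.

CYS_SPACING_MIN <- 40L
CYS_SPACING_MAX <- 80L

#' Detect Ig-like domains in an ectodomain sequence
#'
#' @param sequence Ectodomain amino-acid sequence (string or
#'   `protein_record`).
#' @return Data frame with one row per detected domain: `label` (D1..D4,
#'   then "extra"), `category` (`"V"`, `"C2"`, `"degenerate"`), `start`,
#'   `end` (1-based residue bounds), `cys_b`, `cys_f`, `wxc`.  Zero rows
#'   when nothing is detected.
#' @export
detect_domains <- function(sequence) {
  sequence <- as_aa_sequence(sequence)
  chars <- aa_chars(sequence)
  n <- length(chars)
  empty <- data.frame(label = character(0), category = character(0),
                      start = integer(0), end = integer(0),
                      cys_b = integer(0), cys_f = integer(0),
                      wxc = logical(0), stringsAsFactors = FALSE)
  if (n < 60L) return(empty)
  cys <- which(chars == "C")
  rows <- list()
  p <- 1L
  for (b in cys) {
    if (b < p) next
    spacing <- cys - b
    cand <- cys[spacing >= CYS_SPACING_MIN & spacing <= CYS_SPACING_MAX]
    if (length(cand) == 0L) next
    f <- cand[which.min(cand - b)]  # smallest spacing wins ties
    start <- max(1L, b - 15L)
    end <- min(n, f + 2L)
    wxc <- f >= 3L && chars[f - 2L] == "W"
    category <- if (wxc) {
      "C2"
    } else if (v_consensus_count(chars, start) >= 3L) {
      "V"
    } else {
      "degenerate"
    }
    rows[[length(rows) + 1L]] <- data.frame(
      label = NA_character_, category = category,
      start = start, end = end, cys_b = b, cys_f = f, wxc = wxc,
      stringsAsFactors = FALSE
    )
    p <- f + 1L
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out$label <- ifelse(seq_len(nrow(out)) <= 4L,
                      paste0("D", seq_len(nrow(out))), "extra")
  out
}

# V-set start consensus: offsets are relative to the domain start residue
# (1-based): +3 (I/V), +4 (F/Y), +8 G, +11 (A/V), +13 L, +14 P.
v_consensus_count <- function(chars, start) {
  at <- function(off, allowed) {
    i <- start + off
    i <= length(chars) && chars[i] %in% allowed
  }
  sum(at(3L, c("I", "V")), at(4L, c("F", "Y")), at(8L, "G"),
      at(11L, c("A", "V")), at(13L, "L"), at(14L, "P"))
}

#' Architecture string of a domain list
#'
#' @param domains Output of [detect_domains()], or a character vector of
#'   categories.
#' @return List of class `architecture` with `categories` and `string`
#'   (hyphen-joined; degenerate domains rendered as `"V*"`), e.g.
#'   `"V-C2-V-C2"` for the canonical four-domain ectodomain.
#' @export
architecture_string <- function(domains) {
  categories <- if (is.data.frame(domains)) domains$category else domains
  shown <- vapply(categories, function(cat) {
    switch(cat, V = "V", C2 = "C2", degenerate = "V*",
           stop("unknown domain category '", cat, "'"))
  }, character(1), USE.NAMES = FALSE)
  structure(list(categories = categories,
                 string = paste(shown, collapse = "-")),
            class = "architecture")
}

#' @export
print.architecture <- function(x, ...) {
  cat("<architecture> ", if (nzchar(x$string)) x$string else "(empty)", "\n",
      sep = "")
  invisible(x)
}

#' CxxC motif in the membrane-proximal linker
#'
#' Tests the region between the last Ig-like domain and the transmembrane
#' segment for the CxxC motif that marks the hinge of reduced-ectodomain
#' CD4-2 molecules.  Only the stated region is scanned: a CxxC inside a
#' domain does not count.
#'
#' @param sequence Full or ectodomain sequence.
#' @param linker_start,linker_end 1-based residue bounds of the linker
#'   region (typically last domain `end + 1` to TM `start - 1`).
#' @return List with `present` (logical) and `position` (1-based start of
#'   the first match in full-sequence coordinates, or `NA`).
#' @export
linker_cxxc <- function(sequence, linker_start, linker_end) {
  sequence <- as_aa_sequence(sequence)
  linker_start <- max(1L, as.integer(linker_start))
  linker_end <- min(nchar(sequence), as.integer(linker_end))
  if (linker_end - linker_start + 1L < 4L) {
    return(list(present = FALSE, position = NA_integer_))
  }
  region <- substr(sequence, linker_start, linker_end)
  hits <- scan_motif(region, .cxxc)
  if (nrow(hits) == 0L) {
    list(present = FALSE, position = NA_integer_)
  } else {
    list(present = TRUE, position = linker_start + hits$start[1] - 1L)
  }
}
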