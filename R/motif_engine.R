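# Degenerate amino-acid motif grammar, scanner, and start-codon context rule.
#
# Pattern grammar: an upper-case residue letter is a singleton position,
# "x" is a wildcard standing for any of the 20 standard residues, and a
# bracketed class such as "[FY]" allows any listed residue.  The unknown
# residue X never satisfies any position, wildcard included.

#' Compile a degenerate motif pattern
#'
#' Parses a pattern string such as `"Cx[CH]"` (the CD4 zinc-clasp motif
#' Cx(C/H)) or `"[FY]xxL[DE]"` (the LAG-3 ITIM-like motif) into an ordered
#' list of allowed-residue sets.
#'
#' @param spec Pattern string. Upper-case letters are fixed residues, `x`
#'   matches any of the 20 standard amino acids, `[..]` encloses a residue
#'   class.
#' @param name Optional motif name carried on the compiled pattern.
#' @return An object of class `motif_pattern`: a list with `name` and
#'   `positions` (a list of character vectors, one per motif position).
#' @examples
#' p <- compile_pattern("Cx[CH]", name = "zinc_clasp")
#' length(p$positions)  # 3
#' @export
compile_pattern <- function(spec, name = spec) {
  if (!is.character(spec) || length(spec) != 1L || !nzchar(spec)) {
    stop("pattern spec must be a non-empty string")
  }
  chars <- strsplit(spec, "", fixed = TRUE)[[1]]
  positions <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "x") {
      positions[[length(positions) + 1L]] <- AA20
      i <- i + 1L
    } else if (ch == "[") {
      j <- i + 1L
      cls <- character(0)
      while (j <= length(chars) && chars[j] != "]") {
        if (!chars[j] %in% AA20) {
          stop("illegal residue '", chars[j], "' in class at position ", j)
        }
        cls <- c(cls, chars[j])
        j <- j + 1L
      }
      if (j > length(chars)) stop("unbalanced bracket in pattern '", spec, "'")
      if (length(cls) == 0L) stop("empty residue class in pattern '", spec, "'")
      positions[[length(positions) + 1L]] <- unique(cls)
      i <- j + 1L
    } else if (ch %in% AA20) {
      positions[[length(positions) + 1L]] <- ch
      i <- i + 1L
    } else {
      stop("illegal character '", ch, "' in pattern '", spec, "'")
    }
  }
  if (length(positions) == 0L) stop("pattern compiles to zero positions")
  structure(list(name = name, positions = positions), class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat("<motif_pattern> ", x$name, " (", length(x$positions), " positions)\n",
      sep = "")
  invisible(x)
}

pattern_regex <- function(pattern) {
  paste0(vapply(pattern$positions, function(p) {
    if (length(p) == 1L) p else paste0("[", paste(p, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' Scan a sequence for a degenerate motif
#'
#' Reports every match of a compiled (or compilable) pattern, overlapping
#' matches included, in ascending start order.  Positions are 1-based. The
#' unknown residue X fails every position class, including the wildcard.
#'
#' @param sequence Amino-acid sequence (string or `protein_record`).
#' @param pattern A `motif_pattern` or a pattern string.
#' @return A data frame with columns `motif_name`, `start` (1-based) and
#'   `matched`; zero rows when there is no match.
#' @examples
#' scan_motif("RFSALE", "[FY]xxL[DE]")  # one hit at position 2
#' @export
scan_motif <- function(sequence, pattern) {
  if (is.character(pattern)) pattern <- compile_pattern(pattern)
  stopifnot(inherits(pattern, "motif_pattern"))
  sequence <- as_aa_sequence(sequence)
  k <- length(pattern$positions)
  empty <- data.frame(motif_name = character(0), start = integer(0),
                      matched = character(0), stringsAsFactors = FALSE)
  if (nchar(sequence) < k) return(empty)
  # lookahead regex so that overlapping occurrences are all reported
  rx <- paste0("(?=(", pattern_regex(pattern), "))")
  m <- gregexpr(rx, sequence, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  starts <- as.integer(m)
  data.frame(
    motif_name = pattern$name,
    start = starts,
    matched = substring(sequence, starts, starts + k - 1L),
    stringsAsFactors = FALSE
  )
}

#' The motif catalogue of the CD4/LAG-3 family
#'
#' Returns the catalogue of degenerate motifs used throughout the pipeline,
#' read from the TSV shipped with the package (columns `name`, `pattern`,
#' `note`).  The same file is the catalogue format accepted by downstream
#' tooling.
#'
#' @param path Optional path to a catalogue TSV; defaults to the shipped one.
#' @return Data frame with columns `name`, `pattern`, `note`.
#' @export
motif_catalogue <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "motif_catalogue.tsv", package = "cd4lag3")
  }
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Kozak context verdict for a start codon
#'
#' Judges the translational context of an ATG from its 7-nucleotide
#' neighbourhood `NNN-ATG-N`.  The context is favorable when the -3
#' position (first character) is a purine (A/G) or the +4 position (last
#' character) is G; either strong position suffices.
#'
#' @param heptamer 7-character nucleotide string with ATG at positions 4-6
#'   (case-insensitive).
#' @return A list of class `kozak_context` with `heptamer` and `verdict`
#'   (`"favorable"` or `"unfavorable"`).
#' @examples
#' kozak_verdict("cagATGt")$verdict  # "unfavorable"
#' kozak_verdict("cccATGg")$verdict  # "favorable"
#' @export
kozak_verdict <- function(heptamer) {
  if (!is.character(heptamer) || length(heptamer) != 1L ||
      nchar(heptamer) != 7L) {
    stop("heptamer must be a single 7-character string")
  }
  up <- toupper(heptamer)
  if (substr(up, 4L, 6L) != "ATG") {
    stop("no ATG core at positions 4-6 of '", heptamer, "'")
  }
  minus3 <- substr(up, 1L, 1L)
  plus4 <- substr(up, 7L, 7L)
  verdict <- if (minus3 %in% c("A", "G") || plus4 == "G") {
    "favorable"
  } else {
    "unfavorable"
  }
  structure(list(heptamer = heptamer, verdict = verdict),
            class = "kozak_context")
}

#' Classify an inhibitory tail motif
#'
#' Searches a cytoplasmic-tail (sub)sequence for inhibitory-motif classes in
#' fixed precedence order: the canonical ITIM (I/V/L)xYxx(L/V) first, then
#' the ITIM-like (F/Y)xxL(D/E) of LAG-3, then YxxM.
#'
#' @param segment Tail sequence or subsequence.
#' @return One of `"canonical_ITIM"`, `"ITIM_like"`, `"YxxM"`, `"none"`.
#' @examples
#' classify_inhibitory_motif("FSALE")   # "ITIM_like"
#' classify_inhibitory_motif("VAYAQL")  # "canonical_ITIM"
#' @export
classify_inhibitory_motif <- function(segment) {
  segment <- as_aa_sequence(segment)
  if (nrow(scan_motif(segment, .itim_canonical)) > 0L) return("canonical_ITIM")
  if (nrow(scan_motif(segment, .itim_like)) > 0L) return("ITIM_like")
  if (nrow(scan_motif(segment, .yxxm)) > 0L) return("YxxM")
  "none"
}

# Pre-compiled patterns used in hot paths.
.itim_canonical <- compile_pattern("[IVL]xYxx[LV]", name = "canonical_ITIM")
.itim_like <- compile_pattern("[FY]xxL[DE]", name = "ITIM_like")
.fxxl <- compile_pattern("FxxL", name = "FxxL")
.yxxm <- compile_pattern("YxxM", name = "YxxM")
.clasp_cxc <- compile_pattern("CxC", name = "CxC")
.clasp_cxh <- compile_pattern("CxH", name = "CxH")
.clasp_cxf <- compile_pattern("CxF", name = "CxF")
.cxxc <- compile_pattern("CxxC", name = "CxxC")
.cd41_cterm <- compile_pattern("P[KQ]P[KR][AG]FY[HKR]", name = "cd41_cterm")
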