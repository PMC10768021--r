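# Readers/writers for the formats the pipeline touches, and the coordinate
# conventions shared by every module:
#   * protein sequences: upper case, 20-letter alphabet plus X, no gaps
#   * gene-model intervals: 0-based half-open, ordered 5'->3' in
#     transcription order (minus-strand models are normalized at parse time)
#   * GFF3 on disk stays 1-based closed; conversion happens at this boundary

#' Construct a protein record
#'
#' @param id Record identifier.
#' @param sequence Amino-acid sequence over the 20-letter alphabet plus X.
#' @param species Optional species tag.
#' @return Object of class `protein_record`.
#' @export
protein_record <- function(id, sequence, species = NA_character_) {
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("protein_record '", id, "': empty sequence")
  bad <- setdiff(unique(aa_chars(sequence)), c(AA20, "X"))
  if (length(bad) > 0L) {
    stop("protein_record '", id, "': illegal residue(s) ",
         paste(bad, collapse = ", "))
  }
  structure(list(id = id, species = species, sequence = sequence),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat("<protein_record> ", x$id, " (", nchar(x$sequence), " aa)\n", sep = "")
  invisible(x)
}

#' Read a protein FASTA file
#'
#' Record ids are the first whitespace-delimited token of the header line.
#' Sequences must be over the 20-letter amino-acid alphabet plus X; gaps,
#' internal whitespace or other characters raise a parse error naming the
#' offending line.
#'
#' @param path Path to a FASTA file.
#' @return Named list of `protein_record` objects (possibly empty).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) return(structure(list(), names = character(0)))
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop("FASTA parse error at line ", nonblank[1],
         ": expected a '>' header before sequence data")
  }
  for (i in nonblank) {
    ln <- trimws(lines[i])
    if (startsWith(ln, ">")) next
    bad <- setdiff(unique(aa_chars(toupper(lines[i]))), c(AA20, "X"))
    if (length(bad) > 0L) {
      stop("FASTA parse error at line ", i, ": illegal residue(s) ",
           paste(shQuote(bad), collapse = ", "))
    }
  }
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) return(structure(list(), names = character(0)))
  headers <- names(set)
  ids <- vapply(strsplit(headers, "\\s+"), `[[`, character(1), 1L)
  records <- lapply(seq_along(set), function(i) {
    protein_record(ids[i], as.character(set[[i]]))
  })
  names(records) <- ids
  records
}

#' Construct and validate a gene model
#'
#' Intervals are 0-based half-open, non-overlapping, and listed 5'->3' in
#' transcription order (on the minus strand the first listed exon has the
#' highest genomic coordinates).  Every CDS interval must lie inside some
#' exon.  A total CDS length not divisible by 3 sets the `cds_incomplete`
#' flag (with a warning) rather than failing: intron phases remain
#' computable for partial models.
#'
#' @param gene_id,seq_id Identifiers.
#' @param strand `"+"` or `"-"`.
#' @param exons,cds Two-column matrices (start, end) of 0-based half-open
#'   intervals in transcription order.
#' @param tm_exon_index Optional 1-based index (in transcription order) of
#'   the exon encoding the transmembrane segment.
#' @return Object of class `gene_model`.
#' @export
gene_model <- function(gene_id, seq_id, strand, exons, cds,
                       tm_exon_index = NA_integer_) {
  exons <- as_interval_matrix(exons, "exons")
  cds <- as_interval_matrix(cds, "cds")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  check_transcription_order(exons, strand, gene_id, "exon")
  check_transcription_order(cds, strand, gene_id, "CDS")
  for (i in seq_len(nrow(cds))) {
    inside <- any(cds[i, 1] >= exons[, 1] & cds[i, 2] <= exons[, 2])
    if (!inside) {
      stop("gene_model '", gene_id, "': CDS interval [", cds[i, 1], ",",
           cds[i, 2], ") not contained in any exon")
    }
  }
  total <- sum(cds[, 2] - cds[, 1])
  incomplete <- (total %% 3L) != 0L
  if (incomplete) {
    warning("gene_model '", gene_id, "': CDS length ", total,
            " not divisible by 3; flagging model as cds_incomplete")
  }
  structure(list(gene_id = gene_id, seq_id = seq_id, strand = strand,
                 exons = exons, cds = cds,
                 tm_exon_index = as.integer(tm_exon_index),
                 cds_incomplete = incomplete),
            class = "gene_model")
}

as_interval_matrix <- function(x, what) {
  x <- matrix(as.numeric(x), ncol = 2,
              dimnames = list(NULL, c("start", "end")))
  if (nrow(x) == 0L) stop("gene model needs at least one ", what, " interval")
  if (any(x[, 1] < 0) || any(x[, 2] <= x[, 1])) {
    stop("invalid ", what, " interval: need 0 <= start < end (half-open)")
  }
  x
}

check_transcription_order <- function(m, strand, gene_id, what) {
  if (nrow(m) < 2L) return(invisible())
  ok <- if (strand == "+") {
    all(diff(m[, 1]) > 0) && all(m[-nrow(m), 2] <= m[-1, 1])
  } else {
    all(diff(m[, 1]) < 0) && all(m[-1, 2] <= m[-nrow(m), 1])
  }
  if (!ok) {
    stop("gene_model '", gene_id, "': ", what,
         " intervals overlap or are not in transcription order")
  }
  invisible()
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model> ", x$gene_id, " on ", x$seq_id, " (", x$strand, "), ",
      nrow(x$exons), " exons, ", nrow(x$cds), " CDS segments",
      if (isTRUE(x$cds_incomplete)) " [cds_incomplete]" else "", "\n",
      sep = "")
  invisible(x)
}

#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/exon/CDS features (via \pkg{rtracklayer}), converts the
#' on-disk 1-based closed coordinates to the internal 0-based half-open
#' convention, and reorders minus-strand features into transcription order,
#' so that downstream phase arithmetic is strand-free.
#'
#' @param path Path to a GFF3 file.
#' @return Named list of `gene_model` objects, one per mRNA.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  ids <- if ("ID" %in% names(S4Vectors::mcols(gr))) {
    as.character(gr$ID)
  } else {
    rep(NA_character_, length(gr))
  }
  parents <- if ("Parent" %in% names(S4Vectors::mcols(gr))) {
    vapply(as.list(gr$Parent), function(p) {
      if (length(p) == 0L) NA_character_ else p[[1]]
    }, character(1))
  } else {
    rep(NA_character_, length(gr))
  }
  mrna_idx <- which(type %in% c("mRNA", "transcript"))
  models <- list()
  for (i in mrna_idx) {
    mrna_id <- ids[i]
    gene_id <- if (!is.na(parents[i])) parents[i] else mrna_id
    model <- build_model_from_granges(gr, type, parents, mrna_id, gene_id)
    models[[model$gene_id]] <- model
  }
  # genes written without an mRNA level: exons/CDS parented to the gene
  gene_idx <- which(type == "gene")
  for (i in gene_idx) {
    gid <- ids[i]
    if (gid %in% names(models)) next
    if (any(parents %in% gid & type %in% c("exon", "CDS"))) {
      models[[gid]] <- build_model_from_granges(gr, type, parents, gid, gid)
    }
  }
  models
}

build_model_from_granges <- function(gr, type, parents, parent_id, gene_id) {
  strip <- function(x) sub("^(gene:|mrna:|transcript:)", "", x)
  sel_exon <- which(type == "exon" & parents == parent_id)
  sel_cds <- which(type == "CDS" & parents == parent_id)
  if (length(sel_exon) == 0L && length(sel_cds) > 0L) sel_exon <- sel_cds
  if (length(sel_exon) == 0L) {
    stop("GFF3: no exon or CDS features for '", parent_id, "'")
  }
  strand <- as.character(GenomicRanges::strand(gr[sel_exon[1]]))
  if (!strand %in% c("+", "-")) strand <- "+"
  to_mat <- function(sel) {
    s <- GenomicRanges::start(gr[sel]) - 1L  # 1-based closed -> 0-based half-open
    e <- GenomicRanges::end(gr[sel])
    o <- order(s, decreasing = (strand == "-"))
    cbind(start = s[o], end = e[o])
  }
  gene_model(strip(gene_id), as.character(GenomicRanges::seqnames(gr[sel_exon[1]])),
             strand, to_mat(sel_exon),
             if (length(sel_cds) > 0L) to_mat(sel_cds) else to_mat(sel_exon))
}

#' Write evidence reports as JSON
#'
#' Serializes a list of `evidence_report` objects (see
#' [classify_pipeline()]) to a JSON array with stable key order; the file
#' round-trips losslessly through [read_report()].
#'
#' @param reports List of `evidence_report` objects (possibly empty).
#' @param path Output path.
#' @export
write_report <- function(reports, path) {
  payload <- lapply(unname(reports), report_to_list)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

report_to_list <- function(r) {
  stopifnot(inherits(r, "evidence_report"))
  list(
    gene_id = r$gene_id,
    label = r$label,
    scores = list(cd4 = r$cd4_score, lag3 = r$lag3_score),
    features = r$features,
    contributions = lapply(seq_len(nrow(r$contributions)), function(i) {
      as.list(r$contributions[i, , drop = FALSE])
    }),
    error = r$error
  )
}

#' Read evidence reports back from JSON
#'
#' @param path Path written by [write_report()].
#' @return List of `evidence_report` objects.
#' @export
read_report <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(payload, function(p) {
    contrib <- if (length(p$contributions) > 0L) {
      do.call(rbind, lapply(p$contributions, function(row) {
        data.frame(feature = row$feature, value = row$value,
                   lineage = row$lineage, points = row$points,
                   note = row$note, stringsAsFactors = FALSE)
      }))
    } else {
      empty_contributions()
    }
    features <- lapply(p$features, function(v) if (is.null(v)) NA else v)
    new_evidence_report(
      gene_id = p$gene_id, label = p$label,
      cd4_score = p$scores$cd4, lag3_score = p$scores$lag3,
      features = features, contributions = contrib,
      error = if (is.null(p$error)) NA_character_ else p$error
    )
  })
}
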