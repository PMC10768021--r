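# Expression evidence: TPM computation, the thymus-dominance criterion,
# and qPCR relative quantification against a calibrator tissue.

#' TPM from read counts
#'
#' Length-corrected read rates scaled to sum to one million:
#' `rate_i = count_i / length_i; TPM_i = rate_i / sum(rate) * 1e6`.
#'
#' @param counts Non-negative read counts (not all zero).
#' @param effective_lengths Positive effective transcript lengths.
#' @return Numeric vector of TPM values summing to 1e6.
#' @export
tpm_from_counts <- function(counts, effective_lengths) {
  if (length(counts) != length(effective_lengths)) {
    stop("counts and effective_lengths differ in length")
  }
  if (any(effective_lengths <= 0)) stop("effective lengths must be > 0")
  if (any(counts < 0)) stop("counts must be >= 0")
  if (all(counts == 0)) stop("all counts are zero; TPM undefined")
  rate <- counts / effective_lengths
  tpm <- rate / sum(rate) * 1e6
  names(tpm) <- names(counts)
  tpm
}

#' Read a gene x tissue expression table
#'
#' @param path TSV with a `gene` column and one column per tissue.
#' @return Numeric matrix, genes as row names.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene" %in% names(df)) stop("expression TSV needs a 'gene' column")
  m <- as.matrix(df[, setdiff(names(df), "gene"), drop = FALSE])
  rownames(m) <- df$gene
  storage.mode(m) <- "double"
  m
}

#' Tissue-dominance criterion
#'
#' The expression evidence of the pipeline: a gene is called dominant in
#' the test tissue when its expression there is at least `threshold` times
#' the reference-tissue value.  The default threshold of 5 operationalizes
#' the five-fold thymus-over-spleen excess observed for CD4; a pseudocount
#' of 0.01 TPM guards against near-zero reference values.
#'
#' @param matrix Gene x tissue matrix (e.g. from [read_expression()]).
#' @param gene Gene (row) name.
#' @param test_tissue,ref_tissue Column names; defaults thymus vs spleen.
#' @param threshold Dominance ratio threshold (default 5).
#' @param pseudocount Added to the reference value (default 0.01 TPM).
#' @return List with `ratio` and `dominant`.
#' @export
tissue_dominance <- function(matrix, gene, test_tissue = "thymus",
                             ref_tissue = "spleen", threshold = 5,
                             pseudocount = 0.01) {
  if (!gene %in% rownames(matrix)) stop("gene '", gene, "' not in matrix")
  missing_tissue <- setdiff(c(test_tissue, ref_tissue), colnames(matrix))
  if (length(missing_tissue) > 0L) {
    stop("tissue(s) not in matrix: ", paste(missing_tissue, collapse = ", "))
  }
  ratio <- matrix[gene, test_tissue] / (matrix[gene, ref_tissue] + pseudocount)
  list(ratio = unname(ratio), dominant = unname(ratio >= threshold))
}

#' Read a long-format qPCR quantity table
#'
#' @param path TSV with columns `gene`, `tissue`, `replicate`,
#'   `target_amount`, `housekeeping_amount`.
#' @return Data frame.
#' @export
read_qpcr <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("gene", "tissue", "replicate", "target_amount",
              "housekeeping_amount")
  miss <- setdiff(needed, names(df))
  if (length(miss) > 0L) {
    stop("qPCR TSV lacks column(s): ", paste(miss, collapse = ", "))
  }
  df
}

#' qPCR relative quantification against a calibrator tissue
#'
#' Per replicate the target amount is divided by the housekeeping amount;
#' per gene the tissue means of these normalized amounts are then divided
#' by the calibrator-tissue mean, so the calibrator tissue reads exactly 1
#' for every gene.
#'
#' @param table Long-format table as from [read_qpcr()].
#' @param calibrator_tissue Calibrator tissue (default `"spleen"`).
#' @return Gene x tissue matrix of relative expression values.
#' @export
qpcr_relative <- function(table, calibrator_tissue = "spleen") {
  needed <- c("gene", "tissue", "target_amount", "housekeeping_amount")
  stopifnot(all(needed %in% names(table)))
  if (any(table$housekeeping_amount <= 0)) {
    stop("housekeeping amounts must be > 0")
  }
  if (any(table$target_amount <= 0)) stop("target amounts must be > 0")
  table$norm <- table$target_amount / table$housekeeping_amount
  agg <- stats::aggregate(norm ~ gene + tissue, data = table, FUN = mean)
  genes <- unique(table$gene)
  tissues <- unique(table$tissue)
  if (!calibrator_tissue %in% tissues) {
    stop("calibrator tissue '", calibrator_tissue, "' absent from table")
  }
  m <- matrix(NA_real_, nrow = length(genes), ncol = length(tissues),
              dimnames = list(genes, tissues))
  m[cbind(match(agg$gene, genes), match(agg$tissue, tissues))] <- agg$norm
  cal <- m[, calibrator_tissue]
  if (any(is.na(cal))) {
    stop("calibrator tissue missing for gene(s): ",
         paste(genes[is.na(cal)], collapse = ", "))
  }
  sweep(m, 1, cal, "/")
}
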