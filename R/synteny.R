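# Gene-order evidence: the ancestral head-to-tail LAG-3 -> CD4 tandem
# orientation, evaluated on a BED-like gene-order table.
# Coordinates in the table are 0-based half-open.

#' Read a gene-order (synteny) table
#'
#' @param path TSV with columns `gene`, `seq_id`, `start`, `end`, `strand`
#'   (0-based half-open coordinates).
#' @return Data frame sorted by (`seq_id`, `start`).
#' @export
read_synteny <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("gene", "seq_id", "start", "end", "strand")
  miss <- setdiff(needed, names(df))
  if (length(miss) > 0L) {
    stop("synteny TSV lacks column(s): ", paste(miss, collapse = ", "))
  }
  df[order(df$seq_id, df$start), , drop = FALSE]
}

#' Head-to-tail tandem orientation of two genes
#'
#' Tests whether `downstream_gene` lies downstream of `upstream_gene` in
#' transcription orientation on the same sequence and strand, with at most
#' `max_intervening` annotated genes between them.  The default of two
#' intervening genes accommodates the lungfish-type locus in which a third
#' family gene sits between LAG-3 and CD4, as well as stray pseudogene
#' fragments.  A gene missing from the table gives status
#' `"not_evaluable"`, which callers must treat as absent evidence, not as a
#' violated orientation.
#'
#' @param table Gene-order table as from [read_synteny()].
#' @param upstream_gene,downstream_gene Gene names (defaults `"LAG-3"`,
#'   `"CD4"`).
#' @param max_intervening Maximum number of annotated genes allowed between
#'   the pair (default 2).
#' @return List with `status` (`"head_to_tail"`, `"violated"`,
#'   `"not_evaluable"`), `verdict` (`TRUE`/`FALSE`/`NA`) and
#'   `n_intervening`.
#' @export
head_to_tail <- function(table, upstream_gene = "LAG-3",
                         downstream_gene = "CD4", max_intervening = 2L) {
  up <- table[table$gene == upstream_gene, , drop = FALSE]
  down <- table[table$gene == downstream_gene, , drop = FALSE]
  if (nrow(up) == 0L || nrow(down) == 0L) {
    return(list(status = "not_evaluable", verdict = NA,
                n_intervening = NA_integer_))
  }
  for (i in seq_len(nrow(up))) {
    for (j in seq_len(nrow(down))) {
      v <- pair_head_to_tail(table, up[i, ], down[j, ], max_intervening)
      if (isTRUE(v$verdict)) return(v)
    }
  }
  pair_head_to_tail(table, up[1, ], down[1, ], max_intervening)
}

pair_head_to_tail <- function(table, up, down, max_intervening) {
  violated <- function(n = NA_integer_) {
    list(status = "violated", verdict = FALSE, n_intervening = n)
  }
  if (up$seq_id != down$seq_id || up$strand != down$strand) return(violated())
  if (up$strand == "+") {
    if (down$start < up$end) return(violated())
    lo <- up$end; hi <- down$start
  } else {
    if (up$start < down$end) return(violated())
    lo <- down$end; hi <- up$start
  }
  between <- table$seq_id == up$seq_id &
    table$start >= lo & table$end <= hi &
    !(table$gene %in% c(up$gene, down$gene))
  n <- sum(between)
  if (n > max_intervening) return(violated(n))
  list(status = "head_to_tail", verdict = TRUE, n_intervening = as.integer(n))
}

#' Role of one gene in a head-to-tail pair
#'
#' Determines whether `gene` is the upstream or the downstream member of a
#' tandem pair with any other gene in the table (same sequence and strand,
#' within `max_intervening`).  When partners exist on both sides - the
#' situation of a gene inserted between LAG-3 and CD4 - the role is
#' `"none"`; a gene absent from the table is `"unknown"`.
#'
#' @inheritParams head_to_tail
#' @param gene Gene name to evaluate.
#' @return `"upstream"`, `"downstream"`, `"none"` or `"unknown"`.
#' @export
synteny_role <- function(table, gene, max_intervening = 2L) {
  self <- table[table$gene == gene, , drop = FALSE]
  if (nrow(self) == 0L) return("unknown")
  self <- self[1, ]
  others <- table[table$gene != gene & table$seq_id == self$seq_id &
                    table$strand == self$strand, , drop = FALSE]
  is_up <- is_down <- FALSE
  for (k in seq_len(nrow(others))) {
    if (isTRUE(pair_head_to_tail(table, self, others[k, ],
                                 max_intervening)$verdict)) {
      is_up <- TRUE
    }
    if (isTRUE(pair_head_to_tail(table, others[k, ], self,
                                 max_intervening)$verdict)) {
      is_down <- TRUE
    }
  }
  if (is_up && is_down) return("none")
  if (is_up) return("upstream")
  if (is_down) return("downstream")
  "none"
}
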