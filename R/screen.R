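#' Build a gene screening list
#'
#' Targeted list of genes of interest: established neurodegenerative-disease
#' genes ("neurogenes") and genes reported in CNV analyses of comparable
#' cohorts. Symbols are uppercased; matching is by normalized symbol string
#' against the gene-model table used for annotation (no alias resolution).
#'
#' @param symbols Character vector of gene symbols (non-empty).
#' @param source Per-symbol source label, `"NEUROGENE"` or `"LITERATURE"`
#'   (recycled).
#' @return A data.frame `symbol`, `source`.
#' @export
gene_screen_list <- function(symbols, source = "NEUROGENE") {
  symbols <- toupper(trimws(as.character(symbols)))
  if (length(symbols) == 0 || any(!nzchar(symbols))) {
    stop("gene screen list must be non-empty with non-blank symbols")
  }
  source <- rep_len(as.character(source), length(symbols))
  if (!all(source %in% c("NEUROGENE", "LITERATURE"))) {
    stop("screen source labels must be NEUROGENE or LITERATURE")
  }
  unique(data.frame(symbol = symbols, source = source))
}

#' Read a gene screening list from a TSV
#'
#' Columns `symbol` and optionally `source`.
#'
#' @param path Path to the TSV.
#' @return Screen list data.frame (see [gene_screen_list()]).
#' @export
read_gene_screen_list <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"symbol" %in% names(tab)) stop("screen list must have a symbol column")
  src <- if ("source" %in% names(tab)) tab$source else "NEUROGENE"
  gene_screen_list(tab$symbol, src)
}

#' Screen annotated calls against a list of genes of interest
#'
#' Reports one candidate per call that overlaps at least one listed gene,
#' carrying the matched symbols and their source labels. No common-variant
#' hard filter is applied here: calls with high reference-database counts are
#' reported with their annotation so the report can label them benign rather
#' than silently dropping them.
#'
#' @param annotated Calls data.frame with a `genes` list-column.
#' @param screen Screen list from [gene_screen_list()].
#' @return Candidate data.frame: call columns plus `matched_genes` and
#'   `matched_sources` (list-columns) and `provenance = "GENE_SCREEN"`.
#' @export
screen_genes <- function(annotated, screen) {
  if (is.null(screen) || nrow(screen) == 0) {
    stop("gene screen list is empty")
  }
  stopifnot("genes" %in% names(annotated))
  matched <- lapply(annotated$genes, function(g) {
    g[toupper(g) %in% screen$symbol]
  })
  keep <- lengths(matched) > 0
  out <- annotated[keep, , drop = FALSE]
  out$matched_genes <- matched[keep]
  out$matched_sources <- lapply(out$matched_genes, function(g) {
    screen$source[match(toupper(g), screen$symbol)]
  })
  out$provenance <- rep("GENE_SCREEN", nrow(out))
  rownames(out) <- NULL
  out
}
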