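#' Find CNVs of the same copy number sharing genes across individuals
#'
#' Cohort-wide stage: after dropping calls completely localized within
#' `margin` bases of an autosome end, calls are grouped by overlapped gene and
#' exact copy number; groups supported by two or more distinct individuals are
#' reported, and groups backed by the identical set of member calls are
#' consolidated into one row whose `gene_set` lists all shared genes. The
#' `encompassing_*` columns give the union span of the member calls — the
#' largest encompassing region — which is the query used for case/control
#' cohort intersection.
#'
#' Intergenic shared CNVs are invisible to this stage by construction, since
#' grouping is keyed by gene. Two calls in one individual never form a group
#' (distinctness is by sample). Common-flagged calls are reported with their
#' annotation rather than hard-filtered, unless `drop_common = TRUE`.
#'
#' @param annotated Calls data.frame with a `genes` list-column (from
#'   [annotate_genes()] / [filter_calls()]); `is_common` is honoured when
#'   `drop_common = TRUE`.
#' @param chroms Chromosome table (see [chromosome_table()]).
#' @param margin Autosome-end margin in bases (default 2e6).
#' @param drop_common Drop `is_common` calls before grouping (default
#'   `FALSE`: annotate, don't filter).
#' @return Shared-group data.frame: `gene_set` (list-column), `genes`
#'   (comma-joined string), `copy_number`, `n_samples`, `sample_ids`
#'   (list-column), `chrom`, `encompassing_start`, `encompassing_end`,
#'   `member_rows` (list-column of row indices into `annotated`).
#' @export
shared_scan <- function(annotated, chroms, margin = 2e6, drop_common = FALSE) {
  empty <- data.frame(genes = character(), copy_number = integer(),
                      n_samples = integer(), chrom = character(),
                      encompassing_start = numeric(),
                      encompassing_end = numeric())
  empty$gene_set <- list()
  empty$sample_ids <- list()
  empty$member_rows <- list()
  if (nrow(annotated) == 0) return(empty)
  stopifnot("genes" %in% names(annotated))
  keep <- !within_autosome_end(annotated, chroms, margin)
  if (drop_common && "is_common" %in% names(annotated)) {
    keep <- keep & !annotated$is_common
  }
  idx <- which(keep)
  if (length(idx) == 0) return(empty)

  # explode to (call row, gene) pairs
  pairs <- do.call(rbind, lapply(idx, function(i) {
    g <- annotated$genes[[i]]
    if (length(g) == 0) return(NULL)
    data.frame(row = i, gene = g, cn = annotated$copy_number[i])
  }))
  if (is.null(pairs)) return(empty)

  groups <- split(pairs$row, paste(pairs$gene, pairs$cn, sep = "\r"))
  qual <- Filter(function(rows) {
    length(unique(annotated$sample_id[rows])) >= 2
  }, groups)
  if (length(qual) == 0) return(empty)

  # consolidate (gene, CN) groups backed by the identical member-call set
  member_key <- vapply(qual, function(rows) paste(sort(rows), collapse = ","), "")
  rows_out <- lapply(split(names(qual), member_key), function(keys) {
    gene_cn <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
    members <- qual[[keys[1]]]
    calls <- annotated[members, , drop = FALSE]
    gene_set <- sort(unique(gene_cn[, 1]))
    out <- data.frame(
      genes = paste(gene_set, collapse = ", "),
      copy_number = as.integer(gene_cn[1, 2]),
      n_samples = length(unique(calls$sample_id)),
      chrom = calls$chrom[1],
      encompassing_start = min(calls$start),
      encompassing_end = max(calls$end))
    out$gene_set <- list(gene_set)
    out$sample_ids <- list(sort(unique(calls$sample_id)))
    out$member_rows <- list(sort(members))
    out
  })
  out <- do.call(rbind, rows_out)
  out <- out[order(out$chrom, out$encompassing_start, out$copy_number), , drop = FALSE]
  rownames(out) <- NULL
  out
}
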