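#' Configuration for the call-filtering stage
#'
#' Defaults follow standard array-CNV practice: calls supported by at least 10
#' SNPs and at least 50 kb long are retained; adjacent same-state calls are
#' merged when the gap is at most 20% of the merged span (the upstream
#' caller's default merge heuristic); candidate loci entirely within 2 Mb of
#' an autosome end are dropped in the shared-CNV stage.
#'
#' @param min_snps Minimum supporting SNPs per call (default 10).
#' @param min_length Minimum call length in bases (default 50000).
#' @param merge_gap_fraction Maximum gap/span fraction for merging adjacent
#'   same-CN calls of one sample (default 0.2).
#' @param exclusion_regions Interval data.frame of regions to mask
#'   (telomeres, centromeres, segmental duplications, Ig/TCR loci), or `NULL`.
#' @param autosome_end_margin Margin in bases for the autosome-end rule
#'   (default 2e6).
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_snps = 10, min_length = 50000,
                          merge_gap_fraction = 0.2, exclusion_regions = NULL,
                          autosome_end_margin = 2e6) {
  stopifnot(min_snps >= 1, min_length >= 1,
            merge_gap_fraction >= 0, merge_gap_fraction <= 1,
            autosome_end_margin >= 0)
  structure(list(min_snps = min_snps, min_length = min_length,
                 merge_gap_fraction = merge_gap_fraction,
                 exclusion_regions = exclusion_regions,
                 autosome_end_margin = autosome_end_margin),
            class = "filter_config")
}

#' Quality-filter CNV calls by SNP support and length
#'
#' Retains exactly the calls with `n_snps >= min_snps` and length (computed as
#' `end - start + 1`) `>= min_length`; input order is preserved and surviving
#' rows are untouched.
#'
#' @param calls Calls data.frame.
#' @param config A [filter_config()].
#' @return Filtered calls data.frame.
#' @export
filter_quality <- function(calls, config = filter_config()) {
  keep <- calls$n_snps >= config$min_snps &
    interval_length(calls) >= config$min_length
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge adjacent same-state calls of the same sample
#'
#' Two calls of one sample with the same chromosome and copy number are merged
#' when `gap / span <= merge_gap_fraction`, where `gap = next_start - prev_end
#' - 1` and `span` is the length of the would-be merged call. The merged call
#' spans both inputs and sums their supporting-SNP counts. Merging repeats
#' until no further pair qualifies (fixpoint).
#'
#' @param calls Calls data.frame.
#' @param config A [filter_config()].
#' @return Calls data.frame with merged calls, sorted by sample, chromosome,
#'   start.
#' @export
merge_adjacent <- function(calls, config = filter_config()) {
  if (nrow(calls) == 0) return(calls)
  f <- config$merge_gap_fraction
  key <- paste(calls$sample_id, calls$chrom, calls$copy_number, sep = "\r")
  groups <- split(seq_len(nrow(calls)), key)
  merged <- lapply(groups, function(idx) {
    g <- calls[idx[order(calls$start[idx], calls$end[idx])], , drop = FALSE]
    repeat {
      changed <- FALSE
      i <- 1
      while (i < nrow(g)) {
        gap <- g$start[i + 1] - g$end[i] - 1
        span <- max(g$end[i + 1], g$end[i]) - g$start[i] + 1
        if (gap / span <= f) {
          g$end[i] <- max(g$end[i], g$end[i + 1])
          g$n_snps[i] <- g$n_snps[i] + g$n_snps[i + 1]
          g <- g[-(i + 1), , drop = FALSE]
          changed <- TRUE
        } else {
          i <- i + 1
        }
      }
      if (!changed) break
    }
    g
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$sample_id, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove calls overlapping exclusion regions
#'
#' Any call overlapping an exclusion region (telomere, centromere, segmental
#' duplication, Ig/TCR locus) by at least one base is removed — overlap, not
#' containment, is the criterion.
#'
#' @param calls Calls data.frame.
#' @param config A [filter_config()] whose `exclusion_regions` are applied;
#'   `NULL` regions leave the calls unchanged.
#' @return Filtered calls data.frame.
#' @export
apply_exclusions <- function(calls, config = filter_config()) {
  excl <- config$exclusion_regions
  if (is.null(excl) || nrow(excl) == 0 || nrow(calls) == 0) return(calls)
  hits <- GenomicRanges::findOverlaps(as_granges(calls), as_granges(excl))
  drop <- unique(S4Vectors::queryHits(hits))
  out <- if (length(drop)) calls[-drop, , drop = FALSE] else calls
  rownames(out) <- NULL
  out
}

#' Annotate calls with overlapping gene symbols
#'
#' Adds a `genes` list-column: for each call, the symbols of all genes whose
#' span overlaps the call by at least one base, ordered by genomic start.
#'
#' @param calls Calls data.frame.
#' @param genes Gene-model data.frame (`symbol`, `chrom`, `start`, `end`).
#' @return `calls` with a `genes` list-column.
#' @export
annotate_genes <- function(calls, genes) {
  gene_lists <- rep(list(character()), nrow(calls))
  if (nrow(calls) > 0 && nrow(genes) > 0) {
    ord <- order(genes$chrom, genes$start)
    genes <- genes[ord, , drop = FALSE]
    hits <- GenomicRanges::findOverlaps(as_granges(calls), as_granges(genes))
    by_call <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
    for (q in names(by_call)) {
      gene_lists[[as.integer(q)]] <- genes$symbol[sort(by_call[[q]])]
    }
  }
  calls$genes <- gene_lists
  calls
}

#' Flag calls completely contained in common reference structural variants
#'
#' A call is common (`is_common = TRUE`) when some reference SV that is
#' flagged common and has the same dosage class (LOSS for CN 0/1, GAIN for CN
#' 3/4 — reference databases report DEL/DUP types, not integer copy numbers)
#' completely contains the call's interval. Partial overlap never flags.
#'
#' Two annotation columns are added for reporting regardless of commonness:
#' `gnomad_span` describes any gnomAD SV completely spanning the call (e.g.
#' `"LOSS in 4"`, or `"No"`), and `dgv_common_count` counts DGV records of the
#' same dosage class with at least 100 individuals containing the call.
#'
#' @param calls Calls data.frame (a `genes` column, if present, is carried
#'   through).
#' @param refs Reference SV data.frame from [read_reference_svs()] /
#'   [reference_svs()]; may combine gnomAD and DGV rows.
#' @return `calls` with `gnomad_span`, `dgv_common_count`, `is_common`
#'   columns.
#' @export
flag_common <- function(calls, refs) {
  n <- nrow(calls)
  calls$gnomad_span <- rep("No", n)
  calls$dgv_common_count <- rep(0L, n)
  calls$is_common <- rep(FALSE, n)
  if (n == 0 || is.null(refs) || nrow(refs) == 0) return(calls)
  # calls completely contained in a reference SV
  hits <- GenomicRanges::findOverlaps(as_granges(calls), as_granges(refs),
                                      type = "within")
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  cls <- dosage_class(calls$copy_number)
  for (i in unique(q)) {
    ref_i <- s[q == i]
    same <- refs$dosage_class[ref_i] == cls[i]
    gn <- ref_i[refs$source[ref_i] == "GNOMAD_SV"]
    if (length(gn)) {
      ann <- vapply(split(gn, refs$dosage_class[gn]), function(ix) {
        sprintf("%s in %d", refs$dosage_class[ix[1]],
                as.integer(max(refs$n_individuals[ix])))
      }, "")
      calls$gnomad_span[i] <- paste(ann, collapse = "; ")
    }
    calls$dgv_common_count[i] <- sum(refs$source[ref_i] == "DGV" & same &
                                       refs$is_flagged_common[ref_i])
    calls$is_common[i] <- any(refs$is_flagged_common[ref_i] & same)
  }
  calls
}

#' Run the full stage-1 filter on raw calls
#'
#' Convenience chain: quality filter, adjacent-call merging, exclusion
#' masking, gene annotation, common-variant flagging. Returns the annotated
#' calls with common calls still present (flagged); downstream stages drop
#' `is_common` calls.
#'
#' @param calls Raw calls data.frame.
#' @param config A [filter_config()].
#' @param genes Optional gene-model data.frame.
#' @param refs Optional reference SV data.frame.
#' @return Annotated calls data.frame.
#' @export
filter_calls <- function(calls, config = filter_config(), genes = NULL,
                         refs = NULL) {
  out <- filter_quality(calls, config)
  out <- merge_adjacent(out, config)
  # merging can only lengthen calls, but re-check SNP support is unnecessary;
  # exclusions come after merging so a merged call touching a mask is removed
  out <- apply_exclusions(out, config)
  if (!is.null(genes)) out <- annotate_genes(out, genes)
  flag_common(out, refs)
}
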