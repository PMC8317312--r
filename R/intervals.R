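#' Autosome labels handled by the pipeline
#'
#' All analyses are restricted to autosomes (chr1-chr22); calls on other
#' chromosomes are dropped on ingestion with a warning.
#'
#' @return Character vector `c("chr1", ..., "chr22")`.
#' @export
autosomes <- function() {
  paste0("chr", 1:22)
}

#' Normalize chromosome labels to canonical "chrN" form
#'
#' Accepts both "6" and "chr6" spellings (any case of the "chr" prefix).
#'
#' @param x Character vector of chromosome labels.
#' @return Character vector in canonical "chrN" form.
#' @export
#' @examples
#' normalize_chrom(c("6", "chr6", "CHR12"))
normalize_chrom <- function(x) {
  x <- trimws(as.character(x))
  paste0("chr", sub("^[Cc][Hh][Rr]", "", x))
}

#' Construct a validated table of genomic intervals
#'
#' Intervals are 1-based and fully closed: both `start` and `end` are included,
#' so a single base is `start == end` and the length is `end - start + 1`.
#' This matches the PennCNV coordinate convention.
#'
#' @param chrom Chromosome labels (normalized via [normalize_chrom()]).
#' @param start,end Integer base positions, 1-based inclusive.
#' @param require_autosome Reject non-autosomal chromosomes (default `TRUE`).
#' @return A `data.frame` with columns `chrom`, `start`, `end`.
#' @export
#' @examples
#' genomic_intervals("6", 108570894, 108694389)
genomic_intervals <- function(chrom, start, end, require_autosome = TRUE) {
  chrom <- normalize_chrom(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- max(length(chrom), length(start), length(end))
  chrom <- rep_len(chrom, n)
  start <- rep_len(start, n)
  end <- rep_len(end, n)
  if (anyNA(start) || anyNA(end)) {
    stop("interval start/end must be non-missing numbers")
  }
  if (any(start < 1)) {
    stop("interval start must be >= 1 (coordinates are 1-based)")
  }
  if (any(end < start)) {
    stop("interval end must be >= start (closed-interval convention)")
  }
  if (require_autosome && !all(chrom %in% autosomes())) {
    bad <- unique(chrom[!chrom %in% autosomes()])
    stop("non-autosomal chromosome(s): ", paste(bad, collapse = ", "))
  }
  data.frame(chrom = chrom, start = start, end = end)
}

#' Length of a genomic interval in bases
#'
#' With 1-based closed coordinates the length is `end - start + 1`; a
#' single-base interval has length 1.
#'
#' @param x A data.frame with `start` and `end` columns (e.g. from
#'   [genomic_intervals()] or [read_rawcnv()]).
#' @return Numeric vector of base counts, one per row.
#' @export
#' @examples
#' interval_length(genomic_intervals("chr6", 108570894, 108694389)) # 123496
interval_length <- function(x) {
  stopifnot(is.data.frame(x), all(c("start", "end") %in% names(x)))
  x$end - x$start + 1
}

#' Test whether intervals overlap by at least one base
#'
#' Closed-interval semantics: intervals sharing only a boundary base overlap.
#' `a` and `b` are compared row-wise, recycling single rows.
#'
#' @param a,b Interval data.frames (`chrom`, `start`, `end`).
#' @return Logical vector.
#' @export
overlaps <- function(a, b) {
  ab <- recycle_intervals(a, b)
  with(ab, a_chrom == b_chrom & a_start <= b_end & b_start <= a_end)
}

#' Test whether one interval completely contains another
#'
#' Non-strict containment: an interval contains itself. Used for the
#' "complete overlap" criterion of the common-variant filters.
#'
#' @param outer,inner Interval data.frames, compared row-wise.
#' @return Logical vector.
#' @export
contains <- function(outer, inner) {
  ab <- recycle_intervals(outer, inner)
  with(ab, a_chrom == b_chrom & a_start <= b_start & b_end <= a_end)
}

#' Number of bases shared by two intervals
#'
#' @param a,b Interval data.frames, compared row-wise.
#' @return Numeric vector of shared base counts (0 when disjoint).
#' @export
overlap_length <- function(a, b) {
  ab <- recycle_intervals(a, b)
  len <- pmin(ab$a_end, ab$b_end) - pmax(ab$a_start, ab$b_start) + 1
  ifelse(ab$a_chrom == ab$b_chrom & len > 0, len, 0)
}

# Row-wise recycling of two interval frames into one aligned frame.
recycle_intervals <- function(a, b) {
  stopifnot(is.data.frame(a), is.data.frame(b))
  n <- if (nrow(a) == 0 || nrow(b) == 0) 0 else max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n)
  bi <- rep_len(seq_len(nrow(b)), n)
  data.frame(
    a_chrom = a$chrom[ai], a_start = a$start[ai], a_end = a$end[ai],
    b_chrom = b$chrom[bi], b_start = b$start[bi], b_end = b$end[bi]
  )
}

#' Construct a chromosome-length table
#'
#' @param chrom Chromosome labels.
#' @param length Total chromosome lengths in bases (all > 0).
#' @return A `data.frame` with columns `chrom`, `length`.
#' @export
chromosome_table <- function(chrom, length) {
  chrom <- normalize_chrom(chrom)
  length <- as.numeric(length)
  if (anyDuplicated(chrom)) stop("duplicate chromosome in chromosome table")
  if (any(length <= 0)) stop("chromosome lengths must be positive")
  data.frame(chrom = chrom, length = length)
}

#' Test whether an interval lies entirely within a margin of a chromosome end
#'
#' True when the interval is completely inside the first `margin` bases or
#' completely inside the last `margin` bases of its chromosome. Used to drop
#' shared CNVs localized within 2 Mb of autosome ends.
#'
#' @param x Interval data.frame (`chrom`, `start`, `end`).
#' @param chroms Chromosome table from [chromosome_table()].
#' @param margin Margin in bases (default 2e6).
#' @return Logical vector, one per row of `x`.
#' @export
within_autosome_end <- function(x, chroms, margin = 2e6) {
  stopifnot(margin >= 0)
  idx <- match(x$chrom, chroms$chrom)
  if (anyNA(idx)) {
    stop("chromosome(s) missing from chromosome table: ",
         paste(unique(x$chrom[is.na(idx)]), collapse = ", "))
  }
  clen <- chroms$length[idx]
  x$end <= margin | x$start >= clen - margin + 1
}

#' Dosage class of a copy number
#'
#' CN below 2 is a LOSS (deletion), above 2 a GAIN (duplication/triplication).
#' Reference SV databases report DEL/DUP types rather than integer copy
#' numbers, so "same copy number" matching across callsets is done at the
#' dosage-class level.
#'
#' @param copy_number Integer vector of copy numbers (2 itself is not a call).
#' @return Character vector, "LOSS" or "GAIN".
#' @export
dosage_class <- function(copy_number) {
  ifelse(copy_number < 2, "LOSS", "GAIN")
}

# Internal: interval data.frame -> GRanges (for bulk overlap joins).
as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start, end = x$end)
  )
}
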