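# Independent brute-force oracles used across the test files. These stay
# deliberately naive (materialized base sets, double loops, choose() products)
# so they share no code path with the implementation they check.

# Overlap/containment by materializing base-position sets.
overlap_oracle <- function(a, b) {
  a$chrom == b$chrom &&
    length(intersect(seq(a$start, a$end), seq(b$start, b$end))) > 0
}

contains_oracle <- function(outer, inner) {
  outer$chrom == inner$chrom &&
    all(seq(inner$start, inner$end) %in% seq(outer$start, outer$end))
}

# Autosome-end rule by per-base scan: every base of the interval lies in the
# leading margin or every base lies in the trailing margin.
within_end_oracle <- function(start, end, chrom_len, margin) {
  bases <- seq(start, end)
  all(bases <= margin) || all(bases >= chrom_len - margin + 1)
}

# Two-sided Fisher p by full enumeration of tables with the observed margins,
# with probabilities from choose() products (no dhyper).
fisher_oracle <- function(tp, fn, fp, tn) {
  n <- tp + fn + fp + tn
  if (n == 0) return(1)
  r1 <- tp + fn
  r2 <- fp + tn
  c1 <- tp + fp
  a_vals <- max(0, c1 - r2):min(c1, r1)
  probs <- choose(r1, a_vals) * choose(r2, c1 - a_vals) / choose(n, c1)
  p_obs <- probs[a_vals == tp]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Common-variant flag by a double loop over calls and reference records.
flag_common_oracle <- function(call, refs) {
  cls <- if (call$copy_number < 2) "LOSS" else "GAIN"
  for (j in seq_len(nrow(refs))) {
    r <- refs[j, ]
    if (r$is_flagged_common && r$dosage_class == cls &&
        r$chrom == call$chrom && r$start <= call$start && call$end <= r$end) {
      return(TRUE)
    }
  }
  FALSE
}

# TRUE when some same-sample same-chrom same-CN pair still satisfies the
# gap/span merge criterion (fixpoint check for merge_adjacent).
any_mergeable_pair <- function(calls, gap_fraction) {
  n <- nrow(calls)
  if (n < 2) return(FALSE)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (calls$sample_id[i] != calls$sample_id[j]) next
      if (calls$chrom[i] != calls$chrom[j]) next
      if (calls$copy_number[i] != calls$copy_number[j]) next
      lo <- if (calls$start[i] <= calls$start[j]) i else j
      hi <- if (lo == i) j else i
      gap <- calls$start[hi] - calls$end[lo] - 1
      span <- max(calls$end[lo], calls$end[hi]) - calls$start[lo] + 1
      if (gap / span <= gap_fraction) return(TRUE)
    }
  }
  FALSE
}

random_calls <- function(n, chroms = c("chr1", "chr2"), samples = c("S1", "S2", "S3"),
                         max_pos = 1e6, min_len = 1e3, max_len = 5e4) {
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample(min_len:max_len, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE), start = start,
             end = start + len - 1,
             copy_number = sample(c(0L, 1L, 3L, 4L), n, replace = TRUE),
             n_snps = sample(10:200, n, replace = TRUE),
             sample_id = sample(samples, n, replace = TRUE))
}

example_candidates <- function() {
  utils::read.delim(system.file("extdata", "example_candidates.tsv",
                                package = "cnvkindred"),
                    stringsAsFactors = FALSE)
}
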