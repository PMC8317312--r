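#' Configuration for within-family segregation analysis
#'
#' Array-derived CNV boundaries jitter between samples, so two individuals'
#' calls are considered "the same CNV" when they have the same dosage class
#' and a reciprocal overlap of at least `match_min_reciprocal_overlap`, where
#' reciprocal overlap is the shared base count divided by the length of the
#' larger call.
#'
#' @param match_min_reciprocal_overlap Minimum reciprocal overlap in `[0, 1]`
#'   (default 0.5).
#' @param require_same_dosage Require matching dosage class (default `TRUE`).
#' @return A `segregation_config` list.
#' @export
segregation_config <- function(match_min_reciprocal_overlap = 0.5,
                               require_same_dosage = TRUE) {
  stopifnot(match_min_reciprocal_overlap >= 0,
            match_min_reciprocal_overlap <= 1)
  structure(list(match_min_reciprocal_overlap = match_min_reciprocal_overlap,
                 require_same_dosage = require_same_dosage),
            class = "segregation_config")
}

#' Test whether two calls represent the same CNV
#'
#' @param a,b One-row calls data.frames from different samples.
#' @param config A [segregation_config()].
#' @return `TRUE` when the calls match.
#' @export
match_calls <- function(a, b, config = segregation_config()) {
  if (config$require_same_dosage &&
      dosage_class(a$copy_number) != dosage_class(b$copy_number)) {
    return(FALSE)
  }
  ov <- overlap_length(a, b)
  rec <- ov / max(interval_length(a), interval_length(b))
  rec >= config$match_min_reciprocal_overlap
}

# Union-find over call indices; edge when two calls match.
cluster_matched_calls <- function(calls, config) {
  n <- nrow(calls)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n > 1) {
    cls <- dosage_class(calls$copy_number)
    len <- interval_length(calls)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (calls$chrom[i] != calls$chrom[j]) next
        if (config$require_same_dosage && cls[i] != cls[j]) next
        ov <- min(calls$end[i], calls$end[j]) - max(calls$start[i], calls$start[j]) + 1
        if (ov <= 0) next
        if (ov / max(len[i], len[j]) >= config$match_min_reciprocal_overlap) {
          parent[find(i)] <- find(j)
        }
      }
    }
  }
  vapply(seq_len(n), find, 1L)
}

#' Scan one family for CNVs segregating with disease
#'
#' Calls of the family's genotyped members are clustered into maximal groups
#' of matching calls ([match_calls()] closure). Each group becomes a
#' `CANDIDATE` when its carriers include at least one AFFECTED member and no
#' UNAFFECTED member, and a `PROTECTIVE` candidate when all carriers are
#' UNAFFECTED. AT_RISK members (unknown affection) neither qualify nor veto a
#' group. Other carrier patterns are dropped.
#'
#' The reported `region` is the intersection of the member calls (the core
#' shared by all carriers); the union span is kept in `union_start`/
#' `union_end` because downstream cohort intersection queries the largest
#' encompassing region.
#'
#' @param family Sample records of one family (see [read_pedigree()]).
#' @param calls Calls data.frame restricted to that family's members (already
#'   filtered and, if desired, annotated with `genes`).
#' @param config A [segregation_config()].
#' @return Candidate data.frame: `family_id`, `chrom`, `start`, `end`
#'   (intersection), `union_start`, `union_end`, `copy_number` (NA when mixed
#'   within the group), `dosage_class_cnv`, `mixed_cn`, `n_snps` (max over
#'   members), `carrier_ids` (list-column), `n_carriers`, `status`, `genes`
#'   (list-column), `provenance`.
#' @export
segregation_scan <- function(family, calls, config = segregation_config()) {
  stopifnot(all(c("sample_id", "affection") %in% names(family)))
  fam_id <- if (nrow(family)) family$family_id[1] else NA_character_
  empty <- data.frame(family_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      union_start = numeric(), union_end = numeric(),
                      copy_number = integer(), dosage_class_cnv = character(),
                      mixed_cn = logical(), n_snps = integer(),
                      n_carriers = integer(), status = character(),
                      provenance = character())
  empty$carrier_ids <- list()
  empty$genes <- list()
  if (!any(family$affection %in% c("AFFECTED", "UNAFFECTED"))) {
    warning(sprintf("family %s has no genotyped affected or unaffected members; skipping",
                    fam_id))
    return(empty)
  }
  calls <- calls[calls$sample_id %in% family$sample_id, , drop = FALSE]
  if (nrow(calls) == 0) return(empty)

  comp <- cluster_matched_calls(calls, config)
  aff_of <- stats::setNames(family$affection, family$sample_id)
  rows <- lapply(split(seq_len(nrow(calls)), comp), function(idx) {
    members <- calls[idx, , drop = FALSE]
    carriers <- unique(members$sample_id)
    status_set <- aff_of[carriers]
    n_aff <- sum(status_set == "AFFECTED")
    n_unaff <- sum(status_set == "UNAFFECTED")
    status <- if (n_aff >= 1 && n_unaff == 0) {
      "CANDIDATE"
    } else if (n_unaff == length(status_set)) {
      "PROTECTIVE"
    } else {
      return(NULL)
    }
    core_start <- max(members$start)
    core_end <- min(members$end)
    if (core_start > core_end) { # chained matches without a common core
      core_start <- min(members$start)
      core_end <- max(members$end)
    }
    cns <- unique(members$copy_number)
    genes <- if ("genes" %in% names(members)) {
      unique(unlist(members$genes))
    } else {
      character()
    }
    out <- data.frame(
      family_id = fam_id, chrom = members$chrom[1],
      start = core_start, end = core_end,
      union_start = min(members$start), union_end = max(members$end),
      copy_number = if (length(cns) == 1) cns else NA_integer_,
      dosage_class_cnv = names(sort(table(dosage_class(members$copy_number)),
                                    decreasing = TRUE))[1],
      mixed_cn = length(cns) > 1,
      n_snps = max(members$n_snps),
      n_carriers = length(carriers), status = status,
      provenance = "FAMILY")
    out$carrier_ids <- list(sort(carriers))
    out$genes <- list(genes)
    out
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan every family in a pedigree
#'
#' @param pedigree Full sample-record table (all families).
#' @param calls Calls data.frame for the whole cohort.
#' @param config A [segregation_config()].
#' @param exclude_families Family ids to skip (e.g. families with a known
#'   definitely pathogenic variant).
#' @return Row-bound candidate data.frame (see [segregation_scan()]).
#' @export
segregation_scan_all <- function(pedigree, calls,
                                 config = segregation_config(),
                                 exclude_families = character()) {
  fams <- setdiff(unique(pedigree$family_id), exclude_families)
  out <- lapply(fams, function(f) {
    fam <- pedigree[pedigree$family_id == f, , drop = FALSE]
    segregation_scan(fam, calls, config)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Count cohort-wide calls at a candidate locus
#'
#' After a family candidate is found, the rest of the cohort is checked for
#' calls at the same locus: any call overlapping the candidate region by at
#' least one base counts, excluding the candidate family's own samples.
#'
#' @param region One-row interval data.frame (`chrom`, `start`, `end`).
#' @param cohort_calls Calls data.frame for the whole cohort.
#' @param exclude_samples Sample ids to ignore (the candidate's family).
#' @return Integer count of intersecting calls.
#' @export
cohort_lookup <- function(region, cohort_calls, exclude_samples = character()) {
  keep <- !(cohort_calls$sample_id %in% exclude_samples)
  calls <- cohort_calls[keep, , drop = FALSE]
  if (nrow(calls) == 0) return(0L)
  sum(overlaps(calls, region))
}
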