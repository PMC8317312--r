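#' Read PennCNV-style rawcnv call files
#'
#' Each non-empty line holds one call:
#' `chr6:108570894-108694389 numsnp=15 length=123,496 state5,cn=3 SAMPLE_01`
#' with optional trailing `startsnp=`/`endsnp=` fields (ignored). Thousands
#' separators in `length=` are tolerated; the printed length is cross-checked
#' against `end - start + 1` and the computed value is authoritative (a
#' mismatch larger than one base raises a warning naming the line).
#'
#' Copy number must be one of 0, 1, 3, 4 — the diploid state 2 is never
#' emitted as a call. Non-autosomal calls are dropped with a warning.
#'
#' @param path Path to a rawcnv text file.
#' @return A calls `data.frame`: `chrom`, `start`, `end`, `copy_number`,
#'   `n_snps`, `sample_id`.
#' @export
read_rawcnv <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0) return(empty_calls())

  parse_one <- function(line, no) {
    f <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(f) < 5) {
      stop(sprintf("rawcnv parse error at line %d: expected >= 5 fields", no))
    }
    m <- regmatches(f[1], regexec("^(\\S+):(\\d+)-(\\d+)$", f[1]))[[1]]
    if (length(m) != 4) {
      stop(sprintf("rawcnv parse error at line %d: bad position '%s'", no, f[1]))
    }
    nsnp <- suppressWarnings(as.integer(sub("^numsnp=", "", f[2])))
    plen <- suppressWarnings(as.numeric(gsub(",", "", sub("^length=", "", f[3]))))
    cnm <- regmatches(f[4], regexec("^state\\d+,cn=(\\d+)$", f[4]))[[1]]
    if (is.na(nsnp) || is.na(plen) || length(cnm) != 2) {
      stop(sprintf("rawcnv parse error at line %d: bad numsnp/length/state field", no))
    }
    cn <- as.integer(cnm[2])
    if (!cn %in% c(0L, 1L, 3L, 4L)) {
      stop(sprintf("rawcnv validation error at line %d: cn=%d is not a CNV state", no, cn))
    }
    if (nsnp < 1) {
      stop(sprintf("rawcnv validation error at line %d: numsnp must be >= 1", no))
    }
    start <- as.numeric(m[3])
    end <- as.numeric(m[4])
    if (abs(plen - (end - start + 1)) > 1) {
      warning(sprintf(
        "line %d: printed length %.0f differs from end - start + 1 = %.0f; using computed length",
        no, plen, end - start + 1))
    }
    data.frame(chrom = normalize_chrom(m[2]), start = start, end = end,
               copy_number = cn, n_snps = nsnp, sample_id = f[5])
  }

  calls <- do.call(rbind, Map(parse_one, lines, lineno))
  rownames(calls) <- NULL
  drop_non_autosomes(calls)
}

#' Write calls in PennCNV rawcnv format
#'
#' The `length=` field is written with thousands separators, mirroring PennCNV
#' output; HMM state is reconstructed from the copy number (0->state1,
#' 1->state2, 3->state5, 4->state6).
#'
#' @param calls Calls data.frame as returned by [read_rawcnv()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_rawcnv <- function(calls, path) {
  state_of <- c(`0` = 1L, `1` = 2L, `3` = 5L, `4` = 6L)
  lines <- sprintf(
    "%s:%.0f-%.0f numsnp=%d length=%s state%d,cn=%d %s",
    calls$chrom, calls$start, calls$end, calls$n_snps,
    formatC(interval_length(calls), format = "d", big.mark = ","),
    state_of[as.character(calls$copy_number)], calls$copy_number,
    calls$sample_id)
  writeLines(lines, path)
  invisible(path)
}

empty_calls <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             copy_number = integer(), n_snps = integer(),
             sample_id = character())
}

drop_non_autosomes <- function(calls) {
  auto <- calls$chrom %in% autosomes()
  if (!all(auto)) {
    warning(sprintf("dropped %d call(s) on non-autosomal chromosome(s): %s",
                    sum(!auto),
                    paste(unique(calls$chrom[!auto]), collapse = ", ")))
    calls <- calls[auto, , drop = FALSE]
    rownames(calls) <- NULL
  }
  calls
}

#' Read a pedigree (PED) file plus a phenotype table
#'
#' The PED file carries 6 whitespace-separated columns (family, individual,
#' father, mother, sex, affection) with `0` denoting a missing parent.
#' Affection codes map 1 -> UNAFFECTED, 2 -> AFFECTED, 0 or -9 -> AT_RISK.
#' AT_RISK (e.g. unaffected-so-far relatives below the family's onset age) is
#' treated as unknown affection throughout — never as unaffected.
#'
#' The optional phenotype TSV is keyed by `sample_id` and may add `diagnosis`,
#' `age_at_onset`, `age_last_exam` columns.
#'
#' @param ped_path Path to the 6-column PED file.
#' @param phenotype_path Optional path to the phenotype TSV.
#' @return A `data.frame` of sample records: `sample_id`, `family_id`,
#'   `father_id`, `mother_id` (NA when missing), `sex`, `affection`, plus any
#'   phenotype columns.
#' @export
read_pedigree <- function(ped_path, phenotype_path = NULL) {
  ped <- utils::read.table(ped_path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("family_id", "sample_id", "father_id",
                                         "mother_id", "sex", "affection"),
                           colClasses = c("character", "character", "character",
                                          "character", "character", "character"))
  if (anyDuplicated(ped$sample_id)) {
    stop("duplicate sample_id in pedigree: ",
         paste(unique(ped$sample_id[duplicated(ped$sample_id)]), collapse = ", "))
  }
  aff_map <- c(`1` = "UNAFFECTED", `2` = "AFFECTED", `0` = "AT_RISK", `-9` = "AT_RISK")
  if (!all(ped$affection %in% names(aff_map))) {
    stop("unknown affection code(s): ",
         paste(setdiff(ped$affection, names(aff_map)), collapse = ", "))
  }
  ped$affection <- unname(aff_map[ped$affection])
  ped$father_id[ped$father_id == "0"] <- NA_character_
  ped$mother_id[ped$mother_id == "0"] <- NA_character_
  for (col in c("father_id", "mother_id")) {
    ref <- ped[[col]]
    ok <- is.na(ref) | mapply(function(p, f) p %in% ped$sample_id[ped$family_id == f],
                              ref, ped$family_id)
    if (!all(ok)) {
      stop("dangling parent reference(s): ",
           paste(unique(ref[!ok]), collapse = ", "))
    }
  }
  if (!is.null(phenotype_path)) {
    phe <- utils::read.delim(phenotype_path, stringsAsFactors = FALSE)
    if (!"sample_id" %in% names(phe)) stop("phenotype table must have a sample_id column")
    ped <- merge(ped, phe, by = "sample_id", all.x = TRUE, sort = FALSE)
  }
  ped
}

#' Read a reference structural-variant table (gnomAD-SV or DGV style)
#'
#' Expects a TSV with columns `chrom`, `start`, `end`, `svtype`,
#' `n_individuals`, and (for gnomAD) `allele_freq`. SV types are mapped to a
#' dosage class: DEL/loss/deletion -> LOSS, DUP/gain/duplication/triplication
#' -> GAIN, anything else (inversions etc.) -> OTHER with a warning.
#'
#' The `is_flagged_common` column implements the common-variant criteria:
#' for gnomAD, length > 50 bp AND `n_individuals >= 100` AND
#' `allele_freq >= 0.01`; for DGV, `n_individuals >= 100` (evaluated per
#' record, not aggregated across studies).
#'
#' @param path Path to the TSV.
#' @param source `"GNOMAD_SV"` or `"DGV"`.
#' @return A `data.frame`: `source`, `chrom`, `start`, `end`, `dosage_class`,
#'   `n_individuals`, `allele_freq`, `is_flagged_common`.
#' @export
read_reference_svs <- function(path, source = c("GNOMAD_SV", "DGV")) {
  source <- match.arg(source)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "svtype", "n_individuals")
  if (!all(need %in% names(tab))) {
    stop("reference SV table must have columns: ", paste(need, collapse = ", "))
  }
  if (!"allele_freq" %in% names(tab)) tab$allele_freq <- NA_real_
  reference_svs(chrom = tab$chrom, start = tab$start, end = tab$end,
                svtype = tab$svtype, n_individuals = tab$n_individuals,
                allele_freq = tab$allele_freq, source = source)
}

#' Build a reference SV table from vectors
#'
#' Vector-level counterpart of [read_reference_svs()]; applies the same type
#' mapping and common-variant flagging.
#'
#' @param chrom,start,end Interval coordinates (1-based closed).
#' @param svtype SV type strings (DEL, DUP, loss, gain, inversion, ...).
#' @param n_individuals Carrier counts (>= 0).
#' @param allele_freq Allele frequencies in `[0, 1]`; may be NA (DGV).
#' @param source `"GNOMAD_SV"` or `"DGV"`.
#' @return Reference SV `data.frame` (see [read_reference_svs()]).
#' @export
reference_svs <- function(chrom, start, end, svtype, n_individuals,
                          allele_freq = NA_real_, source = c("GNOMAD_SV", "DGV")) {
  source <- match.arg(source)
  iv <- genomic_intervals(chrom, start, end, require_autosome = FALSE)
  n <- nrow(iv)
  n_individuals <- rep_len(as.numeric(n_individuals), n)
  allele_freq <- rep_len(as.numeric(allele_freq), n)
  if (any(n_individuals < 0)) stop("n_individuals must be >= 0")
  af_known <- !is.na(allele_freq)
  if (any(allele_freq[af_known] < 0 | allele_freq[af_known] > 1)) {
    stop("allele_freq must lie in [0, 1]")
  }
  ty <- toupper(rep_len(as.character(svtype), n))
  cls <- rep("OTHER", n)
  cls[ty %in% c("DEL", "LOSS", "DELETION")] <- "LOSS"
  cls[ty %in% c("DUP", "GAIN", "DUPLICATION", "TRIPLICATION")] <- "GAIN"
  unknown <- cls == "OTHER" & !ty %in% c("INV", "INVERSION", "OTHER", "CPX", "INS", "BND")
  if (any(unknown)) {
    warning("unknown svtype(s) kept as OTHER: ",
            paste(unique(ty[unknown]), collapse = ", "))
  }
  len <- iv$end - iv$start + 1
  flagged <- if (source == "GNOMAD_SV") {
    len > 50 & n_individuals >= 100 & !is.na(allele_freq) & allele_freq >= 0.01
  } else {
    n_individuals >= 100
  }
  data.frame(source = source, chrom = iv$chrom, start = iv$start, end = iv$end,
             dosage_class = cls, n_individuals = n_individuals,
             allele_freq = allele_freq, is_flagged_common = flagged)
}

#' Read a BED file of regions as 1-based closed intervals
#'
#' BED is 0-based half-open; the intervals are converted on read by adding one
#' to the start, so BED `chr1 0 100` becomes chr1:1-100 (length 100). Empty
#' BED intervals (`start >= end`) are an error.
#'
#' @param path Path to a BED3+ file.
#' @return Interval `data.frame` (`chrom`, `start`, `end`).
#' @export
read_bed_regions <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 3) stop("BED file must have at least 3 columns")
  s0 <- as.numeric(tab[[2]])
  e0 <- as.numeric(tab[[3]])
  if (any(s0 >= e0)) {
    stop("empty BED interval(s): start must be < end in 0-based half-open coordinates")
  }
  genomic_intervals(tab[[1]], s0 + 1, e0, require_autosome = FALSE)
}

#' Write intervals as BED (0-based half-open)
#'
#' Inverse of [read_bed_regions()].
#'
#' @param x Interval data.frame (1-based closed).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed_regions <- function(x, path) {
  writeLines(sprintf("%s\t%.0f\t%.0f", x$chrom, x$start - 1, x$end), path)
  invisible(path)
}

#' Read a gene-model table
#'
#' TSV with columns `symbol`, `chrom`, `start`, `end`; one record per symbol
#' (the span of the longest transcript).
#'
#' @param path Path to the TSV.
#' @return Gene `data.frame`: `symbol`, `chrom`, `start`, `end`.
#' @export
read_gene_models <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("symbol", "chrom", "start", "end")
  if (!all(need %in% names(tab))) {
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(!nzchar(tab$symbol))) stop("empty gene symbol")
  if (anyDuplicated(tab$symbol)) {
    stop("duplicate gene symbol(s): ",
         paste(unique(tab$symbol[duplicated(tab$symbol)]), collapse = ", "))
  }
  iv <- genomic_intervals(tab$chrom, tab$start, tab$end, require_autosome = FALSE)
  data.frame(symbol = tab$symbol, iv)
}

#' Read a chromosome-length table
#'
#' TSV with columns `chrom`, `length`.
#'
#' @param path Path to the TSV.
#' @return Chromosome table (see [chromosome_table()]).
#' @export
read_chromosome_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  chromosome_table(tab$chrom, tab$length)
}

#' Format CN-stratified intersect counts for reports
#'
#' Produces the `"T (a|b|c|d)"` string giving the total and the per-copy-number
#' (0|1|3|4) carrier counts; all-zero counts render as `"No overlap"`.
#'
#' @param counts Named numeric vector or list with elements `cn0`, `cn1`,
#'   `cn3`, `cn4`.
#' @return A single string.
#' @export
#' @examples
#' format_intersect(c(cn0 = 0, cn1 = 9, cn3 = 13, cn4 = 0)) # "22 (0|9|13|0)"
format_intersect <- function(counts) {
  k <- vapply(c("cn0", "cn1", "cn3", "cn4"), function(nm) as.numeric(counts[[nm]]), 0)
  tot <- sum(k)
  if (tot == 0) "No overlap" else sprintf("%d (%d|%d|%d|%d)", tot, k[1], k[2], k[3], k[4])
}

#' Write the candidate/association report
#'
#' One row per candidate locus with position, supporting-SNP count, length
#' (always recomputed as `end - start + 1`), copy number, carriers, gene list,
#' reference-SV annotation, CN-stratified case/control intersect strings, and
#' the association statistics (Fisher p, LR+, LR-). Infinite likelihood ratios
#' are rendered as `"inf"`. With no candidates a header-only file is written.
#'
#' @param candidates Candidate data.frame (family/shared/screen output); may
#'   have zero rows.
#' @param summaries Association results from [associate()] aligned row-wise
#'   with `candidates`, or `NULL`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(candidates, summaries = NULL, path) {
  cols <- c("position", "n_snps", "length_bases", "cn", "carriers", "genes",
            "gnomad_span", "dgv_common_count", "ukbb_dementia", "ukbb_nondementia",
            "fisher_p", "lr_positive", "lr_negative", "significant")
  n <- if (is.null(candidates)) 0 else nrow(candidates)
  if (n == 0) {
    writeLines(paste(cols, collapse = "\t"), path)
    return(invisible(path))
  }
  get <- function(df, nm, default = NA) {
    if (!is.null(df) && nm %in% names(df)) df[[nm]] else rep(default, n)
  }
  fmt_num <- function(x) {
    ifelse(is.na(x), "NA", ifelse(is.infinite(x), "inf", format(x, digits = 6)))
  }
  genes <- get(candidates, "genes", "")
  if (is.list(genes)) genes <- vapply(genes, paste, "", collapse = ", ")
  carriers <- get(candidates, "carrier_ids", "")
  if (is.list(carriers)) carriers <- vapply(carriers, paste, "", collapse = ", ")
  out <- data.frame(
    position = sprintf("%s:%.0f-%.0f", candidates$chrom, candidates$start, candidates$end),
    n_snps = get(candidates, "n_snps"),
    length_bases = interval_length(candidates),
    cn = get(candidates, "copy_number"),
    carriers = carriers,
    genes = genes,
    gnomad_span = get(candidates, "gnomad_span", "No"),
    dgv_common_count = get(candidates, "dgv_common_count", 0),
    ukbb_dementia = get(summaries, "case_intersect", ""),
    ukbb_nondementia = get(summaries, "control_intersect", ""),
    fisher_p = fmt_num(get(summaries, "fisher_p", NA_real_)),
    lr_positive = fmt_num(get(summaries, "lr_positive", NA_real_)),
    lr_negative = fmt_num(get(summaries, "lr_negative", NA_real_)),
    significant = get(summaries, "significant", NA),
    check.names = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
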