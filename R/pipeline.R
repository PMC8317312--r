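#' Assemble a pipeline configuration
#'
#' Inputs may be given as file paths (read with the package's readers) or as
#' already-loaded data.frames; `NULL` disables the corresponding stage.
#'
#' @param calls Raw calls (rawcnv path or data.frame). Required.
#' @param pedigree Pedigree (PED path or sample-record data.frame).
#' @param phenotypes Phenotype TSV path (only used with a PED path).
#' @param genes Gene models (TSV path or data.frame).
#' @param chroms Chromosome table (TSV path or data.frame). Required.
#' @param gnomad,dgv Reference SV tables (TSV path or data.frame).
#' @param exclusions Exclusion regions (BED path or interval data.frame).
#' @param screen Gene screen list (TSV path or data.frame).
#' @param case_calls,control_calls Case/control cohort calls (rawcnv path or
#'   data.frame).
#' @param n_case,n_control Case/control cohort sizes (individuals).
#' @param alpha Significance level (default 0.05).
#' @param filter A [filter_config()] (exclusions are attached automatically).
#' @param segregation A [segregation_config()].
#' @param exclude_families Family ids excluded from segregation analysis.
#' @param out_dir Output directory for reports, or `NULL` for none.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(calls, pedigree = NULL, phenotypes = NULL,
                            genes = NULL, chroms, gnomad = NULL, dgv = NULL,
                            exclusions = NULL, screen = NULL,
                            case_calls = NULL, control_calls = NULL,
                            n_case = NULL, n_control = NULL, alpha = 0.05,
                            filter = filter_config(),
                            segregation = segregation_config(),
                            exclude_families = character(), out_dir = NULL) {
  stopifnot(alpha > 0, alpha < 1)
  load_as <- function(x, reader, stage) {
    if (is.null(x) || is.data.frame(x)) return(x)
    if (!file.exists(x)) {
      stop(sprintf("[config] %s input not found: %s", stage, x))
    }
    reader(x)
  }
  cfg <- list(
    calls = load_as(calls, read_rawcnv, "calls"),
    pedigree = if (is.character(pedigree)) {
      read_pedigree(pedigree, phenotypes)
    } else pedigree,
    genes = load_as(genes, read_gene_models, "genes"),
    chroms = load_as(chroms, read_chromosome_table, "chromosomes"),
    gnomad = load_as(gnomad, function(p) read_reference_svs(p, "GNOMAD_SV"), "gnomAD"),
    dgv = load_as(dgv, function(p) read_reference_svs(p, "DGV"), "DGV"),
    exclusions = load_as(exclusions, read_bed_regions, "exclusions"),
    screen = load_as(screen, read_gene_screen_list, "screen"),
    case_calls = load_as(case_calls, read_rawcnv, "case calls"),
    control_calls = load_as(control_calls, read_rawcnv, "control calls"),
    n_case = n_case, n_control = n_control, alpha = alpha,
    filter = filter, segregation = segregation,
    exclude_families = exclude_families, out_dir = out_dir)
  cfg$filter$exclusion_regions <- cfg$exclusions
  structure(cfg, class = "pipeline_config")
}

#' Run the full prioritization pipeline
#'
#' Chains filtering (quality, merge, exclusion mask, gene annotation,
#' common-variant flagging), family segregation, shared-gene analysis, gene
#' screening, and case/control association of every candidate locus. Stage
#' in/out call counts are collected in `counts` and written to a run log.
#' Association queries use each candidate's largest encompassing region.
#'
#' When `out_dir` is set, Table-shaped TSV reports are written there
#' (family_candidates.tsv, shared_groups.tsv, screen_hits.tsv,
#' associations.tsv, pipeline_log.txt); on any stage error partial outputs
#' are removed and the error is re-raised with the stage name.
#'
#' @param config A [pipeline_config()].
#' @return List: `annotated` (filtered annotated calls), `family`, `shared`,
#'   `screen`, `associations`, `counts` (named integer vector of per-stage
#'   call counts).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  written <- character()
  counts <- c(input = nrow(config$calls))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  annotated <- stage("filter", {
    x <- filter_quality(config$calls, config$filter)
    counts["after_quality"] <- nrow(x)
    x <- merge_adjacent(x, config$filter)
    counts["after_merge"] <- nrow(x)
    x <- apply_exclusions(x, config$filter)
    counts["after_exclusions"] <- nrow(x)
    if (!is.null(config$genes)) x <- annotate_genes(x, config$genes)
    x <- flag_common(x, rbind_refs(config$gnomad, config$dgv))
    counts["flagged_common"] <- sum(x$is_common)
    x
  })
  rare <- annotated[!annotated$is_common, , drop = FALSE]
  counts["after_common_filter"] <- nrow(rare)

  family <- stage("family", {
    if (is.null(config$pedigree)) NULL else {
      segregation_scan_all(config$pedigree, rare, config$segregation,
                           config$exclude_families)
    }
  })
  if (!is.null(family) && nrow(family) > 0) {
    family$cohort_intersects <- vapply(seq_len(nrow(family)), function(i) {
      fam_samples <- config$pedigree$sample_id[
        config$pedigree$family_id == family$family_id[i]]
      cohort_lookup(family[i, c("chrom", "start", "end")], rare, fam_samples)
    }, 0L)
  }
  counts["family_candidates"] <- if (is.null(family)) 0L else nrow(family)

  shared <- stage("shared", {
    if (is.null(config$genes)) NULL else {
      shared_scan(rare, config$chroms,
                  margin = config$filter$autosome_end_margin)
    }
  })
  counts["shared_groups"] <- if (is.null(shared)) 0L else nrow(shared)

  screen <- stage("screen", {
    if (is.null(config$screen)) NULL else screen_genes(rare, config$screen)
  })
  counts["screen_hits"] <- if (is.null(screen)) 0L else nrow(screen)

  associations <- stage("association", {
    if (is.null(config$case_calls) || is.null(config$control_calls) ||
        is.null(config$n_case) || is.null(config$n_control)) {
      NULL
    } else {
      loci <- candidate_loci(family, shared, screen)
      if (nrow(loci) == 0) loci else {
        res <- do.call(rbind, lapply(seq_len(nrow(loci)), function(i) {
          associate(loci[i, c("chrom", "start", "end")], config$case_calls,
                    config$control_calls, config$n_case, config$n_control,
                    config$alpha)
        }))
        cbind(loci, res)
      }
    }
  })
  counts["associated_loci"] <- if (is.null(associations)) 0L else nrow(associations)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    written <- stage("report", {
      files <- character()
      tsv <- function(df, name) {
        p <- file.path(out_dir, name)
        flat <- flatten_list_cols(df)
        utils::write.table(flat, p, sep = "\t", quote = FALSE, row.names = FALSE)
        files <<- c(files, p)
      }
      tsv(family, "family_candidates.tsv")
      tsv(shared, "shared_groups.tsv")
      tsv(screen, "screen_hits.tsv")
      tsv(associations, "associations.tsv")
      log_path <- file.path(out_dir, "pipeline_log.txt")
      writeLines(c("stage\tcalls",
                   sprintf("%s\t%d", names(counts), counts)), log_path)
      c(files, log_path)
    })
  }

  list(annotated = annotated, family = family, shared = shared,
       screen = screen, associations = associations, counts = counts)
}

# Candidate loci for association: family/shared use the encompassing region,
# screen hits use the call interval itself.
candidate_loci <- function(family, shared, screen) {
  rows <- list()
  if (!is.null(family) && nrow(family) > 0) {
    rows$family <- data.frame(provenance = "FAMILY", label = family$family_id,
                              chrom = family$chrom,
                              start = family$union_start,
                              end = family$union_end)
  }
  if (!is.null(shared) && nrow(shared) > 0) {
    rows$shared <- data.frame(provenance = "SHARED", label = shared$genes,
                              chrom = shared$chrom,
                              start = shared$encompassing_start,
                              end = shared$encompassing_end)
  }
  if (!is.null(screen) && nrow(screen) > 0) {
    rows$screen <- data.frame(
      provenance = "GENE_SCREEN",
      label = vapply(screen$matched_genes, paste, "", collapse = ","),
      chrom = screen$chrom, start = screen$start, end = screen$end)
  }
  if (length(rows) == 0) {
    return(data.frame(provenance = character(), label = character(),
                      chrom = character(), start = numeric(), end = numeric()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

rbind_refs <- function(...) {
  refs <- Filter(Negate(is.null), list(...))
  if (length(refs) == 0) return(NULL)
  do.call(rbind, refs)
}

# Collapse list-columns to comma-joined strings for TSV output.
flatten_list_cols <- function(df) {
  if (is.null(df)) return(data.frame(empty = character()))
  for (nm in names(df)) {
    if (is.list(df[[nm]])) {
      df[[nm]] <- vapply(df[[nm]], paste, "", collapse = ",")
    }
  }
  df
}
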