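#' Specify a planted CNV for the cohort simulator
#'
#' @param chrom,start,end Core locus of the planted CNV (1-based closed).
#' @param copy_number Copy number in 0, 1, 3, 4.
#' @param carriers Sample ids receiving a (jittered) copy of the CNV.
#' @return A `plant_spec` list.
#' @export
plant_spec <- function(chrom, start, end, copy_number, carriers) {
  stopifnot(copy_number %in% c(0, 1, 3, 4), length(carriers) >= 1, end >= start)
  structure(list(chrom = normalize_chrom(chrom), start = start, end = end,
                 copy_number = as.integer(copy_number),
                 carriers = as.character(carriers)),
            class = "plant_spec")
}

#' Default simulated pedigree: a sibling pair and a trio
#'
#' Two families emulating the ascertainment patterns a dementia family study
#' works with: FAM1 has two affected siblings (the proband with FTD) and
#' their unaffected mother; FAM2 is a trio with an affected father and two
#' at-risk relatives, so the unknown-affection handling is exercised.
#'
#' @return Sample-record data.frame (columns as in [read_pedigree()], plus
#'   `diagnosis`).
#' @export
sim_default_pedigree <- function() {
  data.frame(
    sample_id = c("FAM1_MO", "FAM1_SIB1", "FAM1_SIB2",
                  "FAM2_FA", "FAM2_MO", "FAM2_SON"),
    family_id = c("FAM1", "FAM1", "FAM1", "FAM2", "FAM2", "FAM2"),
    father_id = c(NA, NA, NA, NA, NA, "FAM2_FA"),
    mother_id = c(NA, "FAM1_MO", "FAM1_MO", NA, NA, "FAM2_MO"),
    sex = c("2", "1", "2", "1", "2", "1"),
    affection = c("UNAFFECTED", "AFFECTED", "AFFECTED",
                  "AFFECTED", "AT_RISK", "AT_RISK"),
    diagnosis = c("unaffected", "FTD", "dementia", "FTD", "risk", "risk")
  )
}

#' Configuration for the synthetic-cohort simulator
#'
#' The generator emulates the data regime of an OmniExpress-density array
#' study: an SNP grid with exponential spacing (mean 4 kb), per-sample
#' background CNVs at a Poisson rate with log-normal lengths (median 80 kb,
#' comfortably above the 50 kb report threshold), and optional planted CNVs —
#' a family-segregating CNV copied with boundary jitter to designated
#' pedigree members, a shared CNV given to unrelated individuals with
#' identical copy number, and a common CNV that is also emitted as a
#' flagged-common reference SV containing it. Boundary jitter is truncated to
#' at most 12.5% of the planted core length per boundary so every jittered
#' copy keeps at least 50% reciprocal overlap with the core, which keeps
#' recovery decidable at the default matching threshold.
#'
#' Every random draw is fixed by `seed`; per-sample streams are split from it
#' so adding a sample never perturbs the draws of the others.
#'
#' @param seed Integer seed fixing all draws.
#' @param n_chromosomes Number of simulated autosomes (default 4).
#' @param chrom_length Length of each chromosome in bases (default 50 Mb).
#' @param snp_spacing Mean inter-SNP distance in bases (default 4000,
#'   exponential).
#' @param n_case_samples,n_control_samples Unrelated case/control sample
#'   counts (defaults 30/60, a scaled-down case-control panel).
#' @param families Pedigree of simulated families
#'   (default [sim_default_pedigree()]); `NULL` for none.
#' @param background_rate Mean background CNVs per sample (Poisson, default 5).
#' @param background_length_meanlog,background_length_sdlog Log-normal length
#'   parameters (defaults `log(80000)` and 0.6).
#' @param cn_weights Sampling weights for background copy numbers 0/1/3/4.
#' @param planted_family_cnv,planted_shared_cnv,planted_common_cnv Optional
#'   [plant_spec()]s (defaults plant all three; pass `NULL` to disable).
#' @param common_sv_freq Allele frequency assigned to background common
#'   reference SVs (default 0.02).
#' @param boundary_jitter_sd SD of planted-boundary jitter in bases
#'   (default 5000).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_chromosomes = 4, chrom_length = 5e7,
                       snp_spacing = 4000, n_case_samples = 30,
                       n_control_samples = 60,
                       families = sim_default_pedigree(),
                       background_rate = 5,
                       background_length_meanlog = log(80000),
                       background_length_sdlog = 0.6,
                       cn_weights = c(`0` = 0.05, `1` = 0.45, `3` = 0.45, `4` = 0.05),
                       planted_family_cnv = plant_spec(
                         "chr1", 10000000, 10150000, 3,
                         c("FAM1_SIB1", "FAM1_SIB2")),
                       planted_shared_cnv = plant_spec(
                         "chr2", 20000000, 20120000, 1,
                         c("CASE_001", "CASE_002")),
                       planted_common_cnv = plant_spec(
                         "chr3", 15000000, 15100000, 1,
                         c("FAM1_SIB1", "FAM1_SIB2",
                           sprintf("CASE_%03d", 3:10))),
                       common_sv_freq = 0.02,
                       boundary_jitter_sd = 5000) {
  stopifnot(n_chromosomes >= 1, chrom_length > 0, snp_spacing > 0,
            n_case_samples >= 0, n_control_samples >= 0,
            background_rate >= 0, common_sv_freq >= 0, common_sv_freq <= 1,
            boundary_jitter_sd >= 0)
  structure(list(seed = as.integer(seed), n_chromosomes = n_chromosomes,
                 chrom_length = chrom_length, snp_spacing = snp_spacing,
                 n_case_samples = n_case_samples,
                 n_control_samples = n_control_samples, families = families,
                 background_rate = background_rate,
                 background_length_meanlog = background_length_meanlog,
                 background_length_sdlog = background_length_sdlog,
                 cn_weights = cn_weights,
                 planted_family_cnv = planted_family_cnv,
                 planted_shared_cnv = planted_shared_cnv,
                 planted_common_cnv = planted_common_cnv,
                 common_sv_freq = common_sv_freq,
                 boundary_jitter_sd = boundary_jitter_sd),
            class = "sim_config")
}

# Deterministic per-stream seed derivation (kept below 2^31).
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 16807) %% 2147483647)
}

#' Simulate a genome: chromosome table, SNP grid, genes, exclusion regions
#'
#' Chromosomes chr1..chrN of equal length carry an SNP grid with exponential
#' inter-SNP spacing, gene models tiled with log-normal span lengths
#' (median 30 kb) separated by exponential gaps, and exclusion regions
#' emulating telomeres (outer 500 kb) and a centromere (central 500 kb).
#' Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return List with `chroms` (chromosome table), `snps` (named list of
#'   sorted SNP position vectors), `genes` (gene-model data.frame),
#'   `exclusions` (interval data.frame).
#' @export
simulate_genome <- function(config) {
  set.seed(derive_seed(config$seed, 1))
  chrom <- paste0("chr", seq_len(config$n_chromosomes))
  chroms <- chromosome_table(chrom, rep(config$chrom_length, length(chrom)))
  snps <- lapply(chrom, function(cc) {
    n_draw <- ceiling(config$chrom_length / config$snp_spacing * 1.3) + 50
    pos <- cumsum(ceiling(stats::rexp(n_draw, rate = 1 / config$snp_spacing)))
    while (pos[length(pos)] < config$chrom_length) {
      pos <- c(pos, pos[length(pos)] +
                 cumsum(ceiling(stats::rexp(n_draw, rate = 1 / config$snp_spacing))))
    }
    unique(pos[pos <= config$chrom_length])
  })
  names(snps) <- chrom
  genes <- do.call(rbind, lapply(chrom, function(cc) {
    pos <- 1
    starts <- numeric(0)
    ends <- numeric(0)
    repeat {
      gap <- ceiling(stats::rexp(1, rate = 1 / 60000))
      len <- ceiling(stats::rlnorm(1, meanlog = log(30000), sdlog = 0.8))
      s <- pos + gap
      e <- s + len - 1
      if (e > config$chrom_length) break
      starts <- c(starts, s)
      ends <- c(ends, e)
      pos <- e + 1
    }
    data.frame(symbol = sprintf("%s_G%04d", toupper(cc), seq_along(starts)),
               chrom = cc, start = starts, end = ends)
  }))
  tel <- 500000
  cen <- 250000
  mid <- round(config$chrom_length / 2)
  exclusions <- genomic_intervals(
    rep(chrom, each = 3),
    as.vector(vapply(chrom, function(cc) c(1, mid - cen, config$chrom_length - tel + 1),
                     numeric(3))),
    as.vector(vapply(chrom, function(cc) c(tel, mid + cen, config$chrom_length),
                     numeric(3))),
    require_autosome = FALSE)
  list(chroms = chroms, snps = snps, genes = genes, exclusions = exclusions)
}

# Number of grid SNPs inside [start, end] on one chromosome.
count_snps <- function(genome, chrom, start, end) {
  pos <- genome$snps[[chrom]]
  if (is.null(pos)) return(0L)
  sum(pos >= start & pos <= end)
}

# One sample's background CNVs, drawn from the sample's own stream.
draw_background <- function(config, genome, sample_id) {
  n <- stats::rpois(1, config$background_rate)
  if (n == 0) return(empty_calls())
  rows <- lapply(seq_len(n), function(i) {
    cc <- sample(genome$chroms$chrom, 1)
    pos <- genome$snps[[cc]]
    start <- pos[sample.int(length(pos), 1)]
    len <- ceiling(stats::rlnorm(1, config$background_length_meanlog,
                                 config$background_length_sdlog))
    end <- min(start + len - 1, config$chrom_length)
    cn <- as.integer(sample(names(config$cn_weights), 1,
                            prob = config$cn_weights))
    data.frame(chrom = cc, start = start, end = end, copy_number = cn,
               n_snps = count_snps(genome, cc, start, end),
               sample_id = sample_id)
  })
  do.call(rbind, rows)
}

# Jittered copy of a planted CNV for one carrier (uses the current stream).
jitter_plant <- function(plant, config, genome) {
  core_len <- plant$end - plant$start + 1
  cap <- floor(0.125 * core_len)
  clamp <- function(d) max(-cap, min(cap, round(d)))
  d1 <- clamp(stats::rnorm(1, 0, config$boundary_jitter_sd))
  d2 <- clamp(stats::rnorm(1, 0, config$boundary_jitter_sd))
  start <- max(1, plant$start + d1)
  end <- min(config$chrom_length, plant$end + d2)
  ns <- count_snps(genome, plant$chrom, start, end)
  data.frame(chrom = plant$chrom, start = start, end = end,
             copy_number = plant$copy_number, n_snps = ns,
             sample_id = NA_character_)
}

#' Simulate a full cohort: calls, pedigree, phenotypes, reference SVs, truth
#'
#' Samples are the pedigree members plus `CASE_###` and `CTRL_###` unrelated
#' individuals. Each sample receives Poisson background CNVs plus jittered
#' copies of every planted CNV listing it as a carrier; each call's `n_snps`
#' is the exact number of grid SNPs inside its interval. The reference-SV
#' table contains random flagged-common SVs plus, when a common CNV is
#' planted, a flagged-common SV of the same dosage class that contains every
#' jittered carrier copy. Planting a CNV overlapping an exclusion region is
#' an error so the simulated truth stays unambiguous.
#'
#' @param config A [sim_config()].
#' @param genome Optional pre-built genome from [simulate_genome()].
#' @return List: `calls`, `pedigree`, `phenotypes`, `samples` (sample_id,
#'   group, diagnosis), `ref_svs`, `genome`, `truth` (planted loci with
#'   carriers, per-sample background calls).
#' @export
simulate_cohort <- function(config, genome = NULL) {
  if (is.null(genome)) genome <- simulate_genome(config)
  plants <- Filter(Negate(is.null),
                   list(family = config$planted_family_cnv,
                        shared = config$planted_shared_cnv,
                        common = config$planted_common_cnv))
  for (nm in names(plants)) {
    p <- plants[[nm]]
    if (any(overlaps(genome$exclusions,
                     genomic_intervals(p$chrom, p$start, p$end,
                                       require_autosome = FALSE)))) {
      stop(sprintf("planted %s CNV overlaps an exclusion region", nm))
    }
  }
  ped <- config$families
  fam_ids <- if (is.null(ped)) character() else ped$sample_id
  case_ids <- if (config$n_case_samples > 0) {
    sprintf("CASE_%03d", seq_len(config$n_case_samples))
  } else character()
  ctrl_ids <- if (config$n_control_samples > 0) {
    sprintf("CTRL_%03d", seq_len(config$n_control_samples))
  } else character()
  all_ids <- c(fam_ids, case_ids, ctrl_ids)
  groups <- c(rep("FAMILY", length(fam_ids)), rep("CASE", length(case_ids)),
              rep("CONTROL", length(ctrl_ids)))

  call_rows <- vector("list", length(all_ids))
  bg_truth <- vector("list", length(all_ids))
  for (i in seq_along(all_ids)) {
    sid <- all_ids[i]
    set.seed(derive_seed(config$seed, 100 + i))
    bg <- draw_background(config, genome, sid)
    planted <- lapply(plants, function(p) {
      if (!sid %in% p$carriers) return(NULL)
      row <- jitter_plant(p, config, genome)
      row$sample_id <- sid
      row
    })
    planted <- do.call(rbind, Filter(Negate(is.null), planted))
    call_rows[[i]] <- rbind(bg, planted)
    bg_truth[[i]] <- bg
  }
  calls <- do.call(rbind, call_rows)
  calls <- calls[calls$n_snps >= 1, , drop = FALSE]
  rownames(calls) <- NULL

  set.seed(derive_seed(config$seed, 2))
  ref_rows <- list()
  for (cc in genome$chroms$chrom) {
    k <- 3
    starts <- sort(sample.int(config$chrom_length - 600000, k))
    lens <- ceiling(stats::rlnorm(k, log(200000), 0.5))
    ref_rows[[cc]] <- reference_svs(
      chrom = cc, start = starts, end = pmin(starts + lens - 1, config$chrom_length),
      svtype = sample(c("DEL", "DUP"), k, replace = TRUE),
      n_individuals = sample(150:2000, k),
      allele_freq = config$common_sv_freq, source = "GNOMAD_SV")
  }
  ref_svs <- do.call(rbind, ref_rows)
  # keep planted rare CNVs genuinely absent from the reference panel: a
  # random common SV landing on a family/shared plant would silently turn
  # the planted rare variant into a common one and make the truth ambiguous
  rare_plants <- plants[setdiff(names(plants), "common")]
  for (p in rare_plants) {
    hit <- overlaps(ref_svs,
                    genomic_intervals(p$chrom, p$start, p$end,
                                      require_autosome = FALSE))
    ref_svs <- ref_svs[!hit, , drop = FALSE]
  }
  if (!is.null(config$planted_common_cnv)) {
    p <- config$planted_common_cnv
    pad <- ceiling(0.15 * (p$end - p$start + 1))
    ref_svs <- rbind(ref_svs, reference_svs(
      chrom = p$chrom, start = max(1, p$start - pad),
      end = min(config$chrom_length, p$end + pad),
      svtype = if (p$copy_number < 2) "DEL" else "DUP",
      n_individuals = 500, allele_freq = 0.05, source = "GNOMAD_SV"))
  }
  rownames(ref_svs) <- NULL

  set.seed(derive_seed(config$seed, 3))
  dx_pool <- c("MCI", "AD", "FTD")
  samples <- data.frame(
    sample_id = all_ids, group = groups,
    diagnosis = c(if (is.null(ped)) character() else ped$diagnosis,
                  sample(dx_pool, length(case_ids), replace = TRUE),
                  rep("unaffected", length(ctrl_ids))))
  phenotypes <- data.frame(
    sample_id = all_ids, diagnosis = samples$diagnosis,
    age_at_onset = ifelse(samples$diagnosis %in% dx_pool,
                          round(stats::rnorm(length(all_ids), 65, 8)), NA),
    age_last_exam = round(stats::rnorm(length(all_ids), 70, 8)))

  names(bg_truth) <- all_ids
  list(calls = calls, pedigree = ped, phenotypes = phenotypes,
       samples = samples, ref_svs = ref_svs, genome = genome,
       truth = list(planted = plants, background = bg_truth))
}

#' Write a simulated cohort to disk in the pipeline's input formats
#'
#' Emits a combined rawcnv file plus one per sample, a 6-column PED file, the
#' phenotype/gene/chromosome/reference-SV TSVs, the exclusion BED, and a
#' truth.json sidecar.
#'
#' @param sim Result of [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
sim_write <- function(sim, dir) {
  dir.create(file.path(dir, "rawcnv"), recursive = TRUE, showWarnings = FALSE)
  write_rawcnv(sim$calls, file.path(dir, "all_calls.rawcnv"))
  for (sid in unique(sim$calls$sample_id)) {
    write_rawcnv(sim$calls[sim$calls$sample_id == sid, , drop = FALSE],
                 file.path(dir, "rawcnv", paste0(sid, ".rawcnv")))
  }
  if (!is.null(sim$pedigree)) {
    ped <- sim$pedigree
    aff_code <- c(UNAFFECTED = "1", AFFECTED = "2", AT_RISK = "0")
    writeLines(sprintf("%s %s %s %s %s %s", ped$family_id, ped$sample_id,
                       ifelse(is.na(ped$father_id), "0", ped$father_id),
                       ifelse(is.na(ped$mother_id), "0", ped$mother_id),
                       ped$sex, aff_code[ped$affection]),
               file.path(dir, "pedigree.ped"))
  }
  utils::write.table(sim$phenotypes, file.path(dir, "phenotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$genome$genes, file.path(dir, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$genome$chroms, file.path(dir, "chromosomes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  refs <- sim$ref_svs
  refs$svtype <- c(LOSS = "DEL", GAIN = "DUP", OTHER = "INV")[refs$dosage_class]
  utils::write.table(refs[, c("chrom", "start", "end", "svtype",
                              "n_individuals", "allele_freq")],
                     file.path(dir, "reference_svs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_bed_regions(sim$genome$exclusions, file.path(dir, "exclusions.bed"))
  utils::write.table(sim$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(planted = lapply(sim$truth$planted, unclass),
         background = lapply(sim$truth$background, function(df) {
           df[, c("chrom", "start", "end", "copy_number", "n_snps")]
         })),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Draw null case/control contingency tables
#'
#' Replicated 2x2 tables under the null of equal carrier probability in both
#' cohorts: case carriers ~ Binomial(`n_case`, `carrier_p`) and control
#' carriers ~ Binomial(`n_control`, `carrier_p`), independently per
#' replicate. Supports calibration checks of the Fisher test's type-I error
#' (which is conservative for discrete tables).
#'
#' @param n_replicates Number of tables.
#' @param carrier_p Shared carrier probability.
#' @param n_case,n_control Cohort sizes (defaults 2323 and 4567, the sizes of
#'   a post-QC biobank dementia/non-dementia comparison panel).
#' @param seed Integer seed.
#' @return Data.frame with columns `tp`, `fn`, `fp`, `tn`, one row per
#'   replicate.
#' @export
simulate_null_assoc <- function(n_replicates, carrier_p, n_case = 2323,
                                n_control = 4567, seed = 1L) {
  stopifnot(n_replicates >= 1, carrier_p >= 0, carrier_p <= 1)
  set.seed(as.integer(seed))
  tp <- stats::rbinom(n_replicates, n_case, carrier_p)
  fp <- stats::rbinom(n_replicates, n_control, carrier_p)
  data.frame(tp = tp, fn = n_case - tp, fp = fp, tn = n_control - fp)
}
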