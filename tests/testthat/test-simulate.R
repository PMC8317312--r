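small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, n_chromosomes = 2, chrom_length = 2e7,
             n_case_samples = 12, n_control_samples = 0,
             planted_family_cnv = plant_spec("chr1", 5e6, 5.15e6, 3,
                                             c("FAM1_SIB1", "FAM1_SIB2")),
             planted_shared_cnv = plant_spec("chr2", 8e6, 8.12e6, 1,
                                             c("CASE_001", "CASE_002")),
             planted_common_cnv = plant_spec("chr2", 1.4e7, 1.41e7, 1,
                                             c("FAM1_SIB1", "FAM1_SIB2",
                                               sprintf("CASE_%03d", 3:10))),
             ...)
}

test_that("the simulator is deterministic given the seed", {
  cfg <- small_cfg(seed = 5)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$calls, b$calls)
  expect_identical(a$genome$snps, b$genome$snps)
  expect_identical(a$ref_svs, b$ref_svs)
  c <- simulate_cohort(small_cfg(seed = 6))
  expect_false(identical(a$calls, c$calls))
})

test_that("SNP grid density matches the configured mean spacing", {
  for (seed in 1:20) {
    g <- simulate_genome(sim_config(seed = seed, n_chromosomes = 1,
                                    chrom_length = 5e7, snp_spacing = 4000))
    n <- length(g$snps$chr1)
    expect_gt(n, 12500 * 0.95)
    expect_lt(n, 12500 * 1.05)
    expect_false(is.unsorted(g$snps$chr1))
    expect_equal(anyDuplicated(g$snps$chr1), 0)
  }
})

test_that("every emitted call's n_snps equals the brute-force grid count", {
  sim <- simulate_cohort(small_cfg(seed = 9))
  for (i in seq_len(nrow(sim$calls))) {
    row <- sim$calls[i, ]
    pos <- sim$genome$snps[[row$chrom]]
    expect_equal(row$n_snps, sum(pos >= row$start & pos <= row$end))
  }
})

test_that("no background and no plants yields an empty callset", {
  cfg <- small_cfg(seed = 2, background_rate = 0)
  cfg$planted_family_cnv <- NULL
  cfg$planted_shared_cnv <- NULL
  cfg$planted_common_cnv <- NULL
  sim <- simulate_cohort(cfg)
  expect_equal(nrow(sim$calls), 0)
})

test_that("planted carriers receive jittered calls covering the plant design", {
  cfg <- small_cfg(seed = 3, background_rate = 0)
  sim <- simulate_cohort(cfg)
  p <- cfg$planted_family_cnv
  core <- genomic_intervals(p$chrom, p$start, p$end)
  for (sid in p$carriers) {
    carried <- sim$calls[sim$calls$sample_id == sid &
                           sim$calls$chrom == p$chrom, ]
    expect_equal(nrow(carried), 1)
    rec <- overlap_length(carried, core) /
      max(interval_length(carried), interval_length(core))
    expect_gte(rec, 0.5)  # jitter truncation keeps recovery decidable
    expect_equal(carried$copy_number, p$copy_number)
  }
  # the planted common CNV is contained in its emitted flagged-common SV
  pc <- cfg$planted_common_cnv
  common_ref <- sim$ref_svs[sim$ref_svs$is_flagged_common &
                              sim$ref_svs$chrom == pc$chrom &
                              sim$ref_svs$start <= pc$start &
                              sim$ref_svs$end >= pc$end, ]
  expect_gte(nrow(common_ref), 1)
  carrier_calls <- sim$calls[sim$calls$sample_id %in% pc$carriers &
                               sim$calls$chrom == pc$chrom &
                               overlaps(sim$calls, genomic_intervals(pc$chrom, pc$start, pc$end)), ]
  expect_equal(nrow(carrier_calls), length(pc$carriers))
  expect_true(all(contains(common_ref[1, ], carrier_calls)))
})

test_that("a plant colliding with an exclusion region is rejected", {
  cfg <- small_cfg(seed = 4)
  cfg$planted_family_cnv <- plant_spec("chr1", 1, 600000, 3, "FAM1_SIB1")
  expect_error(simulate_cohort(cfg), "exclusion region")
})

test_that("written cohort files round-trip to the simulated truth", {
  cfg <- small_cfg(seed = 12)
  sim <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  sim_write(sim, dir)
  back <- read_rawcnv(file.path(dir, "all_calls.rawcnv"))
  ord <- function(x) {
    x <- x[order(x$sample_id, x$chrom, x$start, x$copy_number), ]
    rownames(x) <- NULL
    x
  }
  expect_equal(ord(back), ord(sim$calls))
  ped <- read_pedigree(file.path(dir, "pedigree.ped"),
                       file.path(dir, "phenotypes.tsv"))
  expect_setequal(ped$sample_id, sim$pedigree$sample_id)
  expect_equal(ped$affection[match(sim$pedigree$sample_id, ped$sample_id)],
               sim$pedigree$affection)
  # carrier lists re-derived from the files reproduce the planted truth
  p <- cfg$planted_family_cnv
  hit <- back[overlaps(back, genomic_intervals(p$chrom, p$start, p$end)) &
                back$copy_number == p$copy_number, ]
  expect_setequal(unique(hit$sample_id), p$carriers)
  refs <- read_reference_svs(file.path(dir, "reference_svs.tsv"), "GNOMAD_SV")
  expect_equal(nrow(refs), nrow(sim$ref_svs))
  expect_equal(refs$is_flagged_common, sim$ref_svs$is_flagged_common)
})

test_that("null association tables have binomial carrier counts", {
  zero <- simulate_null_assoc(50, 0, seed = 4)
  expect_true(all(zero$tp == 0) && all(zero$fp == 0))
  a <- simulate_null_assoc(100, 0.01, seed = 4)
  expect_identical(a, simulate_null_assoc(100, 0.01, seed = 4))
  big <- simulate_null_assoc(2000, 0.01, n_case = 2323, n_control = 4567,
                             seed = 19)
  se <- sqrt(2323 * 0.01 * 0.99 / 2000)
  expect_lt(abs(mean(big$tp) - 23.23), 3 * se)
  expect_true(all(big$tp + big$fn == 2323))
  expect_true(all(big$fp + big$tn == 4567))
})
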