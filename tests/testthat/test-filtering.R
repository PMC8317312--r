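make_call <- function(chrom, start, end, cn = 1L, n_snps = 20L, sample = "S1") {
  data.frame(chrom = chrom, start = start, end = end, copy_number = cn,
             n_snps = n_snps, sample_id = sample)
}

test_that("quality filter applies both the SNP and length thresholds", {
  calls <- rbind(
    make_call("chr6", 108570894, 108694389, 3L, 15L),   # passes both
    make_call("chr1", 1e6, 1e6 + 99999, 1L, 9L),        # too few SNPs
    make_call("chr1", 2e6, 2e6 + 49998, 1L, 50L))       # one base short
  out <- filter_quality(calls, filter_config())
  expect_equal(nrow(out), 1)
  expect_equal(out$start, 108570894)
  # idempotent and field-preserving
  expect_equal(filter_quality(out, filter_config()), out)
})

test_that("adjacent same-state calls merge by the gap/span fraction", {
  pair <- rbind(make_call("chr1", 100001, 150000, 1L, 20L),
                make_call("chr1", 155000, 200000, 1L, 30L))
  merged <- merge_adjacent(pair, filter_config())  # gap 4999 / span 100000
  expect_equal(nrow(merged), 1)
  expect_equal(c(merged$start, merged$end), c(100001, 200000))
  expect_equal(merged$n_snps, 50L)

  wide <- rbind(make_call("chr1", 100001, 150000, 1L),
                make_call("chr1", 180001, 200000, 1L))  # gap fraction 0.3
  expect_equal(merge_adjacent(wide, filter_config()), wide)
  expect_equal(nrow(merge_adjacent(wide, filter_config(merge_gap_fraction = 0.3))), 1)

  mixed_cn <- rbind(make_call("chr1", 100001, 150000, 1L),
                    make_call("chr1", 150001, 200000, 3L))
  expect_equal(nrow(merge_adjacent(mixed_cn, filter_config())), 2)
  other_sample <- rbind(make_call("chr1", 100001, 150000, 1L, sample = "S1"),
                        make_call("chr1", 150001, 200000, 1L, sample = "S2"))
  expect_equal(nrow(merge_adjacent(other_sample, filter_config())), 2)
})

test_that("merge_adjacent reaches a fixpoint on random call sets", {
  set.seed(31)
  for (i in 1:25) {
    calls <- random_calls(30, max_pos = 4e5, min_len = 5e3, max_len = 8e4)
    out <- merge_adjacent(calls, filter_config())
    expect_false(any_mergeable_pair(out, 0.2))
    expect_equal(sum(out$n_snps), sum(calls$n_snps))  # SNP support conserved
    expect_equal(merge_adjacent(out, filter_config()), out)  # idempotent
  }
})

test_that("exclusion masking removes any-overlap calls only", {
  excl <- genomic_intervals("chr1", 5e5, 6e5)
  cfg <- filter_config(exclusion_regions = excl)
  touching <- make_call("chr1", 4e5, 5e5)    # 1-base overlap
  adjacent <- make_call("chr1", 3e5, 499999) # stops one base short
  expect_equal(nrow(apply_exclusions(touching, cfg)), 0)
  expect_equal(apply_exclusions(adjacent, cfg), adjacent)
  expect_equal(apply_exclusions(touching, filter_config()), touching)
  both <- rbind(touching, adjacent)
  once <- apply_exclusions(both, cfg)
  expect_equal(apply_exclusions(once, cfg), once)
})

test_that("gene annotation lists overlapping genes ordered by start", {
  genes <- data.frame(symbol = c("SNX3", "AFG1L", "FAR_AWAY"),
                      chrom = c("chr6", "chr6", "chr6"),
                      start = c(108630000, 108580000, 120000000),
                      end = c(108640000, 108620000, 120100000))
  call <- make_call("chr6", 108570894, 108694389, 3L)
  ann <- annotate_genes(call, genes)
  expect_equal(ann$genes[[1]], c("AFG1L", "SNX3"))
  none <- annotate_genes(make_call("chr6", 1000, 2000), genes)
  expect_equal(none$genes[[1]], character())
  one_base <- annotate_genes(make_call("chr6", 108640000, 108700000), genes)
  expect_equal(one_base$genes[[1]], "SNX3")
})

test_that("common flagging requires containment and matching dosage class", {
  refs <- rbind(
    reference_svs("chr1", 1e6, 2e6, "DEL", 500, 0.05, "GNOMAD_SV"),
    reference_svs("chr1", 1e6, 2e6, "DUP", 40, 0.001, "GNOMAD_SV"),
    reference_svs("chr2", 1e6, 2e6, "DUP", 150, NA, "DGV"))
  del_in <- flag_common(make_call("chr1", 1.2e6, 1.8e6, 1L), refs)
  expect_true(del_in$is_common)
  dup_in <- flag_common(make_call("chr1", 1.2e6, 1.8e6, 3L), refs)
  expect_false(dup_in$is_common)  # only a common deletion spans it
  expect_match(dup_in$gnomad_span, "in")
  partial <- flag_common(make_call("chr1", 1.5e6, 2.5e6, 1L), refs)
  expect_false(partial$is_common)
  dgv_dup <- flag_common(make_call("chr2", 1.2e6, 1.8e6, 3L), refs)
  expect_true(dgv_dup$is_common)
  expect_equal(dgv_dup$dgv_common_count, 1L)
})

test_that("flag_common matches a brute-force double loop on random data", {
  set.seed(99)
  ref_start <- sample.int(9e5, 200)
  refs <- reference_svs(
    chrom = sample(c("chr1", "chr2"), 200, replace = TRUE),
    start = ref_start,
    end = ref_start + sample.int(4e5, 200),
    svtype = sample(c("DEL", "DUP", "INV"), 200, replace = TRUE),
    n_individuals = sample(0:500, 200, replace = TRUE),
    allele_freq = round(runif(200, 0, 0.1), 3), source = "GNOMAD_SV")
  calls <- random_calls(500, max_pos = 9e5, min_len = 1e4, max_len = 3e5)
  flagged <- flag_common(calls, refs)
  oracle <- vapply(seq_len(nrow(calls)),
                   function(i) flag_common_oracle(calls[i, ], refs), NA)
  expect_identical(flagged$is_common, oracle)
  # idempotent: re-flagging does not change the verdict
  expect_identical(flag_common(flagged, refs)$is_common, flagged$is_common)
})
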