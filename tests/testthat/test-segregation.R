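fam_records <- function(ids, affection, family = "FAM1") {
  data.frame(sample_id = ids, family_id = family,
              father_id = NA_character_, mother_id = NA_character_,
              sex = "1", affection = affection)
}

seg_call <- function(sample, chrom = "chr6", start = 108570894,
                     end = 108694389, cn = 3L, n_snps = 15L) {
  data.frame(chrom = chrom, start = start, end = end, copy_number = cn,
             n_snps = n_snps, sample_id = sample)
}

test_that("call matching uses reciprocal overlap of the larger call", {
  cfg <- segregation_config()
  a <- seg_call("S1", start = 1e6, end = 1e6 + 99999)
  expect_true(match_calls(a, seg_call("S2", start = 1e6, end = 1e6 + 99999), cfg))
  # overlap is 40% of the larger call
  b <- seg_call("S2", start = 1e6 + 60000, end = 1e6 + 159999)
  expect_equal(overlap_length(a, b) / max(interval_length(a), interval_length(b)),
               0.4)
  expect_false(match_calls(a, b, cfg))
  # 60 kb call fully inside a 100 kb call: reciprocal 0.6
  c60 <- seg_call("S2", start = 1e6 + 20000, end = 1e6 + 79999)
  expect_true(match_calls(a, c60, cfg))
  # dosage mismatch vetoes regardless of overlap
  expect_false(match_calls(a, seg_call("S2", start = 1e6, end = 1e6 + 99999, cn = 1L), cfg))
  expect_true(match_calls(a, seg_call("S2", start = 1e6, end = 1e6 + 99999, cn = 1L),
                          segregation_config(require_same_dosage = FALSE)))
})

test_that("affected-only carrier groups become candidates", {
  sibs <- fam_records(c("SIB1", "SIB2"), c("AFFECTED", "AFFECTED"))
  calls <- rbind(seg_call("SIB1"), seg_call("SIB2"))
  out <- segregation_scan(sibs, calls)
  expect_equal(nrow(out), 1)
  expect_equal(out$status, "CANDIDATE")
  expect_equal(out$carrier_ids[[1]], c("SIB1", "SIB2"))
  expect_equal(out$copy_number, 3L)
  # identical member calls give exactly the planted boundaries
  expect_equal(c(out$start, out$end), c(108570894, 108694389))
  expect_equal(c(out$union_start, out$union_end), c(108570894, 108694389))
})

test_that("an unaffected carrier vetoes and all-unaffected is protective", {
  trio <- fam_records(c("FA", "MO", "SON"),
                      c("AFFECTED", "UNAFFECTED", "AT_RISK"))
  veto <- rbind(seg_call("FA"), seg_call("MO"))
  expect_equal(nrow(segregation_scan(trio, veto)), 0)
  protective <- seg_call("MO")
  out <- segregation_scan(trio, protective)
  expect_equal(out$status, "PROTECTIVE")
  # at-risk carriers neither qualify nor veto
  with_risk <- rbind(seg_call("FA"), seg_call("SON"))
  out2 <- segregation_scan(trio, with_risk)
  expect_equal(out2$status, "CANDIDATE")
  expect_equal(out2$n_carriers, 2L)
  risk_only <- seg_call("SON")
  expect_equal(nrow(segregation_scan(trio, risk_only)), 0)
  # unaffected + at-risk carriers: neither candidate nor protective
  mixed <- rbind(seg_call("MO"), seg_call("SON"))
  expect_equal(nrow(segregation_scan(trio, mixed)), 0)
})

test_that("families with only at-risk members are skipped with a warning", {
  fam <- fam_records(c("A", "B"), c("AT_RISK", "AT_RISK"))
  expect_warning(out <- segregation_scan(fam, seg_call("A")),
                 "no genotyped affected or unaffected")
  expect_equal(nrow(out), 0)
})

test_that("no CANDIDATE ever carries an unaffected member (random scans)", {
  set.seed(202)
  ids <- paste0("M", 1:4)
  for (i in 1:30) {
    fam <- fam_records(ids, sample(c("AFFECTED", "UNAFFECTED", "AT_RISK"),
                                   4, replace = TRUE))
    calls <- random_calls(12, chroms = "chr1", samples = ids,
                          max_pos = 5e5, min_len = 5e4, max_len = 1e5)
    out <- suppressWarnings(segregation_scan(fam, calls))
    if (nrow(out) == 0) next
    aff <- setNames(fam$affection, fam$sample_id)
    for (r in seq_len(nrow(out))) {
      statuses <- aff[out$carrier_ids[[r]]]
      if (out$status[r] == "CANDIDATE") {
        expect_true(any(statuses == "AFFECTED"))
        expect_false(any(statuses == "UNAFFECTED"))
      } else {
        expect_true(all(statuses == "UNAFFECTED"))
      }
    }
  }
})

test_that("scan output is invariant under permutation of call order", {
  set.seed(77)
  fam <- fam_records(c("A", "B", "C"), c("AFFECTED", "AFFECTED", "UNAFFECTED"))
  calls <- random_calls(15, chroms = c("chr1", "chr2"),
                        samples = c("A", "B", "C"),
                        max_pos = 5e5, min_len = 4e4, max_len = 9e4)
  ref <- segregation_scan(fam, calls)
  for (i in 1:5) {
    perm <- calls[sample.int(nrow(calls)), ]
    expect_equal(segregation_scan(fam, perm), ref)
  }
})

test_that("a fully shared call is vetoed by any unaffected member", {
  members <- c("A", "B", "C")
  calls <- do.call(rbind, lapply(members, seg_call))
  with_unaff <- fam_records(members, c("AFFECTED", "AFFECTED", "UNAFFECTED"))
  expect_equal(nrow(segregation_scan(with_unaff, calls)), 0)
  all_aff <- fam_records(members, rep("AFFECTED", 3))
  out <- segregation_scan(all_aff, calls)
  expect_equal(out$status, "CANDIDATE")
  expect_equal(out$n_carriers, 3L)
})

test_that("cohort lookup counts overlapping non-family calls", {
  region <- genomic_intervals("chr6", 108570894, 108694389)
  cohort <- rbind(seg_call("SIB1"), seg_call("OTHER", chrom = "chr2"))
  expect_equal(cohort_lookup(region, cohort, exclude_samples = "SIB1"), 0L)
  planted <- rbind(cohort, seg_call("COHORT_X", start = 108600000,
                                    end = 108650000, cn = 1L))
  expect_equal(cohort_lookup(region, planted, exclude_samples = "SIB1"), 1L)
})
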