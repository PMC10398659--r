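# Toy genome for calling tests: one chromosome, three 100-bp TEs of family
# "FAM" plus an excluded TE overlapping bins 8-9.
toy_calling_fixture <- function(ref_ratios, tg_ratios, C = 10L) {
  ref <- bin_ratio_records(ref_ratios, C = C)
  tg <- bin_ratio_records(tg_ratios, C = C)
  n <- length(ref_ratios)
  bins <- bin_genome(list(ref = ref, tg = tg),
                     chrom_sizes = c(c = n * 50L), bin_size = 50L)
  list(ref = ref, tg = tg, bins = bins)
}

test_that("hypo-DMR calling applies the strict delta rule within the family scope", {
  # bins: 1 drops 0.9->0.4 (called), 2 drops exactly 0.40 (not called),
  # 3 unchanged, 4 gains methylation (directional mode ignores it)
  fx <- toy_calling_fixture(c(0.9, 0.9, 0.9, 0.4), c(0.4, 0.5, 0.9, 0.9))
  tes <- toy_tes(te_id = "TE1", chrom = "c", start = 0L, end = 200L,
                 strand = "+", family = "FAM")
  dmrs <- call_hypo_dmrs(fx$bins, "ref", "tg", tes, family_scope = "FAM")
  expect_equal(dmrs$bins$start, 0L)
  expect_equal(dmrs$bins$value, 0.5)
  # absolute mode additionally calls the gain bin
  abs_dmrs <- call_hypo_dmrs(fx$bins, "ref", "tg", tes,
                             family_scope = "FAM", directional = FALSE)
  expect_equal(abs_dmrs$bins$start, c(0L, 150L))
})

test_that("bins overlapping an excluded TE are removed even when qualifying", {
  fx <- toy_calling_fixture(rep(0.9, 4), rep(0.1, 4))
  tes <- toy_tes(te_id = c("TE1", "HIUN"), chrom = "c",
                 start = c(0L, 150L), end = c(200L, 200L),
                 strand = "+", family = "FAM")
  dmrs <- call_hypo_dmrs(fx$bins, "ref", "tg", tes, family_scope = "FAM",
                         exclusions = "HIUN")
  expect_equal(dmrs$bins$start, c(0L, 50L, 100L))  # bin [150,200) excluded
  expect_true(all(!bin_key(dmrs$bins) %in% "c:150"))
  expect_warning(
    call_hypo_dmrs(fx$bins, "ref", "tg", tes, family_scope = "FAM",
                   exclusions = "NOSUCH"),
    "unknown exclusion")
  expect_error(call_hypo_dmrs(fx$bins, "ref", "tg", tes,
                              family_scope = character()), "family scope")
  expect_error(call_hypo_dmrs(fx$bins, "ref", "tg", tes,
                              family_scope = "NOPE"), "no TE")
})

test_that("undefined and under-covered ratios never produce calls", {
  # single CG site per bin with 3 reads: bin coverage 3 < min_cov = 4,
  # despite a full 1.0 -> 0.0 methylation drop
  ref <- mk_records("c", c(5L, 55L), 3L, 0L, "CpG")
  tg <- mk_records("c", c(5L, 55L), 0L, 3L, "CpG")
  bt <- bin_genome(list(ref = ref, tg = tg), chrom_sizes = c(c = 100L))
  tes <- toy_tes(te_id = "TE1", chrom = "c", start = 0L, end = 100L,
                 strand = "+", family = "FAM")
  dmrs <- call_hypo_dmrs(bt, "ref", "tg", tes, family_scope = "FAM",
                         min_cov = 4L)
  expect_equal(nrow(dmrs$bins), 0L)
  # the same bins are called once the coverage requirement is met
  dmrs2 <- call_hypo_dmrs(bt, "ref", "tg", tes, family_scope = "FAM",
                          min_cov = 3L)
  expect_equal(nrow(dmrs2$bins), 2L)
})

test_that("VANC-target TE selection uses the strict > 2 bin rule", {
  tes <- toy_tes(te_id = c("T3", "T2", "T0"), chrom = "c",
                 start = c(0L, 200L, 400L), end = c(150L, 350L, 500L),
                 strand = "+", family = "FAM")
  dmr_bins <- data.table::data.table(
    chrom = "c", start = c(0L, 50L, 100L, 200L, 250L),
    end = c(50L, 100L, 150L, 250L, 300L), value = 0.5)
  dmrs <- target_set(dmr_bins, "vanc_hypo_dmr")
  sel <- select_vanc_target_tes(tes, dmrs, min_dmrs_exclusive = 2L)
  expect_equal(sel, "T3")   # 3 bins selected, 2 bins not, 0 bins not
  # monotone in the cutoff: a higher cutoff selects a subset
  sel1 <- select_vanc_target_tes(tes, dmrs, min_dmrs_exclusive = 1L)
  expect_true(all(sel %in% sel1))
  expect_equal(sort(sel1), c("T2", "T3"))
})

test_that("RdDM-target calling uses the strict CHH > 0.1 rule and propagates missingness", {
  chh <- data.table::rbindlist(list(
    mk_records("c", c(5L, 15L), 5L, 15L, "CHH"),    # bin 0: ratio 0.25
    mk_records("c", c(55L, 65L), 2L, 18L, "CHH"),   # bin 1: ratio exactly 0.10
    mk_records("c", 105L, 0L, 0L, "CHH"),           # bin 2: zero coverage
    mk_records("c", 155L, 9L, 1L, "CpG")            # bin 3: CHH absent entirely
  ))
  bins <- bin_genome(list(cmt23 = chh), chrom_sizes = c(c = 200L))
  tes <- toy_tes(te_id = "TE1", chrom = "c", start = 0L, end = 200L,
                 strand = "+", family = "FAM")
  rddm <- call_rddm_targets(bins, "cmt23", scope_tes = tes)
  expect_equal(rddm$bins$start, 0L)
  expect_equal(rddm$bins$value, 0.25)
  expect_error(call_rddm_targets(bins, "missing_sample"), "absent")
})

test_that("lowering thresholds yields supersets of calls (monotonicity)", {
  set.seed(21)
  ref_r <- runif(40, 0.5, 1)
  tg_r <- pmax(0, ref_r - runif(40, 0, 0.8))
  fx <- toy_calling_fixture(round(ref_r, 1), round(tg_r, 1))
  tes <- toy_tes(te_id = "TE1", chrom = "c", start = 0L, end = 2000L,
                 strand = "+", family = "FAM")
  for (pair in list(c(0.4, 0.2), c(0.6, 0.3))) {
    hi <- call_hypo_dmrs(fx$bins, "ref", "tg", tes, "FAM", delta = pair[1])
    lo <- call_hypo_dmrs(fx$bins, "ref", "tg", tes, "FAM", delta = pair[2])
    expect_true(all(bin_key(hi$bins) %in% bin_key(lo$bins)))
  }
})

test_that("merge_adjacent merges exactly the distance-0 runs and is idempotent", {
  ts <- target_set(data.table::data.table(
    chrom = "c", start = c(0L, 50L, 150L), end = c(50L, 100L, 200L),
    value = c(0.4, 0.6, 0.8)), "vanc_hypo_dmr")
  m <- merge_adjacent(ts)
  expect_equal(m$bins$start, c(0L, 150L))
  expect_equal(m$bins$end, c(100L, 200L))
  expect_equal(m$bins$value, c(0.5, 0.8))  # mean of member bins
  # non-adjacent bins unchanged
  ts2 <- target_set(data.table::data.table(
    chrom = "c", start = c(0L, 100L), end = c(50L, 150L), value = 1), "x")
  expect_equal(merge_adjacent(ts2)$bins[, c("start", "end")],
               ts2$bins[, c("start", "end")])
  # adjacency does not leak across chromosomes
  ts3 <- target_set(data.table::data.table(
    chrom = c("a", "b"), start = c(0L, 50L), end = c(50L, 100L), value = 1), "x")
  expect_equal(nrow(merge_adjacent(ts3)$bins), 2L)
  # idempotence
  expect_equal(merge_adjacent(m)$bins, m$bins)
})
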