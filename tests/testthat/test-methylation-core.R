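test_that("methylation ratio is M/C with undefined (never 0) at zero coverage", {
  expect_equal(methylation_ratio(3, 10), 0.3)
  expect_equal(methylation_ratio(10, 10), 1.0)
  expect_true(is.na(methylation_ratio(0, 0)))
  expect_equal(methylation_ratio(c(3, 0, 10), c(10, 0, 10)),
               c(0.3, NA, 1.0))
  expect_error(methylation_ratio(11, 10), "M > C")
})

test_that("aggregate_region sums counts over the interval and is additive", {
  rec <- mk_records("c", c(10L, 20L), m = c(3L, 0L), u = c(7L, 10L), "CpG")
  a <- aggregate_region(rec, list(chrom = "c", start = 0L, end = 50L), "CpG")
  expect_equal(a$M, 3L)
  expect_equal(a$C, 20L)
  expect_equal(a$ratio, 0.15)
  # no cytosines of the requested context
  none <- aggregate_region(rec, list(chrom = "c", start = 0L, end = 50L), "CHH")
  expect_equal(none$M, 0L)
  expect_equal(none$C, 0L)
  expect_true(is.na(none$ratio))
  # additivity: halves sum to the whole
  left <- aggregate_region(rec, list(chrom = "c", start = 0L, end = 15L), "CpG")
  right <- aggregate_region(rec, list(chrom = "c", start = 15L, end = 50L), "CpG")
  expect_equal(left$M + right$M, a$M)
  expect_equal(left$C + right$C, a$C)
})

test_that("change statistic matches hand-computed values exactly", {
  expect_equal(te_change_statistic(50, 100, 50, 100), 0)
  expect_equal(te_change_statistic(100, 100, 0, 100), 5.0, tolerance = 1e-12)
  expect_equal(te_change_statistic(0, 100, 100, 100), -5.0, tolerance = 1e-12)
  # doubling both coverages at fixed ratios scales S by sqrt(2)
  expect_equal(te_change_statistic(200, 200, 0, 200), 5.0 * sqrt(2),
               tolerance = 1e-12)
  # zero coverage flags the score rather than erroring
  expect_true(is.na(te_change_statistic(0, 0, 5, 10)))
  expect_error(te_change_statistic(11, 10, 0, 10), "M > C")
})

test_that("change statistic is antisymmetric and coverage-scaling for random inputs", {
  set.seed(7)
  n <- 1000L
  Cn <- sample(1:500, n, replace = TRUE)
  Ct <- sample(1:500, n, replace = TRUE)
  Mn <- vapply(Cn, function(c) sample(0:c, 1L), integer(1))
  Mt <- vapply(Ct, function(c) sample(0:c, 1L), integer(1))
  s <- te_change_statistic(Mn, Cn, Mt, Ct)
  # antisymmetry: swapping the (n) and (t) roles flips the sign
  expect_equal(te_change_statistic(Mt, Ct, Mn, Cn), -s, tolerance = 1e-12)
  # coverage scaling: k-fold coverage at fixed ratios scales S by sqrt(k)
  k <- 4
  expect_equal(te_change_statistic(Mn * k, Cn * k, Mt * k, Ct * k),
               s * sqrt(k), tolerance = 1e-12)
})

test_that("score_all_tes ranks a fully demethylated TE highest and flags zero coverage", {
  tes <- toy_tes(te_id = c("T1", "T2", "T3"), chrom = "c",
                 start = c(0L, 200L, 400L), end = c(100L, 300L, 500L),
                 strand = "+", family = "F")
  full <- data.table::rbindlist(list(
    mk_records("c", c(10L, 50L), 9L, 1L, "CpG"),
    mk_records("c", c(210L, 250L), 9L, 1L, "CpG"),
    mk_records("c", c(410L, 450L), 9L, 1L, "CpG")
  ))
  lost <- data.table::copy(full)
  lost[pos0 < 100L, `:=`(m = 0L, u = 10L)]   # T1 fully demethylated in t
  s <- score_all_tes(full, lost, tes)
  expect_equal(s$te_id[which.max(s$S)], "T1")
  # identical samples on both axes give S = 0 everywhere
  s0 <- score_all_tes(full, full, tes)
  expect_true(all(s0$S == 0))
  # a TE with zero coverage in t is flagged undefined
  nocov <- full[pos0 >= 200L]
  s1 <- score_all_tes(full, nocov, tes)
  expect_true(is.na(s1[te_id == "T1", S]))
  expect_false(anyNA(s1[te_id != "T1", S]))
})

test_that("score_all_tes warns when an annotation chromosome is uncovered", {
  tes <- toy_tes(te_id = c("T1", "TX"), chrom = c("c", "cX"),
                 start = 0L, end = 100L, strand = "+", family = "F")
  rec <- mk_records("c", 10L, 5L, 5L, "CpG")
  expect_warning(score_all_tes(rec, rec, tes), "cX")
})

test_that("bin_genome tiles chromosomes, truncates the last bin, and conserves counts", {
  rec <- mk_records("c", c(0L, 49L, 50L, 110L), 2L, 3L, "CpG")
  bt <- bin_genome(list(s = rec), chrom_sizes = c(c = 120L), bin_size = 50L)
  cg <- bt$counts[context == "CpG"]
  expect_equal(cg$start, c(0L, 50L, 100L))
  expect_equal(cg$end, c(50L, 100L, 120L))  # terminal bin truncated
  # 1-based position 50 (0-based 49) falls in [0, 50)
  expect_equal(cg[start == 0L, C], 10L)  # two cytosines x 5 reads
  # conservation: bin sums equal the genome-wide totals
  expect_equal(sum(cg$M), sum(rec$m))
  expect_equal(sum(cg$C), sum(rec$m + rec$u))
  expect_error(bin_genome(list(s = rec), bin_size = 0L), "bin_size")
})

test_that("locus_profile is flat on uniform data and consistent with aggregation", {
  rec <- uniform_records(len = 1000L, spacing = 10L, m = 8L, u = 2L,
                         chrom = "c")
  iv <- list(chrom = "c", start = 0L, end = 1000L)
  prof <- locus_profile(rec, iv, window = 100L, step = 50L)
  expect_true(all(abs(prof$ratio - 0.8) < 1e-12))
  # window covering the whole interval equals aggregate_region
  whole <- locus_profile(rec, iv, window = 2000L, step = 50L)
  agg <- aggregate_region(rec, iv, "CpG")
  expect_equal(nrow(whole[context == "CpG"]), 1L)
  expect_equal(whole[context == "CpG", ratio], agg$ratio)
  expect_error(locus_profile(rec, iv, window = 10L, step = 20L), "window")
})

test_that("locus_profile with window = step = bin size reproduces BinTable rows", {
  set.seed(11)
  pos0 <- sort(sample(0:499, 60))
  rec <- mk_records("c", pos0, sample(0:5, 60, TRUE), sample(0:5, 60, TRUE),
                    sample(c("CpG", "CHG", "CHH"), 60, TRUE))
  bt <- bin_genome(list(s = rec), chrom_sizes = c(c = 500L), bin_size = 50L)
  prof <- locus_profile(rec, list(chrom = "c", start = 0L, end = 500L),
                        window = 50L, step = 50L)
  merged <- merge(prof[C > 0], bt$counts,
                  by = c("chrom", "start", "end", "context"))
  expect_gt(nrow(merged), 0L)
  expect_equal(merged$ratio.x, merged$ratio.y)
  expect_equal(merged$M.x, merged$M.y)
})

test_that("region-class summaries average per-TE ratios", {
  tes_dt <- data.table::data.table(
    te_id = c("T1", "T2"), chrom = "c", start = c(0L, 200L),
    end = c(100L, 300L), strand = "+", family = "F")
  regions <- data.table::data.table(
    te_id = c("T1", "T2"), chrom = "c", start = c(0L, 200L),
    end = c(100L, 300L), class = "coding")
  ann <- te_annotation(tes_dt, regions = regions)
  # T1 coding ratio 0.2, T2 coding ratio 0.4 -> mean 0.3
  rec <- data.table::rbindlist(list(
    mk_records("c", c(10L, 20L), 2L, 8L, "CpG"),
    mk_records("c", c(210L, 220L), 4L, 6L, "CpG")
  ))
  s <- summarize_by_region_class(list(x = rec), ann)
  cg <- s[class == "coding" & context == "CpG"]
  expect_equal(cg$mean_ratio, 0.3)
  expect_equal(cg$n_te, 2L)
  # identical ratios give SD 0
  rec2 <- data.table::rbindlist(list(
    mk_records("c", c(10L, 20L), 5L, 5L, "CpG"),
    mk_records("c", c(210L, 220L), 5L, 5L, "CpG")
  ))
  s2 <- summarize_by_region_class(list(x = rec2), ann)
  expect_equal(s2[context == "CpG", sd_ratio], 0)
  # a TE without region classes is excluded with a warning
  ann3 <- te_annotation(
    data.table::rbindlist(list(tes_dt, data.table::data.table(
      te_id = "T3", chrom = "c", start = 400L, end = 500L, strand = "+",
      family = "F"))),
    regions = regions)
  expect_warning(summarize_by_region_class(list(x = rec), ann3), "T3")
})
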