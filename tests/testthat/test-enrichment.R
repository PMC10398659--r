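tiling <- function(n, chrom = "c", bin = 50L) {
  data.table::data.table(chrom = chrom, start = seq(0L, (n - 1L) * bin, bin),
                         end = seq(bin, n * bin, bin))
}

test_that("overlap counts are set arithmetic over the universe", {
  u <- tiling(10)
  A <- target_set(u[c(1, 2)], "a")
  B <- target_set(u[c(2, 3)], "b")
  cnt <- overlap_count(A, B, u)
  expect_equal(cnt, list(N = 10L, K = 2L, n = 2L, k = 1L))
  same <- overlap_count(A, A, u)
  expect_equal(same$k, same$n)
  expect_equal(same$k, same$K)
  disj <- overlap_count(A, target_set(u[5:6], "b"), u)
  expect_equal(disj$k, 0L)
  # duplicated bins do not double count
  dup <- target_set(rbind(u[c(1, 2)], u[c(1, 2)]), "a")
  expect_equal(overlap_count(dup, B, u)$n, 2L)
  # different tilings are rejected
  u2 <- tiling(10, bin = 100L)
  expect_error(overlap_count(A, target_set(u2[1:2], "b"), u), "bin sizes")
})

test_that("hypergeometric tail matches brute-force enumeration", {
  # worked case: draw 4 bins from 10 of which 5 are targets
  expect_equal(hypergeometric_tail(4, 5, 4, 10), 5 / 210, tolerance = 1e-12)
  # independent oracle: enumerate all C(10, 4) draws
  draws <- utils::combn(10, 4)
  ov <- colSums(draws <= 5)
  for (k in 0:4) {
    expect_equal(hypergeometric_tail(k, 5, 4, 10), mean(ov >= k),
                 tolerance = 1e-12)
  }
  expect_equal(hypergeometric_tail(0, 5, 4, 10), 1.0)
  expect_equal(hypergeometric_tail(7, 7, 7, 7), 1.0)  # degenerate universe
  expect_error(hypergeometric_tail(5, 4, 4, 10), "inconsistent")
  # log-space form agrees and stays finite where exp underflows
  expect_equal(hypergeometric_tail(4, 5, 4, 10, log10p = TRUE),
               log10(5 / 210), tolerance = 1e-12)
  lp <- hypergeometric_tail(500, 500, 500, 1500, log10p = TRUE)
  expect_true(is.finite(lp) && lp < -100)
})

test_that("hypergeometric tail is monotone decreasing in k", {
  p <- vapply(0:20, function(k) hypergeometric_tail(k, 30, 20, 100),
              numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("fold enrichment follows (k/n)/(K/N)", {
  expect_equal(fold_enrichment(10, 5, 4, 4), 2.0)
  # independence expectation k = nK/N gives fold 1
  expect_equal(fold_enrichment(10, 5, 4, 2), 1.0)
  expect_equal(fold_enrichment(10, 5, 4, 0), 0.0)
  expect_true(is.na(fold_enrichment(10, 5, 0, 0)))
  expect_true(is.na(fold_enrichment(10, 0, 4, 0)))
})

test_that("shuffle null is seeded, reproducible, and degenerate when forced", {
  u <- tiling(20)
  ref <- target_set(u[1:5], "ref")
  q <- data.table::data.table(chrom = "c", start = 0L, end = 100L)
  # space exactly the query size: every iteration is the forced placement
  forced <- shuffle_null(q, data.table::data.table(chrom = "c", start = 300L,
                                                   end = 400L),
                         ref, iterations = 20L, seed = 5L)
  expect_true(all(forced$overlaps == forced$overlaps[1]))
  # identical seed and inputs give bit-identical distributions
  s1 <- shuffle_null(q, u[, .(chrom = chrom[1], start = 0L, end = 1000L)],
                     ref, iterations = 50L, seed = 11L)
  s2 <- shuffle_null(q, u[, .(chrom = chrom[1], start = 0L, end = 1000L)],
                     ref, iterations = 50L, seed = 11L)
  expect_identical(s1$overlaps, s2$overlaps)
  s3 <- shuffle_null(q, u[, .(chrom = chrom[1], start = 0L, end = 1000L)],
                     ref, iterations = 50L, seed = 12L)
  expect_false(identical(s1$overlaps, s3$overlaps))
  # reference covering the whole space: observed = total, empirical p = 1
  all_ref <- target_set(u, "ref")
  s4 <- shuffle_null(q, data.table::data.table(chrom = "c", start = 0L,
                                               end = 1000L),
                     all_ref, iterations = 30L, seed = 1L)
  expect_true(all(s4$overlaps == s4$observed))
  expect_equal(s4$p_empirical, 1.0)
  # space smaller than the query errors
  expect_error(
    shuffle_null(q, data.table::data.table(chrom = "c", start = 0L, end = 50L),
                 ref, iterations = 5L, seed = 1L),
    "space")
})

test_that("shuffle mean approaches nK/N against an independent random reference", {
  n_bins <- 200L
  u <- tiling(n_bins)
  set.seed(31)
  ref <- target_set(u[sample(n_bins, 50L)], "ref")
  q_bins <- u[sample(n_bins, 10L)]
  s <- shuffle_null(target_set(q_bins, "q"),
                    data.table::data.table(chrom = "c", start = 0L,
                                           end = n_bins * 50L),
                    ref, iterations = 300L, seed = 17L)
  expected <- 10 * 50 / 200
  se <- stats::sd(s$overlaps) / sqrt(s$iterations)
  expect_lt(abs(s$mean - expected), 3 * se + 1e-9)
})

test_that("enrichment_test composes counts, fold, tail and shuffle", {
  u <- tiling(10)
  A <- target_set(u[1:4], "vanc_hypo_dmr")
  B <- target_set(u[1:5], "rddm_target")
  res <- enrichment_test(A, B, u, iterations = 200L, seed = 3L)
  expect_equal(c(res$N, res$K, res$n, res$k), c(10L, 5L, 4L, 4L))
  expect_equal(res$fold, 2.0)
  expect_equal(res$p_hyper, 5 / 210, tolerance = 1e-12)
  # forced geometry: the merged 200-bp query placed in the 500-bp space has
  # 7 grid slots, 2 of which reach the observed overlap of 4 -> p ~= 2/7
  expect_lt(abs(res$shuffle$p_empirical - 2 / 7), 0.1)
  # empty query: undefined fold, p = 1, no shuffle
  empty <- target_set(data.table::data.table(
    chrom = character(), start = integer(), end = integer(),
    value = numeric()), "vanc_hypo_dmr")
  res0 <- enrichment_test(empty, B, u, iterations = 10L, seed = 3L)
  expect_true(is.na(res0$fold))
  expect_equal(res0$p_hyper, 1.0)
  expect_null(res0$shuffle)
})
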