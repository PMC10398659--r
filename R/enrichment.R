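# Overlap enrichment between VANC hypo-DMR targets and RdDM targets:
# counts over a bin universe, exact hypergeometric upper tail, fold
# overrepresentation, and a size-matched shuffle null.

#' Coverage-qualified bin universe
#'
#' Builds the universe for the hypergeometric model: all bins of the
#' tiling that (i) overlap the scope TEs (by id or family), (ii) do not
#' overlap an excluded TE, and (iii) are coverage-qualified, i.e. have at
#' least `min_cov` total counts for every required (sample, context) pair.
#' The universe definition is recorded by callers in output metadata.
#'
#' @param bins a `BinTable`.
#' @param tes a [te_annotation()].
#' @param te_ids,families scope selectors (at least one non-`NULL`).
#' @param exclusions TE ids removed from the scope.
#' @param required data.frame with columns `sample` and `context`: the
#'   coverage requirements; `NULL` skips coverage qualification.
#' @param min_cov minimum total count per required pair; default 4.
#' @return data.table of universe bins (`chrom`, `start`, `end`).
#' @export
universe_bins <- function(bins, tes, te_ids = NULL, families = NULL,
                          exclusions = character(), required = NULL,
                          min_cov = 4L) {
  stopifnot(inherits(bins, "BinTable"))
  scope <- if (!is.null(te_ids)) {
    tes[tes$te_id %in% te_ids]
  } else if (!is.null(families)) {
    tes[tes$family %in% families]
  } else {
    stop_fmt("provide te_ids or families for the universe scope")
  }
  if (!nrow(scope)) stop_fmt("empty universe scope")
  u <- unique(bins$counts[, .(chrom, start, end)])
  u <- u[bins_overlapping(u, scope)]
  excl_iv <- tes[tes$te_id %in% exclusions]
  if (nrow(excl_iv)) u <- u[!bins_overlapping(u, excl_iv)]
  if (!is.null(required)) {
    required <- as.data.table(required)
    for (i in seq_len(nrow(required))) {
      sm <- required$sample[i]; cx <- required$context[i]
      ok <- bins$counts[sample == sm & context == cx & C >= min_cov,
                        .(chrom, start)]
      u <- u[bin_key(u) %in% bin_key(ok)]
    }
  }
  setorderv(u, c("chrom", "start"))
  u[]
}

#' Overlap counts over a bin universe
#'
#' Counts, with set semantics on bin coordinates (no double counting):
#' universe size `N`, reference-set bins in the universe `K`, query-set
#' bins in the universe `n`, and their overlap `k`.
#'
#' @param setA query `TargetSet` (e.g. VANC hypo-DMR bins).
#' @param setB reference `TargetSet` (e.g. RdDM-target bins).
#' @param universe data.table of universe bins ([universe_bins()]).
#' @return named list `(N, K, n, k)`.
#' @export
overlap_count <- function(setA, setB, universe) {
  a <- if (inherits(setA, "TargetSet")) setA$bins else as.data.table(setA)
  b <- if (inherits(setB, "TargetSet")) setB$bins else as.data.table(setB)
  u <- as.data.table(universe)
  wa <- unique(a$end - a$start); wb <- unique(b$end - b$start)
  if (nrow(a) && nrow(b)) {
    # allow the truncated terminal bin, but not different tilings
    if (!length(intersect(wa, wb)) && max(wa) != max(wb)) {
      stop_fmt("target sets come from different bin sizes (%s vs %s)",
               paste(wa, collapse = "/"), paste(wb, collapse = "/"))
    }
  }
  ku <- unique(bin_key(u))
  ka <- intersect(unique(bin_key(a)), ku)
  kb <- intersect(unique(bin_key(b)), ku)
  list(N = length(ku), K = length(kb), n = length(ka),
       k = length(intersect(ka, kb)))
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` bins from a
#' universe of `N` of which `K` are reference targets.  Computed in log
#' space by `stats::phyper`, numerically stable for large `N`.
#'
#' @param k observed overlap.
#' @param K reference-set size in the universe.
#' @param n query-set size in the universe.
#' @param N universe size.
#' @param log10p if `TRUE` return `log10` of the tail probability.
#' @return probability in `(0, 1]` (or its `log10`).
#' @export
hypergeometric_tail <- function(k, K, n, N, log10p = FALSE) {
  if (any(c(k, K, n, N) < 0) || k > min(n, K) || n > N || K > N) {
    stop_fmt("inconsistent hypergeometric counts: k=%d K=%d n=%d N=%d",
             k, K, n, N)
  }
  lp <- phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE)
  if (log10p) lp / log(10) else exp(lp)
}

#' Fold overrepresentation
#'
#' `(k/n) / (K/N)`: the proportion of query bins that are reference
#' targets, relative to the background proportion in the universe.  Equals
#' 1 under independence; undefined (`NA`) when `n = 0` or `K = 0`.
#'
#' @inheritParams hypergeometric_tail
#' @return fold enrichment (numeric, `NA` when undefined).
#' @export
fold_enrichment <- function(N, K, n, k) {
  if (n == 0 || K == 0) return(NA_real_)
  (k / n) / (K / N)
}

# Place regions of the given lengths uniformly at random, without mutual
# overlap, into the placeable space, starts aligned to `grid`.
place_regions <- function(lengths, space, grid, max_attempts = 1000L) {
  placed <- data.table(chrom = character(), start = integer(), end = integer())
  for (L in sort(lengths, decreasing = TRUE)) {
    slots <- pmax(0L, (space$end - space$start - L) %/% grid + 1L)
    if (!any(slots > 0L)) stop_fmt("placeable space too small for a %d-bp region", L)
    done <- FALSE
    for (att in seq_len(max_attempts)) {
      j <- sample.int(nrow(space), 1L, prob = slots)
      s <- space$start[j] + (sample.int(slots[j], 1L) - 1L) * grid
      e <- s + L
      hit <- placed[chrom == space$chrom[j] & start < e & end > s]
      if (!nrow(hit)) {
        placed <- rbind(placed,
                        data.table(chrom = space$chrom[j], start = s, end = e))
        done <- TRUE
        break
      }
    }
    if (!done) stop_fmt("failed to place a %d-bp region after %d attempts",
                        L, max_attempts)
  }
  placed
}

# Number of reference bins overlapped by a set of regions (grid-aligned,
# mutually disjoint regions cannot double-count a bin).
count_ref_bins_hit <- function(regions, ref_keys, grid) {
  if (!nrow(regions)) return(0L)
  hits <- unlist(lapply(seq_len(nrow(regions)), function(i) {
    s0 <- (regions$start[i] %/% grid) * grid
    starts <- seq.int(s0, regions$end[i] - 1L, by = grid)
    paste(regions$chrom[i], starts, sep = ":")
  }))
  length(intersect(unique(hits), ref_keys))
}

#' Size-matched shuffle null for target overlap
#'
#' Monte-Carlo analog of a bedtools-shuffle control: in each iteration,
#' regions with the same lengths as the (merged) query regions are placed
#' uniformly at random, without mutual overlap, into the placeable space,
#' and the number of reference bins they overlap is recorded.  Placements
#' are aligned to the bin grid so that shuffled overlaps are measured in
#' the same units as the observed overlap.  The empirical p-value uses the
#' add-one permutation estimator
#' `(1 + #\{shuffled >= observed\}) / (1 + iterations)` and the whole
#' procedure is reproducible given `seed`.
#'
#' @param query `TargetSet` (bins are merged into regions internally) or a
#'   data.table of regions.
#' @param placeable_space data.table of intervals (`chrom`, `start`,
#'   `end`) into which regions may be placed; total length must
#'   accommodate the query.
#' @param reference `TargetSet` of reference bins the overlap is counted
#'   against.
#' @param iterations number of shuffles (default 1000).
#' @param seed RNG seed; the caller's RNG state is restored afterwards.
#' @param grid placement grid in bp; defaults to the reference bin size.
#' @param max_attempts placement attempts per region before erroring.
#' @return list with `iterations`, `seed`, `observed`, `overlaps`
#'   (per-iteration counts), `mean` and `p_empirical`.
#' @export
shuffle_null <- function(query, placeable_space, reference,
                         iterations = 1000L, seed = 1L, grid = NULL,
                         max_attempts = 1000L) {
  q <- if (inherits(query, "TargetSet")) merge_adjacent(query)$bins
       else as.data.table(query)
  ref <- if (inherits(reference, "TargetSet")) reference$bins
         else as.data.table(reference)
  space <- as.data.table(placeable_space)[, .(chrom, start, end)]
  if (is.null(grid)) {
    grid <- if (nrow(ref)) max(ref$end - ref$start) else 50L
  }
  grid <- as.integer(grid)
  if (sum(space$end - space$start) < sum(q$end - q$start)) {
    stop_fmt("placeable space (total %d bp) smaller than query (total %d bp)",
             sum(space$end - space$start), sum(q$end - q$start))
  }
  ref_keys <- unique(bin_key(ref))
  observed <- count_ref_bins_hit(q, ref_keys, grid)
  overlaps <- with_seed(seed, {
    vapply(seq_len(iterations), function(i) {
      count_ref_bins_hit(place_regions(q$end - q$start, space, grid,
                                       max_attempts),
                         ref_keys, grid)
    }, integer(1L))
  })
  list(iterations = as.integer(iterations), seed = as.integer(seed),
       observed = observed, overlaps = overlaps, mean = mean(overlaps),
       p_empirical = (1 + sum(overlaps >= observed)) / (1 + iterations))
}

#' Overlap enrichment between VANC and RdDM target sets
#'
#' Composes [overlap_count()], [fold_enrichment()],
#' [hypergeometric_tail()] and [shuffle_null()] into one result.  With an
#' empty query set the fold is undefined and `p_hyper = 1`.  Both the
#' model-based fold (`fold`, against the hypergeometric expectation
#' `n*K/N`) and the model-free fold against the shuffle mean
#' (`fold_vs_shuffle`) are reported.
#'
#' @param vanc_set `TargetSet` of CG hypo-DMR bins.
#' @param rddm_set `TargetSet` of RdDM-target bins.
#' @param universe data.table of universe bins ([universe_bins()]).
#' @param iterations shuffle iterations (default 1000).
#' @param seed RNG seed for the shuffle null.
#' @param placeable_space intervals for shuffle placement; defaults to the
#'   merged universe.
#' @return an `EnrichmentResult`: list with `N`, `K`, `n`, `k`, `fold`,
#'   `fold_vs_shuffle`, `p_hyper`, `log10_p_hyper`, `shuffle` and
#'   `params`.
#' @export
enrichment_test <- function(vanc_set, rddm_set, universe,
                            iterations = 1000L, seed = 1L,
                            placeable_space = NULL) {
  u <- as.data.table(universe)
  cnt <- overlap_count(vanc_set, rddm_set, u)
  fold <- fold_enrichment(cnt$N, cnt$K, cnt$n, cnt$k)
  p <- hypergeometric_tail(cnt$k, cnt$K, cnt$n, cnt$N)
  lp <- hypergeometric_tail(cnt$k, cnt$K, cnt$n, cnt$N, log10p = TRUE)
  shuffle <- NULL
  fold_vs_shuffle <- NA_real_
  if (cnt$n > 0) {
    if (is.null(placeable_space)) {
      gr <- GenomicRanges::reduce(to_gr(u))
      placeable_space <- data.table(
        chrom = as.character(GenomicRanges::seqnames(gr)),
        start = GenomicRanges::start(gr) - 1L,
        end = GenomicRanges::end(gr)
      )
    }
    # restrict the query to universe bins so sizes match the counts
    vb <- if (inherits(vanc_set, "TargetSet")) vanc_set$bins else as.data.table(vanc_set)
    vb <- vb[bin_key(vb) %in% bin_key(u)]
    q <- merge_adjacent(target_set(vb, "query"))
    rb <- if (inherits(rddm_set, "TargetSet")) rddm_set$bins else as.data.table(rddm_set)
    rb <- rb[bin_key(rb) %in% bin_key(u)]
    shuffle <- shuffle_null(q, placeable_space, target_set(rb, "ref"),
                            iterations = iterations, seed = seed)
    if (shuffle$mean > 0) fold_vs_shuffle <- cnt$k / shuffle$mean
    shuffle$overlaps <- NULL  # summary only in the result object
  }
  structure(
    list(N = cnt$N, K = cnt$K, n = cnt$n, k = cnt$k,
         fold = fold, fold_vs_shuffle = fold_vs_shuffle,
         p_hyper = p, log10_p_hyper = lp,
         shuffle = shuffle,
         params = list(iterations = as.integer(iterations),
                       seed = as.integer(seed))),
    class = "EnrichmentResult"
  )
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf(
    "EnrichmentResult: N=%d K=%d n=%d k=%d\n  fold=%.3f  p_hyper=%.3g (log10 %.2f)\n",
    x$N, x$K, x$n, x$k, x$fold, x$p_hyper, x$log10_p_hyper))
  if (!is.null(x$shuffle)) {
    cat(sprintf("  shuffle: mean=%.2f observed=%d empirical p=%.4g (%d iterations)\n",
                x$shuffle$mean, x$shuffle$observed, x$shuffle$p_empirical,
                x$shuffle$iterations))
  }
  invisible(x)
}
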