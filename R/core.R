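# Core methylation arithmetic: ratios, interval aggregation, the per-TE
# coverage-weighted change statistic, genome binning.

#' Methylation ratio
#'
#' `M/C` when `C > 0`; `NA` when `C = 0`.  An undefined ratio is never
#' coerced to 0 — zero-coverage positions must not look hypomethylated.
#'
#' @param M methylated counts (vectorised).
#' @param C total counts (`M + U`).
#' @return numeric vector of ratios in `[0, 1]` with `NA` where `C = 0`.
#' @export
methylation_ratio <- function(M, C) {
  if (any(M < 0 | C < 0, na.rm = TRUE)) stop_fmt("negative counts")
  if (any(M > C, na.rm = TRUE)) stop_fmt("M > C violates 0 <= M <= C")
  fifelse(C > 0, M / C, NA_real_)
}

#' Aggregate cytosine counts over an interval
#'
#' Sums methylated (`M`) and total (`C = M + U`) counts over all cytosines
#' of the requested context whose 0-based position lies in
#' `[start, end)`.  Both strands contribute.  An interval without matching
#' cytosines yields `M = 0, C = 0` and an undefined ratio.
#'
#' @param records cytosine record table ([read_cytosine_report()]).
#' @param interval list or single-row data.frame with `chrom`, `start`,
#'   `end` (0-based half-open).
#' @param context one of `"CpG"`, `"CHG"`, `"CHH"`, or `"combined"` to pool
#'   all contexts.
#' @return list with `M`, `C` and `ratio`.
#' @export
aggregate_region <- function(records, interval, context = "CpG") {
  stopifnot(interval$start < interval$end)
  ctx_req <- context
  r <- records[chrom == interval$chrom & pos0 >= interval$start &
                 pos0 < interval$end]
  if (ctx_req != "combined") r <- r[context == ctx_req]
  M <- sum(r$m)
  C <- sum(r$m + r$u)
  list(M = M, C = C, ratio = if (C > 0) M / C else NA_real_)
}

#' Per-TE methylation-change significance statistic
#'
#' The coverage-weighted difference of methylation ratios between a
#' nontransgenic (`n`) and a transgenic (`t`) sample:
#' \deqn{S = \frac{M_n/C_n - M_t/C_t}{1/\sqrt{C_n} + 1/\sqrt{C_t}}}
#' where `M` and `C` are methylated and total cytosine counts summed over a
#' TE.  Positive `S` means hypomethylation in the transgenic sample.  The
#' statistic is used as a ranking/scatter value, not calibrated to a
#' p-value.
#'
#' When `Cn = 0` or `Ct = 0` the score is undefined and returned as `NA`
#' (the TE is flagged, not an error).
#'
#' @param Mn,Cn methylated/total counts in the nontransgenic sample.
#' @param Mt,Ct methylated/total counts in the transgenic sample.
#' @return numeric vector of scores (`NA` where undefined).
#' @export
te_change_statistic <- function(Mn, Cn, Mt, Ct) {
  n <- max(length(Mn), length(Cn), length(Mt), length(Ct))
  Mn <- rep_len(as.numeric(Mn), n); Cn <- rep_len(as.numeric(Cn), n)
  Mt <- rep_len(as.numeric(Mt), n); Ct <- rep_len(as.numeric(Ct), n)
  if (any(Mn > Cn, na.rm = TRUE) || any(Mt > Ct, na.rm = TRUE)) {
    stop_fmt("M > C violates 0 <= M <= C")
  }
  if (any(c(Mn, Mt, Cn, Ct) < 0, na.rm = TRUE)) stop_fmt("negative counts")
  ok <- !is.na(Cn) & !is.na(Ct) & Cn > 0 & Ct > 0
  s <- rep(NA_real_, n)
  s[ok] <- (Mn[ok] / Cn[ok] - Mt[ok] / Ct[ok]) /
    (1 / sqrt(Cn[ok]) + 1 / sqrt(Ct[ok]))
  s
}

# Sum (m, m+u) per TE per context for one sample.
agg_counts_by_te <- function(records, tes) {
  hits <- GenomicRanges::findOverlaps(records_gr(records), to_gr(tes))
  qi <- S4Vectors::queryHits(hits)
  dt <- data.table(
    te_id = tes$te_id[S4Vectors::subjectHits(hits)],
    context = records$context[qi],
    m = records$m[qi],
    c = records$m[qi] + records$u[qi]
  )
  dt[, .(M = sum(m), C = sum(c)), by = .(te_id, context)]
}

#' Score methylation change for all TEs
#'
#' Computes the change statistic [te_change_statistic()] for every TE in an
#' annotation, comparing a nontransgenic sample (`sample_n`) with a
#' transgenic sample (`sample_t`).  Scores can be computed per context or
#' with all contexts pooled (`"combined"`, the default used for
#' scatter-style comparisons).  TEs with zero coverage in either sample are
#' flagged with `NA` scores; annotation chromosomes absent from both
#' samples raise a warning.
#'
#' @param sample_n,sample_t cytosine record tables.
#' @param tes a [te_annotation()].
#' @param context `"combined"` (default), `"CpG"`, `"CHG"` or `"CHH"`.
#' @return data.table with one row per TE: `te_id`, `family`, `context`,
#'   `Mn`, `Cn`, `Mt`, `Ct`, `S`.
#' @export
score_all_tes <- function(sample_n, sample_t, tes, context = "combined") {
  stopifnot(context %in% c("combined", "CpG", "CHG", "CHH"))
  missing_chrom <- setdiff(unique(tes$chrom),
                           union(unique(sample_n$chrom), unique(sample_t$chrom)))
  if (length(missing_chrom)) {
    warn_fmt("annotation chromosome(s) absent from both samples: %s",
             paste(missing_chrom, collapse = ", "))
  }
  an <- agg_counts_by_te(sample_n, tes)
  at <- agg_counts_by_te(sample_t, tes)
  ctx_req <- context
  if (ctx_req == "combined") {
    an <- an[, .(M = sum(M), C = sum(C)), by = te_id]
    at <- at[, .(M = sum(M), C = sum(C)), by = te_id]
  } else {
    an <- an[context == ctx_req, .(te_id, M, C)]
    at <- at[context == ctx_req, .(te_id, M, C)]
  }
  grid <- data.table(te_id = tes$te_id)
  out <- merge(grid, setnames(copy(an), c("M", "C"), c("Mn", "Cn")),
               by = "te_id", all.x = TRUE)
  out <- merge(out, setnames(copy(at), c("M", "C"), c("Mt", "Ct")),
               by = "te_id", all.x = TRUE)
  for (cc in c("Mn", "Cn", "Mt", "Ct")) {
    out[is.na(get(cc)), (cc) := 0L]
  }
  out[, `:=`(
    family = tes$family[match(te_id, tes$te_id)],
    context = ctx_req,
    S = te_change_statistic(Mn, Cn, Mt, Ct)
  )]
  setorderv(out, "te_id")
  out[, .(te_id, family, context, Mn, Cn, Mt, Ct, S)]
}

#' Bin the genome into fixed-size tiles and aggregate methylation counts
#'
#' Tiles every chromosome with half-open bins `[0, b), [b, 2b), ...`
#' (default `b = 50`), the last bin truncated at the chromosome end, and
#' aggregates per-sample, per-context methylated/total counts into the
#' bins.  Every cytosine belongs to exactly one bin; bins without cytosines
#' of a given context are absent from the (sparse, long-format) count
#' table and their ratio is undefined.
#'
#' @param samples a named list of cytosine record tables, or a single table
#'   (then named `"sample1"`).
#' @param chrom_sizes named integer vector of chromosome lengths; inferred
#'   as the maximum observed position per chromosome when `NULL`.
#' @param bin_size bin width in bp (> 0).
#' @return a `BinTable`: list with `counts` (data.table `chrom`, `start`,
#'   `end`, `sample`, `context`, `M`, `C`, `ratio`), `bin_size` and
#'   `chrom_sizes`.
#' @export
bin_genome <- function(samples, chrom_sizes = NULL, bin_size = 50L) {
  if (is.data.frame(samples)) samples <- list(sample1 = samples)
  if (is.null(names(samples)) || any(!nzchar(names(samples)))) {
    stop_fmt("samples must be a named list")
  }
  bin_size <- as.integer(bin_size)
  if (is.na(bin_size) || bin_size <= 0L) stop_fmt("bin_size must be > 0")
  if (is.null(chrom_sizes)) {
    mx <- rbindlist(lapply(samples, function(s) s[, .(mx = max(pos0) + 1L), by = chrom]))
    mx <- mx[, .(size = max(mx)), by = chrom]
    chrom_sizes <- setNames(mx$size, mx$chrom)
  }
  counts <- rbindlist(lapply(names(samples), function(nm) {
    s <- samples[[nm]]
    bad <- setdiff(unique(s$chrom), names(chrom_sizes))
    if (length(bad)) stop_fmt("sample '%s' has chromosome(s) without a size: %s",
                              nm, paste(bad, collapse = ", "))
    a <- s[, .(M = sum(m), C = sum(m + u)),
           by = .(chrom, start = (pos0 %/% bin_size) * bin_size, context)]
    a[, `:=`(end = pmin(start + bin_size, chrom_sizes[chrom]), sample = nm)]
    a
  }))
  counts[, ratio := fifelse(C > 0, M / C, NA_real_)]
  setorderv(counts, c("sample", "context", "chrom", "start"))
  structure(
    list(counts = counts[, .(chrom, start, end, sample, context, M, C, ratio)],
         bin_size = bin_size, chrom_sizes = chrom_sizes),
    class = "BinTable"
  )
}

#' @export
print.BinTable <- function(x, ...) {
  cat(sprintf("BinTable: %d-bp bins, %d chromosome(s), samples: %s\n",
              x$bin_size, length(x$chrom_sizes),
              paste(unique(x$counts$sample), collapse = ", ")))
  print(head(x$counts))
  invisible(x)
}
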