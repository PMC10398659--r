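# Per-locus methylation tracks and coding/noncoding summaries.

#' Sliding-window methylation track across a locus
#'
#' Computes per-context methylation ratios in sliding windows of `window`
#' bp advanced by `step` bp across an interval, for plotting per-locus
#' methylation patterns.  Windows with zero coverage have an undefined
#' ratio (`NA`).  When `window` exceeds the interval the whole interval is
#' a single window.  With `window = step = bin_size` the track reproduces
#' the corresponding [bin_genome()] rows exactly.
#'
#' @param records cytosine record table.
#' @param interval list with `chrom`, `start`, `end` (0-based half-open).
#' @param window window size in bp (`window >= step`).
#' @param step step size in bp (> 0).  Default smoothing is a 50-bp window
#'   advanced by 25 bp.
#' @return data.table with `chrom`, `start`, `end`, `center`, `context`,
#'   `M`, `C`, `ratio` (coordinates at window centers for plotting).
#' @export
locus_profile <- function(records, interval, window = 50L, step = 25L) {
  window <- as.integer(window); step <- as.integer(step)
  if (is.na(step) || step <= 0L || is.na(window) || window < step) {
    stop_fmt("require window >= step > 0")
  }
  len <- interval$end - interval$start
  if (window >= len) {
    starts <- interval$start
    window <- len
  } else {
    starts <- seq.int(interval$start, interval$end - window, by = step)
  }
  r <- records[chrom == interval$chrom & pos0 >= interval$start &
                 pos0 < interval$end]
  contexts <- c("CpG", "CHG", "CHH")
  out <- rbindlist(lapply(starts, function(s) {
    w <- r[pos0 >= s & pos0 < s + window,
           .(M = sum(m), C = sum(m + u)), by = context]
    full <- merge(data.table(context = contexts), w, by = "context", all.x = TRUE)
    full[is.na(M), `:=`(M = 0L, C = 0L)]
    full[, `:=`(chrom = interval$chrom, start = s, end = s + window,
                center = s + window / 2)]
    full
  }))
  out[, ratio := fifelse(C > 0, M / C, NA_real_)]
  setorderv(out, c("context", "start"))
  out[, .(chrom, start, end, center, context, M, C, ratio)]
}

#' Summarise methylation by coding/noncoding region class
#'
#' For annotations carrying coding/noncoding sub-intervals (exons are
#' coding; intergenic stretches, introns and TIRs are noncoding), computes
#' the per-TE methylation ratio of each region class and context in each
#' sample, then the mean and standard deviation across TEs.  TEs lacking
#' region classes are excluded with a warning.
#'
#' @param samples named list of cytosine record tables.
#' @param tes a [te_annotation()] with a region-class table attached.
#' @return data.table with `sample`, `class`, `context`, `mean_ratio`,
#'   `sd_ratio`, `n_te` (number of TEs with a defined ratio).
#' @export
summarize_by_region_class <- function(samples, tes) {
  regions <- region_classes(tes)
  if (is.null(regions)) stop_fmt("annotation has no region classes attached")
  lacking <- setdiff(tes$te_id, unique(regions$te_id))
  if (length(lacking)) {
    warn_fmt("TE(s) without region classes excluded: %s",
             paste(lacking, collapse = ", "))
  }
  if (is.data.frame(samples)) samples <- list(sample1 = samples)
  rg <- to_gr(regions)
  per_te <- rbindlist(lapply(names(samples), function(nm) {
    rec <- samples[[nm]]
    hits <- GenomicRanges::findOverlaps(records_gr(rec), rg)
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    dt <- data.table(
      te_id = regions$te_id[si], class = regions$class[si],
      context = rec$context[qi], m = rec$m[qi], c = rec$m[qi] + rec$u[qi]
    )
    a <- dt[, .(M = sum(m), C = sum(c)), by = .(te_id, class, context)]
    a[, `:=`(sample = nm, ratio = fifelse(C > 0, M / C, NA_real_))]
    a
  }))
  out <- per_te[!is.na(ratio),
                .(mean_ratio = mean(ratio), sd_ratio = sd(ratio), n_te = .N),
                by = .(sample, class, context)]
  setorderv(out, c("sample", "class", "context"))
  out[]
}
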