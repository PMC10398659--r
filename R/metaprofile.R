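# Methylation metaprofiles anchored at target points: mean per-context
# methylation as a function of distance from the anchors, per sample.

#' Derive anchor points from a target set
#'
#' Adjacent bins are merged first ([merge_adjacent()]); each merged region
#' contributes one anchor at its midpoint (floor on ties).  Orientation is
#' taken from the strand of the host TE when an annotation is supplied
#' (first overlapping TE), otherwise `'+'`.
#'
#' @param set non-empty `TargetSet`.
#' @param tes optional [te_annotation()] supplying anchor orientation.
#' @return data.table with `chrom`, `pos` (0-based anchor coordinate) and
#'   `strand`.
#' @export
anchors_from_targets <- function(set, tes = NULL) {
  stopifnot(inherits(set, "TargetSet"))
  if (!nrow(set$bins)) stop_fmt("cannot derive anchors from an empty target set")
  m <- merge_adjacent(set)$bins
  anchors <- data.table(
    chrom = m$chrom,
    pos = (m$start + m$end) %/% 2L,
    strand = "+"
  )
  if (!is.null(tes)) {
    pts <- data.table(chrom = anchors$chrom, start = anchors$pos,
                      end = anchors$pos + 1L)
    hit <- GenomicRanges::findOverlaps(to_gr(pts), to_gr(tes), select = "first")
    host <- tes$strand[hit]
    anchors[!is.na(hit) & host %in% c("+", "-"),
            strand := host[!is.na(hit) & host %in% c("+", "-")]]
  }
  anchors[]
}

#' Methylation metaprofile around anchor points
#'
#' For each offset window `[o, o + step)` relative to each anchor
#' (strand-flipped for `'-'` anchors, so the profile reads in the host
#' TE's orientation), pools methylated and total counts across anchors and
#' reports the pooled ratio per context and sample.  Pooled-count
#' averaging weights anchors by coverage and is robust where individual
#' anchors have sparse data; windows with pooled `C = 0` are undefined.
#' Anchors near a chromosome edge contribute truncated windows rather than
#' being dropped.
#'
#' @param samples named list of cytosine record tables (or one table).
#' @param anchors anchor table from [anchors_from_targets()] (columns
#'   `chrom`, `pos`, `strand`).
#' @param flank bp on each side of the anchor (default 2000).
#' @param step offset window width in bp (default 50).
#' @return a `MetaProfile`: list with `profile` (data.table `sample`,
#'   `context`, `offset`, `M`, `C`, `ratio`, `n_anchors`), `anchors`,
#'   `flank`, `step`.
#' @export
compute_metaprofile <- function(samples, anchors, flank = 2000L, step = 50L) {
  flank <- as.integer(flank); step <- as.integer(step)
  if (is.na(flank) || is.na(step) || flank <= 0L || step <= 0L) {
    stop_fmt("flank and step must be > 0")
  }
  anchors <- as.data.table(anchors)
  if (!nrow(anchors)) stop_fmt("no anchors")
  if (is.data.frame(samples)) samples <- list(sample1 = samples)

  profile <- rbindlist(lapply(names(samples), function(nm) {
    rec <- samples[[nm]]
    per_anchor <- rbindlist(lapply(seq_len(nrow(anchors)), function(i) {
      ac <- anchors$chrom[i]; ap <- anchors$pos[i]; as_ <- anchors$strand[i]
      r <- rec[chrom == ac & pos0 >= ap - flank & pos0 <= ap + flank]
      if (!nrow(r)) return(NULL)
      rel <- if (as_ == "-") ap - r$pos0 - 1L else r$pos0 - ap
      off <- (rel %/% step) * step
      keep <- off >= -flank & off <= flank - step
      if (!any(keep)) return(NULL)
      data.table(anchor = i, offset = off[keep], context = r$context[keep],
                 m = r$m[keep], c = r$m[keep] + r$u[keep])
    }))
    if (!nrow(per_anchor)) return(NULL)
    a <- per_anchor[, .(M = sum(m), C = sum(c)), by = .(anchor, offset, context)]
    p <- a[, .(M = sum(M), C = sum(C), n_anchors = sum(C > 0)),
           by = .(offset, context)]
    p[, `:=`(sample = nm, ratio = fifelse(C > 0, M / C, NA_real_))]
    p
  }))
  if (!nrow(profile)) stop_fmt("no coverage within the flank of any anchor")
  setorderv(profile, c("sample", "context", "offset"))
  structure(list(profile = profile[, .(sample, context, offset, M, C,
                                       ratio, n_anchors)],
                 anchors = anchors, flank = flank, step = step,
                 pooling = "pooled-counts"),
            class = "MetaProfile")
}

#' @export
print.MetaProfile <- function(x, ...) {
  cat(sprintf("MetaProfile: %d anchor(s), flank %d bp, step %d bp\n",
              nrow(x$anchors), x$flank, x$step))
  print(head(x$profile))
  invisible(x)
}

#' Write a metaprofile matrix as TSV
#'
#' @param profile a `MetaProfile`.
#' @param path output path (TSV, offset x sample x context, long format).
#' @return `path`, invisibly.
#' @export
write_metaprofile <- function(profile, path) {
  stopifnot(inherits(profile, "MetaProfile"))
  fwrite(profile$profile, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}
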