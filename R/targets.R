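# Target calling: CG hypo-DMR bins in the presence of a VANC-expressing
# transgene, VANC-target TE selection, and RdDM-target bins (residual CHH
# methylation in the cmt2 cmt3 mutant).  All thresholds follow the strict
# inequalities they are printed with (> 0.4, > 2, > 0.1).

#' Construct a labelled interval target set
#'
#' @param bins data.frame-like with `chrom`, `start`, `end` and optionally
#'   `value` (the per-bin delta or ratio).
#' @param label set label, e.g. `"vanc_hypo_dmr"` or `"rddm_target"`.
#' @param params list of calling parameters kept for provenance.
#' @return a `TargetSet` (list with `bins`, `label`, `params`).
#' @export
target_set <- function(bins, label, params = list()) {
  b <- as.data.table(bins)
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(b))
  if (length(miss)) stop_fmt("target set lacks columns: %s", paste(miss, collapse = ", "))
  if (!"value" %in% names(b)) b[, value := NA_real_]
  setorderv(b, c("chrom", "start"))
  structure(list(bins = b[, .(chrom, start, end, value)],
                 label = label, params = params),
            class = "TargetSet")
}

#' @export
print.TargetSet <- function(x, ...) {
  cat(sprintf("TargetSet '%s': %d interval(s)\n", x$label, nrow(x$bins)))
  if (length(x$params)) {
    cat("  params:", paste(names(x$params), collapse = ", "), "\n")
  }
  invisible(x)
}

# Bins (data.table chrom/start/end) overlapping any interval of `ivs`.
bins_overlapping <- function(bins, ivs) {
  if (!nrow(bins) || !nrow(ivs)) return(rep(FALSE, nrow(bins)))
  GenomicRanges::countOverlaps(to_gr(bins), to_gr(ivs)) > 0L
}

#' Call CG hypo-DMR bins between a reference and a transgenic sample
#'
#' A bin is a CG hypo-DMR when its CG methylation ratio drops by more than
#' `delta` (strictly) from the reference (nontransgenic) to the
#' VANC-expressing (transgenic) sample, both ratios are defined at the
#' minimum coverage, the bin overlaps a TE of the family scope (any
#' overlap), and the bin does not overlap any excluded TE (e.g. the
#' transgene-donor copy, whose methylation does not reflect the endogenous
#' state).
#'
#' The change is directional by default (hypomethylation in the transgenic
#' sample); set `directional = FALSE` for an absolute-change mode.
#'
#' @param bins a `BinTable` from [bin_genome()] containing both samples.
#' @param sample_ref,sample_tg sample names in `bins` (reference /
#'   transgenic).
#' @param tes a [te_annotation()].
#' @param family_scope character vector of family labels defining the
#'   calling scope; must be non-empty and match at least one TE.
#' @param exclusions TE ids whose bins are excluded; unknown ids warn.
#' @param delta ratio-change threshold (strict `>`); default 0.4.
#' @param min_cov minimum total CG count per bin per sample for the ratio
#'   to count as defined; default 4.
#' @param directional if `TRUE` (default) only reference-minus-transgenic
#'   drops qualify.
#' @return a `TargetSet` labelled `"vanc_hypo_dmr"`; `value` carries the
#'   per-bin ratio change.
#' @export
call_hypo_dmrs <- function(bins, sample_ref, sample_tg, tes, family_scope,
                           exclusions = character(), delta = 0.4,
                           min_cov = 4L, directional = TRUE) {
  stopifnot(inherits(bins, "BinTable"))
  if (length(family_scope) == 0L) stop_fmt("empty family scope")
  have <- unique(bins$counts$sample)
  for (s in c(sample_ref, sample_tg)) {
    if (!s %in% have) stop_fmt("sample '%s' absent from BinTable", s)
  }
  if (sample_ref == sample_tg) stop_fmt("reference and transgenic sample are identical")
  scope_tes <- tes[tes$family %in% family_scope]
  if (!nrow(scope_tes)) stop_fmt("no TE matches family scope: %s",
                                 paste(family_scope, collapse = ", "))
  unknown <- setdiff(exclusions, tes$te_id)
  if (length(unknown)) {
    warn_fmt("unknown exclusion id(s): %s", paste(unknown, collapse = ", "))
  }

  cg <- bins$counts[context == "CpG" & sample %in% c(sample_ref, sample_tg) &
                      C >= min_cov]
  w <- dcast(cg, chrom + start + end ~ sample, value.var = "ratio")
  if (!all(c(sample_ref, sample_tg) %in% names(w))) {
    w <- w[0L]  # one sample had no qualifying bins
  } else {
    w <- w[!is.na(get(sample_ref)) & !is.na(get(sample_tg))]
  }
  if (nrow(w)) {
    chg <- w[[sample_ref]] - w[[sample_tg]]
    if (!directional) chg <- abs(chg)
    w <- w[chg > delta]
    chg <- chg[chg > delta]
    w[, value := chg]
    w <- w[bins_overlapping(w, scope_tes)]
    excl_iv <- tes[tes$te_id %in% exclusions]
    if (nrow(w) && nrow(excl_iv)) w <- w[!bins_overlapping(w, excl_iv)]
  } else {
    w[, value := numeric()]
  }
  target_set(
    w[, .(chrom, start, end, value)], "vanc_hypo_dmr",
    params = list(sample_ref = sample_ref, sample_tg = sample_tg,
                  family_scope = family_scope, exclusions = exclusions,
                  delta = delta, min_cov = min_cov, directional = directional,
                  bin_size = bins$bin_size)
  )
}

#' Select VANC-target TEs
#'
#' TEs overlapped by strictly more than `min_dmrs_exclusive` CG hypo-DMR
#' bins (the printed rule "> 2") are selected as VANC-target TEs.
#'
#' @param tes a [te_annotation()].
#' @param dmrs `TargetSet` of hypo-DMR bins from [call_hypo_dmrs()].
#' @param min_dmrs_exclusive exclusive lower bound on the DMR-bin count
#'   (default 2, i.e. 3 or more bins select a TE).
#' @return character vector of selected TE ids.
#' @export
select_vanc_target_tes <- function(tes, dmrs, min_dmrs_exclusive = 2L) {
  if (!nrow(dmrs$bins)) return(character())
  n <- GenomicRanges::countOverlaps(to_gr(tes), to_gr(dmrs$bins))
  tes$te_id[n > min_dmrs_exclusive]
}

#' Call RdDM-target bins
#'
#' In the *cmt2 cmt3* double mutant, CH methylation maintained by CMTs is
#' gone and residual CHH methylation reflects RdDM activity.  A bin is an
#' RdDM target when its CHH methylation ratio in the cmt23-genotype sample
#' strictly exceeds `threshold` at the minimum coverage.  Calling is
#' usually restricted to the VANC-target TEs (`scope_tes`); pass
#' `scope_tes = NULL` for a genome-wide mode.
#'
#' @param bins a `BinTable`.
#' @param sample_cmt23 name of the cmt23-genotype sample in `bins`.
#' @param scope_tes a [te_annotation()] (or subset) restricting the scope,
#'   or `NULL` for genome-wide.
#' @param threshold CHH ratio threshold (strict `>`); default 0.1.
#' @param min_cov minimum CHH coverage per bin; default 4.
#' @return a `TargetSet` labelled `"rddm_target"`; `value` is the CHH
#'   ratio.
#' @export
call_rddm_targets <- function(bins, sample_cmt23, scope_tes = NULL,
                              threshold = 0.1, min_cov = 4L) {
  stopifnot(inherits(bins, "BinTable"))
  if (!sample_cmt23 %in% unique(bins$counts$sample)) {
    stop_fmt("sample '%s' absent from BinTable", sample_cmt23)
  }
  sm <- sample_cmt23
  b <- bins$counts[context == "CHH" & sample == sm & C >= min_cov &
                     !is.na(ratio) & ratio > threshold,
                   .(chrom, start, end, value = ratio)]
  if (!is.null(scope_tes) && nrow(b)) {
    b <- b[bins_overlapping(b, scope_tes)]
  }
  target_set(b, "rddm_target",
             params = list(sample = sample_cmt23, threshold = threshold,
                           min_cov = min_cov, bin_size = bins$bin_size,
                           scope = if (is.null(scope_tes)) "genome" else "tes"))
}

#' Merge adjacent bins of a target set into regions
#'
#' Maximal runs of directly adjacent (distance-0) bins are merged into one
#' region whose value is the mean of its member bins.  Idempotent.  Merged
#' regions define the anchor points for metaprofiles.
#'
#' @param set a `TargetSet`.
#' @return a `TargetSet` with merged intervals.
#' @export
merge_adjacent <- function(set) {
  stopifnot(inherits(set, "TargetSet"))
  b <- copy(set$bins)
  if (!nrow(b)) return(set)
  setorderv(b, c("chrom", "start"))
  b[, grp := cumsum(!(chrom == shift(chrom, fill = "") &
                        start == shift(end, fill = -1L)))]
  m <- b[, .(chrom = chrom[1L], start = min(start), end = max(end),
             value = mean(value)), by = grp]
  target_set(m[, .(chrom, start, end, value)], set$label,
             modifyList(set$params, list(merged = TRUE)))
}
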