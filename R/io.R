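# Readers and writers for the standard formats the pipeline consumes and
# emits: Bismark-style cytosine/CX reports, BED6/GFF3 TE annotations, BED
# interval sets, TSV score tables and JSON enrichment reports.

#' Normalise a cytosine-context token
#'
#' Report dialects differ: `CG` and `CpG` both denote symmetric CpG
#' methylation.  Matching is case-insensitive.  Unknown tokens map to `NA`.
#'
#' @param x character vector of context tokens.
#' @return character vector with values in `c("CpG", "CHG", "CHH")` or `NA`.
#' @export
normalize_context <- function(x) {
  up <- toupper(x)
  out <- rep(NA_character_, length(x))
  out[up %in% c("CG", "CPG")] <- "CpG"
  out[up == "CHG"] <- "CHG"
  out[up == "CHH"] <- "CHH"
  out
}

#' Read a per-cytosine methylation report
#'
#' Parses a Bismark-style cytosine/CX report: a tab-separated file with
#' columns chromosome, 1-based position, strand, methylated count,
#' unmethylated count, context and (optionally) trinucleotide.  Parsing is
#' strict: a malformed line (wrong column count, non-integer count, unknown
#' context or strand) raises an error naming the line number; counts are
#' never silently coerced.
#'
#' Positions are kept as read (`pos`, 1-based) and additionally converted to
#' the package-internal 0-based convention (`pos0`); all downstream
#' consumers use `pos0`.
#'
#' @param path path to the report file.
#' @param contexts contexts to retain; records of other contexts are
#'   skipped.  Defaults to all three.
#' @return a `data.table` with columns `chrom`, `pos`, `pos0`, `strand`,
#'   `m`, `u`, `context` and `trinucleotide` (`NA` when the report has six
#'   columns), in file order.
#' @export
read_cytosine_report <- function(path, contexts = c("CpG", "CHG", "CHH")) {
  contexts <- normalize_context(contexts)
  if (anyNA(contexts)) stop_fmt("unknown context requested")
  lines <- readLines(path)
  keep <- nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  empty <- data.table(
    chrom = character(), pos = integer(), pos0 = integer(),
    strand = character(), m = integer(), u = integer(),
    context = character(), trinucleotide = character()
  )
  if (!length(lines)) return(empty)

  nf <- nchar(lines) - nchar(gsub("\t", "", lines, fixed = TRUE)) + 1L
  bad <- which(nf < 6L | nf > 7L)
  if (length(bad)) {
    stop_fmt("%s: line %d: expected 6 or 7 tab-separated fields, found %d",
             path, lineno[bad[1L]], nf[bad[1L]])
  }
  cols <- tstrsplit(lines, "\t", fixed = TRUE)

  check_int <- function(x, what) {
    ok <- grepl("^[0-9]+$", x)
    if (!all(ok)) {
      i <- which(!ok)[1L]
      stop_fmt("%s: line %d: %s is not a non-negative integer: '%s'",
               path, lineno[i], what, x[i])
    }
    as.integer(x)
  }
  pos <- check_int(cols[[2L]], "position")
  if (any(pos < 1L)) {
    i <- which(pos < 1L)[1L]
    stop_fmt("%s: line %d: position must be >= 1", path, lineno[i])
  }
  strand <- cols[[3L]]
  strand[strand == "−"] <- "-"  # unicode minus
  oks <- strand %in% c("+", "-")
  if (!all(oks)) {
    i <- which(!oks)[1L]
    stop_fmt("%s: line %d: strand must be '+' or '-': '%s'",
             path, lineno[i], strand[i])
  }
  m <- check_int(cols[[4L]], "methylated count")
  u <- check_int(cols[[5L]], "unmethylated count")
  ctx <- normalize_context(cols[[6L]])
  if (anyNA(ctx)) {
    i <- which(is.na(ctx))[1L]
    stop_fmt("%s: line %d: unknown context token '%s'",
             path, lineno[i], cols[[6L]][i])
  }
  tri <- if (length(cols) >= 7L) cols[[7L]] else rep(NA_character_, length(pos))

  dt <- data.table(
    chrom = cols[[1L]], pos = pos, pos0 = pos - 1L, strand = strand,
    m = m, u = u, context = ctx, trinucleotide = tri
  )
  dt[context %in% contexts]
}

#' Build a TE annotation table
#'
#' Constructor and validator for the annotation container used throughout
#' the package: a `data.table` with columns `te_id`, `chrom`, `start`,
#' `end` (0-based half-open), `strand` and `family`, sorted by
#' `(chrom, start)`, optionally carrying coding/noncoding sub-intervals as
#' the `"regions"` attribute (see [read_region_classes()]).
#'
#' @param tes data.frame-like with the columns above.
#' @param regions optional data.frame-like with columns `te_id`, `chrom`,
#'   `start`, `end`, `class` where `class` is `"coding"` or `"noncoding"`.
#'   Sub-intervals must lie within their TE and must not overlap each other.
#' @return a `te_annotation` data.table.
#' @export
te_annotation <- function(tes, regions = NULL) {
  tes <- as.data.table(tes)
  need <- c("te_id", "chrom", "start", "end", "strand", "family")
  miss <- setdiff(need, names(tes))
  if (length(miss)) stop_fmt("annotation lacks columns: %s", paste(miss, collapse = ", "))
  if (any(!is.finite(tes$start)) || any(!is.finite(tes$end))) {
    stop_fmt("annotation has non-finite coordinates")
  }
  if (any(tes$start >= tes$end)) {
    i <- which(tes$start >= tes$end)[1L]
    stop_fmt("annotation interval with start >= end: %s", tes$te_id[i])
  }
  dup <- tes$te_id[duplicated(tes$te_id)]
  if (length(dup)) stop_fmt("duplicate TE id(s): %s", paste(unique(dup), collapse = ", "))
  setorderv(tes, c("chrom", "start"))
  if (!is.null(regions)) {
    regions <- as.data.table(regions)
    rn <- c("te_id", "chrom", "start", "end", "class")
    miss <- setdiff(rn, names(regions))
    if (length(miss)) stop_fmt("region table lacks columns: %s", paste(miss, collapse = ", "))
    if (!all(regions$class %in% c("coding", "noncoding"))) {
      stop_fmt("region class must be 'coding' or 'noncoding'")
    }
    parent <- tes[match(regions$te_id, tes$te_id)]
    if (anyNA(parent$te_id)) stop_fmt("region table references unknown TE id")
    inside <- regions$chrom == parent$chrom &
      regions$start >= parent$start & regions$end <= parent$end &
      regions$start < regions$end
    if (!all(inside)) stop_fmt("sub-interval outside its TE or empty")
    setorderv(regions, c("te_id", "start"))
    ovl <- regions[, any(start < shift(end, fill = -1L)), by = te_id]$V1
    if (any(ovl)) stop_fmt("overlapping sub-intervals within a TE")
    setattr(tes, "regions", regions)
  }
  setattr(tes, "class", c("te_annotation", class(tes)))
  tes
}

#' @rdname te_annotation
#' @param x object to query.
#' @export
region_classes <- function(x) attr(x, "regions", exact = TRUE)

#' Read a TE annotation (BED6 or GFF3)
#'
#' BED6 input is 0-based half-open and used verbatim; the name field is
#' parsed as `"<te_id>|<family>"` (family omitted when no `|` is present).
#' GFF3 input is 1-based closed and converted to the internal 0-based
#' half-open convention on read; the TE id is taken from the `ID` (or
#' `Name`) attribute and the family from a `family` (or `Alias`) attribute.
#'
#' @param path annotation file.
#' @param dialect `"BED6"` or `"GFF3"`.
#' @return a [te_annotation()] table sorted by `(chrom, start)`; duplicate
#'   ids or `start >= end` raise an error.
#' @export
read_te_annotation <- function(path, dialect = c("BED6", "GFF3")) {
  dialect <- match.arg(dialect)
  if (dialect == "BED6") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                     !startsWith(lines, "track")]
    if (!length(lines)) stop_fmt("%s: empty BED file", path)
    f <- tstrsplit(lines, "\t", fixed = TRUE)
    if (length(f) < 6L) stop_fmt("%s: BED6 requires 6 columns", path)
    suppressWarnings({
      start <- as.integer(f[[2L]])
      end <- as.integer(f[[3L]])
    })
    if (anyNA(start) || anyNA(end)) stop_fmt("%s: non-numeric BED coordinates", path)
    name <- tstrsplit(f[[4L]], "|", fixed = TRUE)
    tes <- data.table(
      te_id = name[[1L]], chrom = f[[1L]], start = start, end = end,
      strand = f[[6L]],
      family = if (length(name) >= 2L) name[[2L]] else NA_character_
    )
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    mc <- S4Vectors::mcols(gr)
    id <- if ("ID" %in% names(mc)) as.character(mc$ID) else as.character(mc$Name)
    fam <- if ("family" %in% names(mc)) {
      as.character(mc$family)
    } else if ("Alias" %in% names(mc)) {
      vapply(mc$Alias, function(a) if (length(a)) as.character(a[[1L]]) else NA_character_,
             character(1L))
    } else {
      rep(NA_character_, length(gr))
    }
    tes <- data.table(
      te_id = id,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,  # 1-based closed -> 0-based half-open
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      family = fam
    )
    tes[strand == "*", strand := "."]
  }
  te_annotation(tes)
}

#' Read coding/noncoding sub-intervals from BED
#'
#' Each BED line names one sub-interval as `"<te_id>|<class>"` with `class`
#' in `coding`/`noncoding`.  Use together with [te_annotation()].
#'
#' @param path BED file of sub-intervals.
#' @return data.table with columns `te_id`, `chrom`, `start`, `end`, `class`.
#' @export
read_region_classes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  f <- tstrsplit(lines, "\t", fixed = TRUE)
  if (length(f) < 4L) stop_fmt("%s: region BED requires 4+ columns", path)
  name <- tstrsplit(f[[4L]], "|", fixed = TRUE)
  if (length(name) < 2L) stop_fmt("%s: region names must be '<te_id>|<class>'", path)
  data.table(
    te_id = name[[1L]], chrom = f[[1L]],
    start = as.integer(f[[2L]]), end = as.integer(f[[3L]]),
    class = name[[2L]]
  )
}

#' Write an interval set as BED
#'
#' Emits 0-based half-open BED with the per-interval value (methylation
#' delta or ratio) in the score column.  An empty set produces a
#' zero-length file with no header.  Optionally writes a JSON sidecar with
#' the set's calling parameters for provenance.
#'
#' @param x a [target_set()] or a data.frame with `chrom`, `start`, `end`
#'   and optionally `value`.
#' @param path output BED path.
#' @param params_path optional path for a JSON sidecar of `x$params`.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(x, path, params_path = NULL) {
  if (inherits(x, "TargetSet")) {
    b <- x$bins
    label <- x$label
    params <- x$params
  } else {
    b <- as.data.table(x)
    label <- "interval"
    params <- NULL
  }
  n <- nrow(b)
  val <- if ("value" %in% names(b)) b$value else rep(0, n)
  lines <- if (n) {
    sprintf("%s\t%d\t%d\t%s\t%s\t.", b$chrom, b$start, b$end,
            paste0(label, "_", seq_len(n)), format(val, trim = TRUE, digits = 15))
  } else {
    character()
  }
  writeLines(lines, path)
  if (!is.null(params_path) && !is.null(params)) {
    jsonlite::write_json(params, params_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  }
  invisible(path)
}

#' Read a BED interval set written by [write_intervals()]
#'
#' @param path BED file.
#' @return data.table with `chrom`, `start`, `end`, `value`.
#' @export
read_intervals <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), value = numeric()))
  }
  f <- tstrsplit(lines, "\t", fixed = TRUE)
  data.table(
    chrom = f[[1L]], start = as.integer(f[[2L]]), end = as.integer(f[[3L]]),
    value = if (length(f) >= 5L) as.numeric(f[[5L]]) else NA_real_
  )
}

#' Write a score table as TSV
#'
#' @param table data.frame-like score table (e.g. from [score_all_tes()]).
#' @param path output path; the file has a header row.
#' @return `path`, invisibly.
#' @export
write_scores <- function(table, path) {
  fwrite(as.data.table(table), path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Write / read an enrichment result as JSON
#'
#' The JSON round-trips all counts, the fold, the hypergeometric tail and
#' the shuffle-null summary losslessly (`digits = NA`).
#'
#' @param result an `EnrichmentResult` from [enrichment_test()].
#' @param path output path.
#' @return `path` (write) or the parsed list (read).
#' @export
write_enrichment <- function(result, path) {
  jsonlite::write_json(unclass(result), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_enrichment
#' @export
read_enrichment <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
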