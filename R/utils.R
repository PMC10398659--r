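# Internal helpers shared across modules.

# Convert a data.table/data.frame of 0-based half-open intervals
# (chrom, start, end) to a GRanges (1-based closed) for overlap work.
to_gr <- function(x) {
  GenomicRanges::GRanges(
    seqnames = as.character(x$chrom),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

# Point-GRanges for per-cytosine records (0-based pos0).
records_gr <- function(rec) {
  GenomicRanges::GRanges(
    seqnames = as.character(rec$chrom),
    ranges = IRanges::IRanges(start = rec$pos0 + 1L, width = 1L)
  )
}

# Evaluate `code` with the RNG seeded reproducibly, restoring the caller's
# RNG state afterwards.  Generator kinds are pinned so that streams are
# identical across platforms and R versions >= 3.6.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(code)
}

# Unique string key for a bin, used for set arithmetic on tilings.
bin_key <- function(x) paste(x$chrom, x$start, sep = ":")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn_fmt <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
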