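# Shared fixture builders and a per-session cache for the (expensive)
# synthetic scenario and pipeline run, so they are generated once per test
# run.

.temeth_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .temeth_test_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .temeth_test_cache)
  }
  get(key, envir = .temeth_test_cache, inherits = FALSE)
}

# The study-condition scenario: seed 42, defaults (depth 30x, 10 target
# copies, noncoding fraction 1/3).
test_suite <- function() cached("suite", temeth::scenario_suite(42L))

# Full demo pipeline on the same seed, run twice for determinism checks.
test_pipeline <- function() {
  cached("pipe1", temeth::run_pipeline(
    temeth::demo_config(seed = 42L),
    file.path(tempdir(), "temeth-test-run1")
  ))
}
test_pipeline_rerun <- function() {
  cached("pipe2", temeth::run_pipeline(
    temeth::demo_config(seed = 42L),
    file.path(tempdir(), "temeth-test-run2")
  ))
}

# Minimal cytosine record table in the internal layout.
mk_records <- function(chrom, pos0, m, u, context, strand = "+") {
  data.table::data.table(
    chrom = chrom, pos = pos0 + 1L, pos0 = as.integer(pos0),
    strand = strand, m = as.integer(m), u = as.integer(u),
    context = context, trinucleotide = NA_character_
  )
}

# CG records realising exact per-50bp-bin methylation ratios: 5 CG sites
# per bin at offsets 5,15,25,35,45, each with C reads.
bin_ratio_records <- function(bin_ratios, chrom = "c", C = 10L) {
  data.table::rbindlist(lapply(seq_along(bin_ratios), function(i) {
    base <- (i - 1L) * 50L
    m <- as.integer(round(bin_ratios[i] * C))
    mk_records(chrom, base + c(5L, 15L, 25L, 35L, 45L), m, C - m, "CpG")
  }))
}

# Records with a constant methylation ratio m/(m+u) at regular spacing,
# for all three contexts.
uniform_records <- function(len = 10000L, spacing = 10L, m = 8L, u = 2L,
                            chrom = "chrU") {
  pos0 <- seq(0L, len - 1L, by = spacing)
  data.table::rbindlist(lapply(c("CpG", "CHG", "CHH"), function(cx) {
    mk_records(chrom, pos0, m, u, cx)
  }))
}

toy_tes <- function(...) {
  temeth::te_annotation(data.table::data.table(...))
}

write_tsv_lines <- function(rows) {
  path <- tempfile(fileext = ".tsv")
  writeLines(vapply(rows, function(r) paste(r, collapse = "\t"), character(1)),
             path)
  path
}
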