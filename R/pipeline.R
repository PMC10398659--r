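# End-to-end pipeline driver: simulate (or load) -> score -> call DMRs ->
# select target TEs -> call RdDM targets -> enrichment -> metaprofile,
# with a single declarative config and reproducible outputs.

#' Demo pipeline configuration
#'
#' A complete [run_pipeline()] config running on the built-in synthetic
#' scenario suite.  Thresholds carry the package defaults: 50-bp bins, CG
#' ratio drop > 0.4, CHH ratio > 0.1 in the cmt23-genotype sample, > 2
#' DMR bins per VANC-target TE, minimum bin coverage 4, scatter score
#' threshold 5.
#'
#' @param seed base seed; every stochastic step derives its seed from it.
#' @return nested config list.
#' @export
demo_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = TRUE,
    scenario = list(),  # overrides passed to scenario_config()
    samples = list(ref = "WT", tg = "plus_tg", recovered = "minus_tg",
                   cmt23 = "cmt23"),
    input = NULL,  # list(sample_paths = named reports, annotation = BED6 path)
    bin_size = 50L,
    delta = 0.4,
    chh_threshold = 0.1,
    min_dmrs_exclusive = 2L,
    min_cov = 4L,
    score_threshold = 5,
    family_scope = NULL,   # default: scenario target family
    exclusions = NULL,     # default: scenario excluded ids
    enrichment = list(iterations = 1000L, universe = "target-tes"),
    metaprofile = list(flank = 2000L, step = 50L,
                       samples = c("WT", "minus_tg", "drm12_minus_tg", "cmt23"))
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  modifyList(demo_config(seed = config$seed %||% 1L), config)
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load, per-TE scoring (two comparison axes:
#' demethylation induced by the transgene, and residual change after its
#' segregation), genome binning, CG hypo-DMR calling, VANC-target TE
#' selection, RdDM-target calling, overlap enrichment with hypergeometric
#' and shuffle nulls, and the anchored methylation metaprofile.  Writes
#' six artifacts into `outdir`:
#' `scores.tsv`, `dmrs.bed`, `rddm.bed`, `enrichment.json`,
#' `metaprofile.tsv`, `run_manifest.json`.
#'
#' The pipeline is a pure function of (inputs, config, seed): a rerun with
#' the same config produces byte-identical outputs.  The manifest records
#' the full config, its MD5 hash, derived seeds and package/R versions
#' (no timestamps).
#'
#' @param config config list (see [demo_config()]) or path to a YAML file.
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with the in-memory results and output paths.
#' @export
run_pipeline <- function(config = demo_config(), outdir) {
  cfg <- read_pipeline_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  if (isTRUE(cfg$simulate)) {
    sc_cfg <- do.call(scenario_config,
                      c(list(seed = cfg$seed), cfg$scenario))
    suite <- scenario_suite(cfg$seed, sc_cfg)
    samples <- suite$samples
    tes <- suite$genome$tes
    chrom_sizes <- sc_cfg$chrom_lengths
    family_scope <- cfg$family_scope %||% sc_cfg$target_family
    exclusions <- cfg$exclusions %||% suite$genome$truth$excluded_ids
  } else {
    if (is.null(cfg$input)) stop_fmt("config$input required when simulate = FALSE")
    need <- unique(c(unlist(cfg$samples), cfg$metaprofile$samples))
    paths <- cfg$input$sample_paths
    miss <- setdiff(c(cfg$samples$ref, cfg$samples$tg,
                      cfg$samples$recovered, cfg$samples$cmt23),
                    names(paths))
    if (length(miss)) stop_fmt("missing sample report(s): %s",
                               paste(miss, collapse = ", "))
    samples <- lapply(paths[intersect(need, names(paths))],
                      read_cytosine_report)
    tes <- read_te_annotation(cfg$input$annotation,
                              dialect = cfg$input$dialect %||% "BED6")
    chrom_sizes <- NULL
    family_scope <- cfg$family_scope %||% stop_fmt("family_scope required")
    exclusions <- cfg$exclusions %||% character()
  }
  for (s in c(cfg$samples$ref, cfg$samples$tg, cfg$samples$recovered,
              cfg$samples$cmt23)) {
    if (!s %in% names(samples)) stop_fmt("sample '%s' not available", s)
  }

  # per-TE change scores on two axes
  s_gain <- score_all_tes(samples[[cfg$samples$ref]],
                          samples[[cfg$samples$tg]], tes, "combined")
  s_resid <- score_all_tes(samples[[cfg$samples$ref]],
                           samples[[cfg$samples$recovered]], tes, "combined")
  scores <- merge(
    setnames(s_gain, c("Mn", "Cn", "Mt", "Ct", "S"),
             c("Mn_gain", "Cn_gain", "Mt_gain", "Ct_gain", "S_gain")),
    s_resid[, .(te_id, S_residual = S)], by = "te_id"
  )
  scores[, called := !is.na(S_gain) & S_gain > cfg$score_threshold]
  setorderv(scores, "te_id")

  bins <- bin_genome(samples[unique(c(cfg$samples$ref, cfg$samples$tg,
                                      cfg$samples$cmt23))],
                     chrom_sizes = chrom_sizes, bin_size = cfg$bin_size)

  dmrs <- call_hypo_dmrs(bins, cfg$samples$ref, cfg$samples$tg, tes,
                         family_scope = family_scope,
                         exclusions = exclusions, delta = cfg$delta,
                         min_cov = cfg$min_cov)
  vanc_tes <- select_vanc_target_tes(tes, dmrs,
                                     min_dmrs_exclusive = cfg$min_dmrs_exclusive)
  rddm_scope <- if (identical(cfg$enrichment$universe, "genome")) {
    NULL
  } else {
    tes[tes$te_id %in% vanc_tes]
  }
  rddm <- call_rddm_targets(bins, cfg$samples$cmt23, scope_tes = rddm_scope,
                            threshold = cfg$chh_threshold,
                            min_cov = cfg$min_cov)

  required <- data.table(
    sample = c(cfg$samples$ref, cfg$samples$tg, cfg$samples$cmt23),
    context = c("CpG", "CpG", "CHH")
  )
  universe <- if (identical(cfg$enrichment$universe, "family")) {
    universe_bins(bins, tes, families = family_scope,
                  exclusions = exclusions, required = required,
                  min_cov = cfg$min_cov)
  } else {
    universe_bins(bins, tes, te_ids = vanc_tes, exclusions = exclusions,
                  required = required, min_cov = cfg$min_cov)
  }
  enr <- enrichment_test(dmrs, rddm, universe,
                         iterations = cfg$enrichment$iterations,
                         seed = cfg$seed + 97L)
  enr$params$universe <- cfg$enrichment$universe
  enr$params$thresholds <- list(delta = cfg$delta,
                                chh_threshold = cfg$chh_threshold,
                                min_dmrs_exclusive = cfg$min_dmrs_exclusive,
                                min_cov = cfg$min_cov)

  anchors <- anchors_from_targets(dmrs, tes)
  mp_samples <- intersect(cfg$metaprofile$samples, names(samples))
  profile <- compute_metaprofile(samples[mp_samples], anchors,
                                 flank = cfg$metaprofile$flank,
                                 step = cfg$metaprofile$step)

  paths <- list(
    scores = file.path(outdir, "scores.tsv"),
    dmrs = file.path(outdir, "dmrs.bed"),
    rddm = file.path(outdir, "rddm.bed"),
    enrichment = file.path(outdir, "enrichment.json"),
    metaprofile = file.path(outdir, "metaprofile.tsv"),
    manifest = file.path(outdir, "run_manifest.json")
  )
  write_scores(scores, paths$scores)
  write_intervals(dmrs, paths$dmrs)
  write_intervals(rddm, paths$rddm)
  write_enrichment(enr, paths$enrichment)
  write_metaprofile(profile, paths$metaprofile)

  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                               null = "null", dataframe = "rows")
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  cfg_md5 <- unname(tools::md5sum(tmp))
  unlink(tmp)
  manifest <- list(
    package = "temeth",
    package_version = as.character(utils::packageVersion("temeth")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config_md5 = cfg_md5,
    seed = cfg$seed,
    derived_seeds = list(shuffle = cfg$seed + 97L),
    thresholds = list(bin_size = cfg$bin_size, delta = cfg$delta,
                      chh_threshold = cfg$chh_threshold,
                      min_dmrs_exclusive = cfg$min_dmrs_exclusive,
                      min_cov = cfg$min_cov,
                      score_threshold = cfg$score_threshold),
    family_scope = family_scope,
    exclusions = exclusions,
    n_vanc_target_tes = length(vanc_tes),
    vanc_target_tes = vanc_tes,
    outputs = lapply(paths, basename)
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")

  invisible(list(scores = scores, bins = bins, dmrs = dmrs,
                 vanc_target_tes = vanc_tes, rddm = rddm,
                 universe = universe, enrichment = enr, profile = profile,
                 anchors = anchors, paths = paths, config = cfg))
}
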