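# Synthetic bisulfite data: a toy genome carrying TE families with coding
# and noncoding segments, per-cytosine methylation count tables under a
# panel of genotype scenarios, and the ground truth every downstream test
# compares against.
#
# Noise model: per-cytosine coverage ~ Poisson(depth); methylated count ~
# Beta-Binomial(C, mean = true ratio, dispersion rho); rho = 0 reduces to
# Binomial.

#' Genotype scenarios of the simulator
#' @return character vector of genotype names.
#' @export
scenario_genotypes <- function() {
  c("WT", "plus_tg", "minus_tg", "drm12_minus_tg", "cmt23", "ddcc", "met1")
}

#' Default true methylation levels per genotype, region class and context
#'
#' Encodes the qualitative methylation structure of the study system:
#' * `WT` / `minus_tg` (recovered): TEs fully methylated (mCG 0.9,
#'   mCHG 0.7, mCHH 0.4), genome background low.
#' * `plus_tg`: VANC-target-family noncoding bins lose mCG and mCH;
#'   CH loss spreads into coding bodies (mCG kept there).
#' * `drm12_minus_tg`: after transgene segregation without RdDM, noncoding
#'   mCG/mCHH stay low while coding mCH recovers.
#' * `cmt23`: CMT-dependent body mCH gone, RdDM-dependent noncoding CHH
#'   peak retained, mCG intact.
#' * `ddcc`: all mCH gone.  `met1`: all mCG gone.
#'
#' Region classes: `target_coding` / `target_noncoding` (VANC-target
#' family), `bg_coding` / `bg_noncoding` (other TE family), `genome`
#' (everything else).
#'
#' @return data.table with columns `genotype`, `class`, `context`, `p`.
#' @export
default_methylation_levels <- function() {
  classes <- c("target_coding", "target_noncoding", "bg_coding",
               "bg_noncoding", "genome")
  base <- CJ(class = classes, context = c("CpG", "CHG", "CHH"))
  base[, p := fifelse(class == "genome",
                      fifelse(context == "CpG", 0.10, 0.03),
                      fifelse(context == "CpG", 0.90,
                              fifelse(context == "CHG", 0.70, 0.40)))]
  set_p <- function(dt, cls, ctx, val) {
    dt[class %in% cls & context %in% ctx, p := val]
    dt
  }
  lv <- rbindlist(lapply(scenario_genotypes(), function(g) {
    d <- copy(base)
    if (g == "plus_tg") {
      d <- set_p(d, "target_noncoding", "CpG", 0.10)
      d <- set_p(d, "target_noncoding", c("CHG", "CHH"), 0.05)
      d <- set_p(d, "target_coding", "CHG", 0.10)
      d <- set_p(d, "target_coding", "CHH", 0.05)
    } else if (g == "drm12_minus_tg") {
      d <- set_p(d, "target_noncoding", "CpG", 0.10)
      d <- set_p(d, "target_noncoding", "CHG", 0.10)
      d <- set_p(d, "target_noncoding", "CHH", 0.05)
    } else if (g == "cmt23") {
      d <- set_p(d, c("target_coding", "bg_coding"), c("CHG", "CHH"), 0.02)
      d <- set_p(d, "target_noncoding", "CHG", 0.10)
      d <- set_p(d, "target_noncoding", "CHH", 0.35)
      d <- set_p(d, "bg_noncoding", "CHG", 0.02)
      d <- set_p(d, "bg_noncoding", "CHH", 0.05)
      d <- set_p(d, "genome", c("CHG", "CHH"), 0.02)
    } else if (g == "ddcc") {
      d <- set_p(d, classes, c("CHG", "CHH"), 0.02)
    } else if (g == "met1") {
      d <- set_p(d, classes, "CpG", 0.02)
    }
    d[, genotype := g]
    d
  }))
  lv[, .(genotype, class, context, p)]
}

#' Simulation scenario configuration
#'
#' Defines the toy genome, the TE families, the noise model and the true
#' methylation levels.  Geometry is kept on the 50-bp bin grid (all
#' lengths and gaps are multiples of 50) so that planted region boundaries
#' coincide with bin boundaries.  The target-family noncoding fraction is
#' `2 * noncoding_length / target_length` (1/3 with the defaults), which
#' fixes the planted within-family enrichment fold at its reciprocal
#' (3.0).
#'
#' @param seed RNG seed for genome layout.
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param target_family,background_family family labels.
#' @param n_target,target_length copies and length (bp) of the VANC-target
#'   family.
#' @param n_background,background_length copies and length of the
#'   background family.
#' @param noncoding_length length of each of the two terminal noncoding
#'   (tandem-repeat) segments per TE copy.
#' @param min_gap minimum gap between TE copies (bp).
#' @param depth mean per-cytosine, per-strand coverage (Poisson).
#' @param rho beta-binomial dispersion of methylation calls in `[0, 1)`.
#' @param densities cytosines per bp per strand for each context.
#' @param exclude_first_target if `TRUE` the first target copy plays the
#'   transgene-donor role and is listed in `excluded_ids`.
#' @param levels true-level table ([default_methylation_levels()]).
#' @return a `ScenarioConfig` list.
#' @export
scenario_config <- function(seed = 1L,
                            chrom_lengths = c(chr1 = 300000L, chr2 = 300000L),
                            target_family = "VANDAL21",
                            background_family = "ATCOPIA",
                            n_target = 10L, target_length = 9000L,
                            n_background = 20L, background_length = 6000L,
                            noncoding_length = 1500L,
                            min_gap = 2000L,
                            depth = 30, rho = 0.05,
                            densities = c(CpG = 1 / 20, CHG = 1 / 15, CHH = 1 / 5),
                            exclude_first_target = TRUE,
                            levels = default_methylation_levels()) {
  cfg <- list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
              target_family = target_family,
              background_family = background_family,
              n_target = as.integer(n_target),
              target_length = as.integer(target_length),
              n_background = as.integer(n_background),
              background_length = as.integer(background_length),
              noncoding_length = as.integer(noncoding_length),
              min_gap = as.integer(min_gap),
              depth = depth, rho = rho, densities = densities,
              exclude_first_target = isTRUE(exclude_first_target),
              levels = as.data.table(levels))
  with(cfg, {
    stopifnot(all(chrom_lengths > 0), !is.null(names(chrom_lengths)))
    stopifnot(target_length %% 50L == 0L, background_length %% 50L == 0L,
              noncoding_length %% 50L == 0L, min_gap %% 50L == 0L,
              all(chrom_lengths %% 50L == 0L))
    stopifnot(2L * noncoding_length < target_length,
              2L * noncoding_length < background_length)
    stopifnot(depth >= 0, rho >= 0, rho < 1)
    stopifnot(all(levels$p >= 0 & levels$p <= 1))
    stopifnot(all(densities >= 0), sum(densities) <= 1)
  })
  structure(cfg, class = "ScenarioConfig")
}

#' Generate the toy genome: cytosine map, TE annotation and ground truth
#'
#' Places the TE copies (round-robin across chromosomes, random 50-bp-grid
#' gaps, never overlapping), marks each copy's noncoding/coding/noncoding
#' layout, scatters cytosine positions on both strands with the configured
#' context densities, and records the ground truth: the class span map,
#' the planted hypo-DMR bins (noncoding bins of non-excluded target
#' copies), the planted RdDM-target bins (identical by construction: the
#' cmt23 noncoding CHH level exceeds the 0.1 threshold exactly there), the
#' bin universe and the planted enrichment fold.  Deterministic given the
#' config seed.
#'
#' @param config a [scenario_config()].
#' @return a `scenario_genome`: list with `cytosines` (chrom, pos0,
#'   strand, context, class), `tes` ([te_annotation()] with regions),
#'   `truth` and `config`.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "ScenarioConfig"))
  cfg <- config
  te_spec <- data.table(
    te_id = c(sprintf("synTE_T%02d", seq_len(cfg$n_target)),
              sprintf("synTE_B%02d", seq_len(cfg$n_background))),
    family = c(rep(cfg$target_family, cfg$n_target),
               rep(cfg$background_family, cfg$n_background)),
    length = c(rep(cfg$target_length, cfg$n_target),
               rep(cfg$background_length, cfg$n_background))
  )

  out <- with_seed(cfg$seed, {
    n_te <- nrow(te_spec)
    if (n_te) {
      te_spec <- te_spec[sample.int(n_te)]
      te_spec[, chrom := names(cfg$chrom_lengths)[
        (seq_len(n_te) - 1L) %% length(cfg$chrom_lengths) + 1L]]
    } else {
      te_spec[, chrom := character()]
    }
    placed <- rbindlist(lapply(names(cfg$chrom_lengths), function(ch) {
      sub <- te_spec[chrom == ch]
      L <- cfg$chrom_lengths[[ch]]
      k <- nrow(sub)
      if (!k) return(NULL)
      slack <- L - sum(sub$length) - (k + 1L) * cfg$min_gap
      if (slack < 0L) stop_fmt("TE total length exceeds genome on %s", ch)
      units <- as.integer(rmultinom(1L, slack %/% 50L, rep(1, k + 1L)))
      gaps <- cfg$min_gap + units * 50L
      starts <- cumsum(c(gaps[1L], head(sub$length + gaps[-1L], -1L)))
      sub[, `:=`(start = starts, end = starts + length)]
      sub
    }))

    # cytosine map, both strands, genotype-independent
    dens_tot <- sum(cfg$densities)
    cyt <- rbindlist(lapply(names(cfg$chrom_lengths), function(ch) {
      L <- cfg$chrom_lengths[[ch]]
      rbindlist(lapply(c("+", "-"), function(st) {
        n <- round(L * dens_tot)
        pos0 <- sort(sample.int(L, n)) - 1L
        n_ctx <- round(n * cfg$densities / dens_tot)
        n_ctx[1L] <- n - sum(n_ctx[-1L])
        ctx <- sample(rep(names(cfg$densities), times = n_ctx))
        data.table(chrom = ch, pos0 = pos0, strand = st, context = ctx)
      }))
    }))
    list(placed = placed, cyt = cyt)
  })
  placed <- out$placed
  cyt <- out$cyt

  if (!is.null(placed) && nrow(placed)) {
    nc <- cfg$noncoding_length
    regions <- placed[, rbindlist(lapply(seq_len(.N), function(i) {
      data.table(
        te_id = te_id[i], chrom = chrom[i],
        start = c(start[i], start[i] + nc, end[i] - nc),
        end = c(start[i] + nc, end[i] - nc, end[i]),
        class = c("noncoding", "coding", "noncoding")
      )
    }))]
    tes <- te_annotation(
      placed[, .(te_id, chrom, start, end, strand = "+", family)],
      regions = regions
    )
  } else {
    tes <- te_annotation(data.table(
      te_id = character(), chrom = character(), start = integer(),
      end = integer(), strand = character(), family = character()
    ))
    regions <- NULL
  }

  spans <- build_class_spans(tes, regions, cfg)
  cyt <- assign_spans(cyt, spans)

  truth <- build_ground_truth(tes, regions, cfg)
  structure(list(cytosines = cyt, tes = tes, truth = truth, config = cfg),
            class = "scenario_genome")
}

# Class span map covering every base: TE sub-regions plus the genome
# complement.
build_class_spans <- function(tes, regions, cfg) {
  spans <- if (!is.null(regions)) {
    r <- copy(regions)
    fam <- tes$family[match(r$te_id, tes$te_id)]
    r[, class := paste0(fifelse(fam == cfg$target_family, "target_", "bg_"),
                        class)]
    r[, .(chrom, start, end, class)]
  } else {
    data.table(chrom = character(), start = integer(), end = integer(),
               class = character())
  }
  genome_spans <- rbindlist(lapply(names(cfg$chrom_lengths), function(ch) {
    s <- spans[chrom == ch]
    setorderv(s, "start")
    bounds <- c(0L, as.vector(rbind(s$start, s$end)), cfg$chrom_lengths[[ch]])
    starts <- bounds[seq(1L, length(bounds) - 1L, by = 2L)]
    ends <- bounds[seq(2L, length(bounds), by = 2L)]
    keep <- starts < ends
    data.table(chrom = ch, start = starts[keep], end = ends[keep],
               class = "genome")
  }))
  out <- rbind(spans, genome_spans)
  setorderv(out, c("chrom", "start"))
  out
}

# Annotate each cytosine with its class span (spans tile the genome).
assign_spans <- function(cyt, spans) {
  cyt <- copy(cyt)
  cyt[, class := NA_character_]
  for (ch in unique(spans$chrom)) {
    s <- spans[chrom == ch]
    idx <- cyt[, which(chrom == ch)]
    if (!length(idx)) next
    j <- findInterval(cyt$pos0[idx], s$start)
    cyt[idx, class := s$class[j]]
  }
  stopifnot(!anyNA(cyt$class))
  cyt
}

expand_bins <- function(iv, bin_size = 50L) {
  if (!nrow(iv)) {
    return(data.table(chrom = character(), start = integer(), end = integer()))
  }
  rbindlist(lapply(seq_len(nrow(iv)), function(i) {
    starts <- seq.int(iv$start[i], iv$end[i] - 1L, by = bin_size)
    data.table(chrom = iv$chrom[i], start = starts, end = starts + bin_size)
  }))
}

build_ground_truth <- function(tes, regions, cfg) {
  excluded <- if (cfg$exclude_first_target && cfg$n_target >= 1L) {
    "synTE_T01"
  } else {
    character()
  }
  if (is.null(regions)) {
    empty <- data.table(chrom = character(), start = integer(), end = integer())
    return(list(spans = build_class_spans(tes, regions, cfg),
                levels = cfg$levels, excluded_ids = excluded,
                planted_dmr_bins = empty, planted_rddm_bins = empty,
                universe_bins = empty, planted_fold = NA_real_))
  }
  target_ids <- tes$te_id[tes$family == cfg$target_family]
  live_ids <- setdiff(target_ids, excluded)
  nc <- regions[te_id %in% live_ids & class == "noncoding"]
  planted <- expand_bins(nc)
  universe <- expand_bins(tes[tes$te_id %in% live_ids,
                              c("chrom", "start", "end")])
  N <- nrow(universe); n <- nrow(planted)
  fold <- if (n > 0) (n / n) / (n / N) else NA_real_  # k = K = n by construction
  list(spans = build_class_spans(tes, regions, cfg), levels = cfg$levels,
       excluded_ids = excluded,
       planted_dmr_bins = planted, planted_rddm_bins = copy(planted),
       universe_bins = universe, planted_fold = fold)
}

#' Simulate one sample's cytosine report
#'
#' Draws per-cytosine coverage `C ~ Poisson(depth)` and methylated counts
#' `m ~ BetaBinomial(C, p, rho)` where `p` is the configured true ratio of
#' the cytosine's region class and context under the genotype.  `rho = 0`
#' gives binomial sampling; `p = 0` / `p = 1` give exactly `m = 0` /
#' `m = C`.  One record per cytosine per strand; zero-coverage records are
#' retained.
#'
#' @param genome a `scenario_genome` from [generate_genome()].
#' @param genotype one of [scenario_genotypes()] (or any genotype present
#'   in the config's level table).
#' @param depth mean coverage; defaults to the config value.
#' @param seed RNG seed.
#' @return a cytosine record table (`chrom`, `pos`, `pos0`, `strand`, `m`,
#'   `u`, `context`, `trinucleotide = NA`).
#' @export
simulate_sample <- function(genome, genotype, depth = NULL, seed = 1L) {
  stopifnot(inherits(genome, "scenario_genome"))
  cfg <- genome$config
  gt <- genotype
  lv <- cfg$levels[genotype == gt]
  if (!nrow(lv)) stop_fmt("unknown genotype '%s'", genotype)
  depth <- depth %||% cfg$depth
  cyt <- genome$cytosines
  p <- lv$p[match(paste(cyt$class, cyt$context),
                  paste(lv$class, lv$context))]
  if (anyNA(p)) stop_fmt("level table incomplete for genotype '%s'", genotype)
  n <- nrow(cyt)
  dat <- with_seed(seed, {
    C <- rpois(n, depth)
    q <- if (cfg$rho > 0) {
      a <- p * (1 - cfg$rho) / cfg$rho
      b <- (1 - p) * (1 - cfg$rho) / cfg$rho
      qq <- rep(0, n)
      mid <- p > 0 & p < 1
      qq[mid] <- rbeta(sum(mid), a[mid], b[mid])
      qq[p == 1] <- 1
      qq
    } else {
      p
    }
    m <- rbinom(n, C, q)
    list(C = C, m = m)
  })
  data.table(
    chrom = cyt$chrom, pos = cyt$pos0 + 1L, pos0 = cyt$pos0,
    strand = cyt$strand, m = dat$m, u = dat$C - dat$m,
    context = cyt$context, trinucleotide = NA_character_
  )
}

#' Generate the full genotype scenario suite
#'
#' One genome plus one simulated sample per genotype scenario
#' (see [scenario_genotypes()]), with per-sample seeds derived from the
#' base seed.  Fully deterministic given `seed`.
#'
#' @param seed base seed.
#' @param config optional [scenario_config()]; defaults to
#'   `scenario_config(seed = seed)`.
#' @return list with `genome`, `samples` (named list of record tables,
#'   names are genotypes), `config`.
#' @export
scenario_suite <- function(seed = 1L, config = NULL) {
  config <- config %||% scenario_config(seed = seed)
  genome <- generate_genome(config)
  gts <- scenario_genotypes()
  samples <- setNames(lapply(seq_along(gts), function(i) {
    simulate_sample(genome, gts[i], seed = config$seed + i)
  }), gts)
  list(genome = genome, samples = samples, config = config)
}

#' Write a simulated sample as a cytosine-report TSV
#'
#' Emits the same 7-column tab-separated format [read_cytosine_report()]
#' consumes (1-based positions; trinucleotide column filled with the
#' context token).
#'
#' @param records record table from [simulate_sample()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(records, path) {
  out <- records[, .(chrom, pos, strand, m, u, context,
                     trinucleotide = fifelse(is.na(trinucleotide),
                                             context, trinucleotide))]
  fwrite(out, path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}
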