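---
title: "Methods: TE methylome change scoring, hypo-DMR calling and target-overlap enrichment"
author: "temeth authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TE methylome change scoring, hypo-DMR calling and target-overlap enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(temeth)
library(data.table)
```

## The scientific problem

Transposable elements (TEs) in plants are kept immobile by DNA methylation
in three cytosine contexts (mCG, mCHG, mCHH).  Mutator-like *VANDAL* TEs in
*Arabidopsis* encode VANC anti-silencing proteins that bind tandem-repeat
**noncoding** regions of their own family's copies and strip methylation
from them, with a spreading loss of CH methylation into the coding bodies.
The host counters with RNA-directed DNA methylation (RdDM), which
re-establishes methylation *de novo*.  The analytical question this package
answers is where these two opposing activities act, and whether they act on
the **same** regions: are the bins that lose CG methylation when a VANC is
expressed (VANC targets) the same bins that carry RdDM-dependent CHH
methylation (RdDM targets)?

`temeth` implements the complete path from per-cytosine bisulfite
methylation calls to that statement: per-TE change scores, bin-level target
calling, overlap enrichment with two null models, and anchored
metaprofiles — plus a synthetic data generator so the whole pipeline can be
exercised and validated end to end without any sequencing data.

## Coordinate and counting conventions

All intervals are **0-based half-open** internally; 1-based cytosine-report
and GFF3 coordinates are converted at the parse boundary and nowhere else.
Strand-resolved cytosine records are aggregated jointly: both strands sum
into one `(M, C)` pair per region, bin and context.  Symmetric CpG
positions on opposite strands are *not* merged into single units — merging
would change `C` and hence every coverage-weighted quantity, and the
per-cytosine report granularity is the natural unit.  Ratios are `M/C`
when `C > 0` and **undefined** (`NA`) otherwise; an undefined ratio is
never treated as 0, because a zero would masquerade as complete
hypomethylation in every downstream comparison.

## The per-TE change statistic

For a TE with methylated/total counts `(Mn, Cn)` in a nontransgenic sample
and `(Mt, Ct)` in a transgenic sample, the change score is

$$S = \frac{M_n/C_n - M_t/C_t}{1/\sqrt{C_n} + 1/\sqrt{C_t}}.$$

The numerator is the methylation-ratio difference (positive = loss in the
transgenic sample); the denominator shrinks as coverage grows, so `S` is a
coverage-weighted ratio difference used for ranking and scatter plots, not
a calibrated test statistic.  Two exact properties pin the implementation
down and are enforced in the tests: antisymmetry
(`S(n,t) = -S(t,n)`) and coverage scaling (multiplying both coverages by
`k` at fixed ratios multiplies `S` by `sqrt(k)`).

```{r statistic}
te_change_statistic(100, 100, 0, 100)      # complete loss at 100x: 5
te_change_statistic(200, 200, 0, 200)      # same ratios, doubled coverage
```

Whether a scatter axis should pool contexts is an open choice; the package
computes per-context scores and a pooled "combined" variant and defaults to
the combined score for scatters, since the anti-silencing phenotype
involves losses in all three contexts.

## Bin-level target calling

The genome is tiled with 50-bp bins (`bin_genome()`), and per-sample,
per-context `(M, C)` counts are aggregated per bin.  Three calls follow,
all with **strict** inequalities, mirroring how the thresholds are
conventionally printed:

* **CG hypo-DMRs** (`call_hypo_dmrs()`): bins whose CG ratio drops by more
  than `delta = 0.4` from the reference to the VANC-expressing sample,
  restricted to bins overlapping TEs of the scoped family (any-overlap:
  with 50-bp bins against kb-scale TEs the rule choice is low-impact), and
  excluding bins that overlap designated TE copies — typically the
  transgene-donor copy, whose methylation does not report the endogenous
  state.  The drop is directional by default because the biological object
  is a *hypo*-DMR; an absolute mode exists for exploration.
* **VANC-target TEs** (`select_vanc_target_tes()`): TEs overlapped by
  strictly more than 2 hypo-DMR bins.
* **RdDM targets** (`call_rddm_targets()`): bins with CHH ratio strictly
  above 0.1 in a *cmt2 cmt3* (cmt23) sample, where CMT-dependent CH
  methylation is absent and residual CHH reports RdDM.

Both ratios entering a call must be defined at a minimum bin coverage of
`C >= 4` per context and sample.  This floor is a package decision (the
convention in the source analyses is unstated); it is configurable and is
recorded in every output's parameters, because it also defines the
enrichment universe below.  Bins failing it are *missing*, not zero.

## Overlap enrichment

Let the **universe** be all coverage-qualified 50-bp bins within the
VANC-target TEs (minus exclusions) — the region set over which both target
definitions are meaningful.  With `N` universe bins, `K` RdDM-target bins,
`n` hypo-DMR bins and `k` bins in both sets:

* fold overrepresentation `= (k/n)/(K/N)` (1 under independence),
* `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)`, computed in log
  space (`log10_p_hyper` stays finite when the tail underflows double
  precision),
* a **shuffle null**: in each iteration, regions with the same lengths as
  the merged hypo-DMR regions are placed uniformly at random, without
  mutual overlap, into the universe space, and their overlap with the
  RdDM set is counted.  The empirical p uses the add-one estimator
  `(1 + #{shuffled >= observed})/(1 + iterations)`, which cannot be zero.

The hypergeometric model conditions on the bin counts and ignores the
spatial contiguity of DMRs; the shuffle null keeps the region length
structure and is the model-free cross-check.  Placements are aligned to
the bin grid so shuffled overlaps are measured in the same units as `k`;
this is the one deliberate difference from a bedtools-style shuffle, and
it is what makes `mean(shuffled)` comparable to `n K / N` when the
reference set is spatially unstructured.  Both the model-based fold and
`k / mean(shuffled)` are reported.  No multiple-testing correction is
applied: the analysis asks one question per VANC family.  Note the two
nulls answer slightly different questions — a clustered reference set
shifts the shuffle mean away from `n K / N` (edge effects of contiguous
placement), which is intended.

## Metaprofiles

`anchors_from_targets()` reduces a target set to points: adjacent bins are
merged and each merged region contributes its midpoint, oriented by the
host TE strand.  `compute_metaprofile()` then pools `(M, C)` across
anchors per offset window (default flank 2000 bp, step 50 bp — axis
extents are a presentation choice) and reports pooled ratios.  Pooled
counts rather than mean-of-ratios: with sparse per-anchor coverage, the
mean of noisy ratios is dominated by low-coverage anchors, while pooling
weights anchors by the evidence they carry.  Anchors near chromosome ends
contribute truncated windows rather than being dropped.  Strand flipping
mirrors windows exactly about the anchor (window `[o, o+step)` maps to
`[-o-step, -o)`), a property the tests verify.

## The synthetic scenario suite

The generator (`scenario_config()`, `generate_genome()`,
`simulate_sample()`, `scenario_suite()`) emulates the study design, with
all conditions fixed in the default configuration:

* genome: 2 chromosomes x 300 kb;
* TEs: 10 copies of a 9-kb VANC-target family, each laid out as
  1.5 kb noncoding + 6 kb coding + 1.5 kb noncoding (noncoding fraction
  exactly 1/3), and 20 copies of a 6-kb background family; copies are
  placed on the 50-bp grid, at least 2 kb apart, so planted region
  boundaries coincide with bin boundaries and metaprofile flanks do not
  collide with neighbouring copies;
* cytosines: densities 1/20 (CpG), 1/15 (CHG), 1/5 (CHH) per bp per
  strand — order-of-magnitude realism for TE sequence;
* noise: coverage `~ Poisson(30)` per cytosine per strand; methylated
  counts `~ BetaBinomial(C, p, rho = 0.05)` (the paper-side analyses give
  no generative model; this one is the package's own, and `rho = 0`
  recovers binomial sampling);
* genotypes: `WT` (TEs fully methylated: mCG 0.9, mCHG 0.7, mCHH 0.4),
  `plus_tg` (target-family noncoding loses CG and CH; coding loses CH —
  the spreading effect — but keeps CG), `minus_tg` (recovery to WT),
  `drm12_minus_tg` (no noncoding CG/CHH recovery without RdDM; coding CH
  recovers, which is the RdDM-independent body-CH pathway),
  `cmt23` (body CH erased, noncoding CHH peak 0.35 retained = planted
  RdDM targets), `ddcc` (all CH erased), `met1` (all CG erased);
* the first target copy plays the transgene-donor role and is excluded
  from DMR calling, mirroring the donor-copy exclusion of the real
  analysis.

The geometry makes the planted truth exact: the planted hypo-DMR bins and
planted RdDM bins are both the noncoding bins of the non-excluded target
copies, so within the target-TE universe the planted fold is
`1 / (noncoding fraction) = 3.0`, and the planted CG drop (0.9 to 0.1)
clears the 0.4 threshold by 7-8 standard errors at 30x bin coverage.
What the generator does **not** emulate: sequence-dependent context
placement, bisulfite conversion failure, mapping bias, copy-number
variation between samples, and biological replicate variance beyond the
beta-binomial dispersion.  Passing tests therefore demonstrate the
correctness and statistical behaviour of the machinery under a faithful
qualitative model of the system — not performance on real WGBS libraries.

## Numerical and degenerate-input choices

* Strict thresholds throughout; a bin at exactly the threshold is never
  called, and the selection rule "more than 2 DMR bins" admits 3.
* `C = 0` propagates as missing everywhere (ratios, bins, profiles).
* Zero-coverage TEs get a flagged `NA` score, not an error, so scatters
  over full annotations do not abort.
* The RNG is pinned (`Mersenne-Twister`, `Rejection` sampling) and every
  stochastic step takes an explicit seed; helper `with_seed()` restores
  the caller's RNG state, so library calls never perturb a session.
* The shuffle placement retries up to 1000 times per region and errors if
  the space is genuinely too fragmented, rather than silently dropping
  regions.

## The pipeline and problem sizes

`run_pipeline(demo_config(seed), outdir)` runs simulate, score (two axes:
transgene-induced loss `S_gain` = WT vs `plus_tg`, and residual change
after segregation `S_residual` = WT vs `minus_tg`), bin, call, select,
enrich (1000 shuffle iterations) and metaprofile, writing `scores.tsv`,
`dmrs.bed`, `rddm.bed`, `enrichment.json`, `metaprofile.tsv` and
`run_manifest.json`.  The manifest records the config and its MD5, the
derived seeds, versions and all thresholds; no timestamps — a rerun with
the same config is byte-identical, which the tests assert file by file.
The default scenario (600 kb, 380,000 cytosines, 7 genotypes, 1000
shuffle iterations) runs end to end in about a minute on one core; these
sizes were chosen so that bin-level recall/precision and enrichment-fold
recovery operate in a regime with hundreds of planted bins per call, and
they scale linearly for larger configurations.

## Known limitations

* The hypergeometric universe is a modelling choice; with a different
  universe (e.g. genome-wide bins) the fold and p change meaning.  The
  universe definition is a config knob and always recorded in outputs.
* Anchor points are midpoints of merged DMR regions; peak summits from
  ChIP-seq, where available, are sharper anchors, and
  `compute_metaprofile()` accepts any externally supplied anchor table.
* `read_cytosine_report()` favours strict validation over speed; for
  multi-gigabyte reports a chunked reader would be the natural extension.
* Family scopes are label-driven; mis-labelled annotations silently scope
  the wrong TEs (garbage in, garbage out).
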