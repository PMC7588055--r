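---
title: "Methods: calling compensated regions of altered replication timing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling compensated regions of altered replication timing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repliRAT)
```

## The problem

In fraction-resolved Repli-seq, S-phase nuclei are sorted into early (E),
mid (M) and late (L) fractions, newly replicated DNA is sequenced, and read
density in fixed genomic windows measures how much of each window's
replication happens in each part of S phase. repliRAT compares two
replication programs — typically the mitotic cell cycle against the
endocycle, in which the genome replicates without division — and calls
*Regions of Altered Timing* (RATs): genomic intervals where replication
signal moves between S-phase fractions in one condition relative to the
other. The motivating application is plant (maize-like) root tissue, where
centromeres shift from mid-S replication in cycling cells to late-S
replication in endocycling cells, but nothing in the implementation is
species-specific.

All coordinates are 0-based half-open internally (BED convention); GFF3
input is converted at the boundary by decrementing starts. Tracks live on a
fixed `window_grid` (3-kb windows for replication timing, 5-kb for
copy-number screening, 100-kb for centromere summaries). Terminal windows
shorter than the window size are kept and flagged; statistics weight all
windows equally.

## Normalization chain

Each condition's profile is built by `build_profile()`:

1. **Replicate aggregation.** Replicate counts per fraction are summed.
2. **Blacklist detection** (`detect_blacklist`). The pre-replicative 2C
   reference counts are natural-log-transformed (positive windows only,
   since ln 0 is undefined), a normal is fitted by its moments, and windows
   below the 2.5th percentile of that fit are masked, as are all zero-count
   windows. The upper tail is kept by default: coverage "spikes" from
   collapsed repeats appear in sample and reference alike and cancel in the
   ratio step. With zero variance (all counts equal) only zero-count
   windows are masked.
3. **RPGC scaling** (`scale_rpgc`). Counts are divided by the mean count
   over unmasked windows, so the unmasked mean is exactly 1 (1x genome
   coverage). This makes every later step invariant to sequencing depth.
4. **Reference division** (`normalize_to_reference`). Each scaled fraction
   is divided window-wise by the scaled 2C reference, removing mappability
   structure. Unmasked windows with a zero reference value are added to the
   mask rather than producing infinities.
5. **Haar smoothing** (`haar_smooth`). Per chromosome, masked windows are
   bridged by linear interpolation, the series is padded to the next power
   of two, an orthonormal Haar transform is applied, the `level` finest
   detail bands are zeroed (level 3 by default, i.e. averaging at the
   8-window / 24-kb scale), and the inverse transform is truncated back.

### Numerical choices in the smoother

Padding replicates the edge value rather than reflecting the sequence.
With edge padding, the once-smoothed series padded again is exactly the
block-constant series the first pass produced, so smoothing is idempotent
at a fixed level for any chromosome length; mirror reflection breaks that
property whenever the length is not a power of two (the dropped padded tail
then reflects into a different block). For non-power-of-two lengths the
truncation can still move the mean slightly, so the smoothed series is
rescaled — multiplicatively when both means are positive, additively
otherwise — to preserve the per-chromosome unmasked mean to within 1e-6
relative. Chromosomes with fewer than `2^level` unmasked windows are
returned unchanged with a warning. With masked windows present, the
interpolation bridge means exact idempotence is not guaranteed (bridged
values differ between passes); the mean-preservation guarantee still holds.

## Calling RATs

`call_rats()` implements the calling chain on the per-window differences
(DRT = endocycle − mitotic, per fraction):

* **Thresholds** (`difference_thresholds`). Per fraction, the maximum
  positive and maximum negative window differences are computed per
  chromosome and averaged across chromosomes; their difference is the
  total range, and the calling thresholds are 10% and 25% of it.
  Thresholds are computed per fraction rather than pooled: the procedure
  is defined per profile, and forcing a shared range would couple
  fractions with different dynamic ranges. A zero range disables seeding
  with a warning.
* **Compensation** (`flag_compensated_windows`). A window seeds at
  threshold t for fraction f when |d_f| ≥ t *and* the summed opposite-sign
  differences of the other two fractions reach t:
  Σ_g max(0, −sign(d_f)·d_g) ≥ t. Replication mass lost from one fraction
  must reappear in the others — the signature that distinguishes a genuine
  timing shift from a coverage artifact, which moves all fractions in the
  same direction and cancels nothing. The sum (rather than requiring a
  single compensating fraction, or per-fraction floors) reflects that
  compensation may be split across "one or both" other fractions. By
  default only E and L seed RATs; mid S contributes through compensation.
  A shift out of mid S alone manifests in the E and L differences anyway,
  and seed fractions are configurable.
* **Merging** (`merge_flagged`). Flagged windows within a 6-kb gap are
  merged (the gap absorbs small blacklist interruptions), separately at
  the 10% and 25% levels.
* **Core requirement** (`build_rats`). 10% regions overlapping or within
  the gap distance of a 25% region merge with it; 10% regions with no 25%
  core are discarded. The same 6-kb allowance is used at this second stage
  so that a core separated from its shoulder by a small blacklist gap is
  not orphaned. Requiring a 25% core filters out stand-alone tiny regions
  without an explicit size cutoff.
* **Direction** (`classify_direction`). S = Σ(d_L − d_E) over the region's
  unmasked windows; S > 0 is Earlier-to-Later, S < 0 Later-to-Earlier. An
  exact tie falls back to the sign of Σ d_M. This classifier is
  antisymmetric under swapping the two conditions, which the tests verify
  end to end.
* **Centromeres** (`annotate_cen`, `continuous_cen_size`). Earlier-to-Later
  RATs overlapping a functional centromere by ≥ 1 bp become
  Earlier-to-Later-CEN — partial overlap counts because called RATs often
  extend past annotated centromere boundaries (the outside portion is
  tracked as "presumed" centromeric coverage). Because blacklist windows
  fragment centromeric RATs, `continuous_cen_size` also reports an upper
  size estimate: centromeric RATs plus the blacklist intervals interspersed
  between them, trimmed to the outermost RAT boundaries.

## Region statistics

`shuffle_regions` places each region uniformly at random (chromosome chosen
proportionally to placeable length), wholly within a chromosome and clear
of the exclusion set; region count and the size multiset are preserved
exactly and shuffled regions may overlap one another, matching the default
behavior of the standard interval-shuffling tools. Only functional
centromeres are excluded by default — not blacklist — since that is the
stated exclusion in the procedure this mirrors; anything else can be passed
in `exclude`. `permutation_test` reports both tails with the convention
P = max(k, 1)/n, whose floor 1/n (0.001 at n = 1000) is the value reported
for fully extreme observations. Feature-level summaries (`element_rt`)
include an element only if it covers at least half a window (1.5 kb by
default) of some single window, and average overlapped unmasked windows
unweighted, mirroring a merge-with-mean over window rows.

## Copy-number screening

`window_frequency` converts 5-kb counts to depth-invariant normalized
frequencies (mean 1); `ratio_screen` forms higher-/lower-ploidy ratios on
windows with a positive denominator, flags values outside mean ± 2 SD, and
classifies outliers as low-coverage (denominator raw count below the 2.5th
percentile of positive counts, echoing the blacklist logic), runs
(adjacent outliers — the signature of a real copy-number difference), or
singletons. `screen_report` only states "no evidence of over/under-
replication" when no runs exist. Note the per-window ratio of two
count-derived frequencies has expectation slightly above 1 (Jensen's
inequality contributes ≈ 1/λ at λ reads per window) and its ±2 SD outlier
fraction lies a little below the Gaussian 4.55% tail mass at moderate
depth, approaching it as depth grows; the tests assert exactly this
behavior.

## ChIP enrichment and the redeposition model

`region_enrichment` is the percent of total ChIP reads in a region divided
by the percent of total input reads there; over the whole genome it is
exactly 1. Enrichment ratios across ploidies are summarized by
`ploidy_ratios`, with uncertainty from a seeded bootstrap over replicate
values because replicates are not paired across ploidies (separate sorts).
The dilution model (`expected_ratio`) says each replication round doubles
DNA while the centromeric histone complement carries over, and a fraction
f of the deficit is redeposited: enrichment multiplies by (1 + f)/2 per
round — 0.5 per round with no redeposition, 1 with full replacement.
`infer_redeposition` inverts the one-round model, clipping to [0, 1] with
a flag. The model estimates a population-average f; it cannot distinguish
partial replacement in all nuclei from full replacement in a subset.

## The synthetic data generator

Because the pipeline's calibration and recovery behavior must be testable
without external sequencing data, `simulate_study()` generates a complete
desk-scale experiment with known ground truth:

* **Genome**: 2 chromosomes × 30 Mb, 3-kb windows (20,000 windows), one
  2-Mb centered centromere per chromosome with ±1 Mb pericentromeric
  flanks, random gene islands and TE blocks, and window-aligned blacklist
  runs covering ≈ 4% of windows.
* **Timing**: per-window (pE, pM, pL) on the simplex, from a spatially
  autocorrelated Gaussian field passed through a softmax. Injected RATs
  (default eight per chromosome, 30–150 kb, alternating directions,
  0.6 mass shift) move probability mass between fractions — never create
  it — so every injected shift is compensated by construction, which is
  exactly the structure the caller assumes. Centromeres receive a
  mid-to-late template shift of 0.5. Regions destined to shift are biased
  toward their source fraction in the baseline so the transfer is feasible;
  residual per-window clipping is recorded in the truth object.
* **Counts**: negative-binomial (dispersion 0.05) around means proportional
  to mappability × timing mass, with lognormal per-window mappability
  multipliers shared between conditions and the 2C reference (blacklist
  windows get ≈ 2% mappability so they land in the reference's lower
  tail). Defaults: 2 × 10⁶ expected reads per fraction sample, 3
  replicates — minutes-scale on one core, yet deep enough that replicate
  correlations and rank recovery sit in the regime the QC checks expect.

What the generator does *not* emulate: base-pair-level reads, GC bias,
fraction-sorting impurity (a gate-bleed parameter could be added; the
effective default is zero), chromosome-scale timing gradients, and the
fine repeat structure of real centromeres. Passing recovery tests
(recall/precision ≥ 0.9 at 50% length overlap on the default genome)
therefore demonstrate the *procedure's* correctness under its own model
assumptions, not performance on real maize data.

## Problem sizes and determinism

The test suite and acceptance script use: the 2 × 30 Mb default study for
end-to-end recovery; 100,000 windows for the blacklist and copy-number
calibrations; 1,000 permutations for the P-value floor; 200 null datasets
× 20 permutations for super-uniformity; and 1,000 random instances for the
merge oracle. All randomness flows from one integer seed through named
per-stage substreams (`stage_seed`), so identical configuration and inputs
give byte-identical outputs.

## Known limitations

* The caller is threshold-based, not inferential: no per-RAT significance
  is attached, matching the procedure it implements.
* Per-fraction thresholds derived from chromosome extremes are sensitive
  to single extreme windows on small genomes; the per-chromosome averaging
  damps but does not remove this.
* The continuous centromere size is an upper estimate and cannot account
  for assembly gaps of unknown size.
* `element_rt`'s unweighted window mean slightly favors windows barely
  overlapped by long elements; this mirrors the merge-with-mean operation
  it reproduces.
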