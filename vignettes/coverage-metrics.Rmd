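---
title: "Cohort coverage metrics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cohort coverage metrics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exomecov)
```

# The problem

Exome capture enriches sequencing libraries for coding regions with
hybridization probes. The resulting read depth is far from uniform: probe
layout, GC content, repeats and segmental duplications leave some exons
thinly covered in every sample of a cohort, and others covered in an erratic,
spiky pattern. Both failure modes matter clinically — a variant in a
sub-10X stretch is effectively invisible to callers — and both are
properties of the *cohort*, not of one library. `exomecov` quantifies them
with two complementary per-region statistics computed from per-base depth
files.

# The two metrics

## Cohort Coverage Sparseness (CCS)

For a region of length $L_R$, sample $s$ has deficient-base fraction
$f_s = \#\{i : c_{i,s} < t\} / L_R$, where $c_{i,s}$ is the read depth at
base $i$ and $t$ is the deficiency cutoff (default 10 reads, strict `<`; a
base at exactly 10X is adequate). The region's score is the cohort median
$\mathrm{CCS} = \mathrm{median}_N(f_s)$. The median over samples makes the
score robust to a few outlier libraries while still demanding that coverage
problems recur across the cohort: CCS measures *systematic* sparseness, and
deliberately misses regions that are low in only a minority of samples.

Conventions pinned here: the median of an even cohort is the midpoint of the
two central order statistics; a gene's CCS pools deficient-base counts over
all its exonic bases (denominator = total exonic length) rather than
averaging per-exon scores, because the definition applies to an arbitrary
region of interest and a gene's region of interest is its exonic base set —
an exon-median aggregation is available as an option. Classification uses
strict thresholds: adequate (CCS ≤ 0.2), low (0.2 < CCS ≤ 0.5), severe
(CCS > 0.5).

## Unevenness (U_E)

Sparseness says nothing about *shape*. U_E scores how peaky the coverage of
a region is:

1. **Median profile.** The per-position median across samples (midpoint
   convention) summarizes the cohort while damping single-sample artifacts.
2. **LOWESS smoothing.** Locally weighted degree-1 regression at every base,
   with a *proportional* span: the window is the `max(ceiling(span * L_R), 4)`
   nearest positions (default span 0.03), tricube weights, no robustness
   iterations, distance ties broken toward the lower index. A proportional
   span keeps small peaks visible in short exons while smoothing equally
   small wiggles away in long ones, which is what makes summing over *all*
   detected peaks defensible.
3. **Hill-climbing extrema.** A scan over positions marks local maxima
   (peaks) and minima (troughs). Runs of equal values (plateaus) collapse to
   a single candidate at the floored center and classify by the values
   flanking the run.
4. **Peak geometry and score.** For each peak with apex height $H$ (absolute
   smoothed coverage), base $B$ (mean of the two flanking trough values,
   floored at 0.5 reads) and width $W$ (bp between the flanking troughs,
   falling back to the region endpoints),
   $$U_E = \sum_{\text{peaks}} \frac{H/B}{W/L_R},$$
   reported as `max(., 1)`; a region with no peaks scores exactly 1.

$H$ and $B$ are absolute coverage levels, so scaling every sample's depth by
a constant (a library-size change) leaves $H/B$ — and hence U_E — unchanged.
When a trough drops to zero while the surrounding coverage scales, $H/B$
grows instead: less even coverage scores higher, which is the intended
asymmetry.

# Numerical and boundary choices

These points are underdetermined by the score definitions; the package pins
one deterministic rule for each.

- **Peak base floor.** $B$ is floored at 0.5 reads (half the smallest
  countable depth) so $H/B$ stays finite over zero-coverage troughs. The
  floor is configurable (`b_floor`).
- **Endpoints.** The first and last positions of a region are eligible as
  troughs (they delimit the outermost peak bases) but never as peaks: a
  strictly monotone edge is a capture roll-off, not a peak. An
  endpoint-*touching plateau* whose collapsed center is an interior
  position, however, does count as a peak — a coverage shelf that then
  collapses into a hole is real unevenness. Without this distinction a
  zero-coverage trough punched into an otherwise flat region would create no
  peaks at all and U_E would stay 1, violating the dropout-sensitivity
  property above.
- **Plateau tolerance.** Plateau runs are grouped with a relative tolerance
  of $10^{-8}$ of the profile maximum. Local fits on an exactly flat stretch
  carry ~$10^{-14}$ arithmetic jitter; exact-equality grouping would split
  such a stretch into spurious micro-extrema whose tiny widths dominate the
  score.
- **Short regions.** Regions shorter than 4 bp keep their CCS (well-defined
  at any length) but are skipped for U_E with a warning — a smoothed curve
  over 2–3 points has no usable geometry.
- **Trough extent.** For repeat concordance, a trough's extent is the
  maximal contiguous run of smoothed median strictly below 10X around the
  detected trough position (region edges below 10X included); overlap with a
  repeat interval requires ≥ 1 bp.
- **Friedman statistic.** The cross-platform test uses the plain
  average-rank Friedman statistic without tie correction, so a fully tied
  matrix scores 0 instead of the 0/0 the corrected form produces; the
  p-value uses the $\chi^2_{K-1}$ approximation. The chromosome-distribution
  test is Pearson's chi-square without continuity correction.

# Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `deficiency_cutoff` | 10 | reads | per-base deficiency for CCS (strict `<`) |
| `qc_min_depth` | 75 | reads | minimum mean target depth per sample (inclusive) |
| `ccs_cuts` | 0.2, 0.5 | — | low / severe class cuts (strict `>`) |
| `span` | 0.03 | fraction of $L_R$ | LOWESS window as a share of region length |
| `b_floor` | 0.5 | reads | lower bound on the peak base $B$ |
| `min_length` | 4 | bp | smallest region scored for U_E |
| `length_cut` | 400 | bp | exon-length filter for the Friedman comparison |

All defaults are the values the metrics were designed around; every one is
overridable in `coverage_qa()` and the CLI.

# Annotation and input conventions

All interval I/O is BED-convention 0-based half-open; per-base depth files
are 1-based (both BEDTools per-base dialects are supported, with the
`coverage -d` offset interpreted relative to the region start). Conversion
happens only at I/O boundaries. Overlapping exons of the same gene are
merged into maximal disjoint intervals before scoring; capture targets
restrict and fragment the catalog; only autosomes (1–22) are analyzed. Gene
identity is the case-sensitive symbol. Strand is carried but ignored — depth
is unstranded. Bases listed in a depth file but outside the catalog are
ignored; catalog bases absent from the file are depth 0, *not* missing: an
uncaptured base is the strongest form of low coverage, and treating it as NA
would silently inflate coverage estimates. Only the catalog∩target base set
is scored; capture-target bases outside any annotated exon are not (the
alternative — scoring all target bases — can be had by passing the targets
file as the transcript input).

# The simulator

`simulate_cohort()` generates per-base depths as
`round(mean_depth × bump × dropout × GC multipliers)` with optional Poisson
or negative-binomial (mean $\mu$, variance $\mu + \mu^2/k$) sampling noise,
one RNG substream per sample (`seed + sample index`) for byte-level
reproducibility. Bumps are raised-cosine multiplier profiles (center, width,
apex amplitude); dropouts multiply a half-open sub-interval by a factor in
[0, 1]; GC bias applies a user-supplied monotone response to per-region GC.
Defaults (5 samples, 50X mean, ~120–400 bp exons) reflect a small
well-powered WES cohort: 50X is a typical clinical exome mean and 120–400 bp
spans most coding exons.

What it emulates: planted coverage holes (CCS recovers the dropout fraction
exactly without noise and within binomial error under Poisson noise),
planted peaks (U_E is strictly monotone in bump amplitude), GC-dependent
depth, and repeat-coincident troughs. What it does not emulate: correlated
probe-level biases across samples, mappability artifacts, fragment-length
effects, batch structure, or duplicate-read dynamics. Passing tests on
simulated cohorts therefore validate the *computations*, not the biological
calibration of the thresholds on any particular platform.

A note on noisy U_E values: with a 3% span, a 300 bp exon is smoothed over
~9 bp windows, so per-base sampling noise in the median profile survives as
many narrow peaks and U_E values in the hundreds are normal for noisy
simulated cohorts (real single exons reach the 70–140 range). U_E is a
relative, within-design comparison metric; its absolute scale depends
strongly on region length and noise. This is also why the length–U_E
correlation is strong for deterministic planted structure but attenuated
under heavy per-base noise.

# Problem sizes in the test bench

The suite exercises exhaustive extremum-detection equivalence on every curve
of length ≤ 12 over three depth levels (~800k curves), LOWESS equivalence
against an independent per-point weighted-least-squares reference on
500-point profiles, dropout recovery over 20 replicate cohorts per planted
fraction, and end-to-end byte-determinism of the simulate→score pipeline;
cohorts in tests are 3–9 samples over regions of 100–1000 bp. These sizes
were chosen to give exact or tight-tolerance checks on every code path while
keeping the suite comfortably fast on one CPU.

# Known limitations

- Both metrics are blind to coverage that is *consistently* low across every
  sample only in the sense intended — CCS flags it, but U_E does not
  distinguish a uniformly low region (U_E = 1) from a uniformly high one.
- The exact peak-geometry conventions (mean-of-flanks base, trough-to-trough
  width, endpoint rules) are pinned choices among several defensible ones;
  absolute U_E values are comparable only within one convention.
- Regions absent from the capture design entirely are invisible: the catalog
  defines the measurement universe.
- The chi-square and Friedman tests inherit their usual small-count and
  small-block caveats; the package flags expected counts below 1 rather than
  refusing to test.
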