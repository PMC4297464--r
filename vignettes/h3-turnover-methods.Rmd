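---
title: "Methods: estimating histone H3.3 turnover from TET-OFF ChIP-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating histone H3.3 turnover from TET-OFF ChIP-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(h3turnover)
```

## The measurement and its model

In a TET-OFF pulse-chase, synthesis of epitope-tagged H3.3 is repressed
with doxycycline, so the tagged ChIP-seq signal at any locus can only
decline as previously incorporated histones leave chromatin. Under
first-order kinetics the tagged occupancy obeys

$$N(t) = N(0)\, e^{-\lambda t},$$

with $\lambda$ in h$^{-1}$ the local dissociation rate. The package
estimates $\lambda$ per genomic window from the count change between 0 h
and 6 h after shut-off. Two timepoints close to shut-off are the most
informative choice for rate estimation: later timepoints (12–48 h) are
increasingly contaminated by dilution through replication and by the
depletion of fast-exchanging loci, so the estimator deliberately uses
only the 0 h → 6 h pair and later libraries are treated as optional
plotting material, not part of the fit.

Key assumptions:

* decay is first-order and locus-autonomous over the 6 h interval;
* the 0 h and 6 h libraries sample the same chromatin population, so the
  genome-wide count decline between them *is* the decay signal — the two
  ChIP libraries are therefore **not** rescaled to a common depth by
  default (`normalize_counts()` exists for libraries sequenced to
  deliberately different depths);
* input DNA coverage is locus-independent up to noise, so input counts
  calibrate both the enrichment test and the equilibrium level.

## From reads to windowed dyad counts

A read is stored as (chromosome, 5′ position, strand). `extend_reads()`
extends it to 150 bp — a nucleosome footprint — in the alignment
direction, clipped at chromosome ends; `dyad_positions()` reduces the
extension to its floor midpoint. The dyad is the counting unit: a
plus-strand read at $p$ and a minus-strand read at $p+149$ describe the
same nucleosome and receive the same dyad. `count_dyads()` accumulates
dyads into a window grid; windows tile each chromosome from coordinate 0
and the last partial window is kept. All coordinates are 0-based,
half-open (BED convention), and all I/O is plain text (BED6, bedGraph,
TSV).

Counts on the 250-bp analysis grid are smoothed with `lowpass_filter()`:
the window itself weighted 1, each neighbour 0.5, divided by the sum of
in-bounds weights (2 in the interior, 1.5 at chromosome ends, 1 for a
single-window chromosome). Dividing by the weight sum makes the filter
average-preserving — a constant track passes through unchanged and
interior totals are conserved — and the edge rule avoids attenuating
terminal windows.

## The analysis universe

Rates are only meaningful where tagged H3.3 is actually present at 0 h.
`call_enriched()` defines this universe: for each window the input count
is scaled by the ratio of library sizes (floored at a pseudocount of
0.5 to guard empty input windows), the ChIP count is tested against the
Poisson upper tail of that expectation, p-values are controlled by
Benjamini–Hochberg at FDR 0.05, and a fold-change filter (≥ 2 over the
scaled expectation) removes statistically significant but biologically
trivial excesses. All four knobs (`alpha`, `min_fold`, `pseudocount`,
window width) are arguments. The test is a deliberate minimal model for
count enrichment; it ignores local input variability beyond scaling, so
with very deep libraries the fold filter does most of the work.

## Rate and equilibrium estimators

For a window with filtered counts $n_0$ and $n_6$ and pseudocount
$\varepsilon = 0.5$ (Haldane–Anscombe convention, configurable):

* raw rate: $\lambda_\text{raw} = \ln\!\big((n_0+\varepsilon)/(n_6+\varepsilon)\big) / \Delta t$,
  $\Delta t = 6$ h; negative when counts rise;
* scaled rate:
  $\lambda_\text{out} = (n_0+\varepsilon) / \big((n_0+\varepsilon)+(n_6+\varepsilon)\big)$,
  which is algebraically the logistic transform
  $1/(1+e^{-\lambda_\text{raw}\Delta t})$ — the identity is enforced to
  $10^{-12}$ in the test suite. The scale maps any count pair into
  $[0,1]$: 0.5 means no net change, 1 complete dissociation. The
  logistic form is this package's interpretation of a "scale to
  $[0,1]$" requirement: it is the logistic of the log count ratio,
  reduces to 0.5 at equilibrium and is monotone decreasing in $n_6$;
* equilibrium level:
  $\lambda_\text{equ} = \log_2\!\big((n_0+\varepsilon)/(i_0+\varepsilon)\big)$
  with the input count $i_0$ scaled to the 0 h ChIP library size. The
  log2 scale is the field's standard for enrichment ratios; a
  linear-ratio reading is `2^lambda_equ`.

`turnover_tracks()` applies all three per window inside the enrichment
mask (NA outside), and `turnover_track(..., resample = 10)` re-expresses
a 250-bp track on a 10-bp grid by midpoint lookup — the resolution used
for replicate-concordance analysis. Whether rates are computed on
filtered or raw counts is a user choice: the pipeline filters first
(smoothing stabilizes the ratio in sparse windows); passing unfiltered
tracks to `turnover_tracks()` gives the raw-count behaviour.

## Profiles, regions and feature contrasts

`profile_matrix()` averages a track in bins at fixed offsets around
anchor points (TSS, TES, peak midpoints), reversing rows of minus-strand
anchors so positive offsets always point downstream of transcription;
`mean_profile()` averages rows per group with per-bin counts of finite
contributions, and bins with no underlying windows stay missing rather
than zero. `region_summary()` reports the mean track value over all
windows within a fixed flank (default ±5 kb in the generic tool, ±1 kb
in the desk-scale pipeline) of each site midpoint, per feature set and
track — the numbers behind a rate/equilibrium heatmap.

Promoter-scale geometry needs finer windows than the genome-wide grid: a
250-bp window can never attribute a 50-bp nucleosome-depleted region
(NDR) to its own 50-bp bin, because every window that fully contains the
NDR carries the same mixture of NDR and flank counts. The pipeline
therefore computes a second rate track on a 50-bp counting grid (same
filter, enrichment test and estimator) purely for TSS metaprofiles,
while genome-wide rates stay on the 250-bp grid.

Feature classification is distance-based and strand-blind:
`classify_proximity()` calls a site proximal when its minimum gap
distance to any transcript span is ≤ 5,000 bp (inclusive; overlap is
distance 0), `classify_repeats()` uses the same rule at 2,000 bp for the
genic/non-genic split, and both accept an exon table for an exon-level
alternative to the full TSS–TES span. `tf_binding_overlap()` flags a
repeat as bound when it overlaps any peak by ≥ 1 bp (configurable) and
reports per-set and union ("any") bound fractions per repeat class; a
repeat hit by several factors counts once in the union.
`bin_expression()` stratifies transcripts at FPKM boundaries 1, 3, 10
and 30 with upper-inclusive intervals, chosen so the five verbal ranges
(silent < 1, low 1–3, medium 3–10, top20 10–30, top10 > 30) tile
$[0,\infty)$ without gaps.

## Statistics

`pearson_cor()`/`track_pearson()` wrap the product-moment correlation
with a two-sided $t$ p-value on $n-2$ degrees of freedom, restricted to
windows finite in both tracks (i.e. enriched in both replicates for
concordance — intersection, not union, defines that universe).
`chisq_2x2()` is the raw Pearson chi-square on a 2×2 table without
continuity correction: at the element counts where such contrasts are
interesting the statistic is orders of magnitude beyond the correction
scale, and the uncorrected form matches hand computation exactly.
p-values are reported to floating-point underflow and printed as
`< 1e-300` beyond it. Multiple-testing correction is applied inside the
enrichment caller only; headline correlations are reported unadjusted.

## The synthetic generator: what it emulates, and what not

`build_annotation()` lays out non-overlapping loci of seven archetypes —
promoter NDR, TSS flank (both the first 300 bp of the transcript and the
−1-nucleosome territory 100–450 bp upstream), gene body, heterochromatin
block, distal regulatory site, satellite repeat, diffuse background —
and assigns each a decay rate from its archetype's range and a 0 h
occupancy. Defaults encode the qualitative regime ordering that motivates
the analysis: NDR (0.2–0.5 h⁻¹) > satellite (0.15–0.4) > distal site
(0.12–0.3) > TSS flank (0.06–0.15) > gene body (0.02–0.08) >
heterochromatin (0–0.02). Occupancies are densities (dyads per 100 bp),
so wide heterochromatin domains attain input enrichment just as narrow
promoter elements do, and each NDR is placed 50–100 bp upstream of its
transcript's TSS so promoter geometry is recoverable. A positive
`equ_coupling` (default 2) makes fast loci more enriched at 0 h,
emulating the coupling between deposition and eviction at active
elements; setting it to 0 decouples rate from equilibrium, which the
test suite uses to verify the correlation statistic reflects simulated
coupling rather than an artifact.

`simulate_reads()` draws per-locus, per-timepoint counts as Poisson with
mean $\text{occupancy}_0 \cdot \text{depth} \cdot e^{-\lambda t}$ —
the standard count-sampling model for ChIP-seq, since no noise model is
dictated by the measurement itself — with uniform read placement such
that the extended read's dyad falls inside the locus
(`position_mode = "fragment"`). This emulates sequencing the ends of
nucleosome-sized fragments, so downstream extension recovers occupancy
at the locus; the alternative `"uniform5p"` places raw 5′ ends uniformly
and smears dyads up to 75 bp past locus edges. Input libraries are
uniform over the genome; replicates use distinct deterministic
sub-seeds of one master seed, and identical (parameters, seed) give
byte-identical output.

Deliberately **not** modelled: sequencing error and FASTQ emission, PCR
duplicates, mappability and chromatin-accessibility bias in input, and
replication-coupled dilution. Passing tests on this generator therefore
demonstrates that the estimators recover known rates under Poisson
sampling and realistic genomic geometry — not that real libraries are
free of the biases above.

## Numerical and design choices

* Pseudocount ε = 0.5 everywhere a ratio of counts is formed; the
  closed-form recovery checks use a vanishing ε because noiseless
  expectation counts need no guard.
* Degenerate inputs fail loudly: zero-variance tracks cannot be
  standardized or correlated, zero-margin tables have no chi-square,
  zero-library tracks cannot be normalized, and a synthetic genome too
  small for the requested loci raises a capacity error before anything
  is written.
* Window grids keep the last partial window; dyads use floor midpoints;
  interval anchors use floor midpoints; distance cutoffs are inclusive.
  Ties in profile argmax positions are broken by the first (most
  upstream) bin, which only matters for exactly flat peaks.
* Desk-scale problem sizes: the default synthetic study uses two
  chromosomes totalling 350 kb, 30 genes, ~170 loci, sequencing depth 2
  and two replicates; recovery checks use 2,000 uniform loci at ~100
  reads each and concordance checks 400 loci at two depths. These sizes
  were chosen so the full suite and the acceptance script each run in
  well under a minute while leaving all statistical contrasts
  comfortably powered.

## Known limitations

* Rates come strictly from the 0 h → 6 h pair; multi-timepoint
  regression over 12–48 h and TET-ON incorporation-rate estimation are
  out of scope.
* The enrichment caller's uniform-input assumption understates local
  input structure; with real data, supplying a matched input of adequate
  depth matters more than the choice of `alpha`.
* The logistic scaling interpretation, while uniquely consistent with
  the stated [0,1] range and equilibrium behaviour, cannot be
  cross-checked against an external reference implementation.
* `region_summary()` averages fixed flanks around site midpoints;
  windows shared by nearby sites contribute once per site, so dense
  feature sets blur into their neighbourhoods.
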