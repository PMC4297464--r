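# h3turnover

Genome-wide estimation of histone H3.3 **dissociation rates** and
**equilibrium enrichment levels** from TET-OFF time-course ChIP-seq.

## The problem

H3.3 is the replication-independent H3 variant: it is deposited at
promoters, enhancers, gene bodies and some repeat elements throughout the
cell cycle, and how fast it *leaves* chromatin is a direct readout of
local nucleosome dynamics. In a TET-OFF pulse-chase design, epitope-tagged
H3.3 expression is shut off with doxycycline and the tagged ChIP-seq
signal decays locus by locus. This package turns the aligned reads of
such a time course into per-window decay rates, and provides everything
around that estimate: enrichment masking against input, strand-aware
metaprofiles, proximal/distal and genic/non-genic feature contrasts,
repeat-element transcription-factor enrichment statistics, and a
synthetic simulator with known ground truth so that every stage can be
validated by parameter recovery.

## The model

Reads are extended to 150 bp from their 5′ end; each extended read is
reduced to its **dyad** (floor midpoint) and counted into 250-bp windows,
which are smoothed with a weighted low-pass filter (center weight 1,
neighbours 0.5, divided by the in-bounds weight sum). Windows
significantly enriched over input at 0 h (Poisson upper tail,
Benjamini–Hochberg FDR ≤ 0.05, fold ≥ 2) form the analysis universe.
Within it, tagged-H3.3 occupancy decays exponentially,

    N(t) = N(0) · exp(−λ t),

so the raw rate from the 0 h → 6 h count change is
`λ_raw = ln((n0+ε)/(n6+ε)) / Δt` (ε = 0.5 pseudocount, Δt = 6 h). Rates
are reported on the logistic scale

    λ_out = (n0+ε) / ((n0+ε) + (n6+ε)) = 1 / (1 + exp(−λ_raw · Δt)) ∈ [0, 1],

where 0.5 means no net change and values above 0.5 net loss. Equilibrium
levels are `λ_equ = log2((n0+ε)/(i0+ε))` against the depth-scaled input.

## Worked example

Simulate a small TET-OFF study with known per-locus rates and estimate
them back:

```r
library(h3turnover)

cs   <- chrom_sizes(c("chrS1", "chrS2"), c(2e5, 1.5e5))
ann  <- build_annotation(cs, synth_params(), seed = 42)
sim  <- simulate_reads(ann$truth, depth = 2, n_replicates = 2, seed = 42)

grid  <- window_grid(cs, width = 250)
c0    <- lowpass_filter(count_dyads(get_library(sim, 0, 1), grid))
c6    <- lowpass_filter(count_dyads(get_library(sim, 6, 1), grid))
input <- lowpass_filter(count_dyads(get_library(sim, NA, 1), grid))

calls <- call_enriched(c0, input, alpha = 0.05, min_fold = 2)
est   <- turnover_tracks(c0, c6, input, calls, dt = 6, eps = 0.5)
glance(est)
#> # A tibble: 1 × 5
#>   n_windows n_enriched mean_lambda_out mean_lambda_raw mean_lambda_equ
#>       <int>      <int>           <dbl>           <dbl>           <dbl>
#> 1      1400        281           0.715           0.165            1.69
```

1,400 windows tile the two synthetic chromosomes; 281 pass the
enrichment mask, and their mean scaled dissociation rate is 0.72 (net
loss of tagged H3.3 over 6 h, as expected after shut-off). Per-window
estimates are a tidy table:

```r
head(tidy(est), 3)
#>   chrom start   end    n0    n6 lambda_raw lambda_out lambda_equ
#> 1 chrS1  3750  4000  99.2  80       0.0357      0.553       1.66
#> 2 chrS1  4000  4250 124.  105.      0.0283      0.542       1.78
#> 3 chrS1  4250  4500  91.8  82.5     0.0176      0.526       1.40
```

Dissociation rates and equilibrium levels are positively coupled in the
generator, and the estimates recover that:

```r
track_pearson(turnover_track(est, "lambda_out"),
              turnover_track(est, "lambda_equ"))
#> Pearson product-moment correlation: r = 0.3040 (n = 281, df = 279, p = 2.03e-07)
```

`run_pipeline(out_dir, config = list(seed = 1))` drives the whole
analysis — simulate, count, filter, enrich, rates, classify, profiles,
statistics — writing bedGraph tracks, tidy report tables and a JSON
manifest. `autoplot()` methods exist for profile curves, region
summaries and replicate-concordance densities, and `plot_recovery()`
shows estimated versus true rates.

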