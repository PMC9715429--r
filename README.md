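# foramshift

Quantifying how marine microplankton communities reorganised from the last
ice age to the present.

`foramshift` is an R package for analysing millennial-scale time series of
planktonic foraminifera census data — sample-by-species tables with site,
latitude and calibrated age (kyr BP, 0 ka = 1950 CE) metadata. It asks, for
a collection of sediment-core records spanning a latitudinal gradient and
the past ~24 kyr:

* **How did assemblage composition change in space and time?**
  Morisita–Horn (M–H) dissimilarity between all sample pairs,

  `C = 1 − 2 Σ xᵢyᵢ / (Σ xᵢ² + Σ yᵢ²)`,

  with `xᵢ`, `yᵢ` the relative abundances of species *i* (0 = identical,
  1 = no shared species), reduced by PCA and visualised as RGB colours on a
  1 kyr × 2.5° latitude (Hovmöller) grid.
* **How coherent was the change?** Per-site PCA of the composition matrix,
  PC1 polarity aligned across sites by linear-model slope, interpolated to
  a 0.5 kyr grid on the common 2.5–23 ka window, and stacked with a LOESS
  smoother for comparison against a temperature forcing curve.
* **Who came and who left?** Identity-aware species gains and losses
  relative to the oldest sample of each series, normalised by the pooled
  species set, and their linear rates of change (slope vs time toward the
  present).
* **Did novel communities emerge?** Distance to the nearest analogue in a
  Last Glacial Maximum (LGM, 19–23 ka) reference compilation, judged
  against a self-referential null: the 95th/99th percentiles of
  nearest (and 2nd-/3rd-nearest) non-self analogue distances *within* the
  reference. Samples beyond the threshold have no glacial analogue.
* **How did the latitudinal diversity gradient (LDG) evolve?** Richness
  and Shannon entropy `H = −Σ pᵢ log pᵢ` per sample, per-millennium LOESS
  gradients against latitude, and anomalies relative to each site's LGM
  mean.

Real census data (counts or percentages) are read from plain CSV/TSV with a
harmonized 41-species taxonomy; a bundled synthetic generator —
temperature-controlled Gaussian niches, multinomial count noise, a
glacial–deglacial–Holocene forcing with optional Heinrich-like cooling and
an optional Holocene-only "secondary driver" that creates genuinely novel
compositions — produces data with the same schema and a ground-truth record
for method validation.

## Worked example

```r
library(foramshift)

# the M-H index on two half-overlapping assemblages
morisita_horn(c(0.5, 0.5, 0), c(0.5, 0, 0.5))
#> [1] 0.5

# a synthetic study: 25 sites, 0-24 ka, no-analogue driver on after 11 ka
ds <- simulate_dataset(synthetic_config(secondary_driver = TRUE), seed = 42)
ds$reference
#> Reference set: 415 samples from 85 sites, window 19 - 23 ka

# null thresholds from within-reference analogue distances
thr <- null_thresholds(ds$reference, percentiles = c(95, 99), ranks = 1:3)
round(unclass(thr), 4)
#>      rank1  rank2  rank3
#> p95 0.0303 0.0325 0.0365
#> p99 0.0379 0.0399 0.0435

# classify every sample against the 99th-percentile nearest-analogue null
cls <- classify_no_analogue(ds$samples, ds$reference,
                            threshold = thr["p99", "rank1"])
table(flagged = cls$samples$no_analogue, holocene = cls$samples$age_ka < 11)
#>        holocene
#> flagged FALSE TRUE
#>   FALSE   545  307
#>   TRUE      5  168
```

The thresholds say: within the glacial reference, 99% of samples find a
nearest analogue closer than ≈0.038, so larger distances are unlikely by
chance. Almost all flagged samples (168 of 173) post-date 11 ka — the
detector recovers the Holocene emergence of no-analogue assemblages that
the generator imposed at mid-latitude sites, with glacial-age false alarms
at roughly the nominal 1% rate.

```r
# rates of biodiversity change per site (species / kyr, proportion / kyr)
rates <- rates_table(ds$samples)
round(colMeans(rates[, 3:5]), 4)
#> richness_rate    gains_rate   losses_rate
#>       -0.0020        0.0082        0.0073
```

The whole chain — simulate/load, dissimilarity + RGB grid, trends, rates,
no-analogue detection, LDG — runs from one configuration:

```r
run_pipeline(default_run_config(), "out/")   # writes CSVs + manifest.json
```

or from the shell via `Rscript inst/scripts/foramshift.R all --config run.yaml`.

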