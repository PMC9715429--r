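---
title: "Methods: compositional change, no-analogue detection and diversity gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compositional change, no-analogue detection and diversity gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foramshift)
```

## The analysis model

`foramshift` treats a paleoecological dataset as a collection of site time
series of census samples. Each sample is a vector of abundances over a
harmonized taxonomy of 41 planktonic foraminifera species, with site,
latitude, longitude and calibrated age (kyr BP; 0 ka = 1950 CE) metadata.
Two merge rules are applied on input: the *Globigerinoides ruber*
morphotypes (ruber/albus) are pooled, and P/D intergrades are pooled with
*Neogloboquadrina incompta*; species not reported by a record are taken as
absent (zero abundance). All downstream statistics operate on relative
abundances.

Five analyses are built on this container.

**Compositional dissimilarity.** The Morisita–Horn index
$C = 1 - 2\sum_i x_i y_i / (\sum_i x_i^2 + \sum_i y_i^2)$ on relative
abundances $x_i, y_i$. It is 0 for identical compositions, 1 for disjoint
species sets, and comparatively robust to uneven census sizes, which makes
it suitable for heterogeneous core-top and down-core data. The full
pairwise matrix is reduced by PCA — each sample's row of dissimilarities
is taken as its feature vector, column-centred, and decomposed without
unit-variance scaling. This "PCA on the dissimilarity matrix" reading is
deliberate; classical PCoA (double-centred eigendecomposition) is a
different operator and is not silently substituted. One consequence worth
knowing: a perfectly one-dimensional compositional gradient does not map
to a rank-1 distance-row configuration — the rows are a quadratic image of
the gradient (the familiar arch), so the gradient appears as a dominant
first axis (~85% in our tests) plus a small arch axis, rather than as a
single axis with ~100%. The first three axes are mapped to colour channels
(axis 1 → blue, axis 2 → red, axis 3 → green, each min–max rescaled over
the full sample set) and aggregated onto a Hovmöller grid.

**Per-site trends.** Per-site PCA of the relative-abundance matrix
(covariance-based; abundance columns share a scale, so no rescaling), PC1
extracted with its variance fraction. PCA sign is arbitrary, so polarities
are aligned by fitting `score ~ age` and negating sites with positive
slope; the convention is scores increasing toward the present. Scores are
linearly interpolated to a 0.5 kyr grid restricted to the 2.5–23 ka window
covered by all series (avoiding edge effects), pooled, and smoothed by
LOESS (span 0.75, degree 2 — the conventional defaults, pinned because
"standard settings" is otherwise ambiguous) with a 95% pointwise band from
the smoother's standard errors under approximate normality. A bootstrap
band was considered and not implemented; the pointwise band is what the
stacked display needs.

**Gains and losses.** Against the oldest sample of each series, gains are
the proportion of species present now but absent then, losses the reverse,
both normalised by the pooled species richness of the pair; presence is
strictly positive abundance (a single individual counts; an optional
minimum-proportion threshold exists for sensitivity analysis, default
off). The integer identity
`richness(sample) − richness(baseline) = (gains − losses) × union`
holds exactly and is enforced in tests. Rates are unweighted OLS slopes
against time-toward-present (−age), so positive = increase through time.
Note the intended asymmetry: the gains/losses baseline is the single
oldest sample, while diversity anomalies (below) use the 19–23 ka mean —
both conventions are used where they belong.

**No-analogue detection.** Each sample's M–H distance to every member of
an LGM (19–23 ka, closed interval) reference compilation; the detection
threshold is self-referential — the 95th/99th percentile (linear
interpolation between order statistics, `quantile` type 7) of
within-reference non-self nearest (and 2nd-/3rd-nearest) analogue
distances. Classification is strict (`distance > threshold`); a sample that
is itself a reference member is excluded from its own search by the
`(site, age)` identity key, the same key used to deduplicate samples
present in both the series and the external compilation.

**Latitudinal diversity gradient.** Richness and Shannon entropy
$H = -\sum p_i \log p_i$ in nats (natural log; a base flag converts),
computed directly on relative abundances — no rarefaction or coverage
correction, since the entropy is applied to $p_i$ as given. Samples are
pooled in left-closed millennial bins `[k, k+1)` anchored at 0 ka (the
same convention as the Hovmöller time axis, so a sample at exactly 3.0 ka
joins `[3,4)`), LOESS curves of metric vs latitude are fitted per
millennium (unweighted), and per-sample anomalies are referenced to each
site's LGM-window mean.

## The synthetic generator

The generator produces data with the statistical structure the analyses
assume, plus a ground-truth record for recovery tests. Its defaults define
the study conditions used throughout the test suite and the acceptance
script:

* **Sites**: 25, evenly spaced 2.5–62.5° N; modern SST declines linearly
  from ~27.5 °C to ~2.3 °C along the gradient.
* **Sampling**: ages `seq(0, 24, 0.6)` kyr — 41 censuses per site, the
  ~0.6 kyr median resolution typical of such records; census depth 300
  individuals (a typical micropaleontological count), multinomial noise.
* **Forcing**: global anomaly −6 °C at the glacial plateau (>17 ka), a
  smooth cosine deglacial ramp 17→11 ka, flat Holocene, referenced to the
  0–2 ka mean. Local SST = modern + scale × anomaly, with polar-amplified
  scale `1.5·lat/65`, plus an optional Heinrich-like −4 °C excursion at
  15–17 ka for sites at 40–55° N (on by default).
* **Niches**: 41 Gaussian thermal response curves (the standard
  species-response model, consistent with stable thermal niches), optima
  evenly spread over −4…30 °C, tolerance 3 °C, equal amplitudes.
* **Reference pool**: besides the in-window series samples, 60
  reference-only glacial sites (4 censuses each at 19.5–22.5 ka) emulate
  the spatially dense external LGM compilation; without that density the
  null thresholds would be dominated by same-site resampling and the
  detector would over-fire on spatial interpolation error rather than
  genuine novelty.
* **No-analogue mechanism**: a second environmental axis, zero before
  11 ka, ramping to 1 over 1 kyr, affecting sites at 30–50° N. Mid-thermal
  species carry alternating ±2 sensitivities to it, so Holocene
  mid-latitude compositions drift off the one-dimensional thermal manifold
  that the glacial reference spans — novelty arises from the mechanism,
  not from hard-coding the detector's answer.
* **Determinism**: one master seed; per-site streams derived from
  `(seed, site index)` so any series can be regenerated in isolation.

What the generator does *not* emulate: age-model uncertainty (ages are
exact), spatial autocorrelation beyond the latitudinal SST gradient,
dispersal limitation or response lags, taphonomic loss, and real niche
geometry (optima are evenly spaced by construction). Passing recovery
tests therefore demonstrates that the estimators recover what they claim
under multinomial noise and realistic design sizes — not that real
foraminifera obey Gaussian niches.

A separate calibration scenario, `simulate_richness_ramp()`, imposes a
linear true-richness trend (nested species sets, uniform proportions) for
rate-recovery checks.

## Numerical choices and edge cases

* Time windows are closed intervals `[min, max]` so window-edge samples
  (e.g. exactly 19 or 23 ka) are captured deterministically; grid and
  millennium bins are left-closed and anchored at 0.
* Percent-unit input must row-sum within [99, 101] and is renormalised;
  count input is normalised as-is; all-zero samples are hard errors.
* M–H values are clamped to [0, 1] against roundoff; "identical
  compositions" tests allow ~1e−12 noise.
* Polarity alignment treats a slope as zero when it is numerically zero
  relative to the data scale (an exactly-constant series yields ~1e−17
  from `lm`, never exact 0) and then warns rather than flips.
* PCA axes beyond the matrix rank are truncated with a warning; an
  all-identical sample set yields zero scores and zero variance fractions
  rather than an error.
* Grid cells without samples are absent from the output (missing, not
  zero), and per-cell counts must sum to the sample count.
* Unknown taxa are a hard error by default (protecting harmonization),
  with an explicit opt-in to warn-and-drop.

## Problem sizes

The shipped tests and the acceptance script use the default design (25 ×
41 samples; 415-sample reference), 20 replicate simulations for the
no-analogue precision/recall estimate, 100 series for rate recovery, and
1,000 randomized vector pairs for the M–H and gains/losses identities —
sizes at which every property is stable across seeds while the whole
suite completes in well under a minute.

## Known limitations

* The dissimilarity PCA is not a PCoA; ordination distances are not
  preserved isometrically, and strongly curved gradients produce arch
  axes (see above).
* LOESS confidence bands are pointwise and assume approximate normality
  of the smoother; they are display bands, not simultaneous inference.
* The no-analogue null is purely compositional: it inherits whatever
  spatial and temporal coverage the reference has, and a sparse reference
  inflates thresholds (conservative) while a dense one tightens them.
* No age-model propagation: ages are taken as given, and interpolation
  error near large sampling gaps is not modelled.
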