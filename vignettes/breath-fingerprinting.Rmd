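---
title: "Breath-metabolome fingerprinting: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breath-metabolome fingerprinting: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breathmap)
```

## The problem

Exhaled breath carries hundreds of volatile and semivolatile organic
compounds. Captured on a sorbent and run through headspace GC/MS, each
breath sample becomes a chromatogram: detector intensity against retention
time over a roughly 50-minute program. In rare diseases such as pulmonary
arterial hypertension (PAH), where no blood screening test exists, the hope
is that the *pattern* of these compounds — a breath fingerprint — separates
patient subgroups even when no single compound does.

`breathmap` implements a two-stage analysis of such cohorts:

1. **Peak detection.** Find each chromatogram's significant peaks, measure
   them (height, prominence, width, integration bounds, area,
   area/intensity ratio), and confirm them against lowpass wavelet
   approximations of the trace.
2. **Profiling and clustering.** Condense each sample to a fixed
   ten-feature profile, standardize, choose the number of clusters by the
   elbow criterion on a k-means inertia curve, and partition the cohort
   (spectral clustering by default; k-means, Ward agglomerative and DBSCAN
   behind the same interface). Clusters are then characterized by their
   unique compounds and covariate summaries.

Because raw clinical breath data are generally not public, the package
ships a synthetic-cohort generator with planted class structure; every
recovery claim in the test suite is made against that generator's ground
truth, not against clinical data.

## Stage one: peak detection

### Local maxima, prominence, and the significance filter

A peak is an interior grid point strictly above both neighbors; a plateau
flanked by strictly lower values counts once, at its leftmost index
(deterministic tie-break). Peaks are kept when they pass a significance
filter of 10,000 detector units — an experimentally established threshold
conventional for this instrument class.

The quantity compared against that filter deserves care. Raw peak *height*
shifts one-for-one with the baseline; topographic *prominence* — the height
above the higher of the two valley minima separating the peak from higher
terrain — is invariant to baseline level and matches the intuition of "how
much the peak stands out relative to its surroundings". `peak_params()`
therefore filters on prominence by default (`intensity_basis =
"prominence"`), with `"height"` available, and records both per peak. The
same basis is the denominator of the area/intensity ratio.

### Integration bounds and area

Each peak's integration range runs between the nearest flanking local
minima (signal edges where none exist). The area is the trapezoidal
integral of the raw intensity over that range — no baseline subtraction, so
areas are interpretable on the instrument's own scale. Peak width is
measured at half prominence by linear interpolation on both flanks.

### Wavelet confirmation

The trace is decomposed with a reverse-biorthogonal filter bank
(`rbio2.2`; half-point symmetric boundary extension) and reconstructed from
approximation coefficients only, at levels 1 and 2. A detected peak is
*confirmed* when each level's approximation has a local maximum within
`confirm_rt_tol` (default 0.1 min) of the peak **and** that maximum retains
at least `confirm_min_retention` (default 0.5) of the peak's height.

The retention condition is load-bearing. A one-sample spike's lowpass
approximation still bumps near the spike — co-location alone confirms it —
but the spike surrenders most of its amplitude to the detail bands: on a
1,001-point grid a unit impulse retains only ~19% of its height at level 2,
while Gaussian peaks of realistic width (sigma of two or more samples)
retain 84% or more. The 0.5 threshold sits comfortably between the two
regimes. Unconfirmed peaks are flagged, not dropped (`drop_unconfirmed =
TRUE` drops them), since flagging preserves the detection record.

```{r confirm-demo, eval = FALSE}
rt <- seq(0, 10, by = 0.01)
gauss <- chromatogram(rt, 30000 * exp(-(rt - 5)^2 / (2 * 0.05^2)))
confirm_peaks(detect_peaks(gauss), gauss)$confirmed    # TRUE

spike <- chromatogram(rt, replace(numeric(length(rt)), 501, 30000))
p <- peak_params(confirm_levels = 2L)
confirm_peaks(detect_peaks(spike, p), spike, p)$confirmed  # FALSE
```

## Stage two: profiles and clustering

### The ten features

Each sample's peak table is condensed to ten numbers: peak count, mean and
maximum height, mean prominence, mean width, total area, mean
area/intensity ratio, retention time of the tallest peak, the SD of peak
retention times, and the fraction of peaks eluting in the first half of the
axis. The set deliberately spans count, magnitude, shape, area and
positional statistics, all computable from stage-one outputs; an empty peak
table maps to the all-zero profile so degenerate samples remain
clusterable.

Features are column z-scored (population SD; zero-variance columns map to
zeros) before clustering. Counts and areas differ by orders of magnitude,
so Euclidean distances on raw features would be dominated by whichever
feature happens to have the largest unit. `standardize_profiles = FALSE`
gives the raw alternative.

### Choosing k: the elbow, formalized

The visual elbow — "the point where the inertia curve becomes flat" — is
formalized as the k in 2..k_max−1 maximizing the second forward difference
d(k) = (I(k−1) − I(k)) − (I(k) − I(k+1)), ties broken toward smaller k.
The inertia curve uses best-of-10-restart k-means (k-means++ seeding, Lloyd
iterations) at each k, and each k additionally tries an initialization that
splits the previous solution's widest cluster, which makes the curve
provably non-increasing rather than merely non-increasing in expectation.

### The algorithms

* **k-means** — k-means++ seeding written here, Lloyd iterations delegated
  to `stats::kmeans`, best inertia over restarts, deterministic per seed.
* **Spectral** — the standard normalized recipe: RBF affinity with the
  median heuristic gamma = 1/(2 × median pairwise squared distance),
  symmetric normalized Laplacian, row-normalized eigenvectors of the k
  smallest eigenvalues, k-means in the embedding. Spectral handles the
  non-convex, unevenly scaled cluster shapes breath profiles can produce.
* **Agglomerative** — Ward's minimum-variance linkage on Euclidean
  distances (`stats::hclust`, `"ward.D2"`), consistent with the
  inertia-based elbow.
* **DBSCAN** — written in-package (no density-based implementation among
  the package's dependencies); deterministic row-order expansion,
  `min_samples = 3` and the median 3-NN distance as the default `eps`.
  DBSCAN is exploratory here: it chooses its own cluster count and flags
  noise, so it never drives k selection.

Partitions are evaluated against planted truth with the adjusted Rand
index, implemented from the pair-counting formula and cross-checked in the
tests against an independent implementation.

## The synthetic cohort generator

`default_scenario()` describes "bnp37": 37 samples in four latent classes
of sizes 10, 8, 11 and 8 — the cohort geometry of a PAH registry
breathomics study — on a 0.5–52.75 min retention axis at 120 points/min
(the span of a 36→250 °C GC program with holds), baseline 2,000 units with
30 units/min drift and Gaussian detector noise (SD 400).

Every sample carries 12 shared peaks — classic breath VOCs (acetone,
isoprene, ethanol, ...) — of which two (6,500 and 8,800 units) sit below
the 10,000 filter and the rest above it, so roughly 15% of true peaks
exercise the threshold. Each class adds 6 unique compounds, all well above
the filter, with names drawn from published per-cluster breath-compound
lists. Realized peaks are Gaussian in shape: height drawn with a 3%
coefficient of variation (replicate-level GC/MS intensity repeatability)
truncated at 10% of the mean, center jittered with SD 0.015 min, intensity
clipped at zero.

Three class axes are deliberately *decoupled*: the retention band the
unique compounds occupy (which class elutes where), the abundance ladder
(how tall they are, 40–115 × 10³ across classes), and the peak width
(0.030–0.054 min sigma) each order the four classes differently. A design
in which one latent severity axis drives everything puts the four class
centroids along a line; the best 2-partition then captures most of the
variance and the elbow's second difference peaks at k = 2. Decoupling the
axes spreads the centroids toward mutual equidistance, which is the regime
in which the elbow criterion is actually informative — and is also the more
realistic picture of metabolic phenotypes that differ in *which* compounds
they exhale, not merely in overall intensity.

All randomness flows through one master seed, with per-sample substreams
derived by fixed increments, so a cohort is a pure function of its scenario
regardless of generation order.

What the generator does **not** emulate: the m/z dimension (no mass
spectra), co-elution and deconvolution, retention-index drift between
batches, non-Gaussian (exponentially modified) peak shapes, and
heteroscedastic detector noise. Recovery results on bnp37 therefore
demonstrate the pipeline's internal correctness — that the features retain
the planted structure and the clustering recovers it — not clinical
performance on real breath data.

## Numerical choices and degenerate inputs

* Wavelet boundary handling is half-point symmetric; the analysis/synthesis
  pair reconstructs inputs to < 1e-8, and decomposition requires at least
  filter-length × 2^level points.
* Plateau maxima and plateau valleys take deterministic (leftmost /
  far-edge) indices.
* k-means at k = 1 and k = n use closed forms (grand centroid; singletons
  with zero inertia).
* A spectral affinity over coincident points is an error (degenerate
  median); a zero-variance profile column standardizes to zeros rather than
  NaN; an empty peak table profiles to zeros.
* Single-member clusters report SD as `NA` in covariate summaries
  (sample SD, n−1, is undefined).

## Problem sizes

The shipped validation runs on the full 37-sample bnp37 cohort (6,271
points per chromatogram) for end-to-end checks, a 9-sample mini-cohort for
fast pipeline tests, 100-replicate property sweeps for the brute-force
oracle comparisons, and 100 seeded planted-blob replicates (K ∈ 2..5,
centers ≥ 6 within-class SDs apart) for elbow robustness.

## Known limitations

* The ten features are one defensible realization of a fixed-length signal
  profile; the original study never enumerated its feature set, and other
  choices (quantiles of peak height, binned densities) are plausible.
* Confirmation depends on the wavelet member and the retention threshold;
  `rbio2.2` and 0.5 are defaults, not dogma, and both are parameters.
* The elbow's second-difference formalization inherits the elbow method's
  known weakness on hierarchically structured data (a dominant two-way
  split masks finer structure); the generator documentation above explains
  the geometry in which it is reliable.
* DBSCAN's `eps` heuristic is a rule of thumb; on standardized profiles of
  small cohorts its output is sensitive to `min_samples`.
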