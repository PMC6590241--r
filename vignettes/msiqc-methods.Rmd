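---
title: "Quality control for MALDI imaging: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality control for MALDI imaging: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(msiqc)
```

## The problem

Peptide MALDI mass spectrometry imaging (MSI) of formalin-fixed
paraffin-embedded (FFPE) tissue acquires one mass spectrum per pixel of a
tissue raster, typically at a 50 µm pitch. The wet preparation steps —
on-slide tryptic digestion under controlled humidity, enzyme and matrix
spraying — can delocalize analytes laterally and introduce run-to-run
variability, so any workflow intended for multi-site or clinical use needs
quantitative quality control. `msiqc` implements four complementary QC
computations:

1. a **mixed-pixel spatial-resolution score** measuring the overlap of two
   ion images specific to adjacent tissue regions;
2. **spectral-quality metrics**: per-spectrum peak counts summarised by
   medians with percentile-bootstrap confidence intervals;
3. a cross-run **peak-intensity coefficient of variation** (CV) table;
4. **spatial segmentation** by bisecting *k*-means with correlation
   distance, and PCA with unit-variance scaling, to check that structure in
   pooled data follows biology rather than batch.

Because no public reference datasets exist for this kind of QC, the package
ships a **synthetic phantom generator** with full ground truth; every
scoring operation is validated against phantoms in the test suite.

## Mixed-pixel spatial-resolution score

Two marker channels are extracted as ion images (closed m/z windows,
half-width 0.25 Th by default; `sum` reducer, i.e. proportional to the ion
count in the window), after per-pixel TIC normalization. Each channel is
clipped to its 3rd and 97th percentile, computed **over on-tissue pixels
only** — including off-tissue background would let background set the floor.
Then each on-tissue pixel is classified: with clipped channel values $a$
(red) and $b$ (green),

$$\text{YELLOW if } \min(a,b) \ge 0.70 \cdot \max(a,b),$$

otherwise the pixel takes the colour of the larger channel. The score is

$$S = 100 \cdot \frac{|\text{YELLOW}|}{|\text{RED}| + |\text{GREEN}| + |\text{YELLOW}|} \%$$

Off-mask or unmeasured pixels are excluded. Even a perfect preparation has
some yellow pixels (a 50 µm pixel cannot resolve the region boundary);
excess delocalization raises the score.

Design choices that the score definition leaves open, and how `msiqc`
resolves them:

* **"Set zero to the 3rd percentile, maximum to the 97th" is read as
  contrast stretching**: each channel is clamped to its percentile bounds
  and then affinely rescaled to $[0,1]$ on that range
  (`rescale_after_clip = TRUE`, the default). This is how an imaging
  display maps a channel to its colour range, and it is the only reading
  under which the ratio rule is well defined: the two channels are
  intensities of unrelated ions with arbitrary relative units, and with
  clamping alone the score is not invariant to a positive scale factor on
  one channel (scaling one channel far enough collapses the score to zero)
  — in phantom experiments the clamp-only score swings by an order of
  magnitude with the run-level intensity jitter of the markers, while the
  rescaled score is stable and exactly scale invariant. The clamp-only
  reading remains available as `rescale_after_clip = FALSE` for
  sensitivity analysis, so both interpretations stay testable.
* **Exact ties are yellow**, including pixels where both clipped channels
  sit at the common floor: $\min = \max \ge 0.7\max$. An optional
  `min_signal_fraction` can exclude such low-signal pixels; the default
  classifies them, because the rule itself has no signal floor.
* **Percentiles** use linear interpolation between order statistics
  (`quantile` type 7), fixed for reproducibility.
* The score is invariant to swapping the channels and to a positive scale
  factor on either channel.

## Peak picking and S/N

The commercial picking algorithm the field uses for monoisotopic peptide
peaks is proprietary; `msiqc` implements a documented approximation with the
same observable behaviour:

* **Noise**: per point, $1.4826 \times$ the running median of absolute
  deviations from the running median, over a sliding 50 Th window (the
  factor scales the MAD of Gaussian noise to its standard deviation). The
  estimate is floored at a machine-epsilon multiple of the maximum intensity
  so it is strictly positive.
* **S/N of an apex** is its height *above the local running-median
  baseline*, divided by the local noise. The baseline correction matters: on
  a spectrum with a chemical-background offset, an uncorrected ratio passes
  every point of the elevated baseline regardless of threshold, and on
  baseline-subtracted (non-negative, folded) noise the MAD underestimates
  the upper tail. With the corrected definition the picker achieves, on
  planted-peak spectra, recall above 0.95 for true S/N ≥ 5 and false
  discovery below 0.05 at `min_snr = 3` — the operating regime the QC
  metrics rely on. Reported peak intensities remain raw apex heights.
* **Monoisotopic reduction**: peaks chained at the charge-1 isotope spacing
  (1.00235 Th, ±0.05 Th) whose intensity profile correlates (Pearson
  r ≥ 0.9) with the averagine-model envelope of the chain's monoisotopic
  mass are collapsed to the lowest-mass member. The averagine composition is
  C4.9384 H7.7583 N1.3577 O1.4773 S0.0417 per 111.1254 Da, envelopes
  truncated at 5 isotopologues; charge is fixed at 1 (MALDI peptides are
  singly protonated). Chains that do not match the envelope pass through
  unchanged, so the reduction never invents peaks and never increases the
  count.
* Duplicate maxima within 0.1 Th merge to the most intense.

The permissive listing stage uses `min_snr = 1` and `max_peaks = 10000`;
downstream metrics re-filter at stricter thresholds.

## Spectral-quality metrics

From `n = 100` spectra sampled uniformly without replacement from on-tissue
pixels (seeded, reproducible), four counts are computed per spectrum: picked
peaks, peaks with S/N strictly above 3, peaks strictly over m/z 1500, and
strictly over m/z 2000. "Above"/"over" are read literally as strict
inequalities; boundary peaks are measure-zero in practice. Each count is
summarised by its median with a **percentile-bootstrap** 95% confidence
interval (1000 resamples by default; the percentile method is the simplest
defensible choice where the bootstrap flavour is not further specified).
A coverage simulation in the acceptance suite (500 replications of n = 50
standard-normal samples) checks that the empirical coverage of the true
median lies in [0.91, 0.98].

## Peak-intensity CV across runs

Per run, peaks are picked (S/N ≥ 3) on the TIC-normalized average spectrum.
Each target m/z matches at most one peak within ±0.25 Th; multiple matches
are an explicit ambiguity error, and an unmatched target contributes
intensity 0 with a cleared completeness flag rather than being dropped —
silent dropping would bias the CV downward. Across runs the table reports
mean, sample standard deviation (n−1 denominator, appropriate for cohorts of
~10 runs) and $\mathrm{CV} = 100 \cdot s/\bar{x}$ %.

## Spatial segmentation and PCA

Pixels become rows of a peak-aligned feature matrix: peaks are picked on
each dataset's mean spectrum, consensus m/z bins are formed across datasets
by single-linkage merging within 0.3 Th (the scale of TOF peak jitter), and
each pixel's TIC-normalized intensity is integrated over ±0.25 Th per bin.
"Weak denoising" is realized as a 3-point moving average along m/z before
integration — the weakest sensible smoother, since the term is otherwise
undefined; `denoise_window = 0` disables it.

**Bisecting k-means** is authored in the package (the standard `kmeans` is
Euclidean-only, and the correlation metric is the point): repeatedly, the
leaf with the largest within-cluster sum of correlation distances
($d = 1 - r$) to its centroid is split by 2-means with 10 restarts,
assignment by correlation distance and centroids as arithmetic row means,
keeping the restart with the lowest within-cluster distance sum. The
leaf-selection rule is stated explicitly so trees are reproducible; it is
the standard bisecting heuristic. Zero-variance rows cannot be correlated;
they are assigned by a Euclidean fallback and contribute the neutral
distance 1 to objectives. Recursion stops at `max_depth` or when no leaf
holds two distinct rows. PCA centres and unit-variance-scales columns
(zero-variance columns are dropped with a warning) and reports scores and
explained-variance fractions of the correlation matrix's eigenstructure.

## The phantom generator

The phantom emulates a two-region tissue at 50 µm pitch on a 100×100 grid:
a 10% off-tissue margin per side, an outer "muscle" band (20% of the tissue
extent, half per side) and an inner "villi" area. Marker analytes default to
m/z 944.6 (villi) and 1105.6 (muscle) with apex intensity 100, plus two
trypsin-autolysis peptides (m/z 842.51, 2211.10) shared across all tissue —
the same channels a real QC run would use. The shared m/z axis spans
600–3200 Th at 0.1 Th (26001 points), and peaks are Gaussian with
m/z-proportional width (FWHM = m/z / R, R = 10000) with averagine isotope
envelopes.

Per-pixel spectra are the sum of analyte templates scaled by the analyte
map, times a per-analyte **log-normal image jitter**
($\sigma_{\ln} = 0.2$), plus folded-Gaussian baseline noise
($\sigma = 1$; the fold models magnitude noise after on-instrument baseline
subtraction and keeps TICs strictly positive). The jitter is drawn **once
per analyte per generated image**, not per pixel: it models
preparation-level extraction variability, which is what a cross-run CV
measures. A per-pixel i.i.d. factor would average out as $1/\sqrt{n_{px}}$
in the mean spectrum and make run-to-run CVs of ~0.5% — inconsistent with
the analytic log-normal CV $\sqrt{e^{\sigma^2}-1} \approx 20.2\%$ that the
cohort calibration targets. Pixel-level variability is carried by the
baseline noise.

Failure modes:

* **Delocalization** is a Gaussian blur of the analyte maps
  (`blur_sigma_px`, default 1 px ≈ 50 µm of lateral spread — a realistic
  wet-preparation magnitude). The blur is an exact separable convolution
  with zero padding, so a blurred step edge follows the Gaussian error
  function; the test suite checks the 10–90% rise distance against that
  closed form. Zero-padding semantics are part of the generator's contract,
  which is why the convolution is written out rather than delegated to an
  image library with circular or replicated boundaries.
* **Condensation droplets** replace each analyte map inside a disc by its
  disc mean, then locally re-blur — local homogenization, not signal
  deletion, matching the observed phenomenology of condensation artifacts.
  A droplet straddling a region boundary carries both markers and turns its
  pixels yellow.

Analyte maps are raster region indicators times mean intensity; there is no
sub-pixel area mixing. Consequently, with zero blur and zero noise the set
of pixels reached by both markers is empty and so is the yellow set — the
hard-edge equality the acceptance suite asserts exactly. Boundary mixing
appears through the blur, which is also what the monotonicity check varies.

Cohorts (`replicate_cohort`) are independent noise/jitter realizations of
one geometry, each scaled by a per-run multiplicative site effect; run seeds
derive deterministically from the master seed (`derive_seed`, a documented
counter scheme), so one seed fixes an entire multi-run study.

What the phantom does **not** model: digestion kinetics, matrix
crystallization, ionization physics, mass-accuracy drift, or sub-pixel
boundary geometry. Passing tests demonstrate correctness of the scoring
computations under known truth and realistic magnitudes — not instrument
fidelity. Real-data scores depend on tissue, instrument state and
preparation and can only be compared within a consistent workflow.

## Validation sizes and numerical choices

The test and acceptance suites size their simulations so the whole
validation runs comfortably on one CPU; these are the package's documented
validation conditions:

* brute-force oracle equivalence: 100 random instances up to 10×10;
* blur monotonicity (σ ∈ {0, 1, 2, 3, 5} px) and droplet comparisons: the
  default geometry at 40×40, 10 seeds (the score's monotonicity is
  grid-size independent; the full-size default grid is exercised by the
  end-to-end determinism check);
* bootstrap coverage: 500 replications, n = 50, 1000 resamples;
* planted-peak suite: 100 spectra on a 600–700 Th axis, 30 peaks each
  (spacing ≥ 3 Th, true S/N 5–30, Gaussian noise on a flat chemical
  baseline); the planted density is chosen so that the irreducible
  Gaussian-tail false-positive rate at S/N 3 (~1.3 false peaks per 1000
  axis points) stays identifiable;
* CV calibration: 10-run cohort at 32×32, jitter σ_ln = 0.2;
* segmentation: five 40×40 phantoms (first-split adjusted Rand index vs
  truth) and a pooled 5-replicate cohort (region-wise vs replicate-wise
  silhouette on correlation distances, 150 pixels subsampled per replicate);
* end-to-end determinism: the full default 100×100 phantom, scored,
  quality-profiled and segmented twice from one seed, byte-identical
  metrics.

Other numerical conventions: m/z windows are closed intervals in Th (not
ppm) — a fixed-Th window is reproducible on TOF data where the true
extraction width of vendor software is unknown; ion-image reducers `sum`
(default), `mean`, `max`; imzML stores m/z as 64-bit and intensities as
32-bit floats by default (64-bit on request for exact round trips); masks
take precedence in the order user-supplied raster > TIC-quantile fallback,
and the TIC fallback uses a strictly-greater comparison so a constant field
yields an all-off mask with a warning rather than an arbitrary split.

## Known limitations

* S/N values are comparable only within this implementation; vendor noise
  estimators are undocumented.
* The isotope-chain reducer assumes charge 1 and does not deconvolve
  overlapping envelopes.
* Processed-mode (per-pixel axis) datasets are supported for I/O and
  per-spectrum operations, but feature matrices and average spectra require
  a shared axis.
* No statistical tests between sites are provided: the choice of test would
  be arbitrary where the workflow being modelled names none.
* No optical-image registration: masks must arrive aligned to the pixel
  grid.
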