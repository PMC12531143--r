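---
title: "Coordinate-based functional connectivity network mapping: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coordinate-based functional connectivity network mapping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the approach

Voxel-based morphometry (VBM) studies of a given trait routinely disagree on
*where* in the brain its gray-matter correlates sit. Functional connectivity
network mapping (FCNM) reframes the question: instead of asking whether
reported coordinates coincide, it asks whether they belong to a common
functional network. Each study contrast's reported coordinates are turned
into a seed; each seed's whole-brain resting-state connectivity is estimated
in a large normative cohort; and the voxels connected to a majority of the
seeds define the trait's network. That network can then be interpreted
against canonical large-scale systems and against the spatial layout of
neurotransmitter receptor and transporter densities.

`fcnmapper` implements this pipeline end to end:

1. **Ingestion** — a delimited study/foci table (per-study sample
   characteristics; per-contrast coordinates in MNI or Talairach space,
   Talairach converted through a configurable affine).
2. **Seeds** — per contrast, the union of spheres (default radius 4 mm)
   around its coordinates, restricted to a gray-matter (GM) mask; foci whose
   nearest voxel is outside GM are dropped and counted.
3. **Temporal preprocessing** of the normative 4D cohort — discard of the
   first 10 volumes, a motion quality gate (fail above 2 mm translation or
   2° rotation, strictly "exceeding"), framewise displacement (Power
   convention, 50 mm head radius), simultaneous nuisance regression
   (constant, linear trend, Friston-24 expansion, one-hot spike regressors
   for FD > 0.5 mm, optional global signal, white-matter and CSF series),
   then an ideal 0.01–0.1 Hz frequency-domain bandpass.
4. **Connectivity statistics** — per subject and contrast, Pearson
   correlation between the seed's mean time series and every GM voxel,
   clipped at |r| ≤ 1 − 1e−7 and Fisher z-transformed; across subjects, a
   voxelwise one-sample t-test; voxel-level Benjamini–Hochberg FDR at
   q = 0.05 over the GM family; binarization restricted to *positive*
   connectivity.
5. **Network definition** — the K contrast-level binary maps are averaged
   into an overlap-probability map (values on {0, 1/K, …, 1}); voxels
   reaching at least 50% define the network mask (inclusive threshold).
6. **Interpretation** — per canonical network L, the overlap proportion
   100·|network ∩ L| / |L| (denominator = the canonical network's own voxel
   count), with involvement called at ≥ 20% (inclusive); and a JuSpace-style
   neurochemical profile: parcel-level Spearman correlation against each
   receptor/transporter map, a 5000-iteration permutation null with the
   add-one p floor (b + 1)/(n + 1), and BH-FDR across the tracer family.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| seed radius | 4 (1, 7 for sensitivity) | mm | conventional FCNM sphere size; sensitivity runs check topographic stability |
| volume discard | 10 | volumes | T1 equilibration |
| motion limits | 2 / 2 | mm / degrees | hard QC gate; values exactly at the limit pass |
| FD spike threshold | 0.5 | mm | strictly greater-than; a frame at exactly 0.5 is kept |
| bandpass | 0.01–0.1 | Hz | conventional resting-state band; inclusive edges, DC removed |
| FDR level q | 0.05 | — | voxel-level, family = in-GM voxels |
| overlap threshold | 0.5 | fraction of contrasts | "at least 50%": inclusive |
| involvement threshold | 20 | % of canonical network | inclusive at exactly 20% |
| permutations | 5000 | — | per tracer; p never exactly 0 |

Open choices the pipeline had to make (the procedure is underdetermined at
these points) are exposed as configuration: the seed time series defaults to
the unweighted mean over seed voxels (`"pc1"` available); positive-FC
restriction is implemented as two-sided BH followed by a t > 0 mask (a
one-sided mode exists); the receptor-map correlation defaults to Spearman
(JuSpace convention) with Pearson available; the map entering the
neurochemical profile defaults to the unthresholded overlap-probability map
restricted to GM (richer gradation than the binary mask, which is also
selectable); and the permutation null is a uniform shuffle of parcel
assignments, with a hook (`perm_fun`) for spatial-autocorrelation-preserving
schemes, which are deliberately not bundled.

## Numerical conventions

- Coordinates are NIfTI RAS+ mm; voxel indices are 0-based; a coordinate's
  "nearest voxel" is the rounded continuous index.
- Sphere voxelization uses a closed ball on voxel-center distance *plus* the
  voxel containing each coordinate. The second clause keeps small spheres
  from vanishing between voxel centers (a 1-mm sphere on a 3-mm grid would
  otherwise be empty almost everywhere) and guarantees every in-grid
  coordinate yields a usable seed, as sphere tools conventionally do.
- Spheres are voxelized directly on the 3-mm analysis grid, not on a finer
  grid followed by resampling.
- Gaussian smoothing (`smooth_gaussian()`, available for upstream-style
  spatial smoothing) is separable with σ = FWHM/(2√(2 ln 2)) per axis and
  reflective padding, which conserves total mass for interior structures.
  The pipeline itself defaults to no smoothing: normative cohorts arrive
  already smoothed, and temporal preprocessing is the pipeline's job.
- The bandpass is an ideal rectangular filter in the frequency domain:
  zero-phase, idempotent, DC always removed.
- All nuisance regressors are removed in one simultaneous least-squares fit
  (rank-deficient designs drop dependent columns with a warning), so no
  regression step reintroduces variance removed by another.
- Zero-variance voxels get z = 0 and are flagged; zero across-subject
  variance yields a signed infinite t sentinel with p = 0 and a QC count.
- Degenerate cases are explicit errors, not silent results: empty seeds,
  contrasts with no in-GM focus (excluded and logged; an error only if none
  survive), geometry mismatches (reported with both grid shapes), bands at
  or above Nyquist.

## The synthetic-data generator

`simulate_cohort()` emulates the normative cohort: a 3-mm isotropic grid
(default 20 × 24 × 20), an ellipsoidal GM envelope, and planted networks —
spherical components whose voxels share a per-subject band-limited
(0.01–0.08 Hz, inside the analysis band) latent series with loading *w*,
plus i.i.d. Gaussian noise σ. Two voxels of the same network then correlate
at w²/(w² + σ²) in expectation (0.5 at the default w = σ = 1). Background GM
voxels are pure noise. Motion traces are low-amplitude random walks with
optional injected 1-mm steps that each produce exactly one FD spike;
WM/CSF nuisance series are supplied as given series. `simulate_study_foci()`
fabricates a literature around the planted truth (foci sampled from truth
voxels with mm jitter, the remainder uniform in GM; per-study sample sizes
30–364 and mean ages 20–72 years, spanning the ranges typical of the
ingested literature). `simulate_receptor_maps()` constructs parcel vectors
with a *target Spearman* correlation to the network by mixing normal scores
of the network's ranks with noise; the mixing weight is found by brute-force
Monte-Carlo calibration, because rank correlations of mixed Gaussians have
no convenient closed form. `simulate_label_atlas()` tiles the GM mask by
Voronoi partition around random in-mask centers (8 labels with the
conventional canonical-network names, or finer parcellations).

Everything is a pure function of its spec and seed (bit-reproducible).

**The global-signal degeneracy.** In this construction the planted network
is the *only* shared variance in the cohort, so the GM-mean "global signal"
is a nearly noiseless copy of the planted latent — global signal regression
(GSR) would remove precisely the signal the experiment plants. That is a
degeneracy of the synthetic construction, not a property of GSR: in real
data the global signal is dominated by brain-wide physiological and scanner
fluctuations. The recovery experiments therefore run with `gsr = FALSE`
(there is no global confound to remove), while `cohort_spec(global_amplitude
> 0)` adds a brain-wide shared component so that the GSR path can be — and
is — exercised end to end: with a planted global confound, GSR recovers the
network and restores specificity, and omitting it visibly inflates the map.

**What passing on synthetic data does and does not show.** The generator has
no hemodynamic model, no scanner noise spectrum, no spatial autocorrelation
in the noise, no inter-subject anatomical variability, and its GM envelope
is an ellipsoid, not a brain. Recovery results therefore validate the
*logic and calibration* of the pipeline (thresholds behave as specified,
FDR is controlled, the network threshold suppresses scattered false
positives, radii don't drive the result) — they do not certify performance
on any real cohort.

## Problem sizes for the shipped experiments

The package's own validation experiments use: a reference setting of 20
subjects × 120 volumes on the 20 × 24 × 20 grid with one planted 3-component
network and 8 synthetic studies (recovery Dice and 1/4/7-mm sensitivity); 20
null cohorts of 10 subjects for FDR calibration; 200 replicates at 500
permutations for permutation-p uniformity; and 50 replicates for the planted
Spearman ρ = 0.4 recovery. These sizes make the whole suite run in a couple
of minutes on one core while leaving each check statistically meaningful.

`run_sensitivity()` preprocesses the cohort once and reuses the time series
across radii — preprocessing and connectivity dominate the cost and are
radius-independent, which makes a disk-level cache unnecessary at these
problem sizes.

## Known limitations

- The Talairach→MNI conversion is a configurable affine (a Lancaster-style
  pooled matrix ships as JSON); no study-specific conversion provenance is
  modeled.
- The permutation null ignores spatial autocorrelation; with spatially
  smooth real maps it is anti-conservative, and a spin-test-style `perm_fun`
  should be supplied.
- Negative-direction foci are included alongside positive ones by default
  (sign-stratified runs are a flag away); no sample-size weighting of
  studies is performed.
- Cluster-extent correction, TFCE and permutation-based voxel inference are
  out of scope; the pipeline is voxel-level FDR only.
- Surface formats, DICOM, registration and normalization are out of scope;
  inputs must arrive on a common grid.
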