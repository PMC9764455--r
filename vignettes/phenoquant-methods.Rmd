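---
title: "phenoquant: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phenoquant: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoquant)
```

# Scope

`phenoquant` implements the quantification layer of a multi-level
(phenomic) characterization of H3K4 monomethylation loss in *Drosophila*:
the same biological perturbation — a catalytically dead Trr
methyltransferase ("TrrCA") versus its catalytic-site control ("TrrWT") —
is read out at the levels of single-locus transcription (FISH imaging of
*svb* transcription sites), chromatin (ChIP-seq coverage tracks), lipid
metabolism (MALDI imaging mass spectrometry of larval populations),
behavior (crawling trajectories), and morphology (trichome counts, body
size). The package provides one module per level plus shared group
statistics, and — because the deposited datasets require large downloads
and manually drawn anatomical masks — a first-class synthetic-data module
that generates every input type with machine-readable ground truth. All
accuracy claims made by the test suite refer to that ground truth.

# Microenvironment imaging

## Model

A field of view is a multi-channel 3D stack with physical voxel sizes
(defaults 0.1 µm laterally, 0.2 µm axially — ordinary high-NA confocal
sampling). Transcription sites appear in the RNA channel as
diffraction-limited puncta; the chromatin-mark channel is modelled as a
multiplicative local enrichment around (a subset of) sites:

$$ I_\text{mark}(\mathbf{x}) = B\,\Big(1 + (A-1) \sum_s
   e^{-\lVert\mathbf{x}-\mathbf{x}_s\rVert^2 / 2\sigma^2}\Big) * \mathrm{PSF} $$

with background $B$, amplitude $A \ge 1$, decay length $\sigma$ (isotropic
in physical space, then sampled onto anisotropic voxels), and a Gaussian
PSF (defaults $\sigma_{xy}$ = 0.1 µm, $\sigma_z$ = 0.25 µm, typical
confocal widths).

## Site detection

Detection thresholds a matched-filtered copy of the channel: the image is
smoothed with a Gaussian of the PSF scale (0.1 µm default) and all
26-neighborhood local maxima above `mean + k * SD` of the smoothed image
(default `k = 4`) are kept, then non-maximum-suppressed at a physical
minimum separation (0.5 µm default). The matched filter is essential, not
cosmetic: at peak SNR 5 the single-voxel miss probability of a raw
`mean + 4 SD` threshold is ≈ 16%, while after smoothing the same rule
yields F1 ≈ 0.99 on the reference phantom (100 sites, SNR 5). On an
equal-intensity plateau the lexicographically earliest voxel (z, y, x) is
kept, which makes flat images yield no maxima and ties deterministic.
Sub-voxel localization is deliberately not performed: all downstream
statistics are radial averages or region counts that do not require it.

## Radial profiles and related statistics

`radial_profile()` bins voxels by *physical* distance to each site
(default shells of 0.1 µm out to 2 µm), normalizes each site's profile by
its outermost-shell mean (so the far field is 1), and averages across
sites; the spread is reported as the across-site variance. Both the
normalization mode and the variance convention are exposed because
published "normalized average" profiles rarely state either; outer-shell
normalization across sites is the default. Sites near the stack border
keep their in-bounds voxels and are flagged rather than dropped.

Site density is defined on the 2D xy grid — the count of sites whose xy
centroid falls in a user-supplied mask divided by the mask's pixel count —
because region masks are drawn on projections. Since the physical pixel
size of such masks varies between setups, the density is reported both
per pixel and per µm².

# Coverage tracks

Track normalization follows the conventional mark-minus-control scheme:
per-bin subtraction of a histone-H3 control track, a centered moving
average of 500 bp (window rounded up to an odd number of bins), and
arithmetic averaging of replicates with pairwise Pearson correlations
reported. Edges use the truncated window (mean over available bins),
which preserves constants everywhere; a reflect mode is available. Both
operations are linear, so subtract-then-smooth equals
smooth-then-subtract to floating tolerance — the suite checks this at
1e-9. Bins are 0-based and half-open, bedGraph is the on-disk format, and
no implicit resampling is ever performed: grid mismatches are errors.
Per-library depth scaling is not applied by default because the order of
scaling and subtraction in the source pipeline is not documented;
subtraction operates on whatever normalization the inputs carry.

# Single-larva MALDI lipidomics

A population section is an ion-image stack: one intensity plane per
annotated m/z channel (annotation happens upstream; channels arrive as a
table of m/z, formula, adduct, lipid class). Larvae are segmented on the
total-ion-current image — Otsu threshold, optional morphological closing,
4-connected component labeling, small-component removal — and labels are
renumbered in row-major centroid order. Closing is **off** by default so
that larvae separated by even one background pixel remain distinct; it is
available for speckly real data. Per-larva abundance is the mean (default)
or sum of each plane over the larva's pixels; the mean is the default
because hypomethylated larvae are systematically larger and sums would
confound size with concentration.

Two deliberately simplified stand-ins are named to avoid overclaiming:

* `batch_adjust()` ("combat_lite") is a per-channel location/scale
  alignment: each batch is centered to the grand mean and scaled to the
  pooled *within-batch* SD. Using the within-batch SD (not the grand SD)
  is what makes the operation exactly idempotent. No empirical-Bayes
  shrinkage is applied and group labels are ignored.
* `class_enrichment()` ("class_ranksum") computes per-channel log2 fold
  changes between the two groups and, per lipid class, reports the median
  member fold change plus a Wilcoxon rank-sum test of members versus all
  non-member channels. It tests coherent within-panel shifts of a class;
  it is not an ontology enrichment.

PCA is column-standardized, drops constant channels with a warning, and
fixes each component's sign so its largest-magnitude loading is positive.

The ion phantom encodes the study conditions: 24 + 20 larvae per section,
77 lipid channels (30 triglycerides, 30 glycerophospholipids, 17 other;
two channels carry the real annotations m/z 744.5537 = C41H78NO8P and
m/z 815.6525 = C49H92O6), 100 µm pixels, and a hypomethylation effect of
×1.72 on triglycerides — the ratio of the reported biochemical
triglyceride concentrations — with ×0.70 on glycerophospholipids, a value
chosen once as a realistic moderate depletion since no magnitude is
reported for that class. "100 µm² per pixel" is ambiguous between side
length and area; pixel size is therefore required configuration with no
inferred default, and the phantom uses a 100 µm side.

# Larval behavior

Trajectories are uniformly sampled planar paths (30 Hz, 2 min — the
recording conditions). Speed is **path length over elapsed time**
(matching per-frame displacement tracking), not net displacement over
time; the two differ greatly for curved paths, and the choice is
documented because source descriptions of "displacement" are ambiguous. A
larva is a *mover* iff net start-to-end displacement ≥ 1 mm **and**
average speed ≥ 0.02 mm/s; the net-displacement clause makes the
classification robust to tracking jitter, which inflates path length but
not net displacement.

Head casts — a manually scored behavior in the source protocol — are
operationalized as *pause-and-reorient* events: a heading change of at
least 45° across a 1 s window while the smoothed forward speed at the
window centre is below a gate. Headings are computed on displacement
vectors smoothed over 0.5 s; the gate defaults to half the larva's own
median smoothed speed, which confines candidates to genuine pauses and is
what gives the detector simultaneous recall and precision of 1.0 on
injected events even at 10°/step heading noise (an ungated detector
drowns in spurious heading wander at that noise level). One event is
reported per contiguous above-threshold run; centres whose window
endpoints carry zero smoothed displacement (deep inside a pause, where
heading is undefined) are excluded. All three parameters are exposed, and
detector accuracy is claimed only against the generator's injected
events, never against manual scores.

The trajectory generator is a correlated random walk: per-larva base
speed N(0.190, 0.04) mm/s (the control-group mean; the SD is a modelling
choice), heading increments N(0, 2°) per step (≈ 11°/√s, gently curving
runs), head casts injected as a 1 s pause followed by a ±90° heading
jump at Poisson rate 1.45/min with a refractory gap (the Poisson count is
drawn first and kept while times are resampled, so the expected event
count is exactly rate × duration), and 15% still larvae showing only
0.01 mm tracking jitter.

# Morphometrics

Trichome counting uses topographic prominence: maxima are found by a
union-find sweep over pixels in decreasing intensity order, and a maximum
survives if its height above the saddle connecting it to any higher
maximum reaches `min_prominence`, followed by non-maximum suppression at
`min_separation_px`. Prominence (rather than a raw threshold) makes the
count invariant to additive illumination offsets and robust to gradients,
and the whole procedure is deterministic and rotation-invariant. ROIs are
user-supplied; anatomical landmark detection is out of scope.

Body metrics threshold the silhouette (Otsu by default), keep the largest
connected component, and report area = pixel count × pixel area and
length = the major-axis length of the component's second-moment ellipse,
$4\sqrt{\lambda_{\max}}$ of the pixel-coordinate covariance — exact for a
solid ellipse and within 2% on rendered phantoms across aspect ratios
2–8. The moment-axis definition is this package's convention for a
length that the source protocol drew by hand.

# Group statistics

`t_test()` is a pooled-variance two-sample Student t (the test named in
the figure conventions; Welch is available via a flag), oriented so that
t > 0 means the *second* group is greater — the orientation is echoed in
every result to prevent silent sign errors, and the right tail tests
"second group greater". Zero pooled variance with equal means returns
t = 0, p = 1; with unequal means it is an error rather than an infinite
statistic. `group_summary()` reports mean, sample SD (n−1) and the
mean ± 2 SD interval — the centre-line/box/tails convention of the
figures. `comparison_report()` applies these per metric over a long
table; raw p values are reported by default (matching the source
convention), with optional `p.adjust` methods and a printed caveat when
more than 10 metrics are tested.

# End-to-end study and calibration checks

`run_phenomics_study()` chains every stage on synthetic data: two
behavior cohorts (26 larvae each, speeds 0.190 vs 0.322 mm/s, head-cast
rates 1.45 vs 0.45 per min), one mixed 24-larva MALDI section
(triglycerides ×1.72), two confocal phantoms (site intensity ×0.7 in the
hypomethylated group — a reduction whose direction but not magnitude is
reported), and 20 body silhouettes per group with *equal* area
distributions. The report should flag exactly the four perturbed metrics;
the unperturbed glycerophospholipid and body-area metrics act as negative
controls and are expected to false-flag at the α = 0.05 rate, so the
suite requires each perturbed metric flagged in ≥ 90% of 25 seeds and
each null metric in ≤ 20% — demanding a literally exact flag set every
seed would fail at rate α per null metric by construction. The t-test's
type-I error is verified directly: 10⁴ two-group draws from one normal
at n = 13/13 must reject at 0.05 ± 0.01.

Problem sizes throughout (32 × 128 × 128 voxel stacks, 100 sites,
24–44 larva sections, 26-larva cohorts, 25-seed repetitions) are the
package's chosen desk-scale study conditions; they match the source group
sizes where those are reported and keep a full run in the minutes range
on one CPU.

# What the phantoms do and do not show

The generators reproduce the *structure* of each data type — punctate
sources under a Gaussian PSF with Gaussian or Poisson noise, elliptical
single-intensity larvae, correlated-random-walk paths with injected
events, binned tracks — with known ground truth, which is exactly what is
needed to verify the estimators. They do not attempt photorealism:
no nuclear texture beyond noise, no optical aberrations or depth-dependent
attenuation, no mass-spectral peak shapes or annotation errors, no larval
posture or peristalsis, no tracker identity switches. Passing tests
therefore demonstrate correctness of the quantification given
well-formed inputs, not robustness to every artifact of real microscopes,
spectrometers, or trackers; parameters most sensitive to such artifacts
(detection `k`, closing radius, head-cast gate) are the ones exposed as
configuration.
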