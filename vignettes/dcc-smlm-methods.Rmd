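---
title: "Counting subunits by dual-color colocalization SMLM: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting subunits by dual-color colocalization SMLM: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dccsmlm)
```

## The counting problem

Membrane protein complexes are built from a small number of identical
subunits, and the subunit count n (monomer, dimer, trimer, tetramer) is
often functionally decisive yet hard to measure in situ. Single-molecule
localization microscopy (SMLM) can resolve individual protein complexes in a
fixed cell, but classical binomial counting from a single photoactivatable
label demands a high recall rate (the probability p that a given fluorophore
is detected at all during the recording) and laborious spatio-temporal
grouping of emission events.

The dual-color colocalization (DCC) strategy implemented here avoids both
demands. Every subunit carries two fluorescent proteins: a bright *marker*
(mVenus-like, green channel) that defines the population of detectable
complexes, and a photoactivatable *indicator* (PAmCherry-like, red channel)
whose detection probability encodes n. The observable is the colocalization
ratio

$$P_d = \frac{N_{MF}}{N_M},$$

the fraction of marker clusters that have an indicator cluster within a
threshold distance d. If each of the n indicators is detected independently
with recall rate p,

$$P_d(n) = 1 - (1-p)^n, \tag{simple model}$$

so P_d grows with n even when p is far below 0.5 — the regime where
binomial counting fails. Low-recall labels are not a bug here but the
working regime.

### The double-loss factor

In fusion constructs a subunit can lose *both* labels at once, e.g. by
truncation within the linker. This breaks the independence of marker and
indicator and is modelled by a per-subunit double-loss probability m.
Conditioning on the complex being marker-visible (at least one subunit
retained its labels), with k the number of retained subunits:

$$P_d(n) = \sum_{k=1}^{n} \binom{n}{k}
  \frac{(1-m)^k m^{\,n-k}}{1-m^n}\left[1-(1-p)^k\right].
\tag{double-loss model}$$

`pd_modified()` implements this closed form; the test suite checks it
against a brute-force Monte-Carlo simulation of subunit states. Setting
m = 0 recovers the simple model, and n = 1 gives P_d = p for any m.

One approximation is worth stating explicitly: the model conditions only on
"at least one subunit retained", whereas the measured denominator
additionally requires that a retained marker was *detected*. When the
marker recall is below 1, complexes with more retained subunits are slightly
over-represented among marker-visible complexes, biasing the measured ratio
upward by a second-order amount (about +0.006 at n = 2, m = 0.3, marker
recall 0.8; up to ~+0.02 at marker recall 0.3). This selection bias exists
in the experiment as much as in the generator; it is well below the
per-cell noise at realistic marker recalls, and the generator tests budget
for it explicitly rather than hiding it.

## Background correction

The red channel carries spurious clusters. Around any marker cluster the
number of background clusters within distance d is Poisson with mean
$\pi d^2 D_{rb}$, where $D_{rb}$ is the background cluster density measured
on the coverslip outside the cell, so a marker colocalizes by chance with
probability

$$P_{rb} = 1 - e^{-\pi d^2 D_{rb}},$$

and the corrected ratio is

$$P_d = \frac{N_{MF} - N_M P_{rb}}{N_M - N_M P_{rb}}.$$

At the default threshold d = 100 nm and a typical background density of
0.8 clusters/µm², `p_background(100, 0.8)` gives 0.0248 — a ~2.5% chance
colocalization rate that the correction removes. Chance colocalization with
*genuine* indicator clusters of neighbouring complexes (≈1% at ~0.35
clusters/µm²) is not corrected — the same convention as in the experimental
procedure — and cancels in comparisons between conditions with equal
complex density.

## From localizations to clusters

Localization tables (frame, x, y in nm; 80 nm/pixel camera convention,
origin top-left, y downward) are grouped into fluorophore clusters with
DBSCAN on the planar coordinates only; time is deliberately ignored, which
is precisely what makes DCC insensitive to activation-control details.
Defaults: eps = 40 nm for both channels; min_samples = 10 (green), 6 (red),
50 (beads). The implementation (compiled, grid-bucketed) is fully
deterministic: clusters are numbered by the lexicographic rank of their
first core point and border points join the lowest-ranked core neighbour,
so results are invariant to row order; the suite verifies exact agreement
with a brute-force reference.

Each cluster is summarized by its mean coordinates and the radius
$\mu + 2\sigma$ of member distances to the center. Clusters with diameter
(2 × radius) above 500 nm are discarded as aggregates; retention is
typically above 98% and is reported per run. The same filter is applied to
cell and background cluster sets. For an isotropic Gaussian scatter of
σ = 15 nm the radius works out to $\sigma(\sqrt{\pi/2} + 2\sqrt{2-\pi/2})
\approx 38.5$ nm, conveniently close to eps.

## Registration

Colocalization at 100 nm only makes sense after registration.

* **Drift.** Fiducial beads are tracked per frame (nearest localization
  within a 200 nm capture radius of the running position; undetected frames
  interpolated linearly). The drift on frame k is the bead-mean displacement
  from frame 1 and is subtracted from every localization. The red channel is
  recorded after the green one, so red coordinates are additionally shifted
  by the drift accumulated at the last green frame. On noiseless synthetic
  beads this correction is exact (cluster radius 0). Recordings with more
  than 300 nm measured axial drift are flagged, not silently dropped.
* **Lateral chromatic aberration (LCA).** Green/red bead clusters are
  paired by mutual nearest neighbours within 200 nm; the shift A = red −
  green grows linearly with distance from a center: $A = K\,(r - r_0)$ with
  one shared slope K, fitted by stacking both axes into a single
  least-squares problem in observed red coordinates. Subtracting the fitted
  field is then an exact inverse for an exactly linear aberration, and the
  residual scatter equals the bead localization noise otherwise. A regional
  alternative (`fit_lca_regional()`) averages shifts per grid square and
  fills empty squares by iterated 8-neighbour averaging; on a linear field
  the two corrections agree to within the grid discretization scale. The
  grid edge is configurable (default 2 µm, a 10×10 grid over a ~20 µm
  field).
* **Axial chromatic aberration** is measured from a focal sweep (peak
  offset of the two intensity profiles, parabolic sub-step interpolation)
  and reported as quality control only; it is never applied as a coordinate
  correction in this two-dimensional pipeline.

## Colocalization threshold

The threshold d is not a free dial: it is read off the radial distribution
function of red clusters around green clusters,

$$g_{MF}(r) = \frac{a}{\pi N_M N_F}
  \sum_i \frac{dN_{F_i}(r)}{(2r+dr)\,dr},$$

computed in 20 nm bins to 400 nm with r the inner bin radius and no edge
correction (ROIs should keep a 400 nm margin; the generator's do).
`correlation_length()` returns the outer edge of the initial contiguous run
of bins with g above 1; on registered two-color data of the reference
constructs this is ≈100 nm, the package default for d. A marker cluster
colocalizes when at least one red cluster lies strictly closer than d
("exactly one" is available as an option, but the Poisson background
derivation above is a ≥1 statement, which settles the default).

## Fitting and classification

`fit_dcc()` fits (p) or (m, p) by exhaustive grid search — p over
[0, 0.4] and m over [0, 1), both in 0.01 steps — maximizing R² against the
calibration observations; ties resolve to the smallest (m, p). Both
per-cell observations (`use = "cells"`, the default) and per-protein means
(`use = "means"`) are supported, since the choice changes what R² weighs.
On the printed reference means (0.172/0.237/0.241/0.293/0.411 for
n = 1,2,2,3,4) the simple model lands on p = 0.12 and the double-loss model
on p = 0.17 with m ≈ 0.3.

`mismatch()` scores a candidate state n against per-cell POI ratios:

$$M^2(n) = 1 - \frac{\sum_i (x_i-\bar x)^2}{\sum_i (x_i-E(n))^2},$$

0 for a perfect match, approaching 1 far from the data. Note the statistic
is not symmetric in the two sums: adding an observation at the sample mean
changes M² unless E(n) equals the mean — a property pinned by a regression
test.

`classify_dcc()` propagates all uncertainty by a global bootstrap (default
B = 10 000): each resample redraws every reference protein's cells and the
POI's cells, *refits* (m, p) on the resampled calibration, and recomputes
M²(n) for n = 1..4. Reported are percentile confidence intervals, the
state n* minimizing the mean bootstrap M², and — as a model-free
cross-check that needs no (m, p) at all — two-sample Kolmogorov–Smirnov
tests of the POI ratios against each reference protein at the
Bonferroni-corrected level α/4 = 0.0125 (exact p-values when both samples
have ≤ 25 cells, asymptotic otherwise).

A sensitivity surface (`sensitivity_surface()`) maps the minimal gap
between E(n) and E(n+1) over the (m, p) plane; separation up to tetramers
is best for p roughly in 0.2–0.4 with m below ~0.3, which is why a
moderate-recall indicator is adequate.

## The synthetic-scene generator

`simulate_scene()` produces localization tables with the statistical
structure the analysis assumes, plus full ground truth, so every stage and
the end-to-end inference are testable without microscope data. Defaults
describe one fixed set of study conditions:

* complexes at 1.5/µm² uniformly in a rectangular cell ROI; a disjoint
  coverslip background ROI, both with ≥400 nm margins;
* per subunit: double-loss with m = 0.30; otherwise marker visible with
  probability 0.8 and indicator with p = 0.17, independently;
* each visible tag emits a localization cloud: isotropic Gaussian σ = 15 nm,
  count min-truncated geometric (means 20 green / 14 red). The truncation
  floors (14 green, 10 red) sit a few counts above the DBSCAN min_samples
  presets because a cluster holding exactly min_samples points of σ = 15 nm
  scatter fails the core condition with appreciable probability; genuine
  tags should survive clustering, while background clusters keep a low
  floor (6, mean 8) and stay small, mirroring their empirical appearance;
* red background clusters as a Poisson process at 0.8/µm² over cell and
  background regions (green background negligible);
* drift: random walk of 2 nm/frame plus 0.05 nm/frame linear, per axis,
  zero on frame 1; the red recording continues after the green one and
  inherits its final drift; 2000 frames per channel;
* a linear chromatic field K = 0.01 centred mid-field, defined on observed
  red coordinates so that the linear correction is its exact inverse;
* 12 fiducial beads on a jittered grid (guaranteeing separation beyond the
  tracking capture radius), one localization per frame per channel,
  σ = 10 nm;
* optional aggregates: a configurable fraction of complexes rendered as
  dense uniform disks (radius 300 nm, ~700 localizations) whose cluster
  diameter ≈ 680 nm robustly trips the 500 nm filter.

What the generator does *not* emulate: camera noise and PSF shape (it is
localization-level), fluorophore photokinetics (blinking dark states,
frame-to-frame correlation of emissions), irregular cell outlines, and
spatial clustering of complexes beyond uniformity. Passing tests therefore
validate the statistical machinery — registration, clustering, background
correction, model fitting, classification — under the stated assumptions;
they do not certify performance on data whose violation of those
assumptions (e.g. strongly clustered membrane proteins) is the dominant
effect.

`simulate_calibration()` generates per-cell reference ratios at two levels.
The `"scene"` level runs every cell through the full localization-level
pipeline. The `"counts"` level is the fast path used for replicate studies:
per cell, N_M ~ Poisson(300) marker clusters and N_MF binomial at the model
ratio perturbed by a cell-level Gaussian (sd 0.04, truncated to (0,1)).
That sd is the one calibrated choice in the generator: it was set so that
bootstrap confidence intervals of (m, p) on a five-protein design with
realistic cell counts reproduce the scale of intervals reported for
calibration experiments of this kind (p ± 0.015, m ± 0.09 at ~110 cells),
and it is frozen at that value.

## Numerical choices and degenerate inputs

* Grid fitting is exhaustive, so there are no convergence issues; ties take
  the smallest (m, p) lexicographically. m = 1 is excluded as degenerate
  (no complex would ever be marker-visible).
* M² returns 0 when both sums vanish (all observations equal E(n)).
* `corrected_ratio()` clamps results marginally outside [0, 1] with a
  warning and refuses a non-positive denominator.
* DBSCAN distances are compared with ≤ eps; the neighbour count includes
  the point itself.
* Bead tracking refuses seeds closer than the capture radius (ambiguous
  assignment) and beads missing from more than 10% of frames.
* The K-S test switches from exact to asymptotic p-values above 25 cells
  per sample.
* All stochastic operations take explicit seeds; a scene, a calibration
  panel and a classification are byte-reproducible given their seeds.

## Problem sizes used in the validation suite

The test suite uses scenes of a few hundred complexes for pipeline checks,
one pair of ~5000-complex scenes for the background-correction property,
100 replicate calibration panels (25 cells × 4 states) for parameter
recovery, 100 bootstrap classifications at B = 1000, and a 45-point
(n, p, m) grid at 10⁷ Monte-Carlo draws for the closed-form check; the
bundled acceptance script refits the printed five-protein calibration
exactly. These sizes are the package's chosen validation conditions and run
comfortably on a laptop-class machine.

## Known limitations

* DCC reports a single average state; mixtures of oligomeric states can be
  simulated (`oligomer = c("1" = 0.5, "2" = 0.5)`) and land between the
  pure predictions, but the package deliberately does not attempt mixture
  deconvolution.
* The marker-recall selection bias described above is accepted, not
  corrected; at marker recalls below ~0.5 combined with large m it would
  become comparable to per-cell noise.
* Chromatic aberration is corrected laterally only (linear or regional
  models); no affine/spline fields, no 3-D registration.
* Pair correlation uses no edge correction; ROIs must keep an r_max margin.
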