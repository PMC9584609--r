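# dccsmlm

Determining the oligomeric state of plasma-membrane proteins in situ from
**dual-color colocalization single-molecule localization microscopy
(DCC-SMLM)** data.

## Who this is for

Labs doing PALM/STORM-style molecular counting of membrane protein
complexes (ion channels, transporters) who tag each subunit with two
fluorescent proteins — a bright *marker* (e.g. mVenus) and a
photoactivatable *indicator* (e.g. PAmCherry) — and want to infer the
subunit count n from how often marker clusters colocalize with indicator
clusters. The approach tolerates low recall rates and background noise and
needs no temporal grouping of emission events, which makes it practical
exactly where classical binomial counting breaks down.

## The model

A complex of n subunits, each with an indicator detected independently with
recall rate p, is detected with probability

    P_d(n) = 1 − (1 − p)^n                                (simple model)

Allowing a per-subunit probability m of losing *both* labels at once
(e.g. linker truncation), and conditioning on the complex being
marker-visible,

    P_d(n) = Σ_{k=1..n} C(n,k) (1−m)^k m^(n−k) / (1 − m^n) · [1 − (1−p)^k]

The measured per-cell colocalization ratio is corrected for chance
colocalization with red background clusters via a Poisson model:

    P_rb = 1 − exp(−π d² D_rb),   P_d = (N_MF − N_M P_rb) / (N_M − N_M P_rb)

with d the colocalization distance (default 100 nm, set from the pair
correlation length) and D_rb the background cluster density measured on the
coverslip. Calibrating (m, p) on reference proteins of known n turns the
ratio into a counting rule; candidate states are scored with a mismatch
coefficient M²(n) under global bootstrap resampling, cross-checked by
Bonferroni-corrected two-sample Kolmogorov–Smirnov tests.

The package covers the full path from raw localization tables to a
classification: reading delimited localization/ROI files, fiducial-bead
drift correction, lateral chromatic-aberration registration (global linear
fit or regional grid), deterministic DBSCAN clustering, aggregate
filtering, pair correlation, background-corrected per-cell ratios, model
fitting, bootstrap classification — plus a ground-truth synthetic scene
generator that makes every stage testable without microscope data. See the
methods vignette (`vignettes/dcc-smlm-methods.Rmd`) for the full account.

## Worked example

Fit the detection model to reference colocalization ratios (cold-methanol
fixation) of five proteins with known oligomeric state:

```r
library(dccsmlm)

cal <- tibble::tibble(
  protein = c("barttin", "ClC-2", "bClC-K", "EAAT2", "Kir2.1"),
  n       = c(1, 2, 2, 3, 4),
  pd      = c(0.172, 0.237, 0.241, 0.293, 0.411))

fit_dcc(cal, model = "modified", use = "means")
#> DCC detection model fit (modified model, per-protein means)
#>   m = 0.32 (double-loss)
#>   p = 0.17 (indicator recall rate)
#>   R^2 = 0.967 over 5 observations
#>   expected ratios: E(1)=0.170, E(2)=0.243, E(3)=0.319, E(4)=0.392
```

The indicator recall rate is only 0.17 — and that is enough: the expected
ratios for monomer through tetramer are well separated. (The simple model,
`model = "simple"`, lands on p = 0.12 but misfits the monomer.)

Simulate a full dual-color recording — drift, chromatic aberration, beads,
background — and run the complete pipeline on it:

```r
sc  <- simulate_scene(scene_config(seed = 7))   # ground-truth dimer scene
run <- run_dcc(sc)
run
#> DCC-SMLM run: 1 cell ROI(s)
#>  cell_id n_m n_mf   d_rb    p_rb     pd density_m
#>   cell_1 272   72 0.7684 0.02385 0.2467     1.297
#> residual chromatic offset: 0.9 nm (bead mean)
```

272 marker clusters were found in the cell, 72 with an indicator partner
within 100 nm; after subtracting the measured background (0.77 clusters/µm²,
a 2.4% chance-colocalization rate) the corrected ratio 0.247 matches the
dimer prediction E(2) = 0.246 of the generator's parameters.

Classify a protein of interest against a calibration panel:

```r
cal2 <- simulate_calibration(seed = 2)                     # 5 references
poi  <- simulate_calibration(n_list = 2, cells_per_protein = 25, seed = 3)
classify_dcc(poi$pd, cal2, B = 10000, seed = 4)
#> DCC oligomeric-state classification (10000 bootstrap resamples)
#>   inferred state n* = 2
#>  n expected    m2 m2_mean m2_lo m2_hi
#>  1    0.170 0.681   0.669 0.452 0.833
#>  2    0.246 0.009   0.060 0.000 0.270
#>  3    0.325 0.747   0.752 0.594 0.876
#>  4    0.401 0.915   0.916 0.862 0.959
#> K-S tests vs references (alpha' = 0.0125):
#>  reference ref_n statistic  p_value reject
#>    ref1_n1     1      0.72 1.58e-06   TRUE
#>    ref2_n2     2      0.20 7.10e-01  FALSE
#>    ref3_n2     2      0.20 7.10e-01  FALSE
#>    ref4_n3     3      0.80 3.35e-08   TRUE
#>    ref5_n4     4      0.92 1.94e-11   TRUE
```

M² is smallest for n = 2 with a confidence interval touching zero, and the
K-S test rejects every reference except the dimers: the protein is a dimer.

Fitted objects support `tidy()`, `glance()` and `autoplot()`; per-result
plots include `plot_rdf()` (pair correlation) and `plot_sensitivity()`
(state-separation surface). A thin command-line front end over the same
functions lives in `inst/cli/dccsmlm.R` (subcommands `simulate`,
`register`, `cluster`, `colocalize`, `fit`, `classify`, `run-full`).

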