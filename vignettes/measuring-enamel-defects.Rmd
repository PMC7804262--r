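---
title: "Measuring enamel defect and perikymata depths from surface topographies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring enamel defect and perikymata depths from surface topographies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enameldepth)
```

## The measurement problem

Linear enamel hypoplasia (LEH) appears as horizontal grooves of locally
reduced enamel thickness on the outer tooth crown, recording early-life
physiological stress. Perikymata are the near-weekly incremental ridges and
grooves of normal enamel growth, typically one to two orders of magnitude
shallower than LEH defects. Confocal profilometry yields micrometre-scale
surface topographies on which both can be measured quantitatively, replacing
qualitative by-eye scoring.

`enameldepth` implements the full measurement chain:

1. **surface I/O** — XYZ `.dat` point clouds (whitespace/comma/semicolon
   delimited, explicit no-data tokens) are parsed into `point_cloud` objects;
   all internal lengths are micrometres, converted only at I/O boundaries.
2. **DEM building** — `interpolate_dem()` grids the measured points by
   piecewise-linear interpolation over their Delaunay triangulation
   (via the `interp` package); nodes outside the convex hull stay missing,
   and no extrapolation is ever performed. `flip_vertical()` corrects the
   orientation of imported grids; `reduce_noise()` is a median/MAD spike
   filter.
3. **profiles** — `extract_profile()` samples the DEM bilinearly along a
   straight transect and orients the result occlusal-end first.
4. **depth measurement** — `find_extrema()` detects ridges and grooves with
   a minimum-amplitude criterion; `measure_defect_depth()` and
   `measure_perikymata_depths()` apply the depth conventions;
   `measure_defect_replicates()` runs the triplicate-transect protocol.
5. **leveling** — `fit_form()` / `remove_form()` implement whole-field plane
   and sphere form removal, and `leveling_comparison()` quantifies the bias
   this introduces.
6. **statistics** — `severity_ratios()`, `group_summary()`,
   `correlate_depths()`, `fit_group_model()`, `posthoc_contrasts()` and
   `replicability_compare()`.
7. **simulation** — `generate_surface()` and `generate_cohort()` provide
   seeded synthetic data with exact ground truth, so every stage above is
   testable without access to fossil scans.

## Depth conventions

**Defects.** Depth is the elevation of the *occlusal-side shoulder* minus
the elevation of the deepest groove minimum that survives amplitude
thresholding. The occlusal shoulder is the nearest retained ridge occlusal
of the floor; when thresholding leaves no occlusal ridge (a smooth monotone
flank), the highest profile sample occlusal of the floor is used. The
cervical shoulder is recorded for audit but never enters the depth.

**Perikymata.** Depth is the difference between a groove and an adjacent
ridge. The package default takes the *higher* of the two adjacent ridges
(the maximum groove-to-ridge difference); the ridge side actually used is
recorded in every measurement, and an occlusal-only convention is available
(`ridge = "occlusal"`).

The higher-ridge default is a deliberate design choice. Under whole-field
plane removal, the change in any occlusal-referenced depth is `s * dy`,
where `s` is the single fitted slope and `dy > 0` is the occlusal-to-floor
(or ridge-to-groove) offset for *both* feature kinds. An occlusal-only
perikymata convention therefore forces leveled defects and leveled
perikymata to move in the same direction, which contradicts the empirically
observed opposite-direction bias (defects shallower, perikymata deeper).
The maximum-difference reading is convex in local surface tilt: a
perikymata site that is level in the raw field can only gain apparent depth
from leveling-induced tilt, whichever way it tips. This reproduces the
observed behaviour and is the convention the package tests and reports.

## Peak detection

`find_extrema()` is a sequential minimum-amplitude (hysteresis) peak
picker: walking from the occlusal end, a running candidate maximum is
committed as a ridge once the profile falls `min_amplitude` below it, after
which a running candidate minimum is tracked, and so on. Committed extrema
strictly alternate and adjacent pairs always span at least `min_amplitude`;
a trailing candidate never confirmed by a full back-swing is not reported.
Plateaus (runs of exactly equal elevation, common on quantised data)
collapse to a single extremum at the plateau midpoint. The implementation
is checked against an independent brute-force segment-rescan oracle on
1 000 random profiles in the test suite.

Defaults: `min_amplitude = 5` um for defect search and `0.2` um for
perikymata search — between the perikymata regime (medians roughly
0.8–4.3 um across taxa and tooth types) and the defect regime (medians
roughly 13–48 um). Both are configurable, and on teeth whose perikymata
approach the defect threshold the defect threshold should be raised above
the local perikymata depth, exactly as one adjusts the amplitude parameter
in interactive peak-finding tools. `find_extrema()` applies no smoothing;
spike cleanup is a separate, explicit step (`reduce_noise()`).

## The synthetic surface model

`generate_surface()` builds elevation as

```
z(x, y) = crown form + perikymata ripple + defect furrows + noise
```

* **Crown form**: a cylindrical cap of radius `crown_radius` (default
  5 000 um; `Inf` = flat) along the cuspo-cervical axis, apex at
  `apex_frac` of the field length. The y axis runs occlusal (0) to
  cervical.
* **Perikymata**: a quasi-periodic ripple; spacing (default mean 60 um)
  shrinks toward the cervix (`spacing_gradient`, default 0.15), matching
  the tighter cervical packing of real crowns. Each increment draws its
  groove depth from a normal distribution (default mean 2, sd 0.5 um,
  floored at 20% of the mean); a monotone warp (`asymmetry`, default 0.3)
  skews each groove occlusally.
* **Defects**: Gaussian furrows (`depth`, `width`; the width must exceed
  the perikymata spacing) or smoothed-box plane-form depressions. The
  default field is a single 30-um furrow centred in a 500 x 1200 um scan at
  0.64 um/pixel — one defect-centred acquisition.
* **Instrument effects** (applied last, in this order): Gaussian height
  noise (default sd 0.05 um), spike outliers (rate 0.001, amplitude
  25 um), and dropouts (rate 0.005, i.e. a 99.5% measured-point scan,
  within the 98–99.9% regime of well-configured acquisitions).

Ground truth is evaluated analytically on a quarter-pixel 1-D grid of the
noise-free surface, using the same shoulder conventions as the measurement
code but none of its DEM/profile/peak machinery. Two truths are recorded
per defect: `depth_true` (in-situ, feature plus crown form — what a raw-DEM
measurement targets) and `depth_feature` (the feature component alone).
On a flat crown they coincide; on curved crowns the in-situ truth is the
correct reference for raw measurements, and the pair quantifies
curvature sensitivity (for a 30-um defect spanning 300 um on a 5 000-um
crown the two differ by under 5%, which is why short, feature-levelled
transects need no form removal).

What the simulator does **not** emulate: wear, calculus, mesiodistal
curvature, scan-strip stitching seams, or spatially correlated instrument
noise. Passing recovery tests therefore demonstrate correctness of the
measurement chain, not robustness to every preservation state of real
teeth.

## The leveling experiment

`leveling_comparison()` reproduces the raw-versus-leveled comparison on one
synthetic crown: defects are measured with triplicate transects on the raw
DEM, perikymata on the defect-free increments nearest the apex (the
flattest raw region, mirroring the protocol of drawing perikymata
transects across level areas); then each form (plane, sphere) is fitted to
the whole field, removed, and the identical transects re-measured. Grooves
are re-paired after leveling by position, since leveling-induced tilt
displaces extrema.

Geometry matters and is chosen on physical grounds, not tuned: plane
removal imposes a residual tilt of roughly `L / (2R)` at a field's apex
(field length `L`, crown radius `R`). Ripple extrema survive tilt only
while it stays below the maximum ripple slope (about `pi * depth /
spacing`). The packaged experiment therefore uses an 800-um field with the
apex near the occlusal end and radii of 5 000–8 000 um; with shorter radii
at this field length the ripple is destroyed by the induced tilt and
nothing remains to re-measure — which is itself an instructive property of
whole-field leveling. Under these conditions leveled defect depths are
strictly shallower than raw (the raw depth includes the crown's tilt
contribution, which the fitted form absorbs; the mean bias in the packaged
run is close to 20% with a plane) and leveled perikymata depths are equal
or deeper (tilt is introduced at the previously level perikymata site).

## Statistics

Depths are natural-log-transformed (they are right-skewed);
`correlate_depths()` runs Pearson correlation on log per-tooth medians.
`fit_group_model()` fits `log(depth) ~ group + (1 | specimen)` with
`lmerTest` and reports the Satterthwaite F test; the specimen random
intercept absorbs within-individual dependence, including matched defects
(which share a `matched_group_id` and are never collapsed).
Severity-ratio models default to the log scale because the ratio is
multiplicative; untransformed analysis is available. Posthoc contrasts use
Tukey adjustment by default (Holm selectable); the method is recorded in
the output. `severity_ratios()` applies the fallback rule exactly: the
same-tooth median perikymata depth where the tooth's perikymata are
preserved, otherwise the taxon-and-tooth-type pool median, with the
reference kind recorded per defect.

Replicability comparisons use the symmetric percent difference
(`100 |a - b| / mean(a, b)`); the leveling report uses the raw depth as
denominator, because its question is "how far from the raw value does
leveling move the measurement".

## The cohort simulator

`generate_cohort()` mirrors the hierarchical structure of a comparative
study: lognormal specimen effects (sd 0.3 on the log scale) shared by a
specimen's perikymata and defects, tooth-level perikymata medians, ten
perikymata records per preserved tooth, and defect depths built as
`severity x tooth perikymata median x noise`. A configurable fraction of
teeth (default 12/71) is flagged as too poorly preserved for perikymata
measurement; their records are withheld so severity referencing must fall
back to the taxon pool. Each taxon-by-tooth-type stratum keeps at least
one preserved tooth, so a fallback pool always exists — in a study this
corresponds to the species reference sample always being measurable.

Calibration checks in the test suite use 18 specimens (9 per group, two
teeth and two matched defects per tooth): the mixed-model type-I error at
alpha = 0.05 stays within [0.03, 0.08] over 500 null replicates, and a
simulated 2.33x between-group depth ratio — a realistic anterior-tooth
effect size — is covered by the 95% Wald-t confidence interval in at
least 90% of 200 replicates.

## Numerical choices and problem sizes

* Grids: bilinear profile sampling snaps to grid nodes within 1e-9 of a
  node, so node-aligned transects are exact. Transect samples crossing
  missing cells are flagged and excluded from extremum search; a transect
  with more than 20% missing samples is rejected.
* Sphere fitting: algebraic (linearised) least squares provides the
  deterministic starting point; Gauss-Newton geometric refinement stops at
  a parameter step below 1e-6 um or 100 iterations. Exactly coplanar cells
  raise an error rather than returning a near-infinite radius.
* Duplicate (x, y) points keep the last-read z with a warning; Delaunay
  tie-breaking on co-circular grids follows the triangulator's
  deterministic rules.
* Test and validation surfaces use 1–2 um pixel pitch on 300 x 800 um
  fields rather than the instrument's native 0.64 um over full scans;
  recovery errors at these sizes are two orders of magnitude below the
  tolerances, so the coarser pitch costs nothing while keeping the suite
  fast. The acceptance script's simulation sizes (12 + 9 recovery
  surfaces, 300 oracle profiles, 200 + 100 model replicates) were chosen
  the same way.

## Known limitations

* Transect placement is ground-truth- or user-driven; there is no
  automatic defect detection on whole crowns.
* The DEM builder does not stitch overlapping scan strips.
* On strongly curved crowns (radius ~2 000 um) only the one or two
  perikymata nearest the apex of a field are measurable — consistent with
  practice, where perikymata transects are drawn on the flattest preserved
  areas and worn or highly curved regions are avoided.
* Furrow- versus plane-form discrimination, perikymata counting and
  spacing chronologies are out of scope.
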