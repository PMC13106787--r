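---
title: "Quantifying ventricular curvature formation: methods and design notes"
author: "cardiocurve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ventricular curvature formation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiocurve)
```

## The problem

Between 36 and 48 hours post-fertilization (hpf) the zebrafish ventricle
acquires its characteristic bean shape: the outer curvature (OC) balloons
while the inner curvature (IC) remains recessed. At the cellular level this
asymmetry is carried by cardiomyocyte shape — OC cells flatten and expand
their apical surfaces, elongating along the circumferential axis, while IC
cells stay small and cuboidal — and by the subcellular distribution of the
actomyosin machinery along the basal, lateral and apical membrane domains.

`cardiocurve` implements the quantification workflow for this biology as a
reproducible pipeline: geometric delineation of the OC and IC from arc-length
landmarks, per-cell 3D morphometrics, membrane-domain intensity profiling,
and the hierarchical statistics used to compare groups. Because interactive
segmentation of real confocal stacks is out of scope, the package ships a
seeded synthetic-ventricle generator with exact ground truth, so every stage
is testable end to end without microscopy data.

## The heart model

The ventricle is modelled as a planar-bent tube: a circle of radius
$r_t$ swept along a circular arc of radius $R_b$ through a bend angle
$\Phi$. Viewed in the bend plane — the lateral view in which dissected
hearts are mounted — the convex face is the OC and the concave face the IC.
Surface coordinates are $(s, \theta)$: $s$ is arc length along the long axis
from the atrioventricular canal (AVC) plane, $\theta$ the circumferential
angle ($\theta = 0$ on the OC face, $\pi$ on the IC face).

Defaults are $R_b = 130\,\mu m$, $r_t = 65\,\mu m$, $\Phi = 1.4$ rad, giving
a ventricle about $180\,\mu m$ along its long axis and $130\,\mu m$ across —
sized so the typical regional cell counts tile the two curvature regions at
a realistic packing fraction (about 0.55 on the OC). These geometry values
are modelling choices, not measured quantities.

## Delineating the OC and IC

Landmarks are placed by arc-length fractions, mirroring the measurement
rules used on real hearts:

* $PB_{OC}$ sits one cell diameter (default $10\,\mu m$, configurable) from
  the AVC along the OC arc; $DB_{OC}$ at $2/3$ of the arc from $PB_{OC}$ to
  the distal OFT boundary on that side.
* $PB_{IC}$ sits at the AVC; $DB_{IC}$ at $1/2$ of the arc to the distal OFT
  boundary on the IC side.
* At 48 hpf, Point I is the OC-arc midpoint between $PB_{OC}$ and $DB_{OC}$;
  Point II lies at $1/3$ of the straight segment from $PB_{IC}$ to Point I;
  Point III is the straight-line midpoint of $DB_{IC}$ and $DB_{OC}$. The OC
  is everything on the convex side of the straight cut through $PB_{OC}$ and
  $DB_{OC}$ (the "oblique slicer", extruded perpendicular to the lateral
  view); the IC is the polygon bounded by $PB_{IC}$–II, II–III, III–$DB_{IC}$
  and the IC arc.
* At 36–37 hpf both regions are polygons with straight medial borders
  through Points I–III (OC) and II–IV (IC), placed at $1/3$ and $2/3$ of the
  $PB_{OC}$–$PB_{IC}$ and $DB_{OC}$–$DB_{IC}$ segments; the strip between
  the two medial borders belongs to neither region.

Design choices where the original procedure is interactive or
underspecified:

* The oblique slicer is interpreted as a single straight cut through the two
  landmarks, extruded perpendicular to the lateral-view plane, with the OC
  on the convex side. Where the IC polygon and the OC half-plane could both
  claim a point, the IC takes precedence, keeping the predicates mutually
  exclusive.
* A cell belongs to a region when at least half of its body lies inside the
  boundary; "half of its body" is operationalised as the fraction of the
  cell's lateral-view projected apical area, evaluated on a deterministic
  28×28 point grid spanning the outline. A fraction of exactly 0.5 assigns
  the cell to the region.
* The proximal/distal OC split, used for subgroup reporting, is placed at
  the arc midpoint of $PB_{OC}$–$DB_{OC}$; with no standard split rule
  available, this midpoint is a package convention.
* In mosaic (transplantation) analyses, donor cells qualify when assigned to
  either curvature region; host cells additionally must lie within graph
  distance 2 of a donor cell on the cell-contact graph (direct contact = 1,
  "one cell-distance" = 2).

## Morphometrics

Four metrics per cell:

* **Apical surface area**: the apical outline is projected onto its
  best-fit plane, emulating an en-face snapshot. If the outline bends out of
  plane by more than `curvatureThreshold` (default $1.0\,\mu m$), it is
  split at the transverse plane that best flattens the two halves —
  candidate cuts are scanned across the middle quantiles of the long-axis
  coordinate and the cut minimising the residual out-of-plane deviation is
  kept — each half is projected onto its own tangent plane, and the halves
  are rejoined rigidly along the cut. At most one split is made by default
  (`maxSegments = 2`). On a test outline draped over a cylinder (half-angle
  30° per side), stitching recovers the true surface area within 1.2%,
  against a 4.5% error for a single projection.
* **Circularity**: $4\pi A / P^2$ on the stitched outline; 1 for a circle.
* **Apicobasal length**: two cutting planes through the apical centroid,
  perpendicular to the apical surface and aligned with the outline's
  principal axes (from the second moments of the projected outline; a
  circularly symmetric outline falls back to deterministic fixed axes with
  a warning). Each plane yields a basal width, an apical width and two
  lateral lengths; the apicobasal length is the mean of the four lateral
  lengths.
* **Volume**: mean basal width × mean apical width × apicobasal length.
  This is the reported estimator, kept deliberately: it is *not* the exact
  prism volume. For a square frustum with basal width $b$ and apical width
  $a$ it equals $abh$, which undershoots the true volume
  $\frac{h}{3}(a^2+ab+b^2)$ whenever $a \ne b$ (AM–GM), with equality for
  the cuboid. The test suite pins this bias direction.

## Intensity profiling

Each cell is bisected along both principal axes and each section rasterised
(default $0.3\,\mu m$/px, matching the acquisition slice thickness) with a
membrane guide channel plus F-actin and pMyosin channels: truth intensity in
a 3-px band just inside each membrane, a constant background (default 5% of
the peak truth value), and Gaussian noise (default SD 8 intensity units).
Intensity units are arbitrary throughout; only ratios and fractions are
meaningful.

Band means emulate the wide-line trace: pixels within `width/2` (default
$0.5\,\mu m$ of a $1\,\mu m$ line) of the membrane polyline on its interior
side, after trimming `cornerExclusion` (default $1.0\,\mu m$) from each end
so corner pixels shared with the adjoining membranes are excluded. The
audited pixel set is returned with every mean. Eight band means per channel
(2 basal, 2 apical, 4 lateral) reduce to three domain means; percentages
normalise the three domain means to 100, and the basal ratio is
$\mathrm{basal}/(\mathrm{apical}+\mathrm{lateral})$. No background
subtraction is applied (reported means are raw 8-bit means); with the
default 5% background the recovered percentages are accordingly compressed
by about 2 points, which is a property of the measurement, not a defect —
recovery tests therefore run at zero background. Native intensity precision
is kept; no 8-bit conversion is applied.

Whole-ventricle summaries take one mean myocardial intensity per embryo
(over a myocardium mask), screen each experimental replicate for outliers —
the original workflow names no rule, so Tukey fences ($1.5\times$IQR,
configurable, and an arbitrary flagging function can be supplied) are the
default; flagged values are excluded from statistics but never deleted —
and min-max rescale each replicate to $[1, 10]$ rfu:
$x \mapsto 1 + 9(x - \min)/(\max - \min)$.

## Statistics

* **SuperPlot summaries** keep cell-level values, superimpose per-embryo
  means, and report the grand mean as the mean of embryo means, with
  "N embryos, n cells" per group.
* **Wilcoxon rank-sum**, two-sided, via `stats::wilcox.test`: exact for
  small untied samples, normal approximation with mid-ranks and tie
  correction otherwise. The exact branch is cross-checked in the tests
  against a from-scratch full-enumeration oracle. Comparisons default to
  cell level (matching how group sizes are reported in figure legends);
  embryo-level comparisons are available by passing embryo means. No
  multiple-testing correction is applied, matching the original analysis.
  Stars: \*, \*\*, \*\*\* for $p<0.05, 0.01, 0.001$.
* **Cross-experiment normalization**: each experimental cell is Z-scored
  against the within-experiment control (control mean and sample SD, $n-1$);
  the group mean Z maps onto the reference scale as
  $\mathrm{mean}_{norm} = \mathrm{mean}_{ref} + SD_{ref}\cdot\overline{Z}$.
  The group-mean shortcut
  $(\bar{x}_{exp}-\bar{x}_{ctrl})/SD_{ctrl}$ is algebraically identical for
  $\overline{Z}$. With the wild-type 48 hpf OC apical-area reference
  (mean 142 $\mu m^2$, SD 43 $\mu m^2$) and $\overline{Z} = -0.67$, the
  normalized mutant mean is $113\,\mu m^2$ after nearest-integer rounding.

## The synthetic generator: what it emulates, and what it does not

The generator reproduces the statistical structure the analysis stages
assume: regional cell counts (defaults 55 OC, 28 IC, 60 elsewhere — the OC
and IC counts match the typical reported ranges of ~50–60 and ~25–30),
apical-area distributions (OC default mean 142 $\mu m^2$, SD 43 $\mu m^2$,
the reported wild-type 48 hpf reference; IC mean 80, SD 24 is a free
choice, as no IC value is printed), circumferential elongation of OC cells
(mean ratio 2.2 vs 1.3 in the IC — free choices consistent with the
qualitative reported anisotropy), apicobasal lengths (OC 4.5 µm squamous vs
IC 8 µm cuboidal, free choices preserving the reported ordering IC > OC),
and per-region membrane fraction triplets (e.g. OC F-actin
basal/lateral/apical = 0.45/0.35/0.20; all triplets are free choices —
the corresponding reported values appear only in plots).

Cohort draws use permuted stratified inverse-CDF sampling of the truncated
(> 0) normal: each draw is marginally exact, while cohort moments
concentrate faster than under iid sampling, so a synthetic cohort of
realistic size carries its nominal mean. Tessellation relaxes per-region
seed points with k-means (Lloyd) iterations on area-weighted surface
samples, builds one elongated elliptical outline per seed with *exactly*
the drawn area (Newton rescaling of the surface ellipse against its
projected area), and separates residual overlaps with a deterministic
push-apart pass followed by an exact polygon-overlap resolution pass on the
unrolled surface chart. Cells therefore near-tile the surface without
overlap; a strict Voronoi tessellation is impossible once per-cell areas
are prescribed exactly, and gaps between cells remain.

Not emulated: heartbeat and flow, trabeculation, photorealistic microscope
point-spread functions, segmentation error (ground-truth outlines stand in
for interactive segmentation), and genuine biological covariance between
shape and intensity. Passing recovery tests therefore demonstrate that the
measurement stages are faithful to known geometry and intensities — not
that segmentation of real micrographs would be.

## Numerical choices and degenerate inputs

* Landmark identities hold to $10^{-9}$; face arcs carry analytic arc
  lengths (circular arcs), with 600-point polylines used only for
  interpolation and nearest-point queries.
* Region-fraction estimation uses a 28×28 grid; classification near the
  0.5 threshold is correspondingly approximate (boundary-straddling cells
  are the legitimately ambiguous ones).
* Degenerate inputs error early and name the constraint: infeasible tiling
  (counts × mean area beyond 80% of a region's surface), a cell diameter
  exceeding the OC arc, zero-area projections or sections, empty bands
  after corner trimming, empty masks, zero control SD, equal min and max in
  rfu scaling.
* Determinism: every random stage runs under an explicit seed
  (`withSeed` restores global RNG state); per-embryo and per-image seeds
  derive from the master seed via a fixed affine stream rule, kept below
  $2^{31}$.

## Problem sizes

Tests and reproduction scripts run synthetic cohorts at the sizes the
study design calls for: single default hearts (143 cells), 280-cell
wild-type OC and 220-cell mutant OC cohorts (generated as replicate
synthetic embryos of ~50 OC cells each), 100-repeat landmark and
significance sweeps, and reduced 34–48-cell hearts where only mechanics,
not population statistics, are under test.

## A worked normalization

```{r}
crossExperimentNormalize(expValues = c(8, 10), ctrlValues = c(10, 12, 14),
                         meanRef = 100, sdRef = 10)
normalizeGroupMean(meanRef = 142, sdRef = 43, meanZ = -0.67)
```

## Known limitations

* The volume metric inherits the estimator bias discussed above.
* Tangent-plane projection is only approximately area-preserving; for the
  default cell and tube sizes the residual is well under the 2% round-trip
  tolerance, but strongly curved cells on small-calibre tubes would need
  more than one split.
* The generator's 'neither' region spans the ventricle faces away from
  both curvatures at lower packing than the OC band; its cell density is
  not calibrated to data.
* Region assignment on real (noisy, segmented) outlines has no error model
  here; the ≥95% truth-agreement property is a statement about geometry,
  not segmentation robustness.
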