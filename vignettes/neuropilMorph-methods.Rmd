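---
title: "Serial-section EM morphometry of synaptic complexes: models and methods"
author: "neuropilMorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serial-section EM morphometry of synaptic complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuropilMorph)
```

## The scientific problem

In cortical neuropil, the sizes of the components of a synaptic complex
— the presynaptic bouton, its synaptic apposition(s), and its
presynaptic mitochondria — scale together. This *ultrastructural size
principle* is thought to keep a bouton's energy supply (mitochondrial
surface area) matched to its demand (bouton and synapse size). Its
breakdown, a *decorrelation* of mitochondrion size from bouton size, is
a candidate mechanism for age-related working-memory impairment: aged
subjects without cognitive impairment retain strong mito–bouton
correlations (Pearson r around 0.65–0.69 on raw surface areas), while
an aged, impaired subject can show essentially none (r around 0.19,
not significantly different from zero), together with an elevated
synapse:bouton area ratio and an overall ~28% lower synapse density in
aged tissue.

`neuropilMorph` implements the measurement chain that produces such
numbers from serial-section electron-microscopy (EM) segmentations, and
— because raw EM volumes of this kind are rarely shareable — a
ground-truthed synthetic-neuropil generator that emulates three study
regimes (young adult YA, aged unimpaired AU, aged impaired AI) so every
stage of the chain is verifiable end to end.

## Pipeline overview

1. **Generate** (`sampleComplexes`, `rasterizeComplexes`,
   `generateRegimeDataset`): sample ground-truth synaptic complexes and
   paint them into three 16-bit label channels (boutons, mitochondria,
   synapses).
2. **Sample** (`makeSamplingPlan`, `includeProfile`,
   `qualifiesAsBouton`): select boutons with unbiased counting frames
   on the reference (middle) section and the three-or-more-vesicles
   rule.
3. **Measure** (`extractMesh`, `meshMeasures`, `contactLengths`,
   `synapseArea`, `measureVolumes`): watertight surface meshes for
   boutons and mitochondria; per-section apposition lengths times
   section thickness for synapses.
4. **Classify** (`classifyMito`, `skeletonizeMito`,
   `detectThroughHole`): straight / curved / toroidal mitochondria by
   the 90-degree bend rule, with topology taking precedence.
5. **Stats** (`buildComplexTable`, `sizePrincipleReport`,
   `pearsonCorrelation`, `fisherZCompare`, `model2Regression`,
   `groupTests`, `densities`): the full statistical battery.

`runPipeline()` chains the stages under one seed (each regime and stage
receives a deterministic sub-seed), writes all tables, a manifest and a
run log, and is also exposed as the `neuropil-morph` command-line
script in `inst/scripts/`.

```{r quick-run}
res <- runPipeline(list(regimes = c("YA", "AI"), seed = 1,
                        classify = FALSE,
                        overrides = list(nBoutons = 20L,
                                        volumeDims = c(900L, 650L, 21L))))
res$report
```

(The example shrinks the stack and bouton count so the vignette builds
quickly; analyses in the test-suite and acceptance script run the full
presets, n = 160 boutons in a 20 x 11 µm x 41–57-section stack.)

## The synthetic-neuropil model

### Joint size model

Bouton surface areas are lognormal. Summed synapse contact area and
summed mitochondrion surface area per bouton are tied to bouton area
through a trivariate Gaussian copula on log sizes. Three calibrations
make the *raw-scale* Pearson correlations equal the requested
`rhoSB`/`rhoMB` (the scale on which the size principle is stated and
tested):

* the latent log-scale correlation is obtained by inverting the exact
  lognormal correlation formula
  $r_{\text{raw}} = \frac{e^{\rho\sigma_1\sigma_2}-1}
  {\sqrt{(e^{\sigma_1^2}-1)(e^{\sigma_2^2}-1)}}$;
* the synapse–mitochondrion latent correlation is the product of the
  two latent correlations (conditional independence given bouton
  size), which keeps the latent matrix positive semi-definite whenever
  the pair is feasible;
* because mitochondrial occupancy increases with bouton size (see
  below) and the mito–bouton correlation is evaluated *among occupied
  boutons*, the generating correlation is pre-inflated by the classic
  restriction-of-range relation with
  $u = \mathrm{Var}(z \mid \text{occupied})$ computed from the
  occupancy model. The full chain is exact in population (verified at
  n = 300{,}000).

Occupancy is Bernoulli with probability logistic in standardized log
bouton size (slope 0.7 per log-SD; intercept solved so the marginal
occupancy equals `mitoOccupancy`); this makes mitochondria-bearing
boutons larger on average, as observed. Summed areas are split over
1–3 synapses (Poisson(0.15) extras) and 1–3 mitochondria
(Poisson(0.2) extras) with Dirichlet(4) weights. Vesicle counts are a
per-bouton attribute only (they exist solely to drive the inclusion
rule); a configurable fraction (default 5%) falls below the
three-vesicle threshold.

### Regime presets

The presets (one editable file, `inst/extdata/regimes.yaml`) anchor on
reported study correlations and ratios; absolute scales are declared
synthetic and were chosen once at plausible EM magnitudes:

| parameter | YA | AU | AI | status |
|---|---|---|---|---|
| r synapse~bouton | 0.68 | 0.80 | 0.61 | anchored |
| r mito~bouton | 0.65 | 0.69 | 0.19 | anchored |
| density scale vs YA | 1.00 | 0.72 | 0.72 | anchored (28% reduction) |
| sections (x 60 nm) | 41 | 57 | 57 | 41 anchored; 57 = 41/0.72 |
| bouton area, geo. mean | 0.90 µm² | 1.15 µm² | 1.15 µm² | synthetic (aged > young) |
| summed synapse area | 0.095 µm² | 0.120 µm² | 0.145 µm² | synthetic (ratio larger in AI) |
| summed mito area | 0.14 µm² | 0.17 µm² | 0.155 µm² | synthetic (AU > YA) |
| occupancy | 0.45 | 0.45 | 0.45 | synthetic (constant by design) |
| morphology mix | .80/.12/.08 | same | same | synthetic (straight >> others) |

The density reduction is realized by *deepening the aged stacks at a
fixed bouton count* (160 boutons whose lateral footprints lie in the
18 x 9 µm analysis region and whose bodies cross the reference
section), so all regimes contribute equally many measured complexes —
mirroring the constant ~160 analyzed boutons per subject — while
per-volume densities fall by the intended factor.

### Geometric realization

Boutons are axis-aligned ellipsoids (axis ratios uniform in
0.75–1.25) with surface area matched to the drawn value (Knud Thomsen
approximation, error well below mesh tolerance), placed without
overlap (bounding-sphere rejection, largest first). Mitochondria are
tubes of radius $r$ swept along a planar circular arc of length $L$
and total turn $\theta$ — by Pappus, area $2\pi r L + 4\pi r^2$ and
volume $\pi r^2 L + \tfrac43\pi r^3$ independent of $\theta$ while the
arc radius exceeds $r$ — or solid tori for the toroidal class (tori
lie parallel to the sections so the through-hole survives the section
anisotropy). Three realization rules keep the raster physically and
statistically faithful:

* straight mitochondria are stout (aspect ~1.5, radius at least 0.8
  sections), matching real presynaptic mitochondrion calibre and
  spanning several sections so their meshes measure reliably;
* curved mitochondria must be elongated ($L \ge \max(4.5r,
  280\,\mathrm{nm})$) — a bend whose arc radius approaches the pixel
  scale is not expressible in the raster — otherwise the draw is
  realized as straight (and recorded as such in the truth table);
* a draw too large to fit as one tube is split into side-by-side
  sibling tubes rather than truncated: censoring oversized draws would
  selectively delete small-bouton/large-mitochondrion pairs and
  artificially strengthen the mito–bouton correlation.

Synapses are ribbons on the bouton surface: on each section the
contact is an arc of the bouton's cross-section ellipse whose lengths
follow an elliptic profile across sections and satisfy
$\sum_k \ell_k \times t = A$ exactly. Ribbons sit on the lateral
surface (the patch plane contains the z axis), where the
length-times-thickness estimator is exact; oblique patches would be
underestimated by the sine of their inclination — a bias intrinsic to
the measurement definition, not to this implementation — and the
generator does not emulate them.

### What the generator does *not* emulate

Membrane noise and segmentation error, vesicle geometry, non-ellipsoid
bouton shapes, obliquely inclined synapses, dendrites/spines/glia,
section-thickness variation (55–70 nm in real series; fixed 60 nm
here), and alignment artifacts. Passing tests therefore demonstrate
that the measurement chain is correct *given a faithful segmentation*,
not that segmentation of real micrographs is solved.

## Measurement methods

### Meshing

Per object: crop with padding, box-average the lateral grid when the
object is wide (factor chosen so the crop stays near 36 voxels across;
the averaged occupancy field then carries sub-voxel information),
Gaussian pre-smooth (sigma 1 voxel, clamped to one fifth of the object
extent so small objects never vanish), extract the 0.5 iso-surface by
marching tetrahedra on the Kuhn 6-tet cube decomposition (welded edge
vertices give watertight, consistently oriented meshes whose Euler
characteristic is meaningful), relax with Taubin lambda-mu smoothing,
and finally push vertices along area-weighted normals until the
enclosed volume equals the voxel-count volume (Newton steps clamped to
half a voxel with backtracking — the linearization breaks down on
plate-like objects). Surface area is the triangle-area sum; volume the
signed-tetrahedron sum. On analytic fixtures at radius >= 8 voxels the
mesh area is within 5% (sphere at r = 20: ~0.5%) and volume within 2%.

Anisotropy is the dominant real error source: an object only 2–3
sections thick has a voxel-count volume that depends on its phase
relative to the section grid by up to ~15%, and the volume constraint
propagates that into its area. This is honest serial-section physics;
the generator's realization rules (above) keep most objects thick
enough that it contributes only a few percent of noise.

### Synapse contact areas

Per section, the contact trace is reduced to its longest geodesic path
through the 8-connected pixel graph, the path is smoothed with
endpoints fixed (removing digital zigzag without shortening a straight
trace), and the reported length is the arc length plus one pixel
(half-pixel caps: an n-pixel straight trace measures exactly
n x pixel). Area = summed lengths x section thickness, exactly.

### Counting frames and densities

The reference section is the middle image; its central 18 x 9 µm
region is tiled into four 9 x 4.5 µm (40.5 µm²) frames. Each frame's
top and left edges include, bottom and right exclude (the standard
unbiased-counting-frame convention; the study does not state the
assignment). Pixel squares are treated as closed sets, so corner
touches count as intersections and exclusion dominates ties — a
deterministic worst-case rule that guarantees at-most-once counting
across the shared-edge tiling.

Two denominators are emitted: per sampled volume (frame area x stack
depth; primary) and per reference-section area. Counting objects by
their reference-section profile — the study's procedure, used by the
pipeline to select which boutons are measured — cannot be unbiased for
an arbitrary homogeneous 3D process (the chance of hitting the
reference plane scales with object height). The unbiasedness property
is therefore demonstrated in the regime the estimator can support:
profiles taken as lateral footprints with a top-tip z associated-point
rule (an unbiased brick), under which simulated Poisson placements
recover the generating intensity within a few percent regardless of
object size. The synthetic regimes place every bouton across the
reference section, so for them the two conventions coincide.

One stack of four ROIs per animal is the default (the study describes
four ROIs per stack and eight ROIs per animal from two stacks;
`nFrames` is configurable and the interpretation is written to the run
log). Repeated-measures one-way ANOVAs run on the per-ROI means;
two-way ANOVAs (mitochondria presence x animal) run on bouton-level
rows.

### Mitochondrial morphology

Toroidal takes precedence: a watertight mesh with genus >= 1 (Euler
characteristic <= 0) is toroidal regardless of bend. Otherwise the
bend decides: curved at >= 90 degrees, else straight.

The bend of a rasterized tube is measured from a *sliced centerline*:
voxels are binned along the cloud's principal axis (bins at least 2.5
pixels wide to avoid pixel-grid aliasing) and per-bin 3D centroids —
which cancel the tube radius — form the centerline; the spherical end
caps, whose sliced centroids flatten the curve, are trimmed off. A
least-squares parabola in the centerline's own principal frame gives
the curvature; because a quadratic fitted to a wide circular arc
over-reads the apex curvature, the radius is recovered by numerically
inverting the same fit applied to an exact model arc. Bend = curvature
x corrected centerline length (restoring the half-bin ends and the
trimmed cap arcs). On tube fixtures across radii 60–120 nm the
straight-to-curved transition falls within 90 +/- 5 degrees and
classification is exact when generated bends stay 15 degrees clear of
the boundary.

`maxBendAngle()` separately implements the windowed-tangent bend of an
arbitrary polyline (maximum angle between window-averaged tangent
directions over all window pairs — the total tangent rotation): 0 for
a line, 90 for a right-angle elbow, ~120 for a 120-degree arc at small
windows. It is the right tool for clean polylines; on voxel-derived
skeletons at 60 nm section thickness its window-length bias and
anisotropy noise are why `classifyMito` uses the slicing estimator
instead. Truncated objects are classified from the centerline only —
a hole can never be confirmed — and flagged uncertain.

### Statistics

Correlations are Pearson on raw surface areas (a log option exists but
is off by default: the size principle is a statement about linear
scaling). Model II regression is the reduced major axis:
slope = sign(r) sd(y)/sd(x). Correlation strengths are compared with
the Fisher r-to-z test, $z = (\mathrm{atanh}\,r_1 -
\mathrm{atanh}\,r_2)/\sqrt{1/(n_1-3) + 1/(n_2-3)}$. ANOVAs gate on
Shapiro–Wilk normality of residuals; on failure a Kruskal–Wallis +
Dunn battery is reported *alongside*, never silently substituted.
Tukey's HSD handles within-family contrasts; no additional correction
is applied across response variables. Every correlation reports its n
explicitly (the cohort n for the mito~bouton family is the number of
included, mitochondria-bearing boutons). Welch's t-test is provided
as a generic utility but not wired into the pipeline (behavioural
scores are outside this package's scope).

## Numerical choices and degenerate inputs

* Iso-level 0.5 (minus machine epsilon against exactly-0.5 fields);
  26-connectivity for objects, 6 for background.
* Taubin (0.5, -0.53), 4 iterations; the volume-compensation step, not
  the iteration count, is the normative contract.
* Objects touching the stack boundary are capped flat at the face,
  measured, flagged `truncated_by_stack`, and included in analyses
  (the flag supports sensitivity analyses).
* Empty counting frames yield zero densities and a missing (not zero)
  synapses-per-bouton. Strata with fewer than 4 boutons omit their
  correlation with a logged reason. A report with mitochondria absent
  everywhere still completes.
* All internal quantities are nm / nm² / nm³; µm units appear only in
  report formatting.

## Problem sizes used by the checks

The test-suite and `scripts/acceptance.R` use: 100 truth-table
replicates for copula fidelity (+/-0.02 on the mean sample r); 20
seeded end-to-end replicates per regime at n = 160 for correlation
recovery (+/-0.08); 30 Poisson replicates x 2 size distributions for
counting-frame unbiasedness (5%); 150 fixtures (50 per class) plus a
60–120-degree sweep for the classifier; 100 statistical replicates for
the Fisher-Z separation of AU vs AI. These sizes were chosen so
Monte-Carlo error sits well below each tolerance while a full run
stays at desk scale.

One check is a statistical knife edge by construction: with ~68
mitochondria-bearing boutons per replicate, the alpha = 0.05 critical
r (0.238) sits just above the AI generating correlation (0.19), so
the probability that a single AI replicate is non-significant is only
~0.55–0.65. The "non-significant in the majority of replicates"
signature holds in expectation — and the paper's own AI subject showed
exactly this marginal behaviour (r = 0.19, p = 0.082) — but any fixed
set of 20 seeds can land on either side of 50%.

## Known limitations

* Measured surface areas of objects thinner than ~3 sections carry
  phase-dependent errors up to ~15%; the generator avoids such objects
  where the study conditions allow, real data cannot.
* The skeleton-based bend is a reproducible proxy for a visual
  criterion; bends expressed only in the cutting-plane direction are
  compressed by the section anisotropy.
* The synapse-area estimator inherits the orientation bias of the
  length-times-thickness definition for oblique contacts.
* Absolute densities and sizes are synthetic; only ratios,
  correlations and their contrasts are anchored to reported study values.
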