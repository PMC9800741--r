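---
title: "Recognizing microvascular occlusion in 3D dual-label angiograms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing microvascular occlusion in 3D dual-label angiograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noreflow)
```

## The measurement problem

After an ischemic stroke is recanalized, part of the downstream microvascular
bed can remain obstructed — the *no-reflow* phenomenon. A dual-label
angiography strategy makes this visible ex vivo: one fluorescent vascular
label (e.g. a lectin conjugate) is injected before ischemia and marks **all**
vessels ("existing vessels"); a second, spectrally distinct label is injected
after reperfusion and marks only vessels with restored flow ("functional
vessels"). A microvessel positive for the first label and negative for the
second is **occluded**. Two auxiliary channels refine the picture: an
alpha-smooth-muscle-actin (αSMA) stain marks arteries and arterioles but not
capillaries, and a neutrophil surface marker plus a nuclear stain identify
intravascular neutrophils, a candidate mechanical cause of capillary
plugging.

`noreflow` turns co-registered 3D stacks of these channels into quantitative
per-sample readouts:

* per-edge perfusion labels on a centerline vessel graph;
* the relative occluded volume and the functional/existing length ratio;
* blockage points — the locations where a perfused vessel transitions into
  an occluded one — classified as arteriolar or capillary;
* local lumen diameters from perpendicular normalized-intensity profiles
  (full width at half maximum, FWHM), including a narrowing index at each
  blockage point;
* blockage–neutrophil co-localization fractions.

No public dataset pairs such stacks with ground truth, so the package ships
a synthetic phantom generator whose outputs have complete graph-level truth.
Every quantitative claim the test suite makes is a parameter-recovery
statement on that phantom.

## The phantom generator

### Geometry

`generate_tree()` grows a rooted tree of straight polyline segments inside a
physical domain. The defaults describe a cleared-tissue sub-volume of
192 × 192 × 96 µm sampled at 1 × 1 × 2 µm voxels (anisotropic z, as in
confocal or light-sheet stacks): two arteriole roots of 5 µm radius enter at
the x = 0 face and branch over six generations of short, straight segments
(22 ± 4 µm, branching angle 35° ± 10°), with radii decaying by 0.75 per
generation and floored at the 2 µm capillary caliber. These sizes were
chosen once, for resolvability and realism: the capillary FWHM spans ≥ 4
in-plane voxels, segments are short enough that a sub-volume holds 60–100 of
them, and deep generations are not starved by boundary clipping. Growth is
collision-aware — a segment that would bring two unrelated branches within
fusing distance is re-aimed or dropped — because real capillaries do not
merge, and fused tubes would be inseparable for any skeleton-based method.

### Occlusion

`apply_occlusion()` expresses occlusion **only through labels**: occluded
edges are omitted from the functional channel while the existing channel
always shows the full geometry, exactly mirroring the dual-label design.
Subtrees to occlude are selected by a seeded greedy pass over all interior
edges that accepts a candidate only if its subtree

* is topologically and spatially disjoint from every previously accepted
  subtree (down to a clearance larger than the mask-closing diameter, so
  two distinct occluded subtrees can never weld into one component in the
  segmented image);
* is long enough to resolve (≥ 12 µm in total; its entry edge clears the
  parent junction tube), since a blocked stub shorter than the spur-pruning
  scale is undetectable in principle;
* does not touch any outside branch beyond its own entry junction (again,
  down to mask-closing clearance).

The pass runs to exhaustion, producing a maximal decomposition of M
disjoint blocked subtrees; `blocked_subtree_fraction` then occludes the
first `round(fraction * M)` of them. Because the selection is a nested
prefix, raising the fraction strictly grows the occluded set — which is what
makes the time-course emulation (progressively worsening obstruction at
longer reperfusion times) strictly monotone by construction. Root trunks are
never candidates: after recanalization the feeding artery is patent, and a
block starting at the volume face would have no visible
functional-to-occluded transition to detect.

Each blocked subtree receives one blockage point at the upstream end of its
entry edge, a tent-shaped radius dip there (`narrowing_depth`, default 0.5
over a 5 µm half-width) recording a true minimum diameter of
`2 r (1 − depth)`, an intravascular neutrophil immediately downstream for a
fraction of blockage points (default 0.3), and extravascular perivascular
nuclei as distractors. Edges whose mean radius exceeds
`asma_radius_threshold_um` (default 3 µm) carry αSMA signal.

### Imaging

`render_channels()` paints channels as filled tubes of local radius
(lectin labels endothelium, but at this imaging scale vessels appear as
filled tubes) and cells as spheres, then applies a Gaussian PSF
(default σ = 0.6, 0.6, 1.8 µm), a constant background (0.03), Poisson shot
noise (80 expected photons at unit signal) and Gaussian read noise
(sd 0.01). All randomness derives from the tree seed, so a phantom is fully
reproducible from one integer. `noiseless_imaging()` disables every
degradation; in that limit the functional channel is exactly the subset of
the existing channel over functional edges.

What the phantom does **not** emulate: clearing-induced tissue deformation,
illumination falloff and stitching seams, red blood cells and platelets, the
hollow-tube appearance of very large vessels, and flow physics of any kind.
Passing recovery tests on the phantom therefore demonstrates that the
algorithms are correct and well-calibrated for resolvable, well-labeled
vasculature — not that they are robust to every artifact of a real cleared
brain.

## Segmentation and graph extraction

`segment_vessels()` subtracts a wide-Gaussian background estimate (default
σ = 40 µm, computed with an O(N) three-pass box filter), thresholds the
residual, closes the binary result with a 1.5 µm Euclidean ball and removes
components below 50 voxels. The threshold is *half* of the 99.9th-percentile
residual value: the percentile estimates the brightness of vascular
structure (vessels occupy well under a percent up to a few percent of the
volume, so a high percentile lands inside the vessel intensity mode, not the
noise), and cutting at half that height makes the mask boundary track the
half-maximum of bright structures — consistent with the FWHM convention used
for diameters. A `median + 8·MAD` noise floor keeps a nearly empty channel
(total no-reflow) from thresholding into speckle, and a fixed threshold
override is available.

`skeletonize_graph()` resamples the mask to isotropic voxels at the smallest
voxel size (3D thinning assumes isotropy), lightly smooths the indicator
(σ = 0.5 µm) to suppress noise-induced surface roughness that would
otherwise seed spurious branches, and thins the volume to a curve skeleton
by sequential, re-checked deletion of simple points (topology-preserving;
endpoints kept; six border directions in a fixed scan order, so the result
is deterministic). Skeleton voxels with other than two neighbors become
nodes; chains become polyline edges. Clean-up follows the usual order:
terminal spurs shorter than `max(2 × local radius, 5 µm)` are pruned,
sliver edges between junction clusters are contracted, degree-2 chains are
re-merged, polylines get a short moving-average smooth (staircase length
bias), terminals are re-grown along their tangent while they remain inside
the mask and clear of the end cap (the distance transform falls off inside
the cap), and per-point radii are attached from the anisotropic Euclidean
distance transform.

## Perfusion classification

`classify_edges()` discretizes the dual-label rule as a per-edge majority
vote: each edge's centerline is sampled every 1 µm against the functional
mask dilated by a 2 µm registration slack, and the edge is functional iff
the covered fraction is at least `coverage_tau` (default 0.5). Both
parameters are reported in output provenance. An edge whose coverage
switches between persistent covered and uncovered runs (≥ 6 µm each) is
split at the transition first — a traced edge that straddles a blockage must
not be forced into a single label, and the split point is itself the best
sub-edge localization of the transition. Raising `coverage_tau` can only
move edges toward "occluded", so the classification is monotone in its
threshold; on noiseless phantoms with zero dilation the labels equal the
generator truth exactly.

`quantify_occlusion()` integrates tube volume as Σ π r(s)² ds along each
edge (default) or assigns mask voxels to nearest edges ("voxel" method),
and reports the occluded volume fraction and the functional length ratio,
optionally restricted to a region mask by the edge-midpoint rule.
Normalization is per-sample to the existing-vessel total of the same
volume; no contralateral reference is assumed.

## Blockage points

`detect_blockage_points()` takes the maximal connected components of
occluded edges (components separated by a gap below 4 µm are clustered —
an imaging gap across a severe constriction can sever one occluded subtree
into fragments, and a fragment with no functional contact at all may rejoin
across a wider gap; truth-side subtree clearances are larger than these
tolerances, so distinct subtrees cannot be merged). Components shorter than
8 µm are discarded as noise fragments. Each component yields one point at
its abutment with the functional network; when several junctions abut, the
one with the thickest occluded contact wins (radius decays root-to-leaf, so
crossing artifacts on thin capillaries lose). The point is refined along the
entry edge to the last functional-covered centerline sample, pulled back by
the dilation slack plus half the local radius (the parent lumen covers the
entry's first stretch regardless of dilation). Components with no
functional contact are *orphans*: if the perfused network passes within
12 µm, the point is placed at the midpoint of the closest approach (the
blockage sits inside the severed gap); otherwise at the component's
lexicographically smallest endpoint, flagged as such.

`classify_vessel_type()` samples the host edge's centerline *away* from the
junction with a 3 µm standoff before testing αSMA coverage — the αSMA tube
of an arteriolar feeder would otherwise bleed into the classification of a
capillary blockage sitting at the feeder's junction.

## Diameters

`diameter_profile()` samples intensity by trilinear interpolation along a
line perpendicular to the local centerline tangent (profile length
`max(6 × local radius, 10 µm)`, step half the smallest voxel size), min-max
normalizes over the window, and takes the FWHM between the two half-maximum
crossings bracketing the center, each located by linear interpolation. Two
orthogonal perpendicular directions are measured and averaged (anisotropy),
the distance-transform diameter `2r` is attached as a cross-check, z-dominant
tangents trigger a warning (axial PSF inflates the width), profiles leaving
the volume are shortened symmetrically, and a flank without a half-maximum
crossing leaves the FWHM undefined with the profile flagged. On noiseless
binary cylinders the estimator is exact to one in-plane voxel across the
3–12 µm range; odd diameters can read one voxel low from rasterization
parity. One caveat worth stating: for a *filled* tube the FWHM is largely
insensitive to blur up to σ of about half the radius and can dip by a
sampling step in that regime before growing monotonically — the PSF-bias
property is therefore tested as non-decreasing within half a sampling step,
with strict growth from zero to large σ.

`diameter_distribution()` samples profiles every few µm along
(optionally capillary-caliber, optionally region-restricted) edges and
returns a relative-frequency histogram with 0.5 µm bins;
`aggregate_diameter_histograms()` averages per-sample histograms with equal
weight, matching a per-animal mean ± SEM presentation. Diameters are
measured on the existing channel, since occluded vessels carry no
functional signal.

## Neutrophil co-localization

`detect_neutrophils()` implements the conjunction rule: a detection counts
as a neutrophil iff a marker blob of neutrophil size (equivalent diameter
4–12 µm) overlaps a nucleus blob and its centroid lies inside the vessel
lumen (existing mask dilated by 1 µm). Blobs are cut at half their peak
brightness — as for vessels, the apparent size then tracks the object, not
the threshold — with a mean + 5·sd noise floor. Running without a nucleus
channel weakens the rule to marker-only and warns prominently.
`colocalize_blockages()` calls a blockage point "with neutrophil" iff at
least one intravascular neutrophil centroid lies within
`matching_radius_um` (default 10 µm, about one neutrophil diameter; the
criterion is configurable and echoed in the report), and reports the
fraction without, plus a neutrophil density per mm of existing-vessel
length so differently sized volumes remain comparable.

## Pipeline and reproducibility

`run_pipeline()` chains segmentation → perfusion recognition → blockage
analysis → co-localization, skipping stages whose channels are absent,
and writes CSV/JSON reports, SWC and JSON graph exports, a run log and a
manifest with an MD5 hash for every output plus the full parameter
provenance. All randomness is seeded from the configuration, so identical
config and inputs give byte-identical reports. `inst/cli/noreflow.R` is a
thin Rscript wrapper with `simulate` and `run` subcommands over these same
functions.

## Validation problem sizes

The automated validation uses phantoms at the generator defaults
(192 × 192 × 96 µm, ≈ 3.5M voxels, 60–100 edges, typically 3–7 blocked
subtrees), five seeds per property, plus a smaller high-resolution field
(144 × 144 × 72 µm at 1 × 1 × 1.5 µm) for the diameter-shift comparison,
where the 0.8× group's capillaries would fall below the resolvability
guard at 2 µm z-sampling. These sizes give each recovered fraction a few
dozen edges and each pooled detection statistic 20–30 events — large enough
for the stated tolerances, small enough to run routinely.

## Known limitations

* Edge-level perfusion labels inherit the skeleton's topology; a vessel
  fused to another by imaging resolution is classified as one object.
* Blockage localization degrades to ~5 µm when the constriction severs the
  mask; the orphan-gap heuristic recovers most but not all of these.
* FWHM diameters are biased upward by the PSF (reported, not corrected);
  comparisons between groups imaged identically are unaffected to first
  order, which is the design of the group-shift validation.
* The phantom's noise model (Poisson + Gaussian on a clean background) is
  optimistic for cleared tissue; absolute error rates on real stacks will
  be worse than the phantom recovery numbers.
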