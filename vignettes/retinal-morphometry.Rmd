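---
title: "Measuring retinal vascular architecture from segmentation masks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring retinal vascular architecture from segmentation masks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`retinavasc` measures vascular architecture downstream of segmentation: its
inputs are binary artery, vein and optic-disc masks plus a physical pixel
spacing, and its output is a per-eye vector of morphometric parameters.
This vignette records the measurement model, the choices behind every
tunable threshold, what the synthetic-data generator does and does not
emulate, and the known limitations.

## The measurement model

### From mask to centerline graph

Each class mask is thinned by Zhang–Suen iteration to an 8-connected,
one-pixel-wide skeleton. Thinning output is then passed through a
minimality pass that deletes any pixel whose foreground neighbours are
already mutually 8-connected without it. This matters: raw thinning leaves
staircase and corner pixels with three neighbours, and on a typical
simulated eye several hundred of them would otherwise masquerade as
junctions. After cleanup, a path pixel has exactly two non-adjacent
neighbours, so the pixel graph is unambiguous: one neighbour = endpoint,
three or more = junction pixel.

Junction pixels that touch merge into one node. Two further repairs address
systematic thinning artifacts at wide junctions, both scaled by the local
caliber because the artifacts are blob-sized:

* a wide Y-junction is frequently split into two or three nearby
  T-junctions; junction nodes connected by a centerline path shorter than
  `junction_gap_factor` (default 1.2) times the *junction* caliber — the
  widest incident segment, not the often-thin crotch connector — are merged;
* contraction can leave short self-loops (junction triangles around a
  crotch hole); loops shorter than three local widths are dropped.

Per-point caliber is twice the Euclidean distance transform of the source
mask sampled on the centerline, times the pixel spacing. This is the
standard caliber proxy; it overestimates odd pixel widths by about one
pixel, which is visible as a small positive bias in absolute caliber but
cancels in ratios such as the asymmetry index.

Terminal segments shorter than `spur_width_factor` (default 2) times their
outer-half caliber are pruned as skeletonization spurs, iterating to a
fixed point and splicing through any node left with degree 2 (the operation
is idempotent). Genuine thinning spurs are about one caliber long, while
anatomical terminal branches run several calibers, so a factor of 2
separates the two populations cleanly; at a factor of 3 we observed real
short, wide terminals being pruned, which silently deletes their
bifurcations. The outer-half caliber is used because the distance transform
is junction-inflated near the attached end.

### Zones

The optic disc is summarized as the circle with the mask's centroid and
equivalent-area diameter `2*sqrt(area/pi)`; "disc diameter" (DD) is the
scalar unit for all zone radii. Zones are annuli measured outward from the
disc *edge*: A = (0, 0.5] DD, B = (0.5, 1] DD, C = (1, 2] DD, with boundary
points assigned to the inner zone (half-open outward). Distances are taken
from the fitted circle rather than the raw mask boundary, which makes zone
membership robust to mask noise. A bifurcation belongs to the zone
containing its node; segments are truncated at zone boundaries.

### Branching statistics (Zone C)

At every degree-3 node the parent is the branch whose direction points back
toward the disc (vessel trees are disc-rooted; this is more robust than the
widest-branch rule when parent and major daughter calibers are within
measurement noise of each other — without zone information the caliber rule
is used). Each branch direction is a least-squares line fit over a
caliber-scaled window: skip `skip_widths` = 1.5 local widths of arc from
the node, fit over `fit_widths` = 4 widths. The skip clears the junction
blob, where the medial axis is biased by the crotch boundaries (measured
angles inflate by roughly 10 degrees if directions are fitted immediately
past the node); the long fit window defines the angle at the scale of the
vessel caliber, below which a branch direction is not meaningful on a
discrete skeleton. These two window factors were calibrated once against
the simulator's ground truth and then frozen; the same window convention is
used when the simulator computes its true angles, so truth and measurement
quantify the same geometric object.

The asymmetry index is `100*(1 - (w_min/w_max)^2)` on the daughter calibers
sampled in the same windows — the squared-caliber form, which lives on the
0–100 scale conventional for this quantity. `branch_avg` is the mean number
of Zone C bifurcations per disc-rooted tree, where a tree is a connected
component with at least one node inside Zone A; the per-image total is a
config alternative (`count_crossings_as_bifurcations` likewise exposes the
choice of treating degree-4 nodes as bifurcations instead of excluding them
as crossing suspects; degree ≥ 5 nodes are always excluded).

### Lengths and tortuosity (Zone C)

Pixel chains overestimate oblique straight lines by up to ~8%, so polylines
are smoothed with a centered, end-preserving moving average
(`smooth_window` = 5 points) before arc-length and direction computations.
Junction positions are additionally refined before length measurement
(`refine_junctions`): each junction is relocated to the least-squares
intersection of the incident branches' direction lines, and the
blob-interior run of each incident segment is replaced by a straight step
from the refined point. Without this, every junction loses 30–50 µm of arc
to the skeleton's shared bisector path, a 5–10% negative bias on mean
segment length at retinal calibers; a guard skips the snap when the
straight step would double back on the branch. Zone-clipped pieces shorter
than `min_piece_um` = 60 µm (boundary-crossing fragments) are excluded from
both averages, in measurement and in simulator truth alike.

Tortuosity is the arc-chord ratio; pieces with coincident endpoints
(closed loops) return `NA` with a warning and are excluded from the mean.

### Fractal panel

Box counting uses a dyadic ladder from `min(h, w)/4` down to
`box_min_size` = 4 px on a single origin-anchored grid, which keeps counts
deterministic. D0 regresses `log N(eps)` on `log(1/eps)`; D1 uses the
Shannon box entropy (the q→1 limit, avoiding the 1/(q−1) singularity); D2
regresses `log sum p^2` on `log eps`. The singularity length is the width
`alpha_max - alpha_min` of the Legendre spectrum of tau(q) over
q ∈ [−3, 3] in steps of 0.5, with alpha(q) from central differences;
negative-q masses use occupied boxes only, and any q whose tau fit falls
below R² = 0.9 is dropped with a warning (all dropped → missing value).

The estimators were validated against closed forms: a line, a filled square
and a Sierpinski gasket give D0 within ±0.05 of 1, 2 and log3/log2, and a
binomial multiplicative cascade (p = 0.7) reproduces its analytic
D0/D1/D2 (1, 0.881, 0.786) and truncated spectrum width. One caveat is
recorded as a known limitation: on near-uniform measures such as vessel
centerlines, finite-range regression estimates can invert the theoretical
ordering D0 ≥ D1 ≥ D2 by a few hundredths. This is a property of
finite-scale box counting (grid-offset averaging does not remove it), not
of the implementation, which is exact on analytic multifractals.

### Calibers

CRAE/CRVE take the per-segment median caliber of Zone B segments as trunk
calibers (median is robust to junction bulges), keep the six largest
(`knudtson_n_largest`), and reduce them pairwise — sort, combine the
current largest with the current smallest via `W = c*sqrt(W1^2 + W2^2)`
(c = 0.88 arterial, 0.95 venular), carry the median element of odd rounds —
until one equivalent remains. Whether six or all trunks enter is
configurable; six is the conventional protocol. The reduction is symmetric
in each pair, scale-equivariant and monotone, properties the test suite
checks against an independently written pairing oracle.

### Densities

`vessel_density` is the artery∪vein mask fraction and
`vessel_length_density` the artery∪vein skeleton fraction of the analysis
region — the full image by default ("overall" density), optionally the
disc-centered field of radius 2 DD beyond the disc edge
(`density_region = "2dd"`). The zone restriction applies only to
branch/length metrics; the denominator choice for densities is exposed
rather than inferred.

## The synthetic-data generator

`grow_tree` emulates a disc-centered 45°-style field scaled to a 512 px
canvas at 10 µm/px with a 400 µm disc radius: four trees per class rooted
on the disc margin, radially oriented, with one deterministic bifurcation
level inside Zone C and a second stochastic one (`branch_prob` = 0.85), so
control eyes carry about 2.8 Zone C bifurcations per tree — the range
reported for real eyes. Branch angles (artery 88° ± 13, vein 77° ± 13),
squared-caliber asymmetry (44/38 ± 12), arc-chord tortuosity (1.10 ± 0.02),
root calibers (120/142 µm, which reduce to CRAE/CRVE near the literature's
185–260 µm range) and segment lengths were all chosen once to sit at
realistic values. Daughter calibers follow the cube-law split implied by
the sampled asymmetry index with a 0.92 taper; headings split the sampled
angle in proportion to the opposite squared caliber, so the wider daughter
hugs the parent axis.

Tortuosity is realized as a sinusoidal perpendicular displacement with a
sin² envelope — zero displacement *and* zero slope at both ends, so node
positions and node-local headings are unperturbed — with the amplitude
solved by quadrature and bisection to hit the sampled arc-chord ratio
(wavelength 1000 µm; much shorter wavelengths make the branching angle
ill-defined at the caliber scale and were rejected for that reason). Each
tree owns an angular sector about the disc center; bifurcations split their
sector between daughters, candidate headings are shrunk toward the local
radial direction until their straight course stays in-sector out to just
beyond the Zone C outer radius, and a daughter pair is redrawn (up to 15
times) until the two strokes clear each other beyond the junction zone.
Sectors narrower than 25° stop bifurcating. These constraints guarantee
resolvable junctions and non-intersecting trees, which is what makes exact
branch-count recovery a meaningful test.

What the generator does *not* emulate: artery-vein crossings within one
mask (classes are rasterized separately, so crossings exist only between
classes), central reflex and caliber variation along a branch, pathology
(microaneurysms, neovascularization), segmentation noise (ragged edges,
gaps, false positives), and the fovea. Passing recovery tests therefore
demonstrates correctness of the measurement chain on clean, resolvable
geometry; they do not certify behavior on noisy clinical segmentations,
where quality flags (`validate_quality`) and the crossing-suspect exclusion
carry more weight.

`generate_cohort` seeds each image from the cohort seed and image index,
applies per-group parameter overrides, and stores the ground-truth ledger.
The default NPDR-like group follows the reported effect directions for
mild-to-moderate NPDR: fewer venous branches (`branch_prob` vein 0.55),
longer segments, smaller venous angle and asymmetry, and ~7% narrower
calibers (lower densities).

## Statistics module

Routing mirrors the conventional workflow: parametric (ANOVA with
unadjusted Fisher-LSD pairwise t-tests, mean ± SD descriptives) only when
every group passes Shapiro–Wilk and the set passes Levene at α = 0.05;
otherwise Kruskal–Wallis with pairwise Mann–Whitney tests and
median (P25, P75); two-valued variables go to chi-square. Pairwise p values
are unadjusted by default to mirror the LSD convention (`p_adjust = "holm"`
is available). The logistic screen enters all pre-screened predictors in a
single block and reports β, Wald χ², SE, p, OR = exp(β) and the 95% CI
exp(β ± 1.96·SE); perfect separation is flagged and coefficients
suppressed. ROC curves are empirical with trapezoidal AUC; for markers
negatively associated with the outcome the orientation is flipped so
AUC ≥ 0.5 and the direction is reported; the operating point maximizes
Youden's J. AUC is verified against the normalized Mann–Whitney U on every
test fixture, which ties the two modules together.

## Problem sizes and determinism

The validation suite runs the full pipeline on 512×512 images: a 50-image
cohort for parameter recovery (branch counts exact; angle within ±3°,
asymmetry within ±5 points, mean length within 5%, mean tortuosity within
2% of ground truth) and a 100-image two-group cohort for the end-to-end
effect-direction check — sizes chosen to keep the whole suite under a few
minutes on one CPU while leaving the statistical checks well-powered.
Everything downstream of a seed is deterministic: same seed, same masks,
byte-identical CSV.

## Known limitations

* Absolute calibers inherit the +0.5–1 px distance-transform bias; CRAE,
  CRVE and asymmetry are consistent internally but not sub-pixel accurate.
* The D0 ≥ D1 ≥ D2 ordering can invert by ≲ 0.04 on near-uniform
  centerline measures (see above); compare fractal values only across
  images measured with the same box ladder.
* Crossing disentanglement is out of scope: degree-4 nodes are excluded
  from branching statistics, not resolved into two vessels.
* The singularity length depends on the q-range and R² floor; values are
  comparable only under a fixed configuration.
* Tortuosity of very short clipped pieces is discretization-limited; the
  60 µm piece floor bounds, but does not eliminate, this effect.
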