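---
title: "Quantifying equine dorsal posture: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying equine dorsal posture: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equimorph)
```

## The problem

Chronic posture is increasingly used as a welfare indicator in horses: animals
living under poor conditions tend to carry a flatter, sometimes hollow, dorsal
profile — flat neck, prominent withers, flattened croup. `equimorph`
implements the full quantitative chain needed to test such associations:

1. landmark-based **geometric morphometrics** of the dorsal outline, digitized
   as 30 ordered points from the first coccygeal vertebra (point 1) over the
   withers (point 15) to the medial canthus of the eye (point 30);
2. **rule-based scoring** of three welfare indicators — stereotypic/abnormal
   repetitive behaviour (SB/ARB), the depressed-like posture, and the
   favourite ear position;
3. **mixed-model ANOVA** linking principal components of shape to the
   indicators, with the individual as a random factor because every horse is
   photographed repeatedly.

Because no photograph archive ships with the package, a synthetic
dorsal-profile generator reproduces the statistical structure the analysis
assumes, so every stage can be exercised and validated end to end.

## Superimposition

Shapes are compared after removing position, scale and orientation with
**Generalized Procrustes Analysis** (partial Procrustes): each configuration
is centred, scaled to unit centroid size, rotated onto the running consensus,
and the consensus re-estimated until its relative change falls below `1e-8`
(at most 100 iterations; non-convergence is flagged, not raised). The planar
least-squares rotation has a closed form, and reflections are never used —
orientation is normalized beforehand with `flip_horizontal()`, since the
anatomical point order (croup to head) must not be mirrored silently.

Two conventions make results reproducible across runs and input orderings:
the final consensus is reported as the plain coordinate-wise mean of the
aligned shapes, and the whole aligned sample is rotated so that the consensus
baseline (point 1 to point 30) lies along the +x axis. The second rule means
the output does not depend on the orientation of whichever photograph happened
to come first.

## Sliding semilandmarks

Only some of the 30 points are anatomically homologous. Two schemes are
provided:

* **SSL** — only the eye (point 30) is a fixed landmark; the 29 outline
  points slide. This minimizes the influence of landmark placement error.
* **mixed** — eight anatomical points are fixed (the seven clay-marked
  skeletal cues plus the eye) and the remaining 22 outline points slide. The
  outline indices of the seven marks between croup and eye are not uniquely
  fixed by anatomy; the default `c(1, 4, 8, 15, 24, 27, 29, 30)` follows
  their order along the spine (coccygeal vertebra, lumbo-sacral junction,
  thoraco-lumbar junction, withers, atlas, temporo-mandibular joint, facial
  crest, eye) at plausible outline positions, and is configurable in
  `method_scheme()` for digitizing protocols that place them elsewhere.

Sliding minimizes **thin-plate-spline bending energy** toward a reference.
With kernel `U(r) = r^2 log r` the bending matrix `B` is the upper-left block
of the inverted TPS system; the energy of a configuration `(x, y)` relative
to the reference is `x'Bx + y'By`, zero exactly on affine images of the
reference. Each sliding point moves only along its local tangent (central
difference of its curve neighbours, one-sided at the window ends); the
optimal magnitudes solve a small linear system, so each pass can only
decrease the energy toward the current reference. The reference is the GPA
consensus, recomputed each pass (superimpose, slide, re-superimpose), for at
most 5 passes or until the per-pass energy drop falls below `1e-6`. Points
are not re-projected onto the originally digitized curve — that curve is not
recoverable from TPS records, so the tangent-plane variant is used.

Because a near-straight outline makes the TPS system ill-conditioned, the
sliding system is solved with a minimum-norm fallback when tangent moves fall
into the affine null space; degenerate references (collinear, coincident)
raise errors rather than being regularized silently.

## Neck-angle stabilization

The balance movement of the neck is a rigid rotation of the neck-and-head
chain about the withers and is posture noise for most questions about the
back. `stabilize_articulation_angle()` cancels it by rotating points 16–30
about point 15 so that the angle formed by points 1–15–30 is identical in
every photograph (the sample circular mean by default — no reference value is
canonical, and the mean keeps the sample centred on its own posture).
Stabilization runs *before* superimposition and only on full-outline
analyses; region-restricted analyses (back and croup, points 1–15; neck and
head, points 15–30, the withers point belonging to both windows) leave it
off.

## Ordination and deformation grids

PCA is computed on the covariance of the flattened Procrustes coordinates —
the standard choice for shape data, where all variables share units. Loading
signs are fixed by making each component's largest-magnitude entry positive,
so score signs are deterministic. `shape_at_score()` reconstructs
`consensus + score * loading`, and `deformation_grid()` warps a regular
lattice (10% margin, 24 nodes on the long axis by default — presentation
parameters only) by the TPS carrying the consensus onto the shape at the
observed minimum or maximum of a component, drawn grey for the consensus, red
for the minimum, blue for the maximum.

## Welfare indicator rules

* **SB/ARB**: a horse scores 1 when some behaviour was observed as at least
  5 events, each of at least 3 successive repeats of the sequence,
  independent of observation time. Events of different behaviours never
  combine, and runs shorter than 3 never count, so the score is monotone in
  added observations.
* **Depressed-like posture**: 1 when seen at least once.
* **Ear position**: over exactly 10 foraging scans, `forward` or `backward`
  when that category reaches 60% (6 scans); otherwise `neutral`
  (asymmetric/lateral positions count as neutral). A 5/5 split is neutral
  because 60% is not reached.
* **Prevalence** is reported raw and rounded half-up to integer percent, the
  style used in published prevalence tables.

## Statistical linkage

Per-photo PC scores are tested against horse-level factors with a
random-intercept model `score ~ factor + (1 | horse)` fitted by REML
(`lme4`). The reported F is the Wald F for the factor; since all tested
factors are constant within individual, the denominator degrees of freedom
follow the containment rule, `n_individuals − n_levels`. When the
between-individual variance is zero and the design is balanced this reduces
to the classical one-way ANOVA on photo values — a property the tests check.
Quantitative covariates are related to per-horse mean scores by Pearson
correlation; qualitative pairs use the chi-square test, with a Monte Carlo
p-value (tables resampled with both margins fixed,
`p = (1 + #{X² ≥ obs}) / (reps + 1)`, 2000 tables by default, seed required)
whenever a count falls below 5; quantitative-vs-qualitative uses
Kruskal–Wallis. All decisions use the 5% level, and no correction is applied
across the PC × indicator grid by default (a Holm option would be easy to add
at the table level; the per-test objects expose raw p-values).

## The synthetic generator

`generate_profile()` draws a deterministic smooth outline: a gentle sinusoid
over arc length plus Gaussian bumps — a croup arch (points 2–7), a narrow
withers bump (point 15), a neck arch (points 16–29) — with the head segment
(points 27–30) scaled relative to the neck and the neck-and-head chain
rotated so the 1–15–30 angle equals `head_neck_angle` (measured as the
dorsal-side opening, in (90°, 270°); values above 180° give a reflex, hollow
carriage). x is strictly increasing croup→head; parameter combinations that
would fold the outline are rejected.

`generate_population()` adds the three layers of variation the analysis must
cope with:

* **between individuals** — Gaussian deviations of every profile parameter
  (SDs: withers 2, neck 2.5, croup 2 units; angle 3°; head size 0.08), with
  the poor-welfare group shifted by `delta = 1.5` of those SDs toward more
  prominent withers, a flatter neck and a relatively smaller head;
* **between photographs** — isotropic landmark jitter (SD 2% of the
  croup-to-head length) and a random rigid neck swing about the withers
  (SD 5° standing, doubled when walking, where 20 photographs are taken
  against 10 standing);
* parameter draws are clamped to plausible ranges and redrawn when the
  outline would self-fold, all deterministically under one master seed split
  into per-stage streams.

The bump amplitudes (base withers 6, neck 10, croup 8 on a 100-unit
baseline) were set once so that postural differences are large relative to
digitizing jitter — features of a few percent of trunk length, which is what
clay-marked photographs resolve. With weaker features the 2% jitter dominates
and no method can recover the group effect at these sample sizes.

What the generator does **not** emulate: perspective distortion, digitizer
bias that varies along the outline, correlated (non-isotropic) landmark
error, allometry, or any biomechanical coupling between parameters. Passing
recovery tests therefore shows the pipeline recovers effects of the assumed
structure and magnitude — not that real photographs carry them.

`generate_observation_streams()` writes behaviour streams consistent with a
record table by construction: SB/ARB-positive horses get ≥5 qualifying events
of one behaviour, negative horses get streams that fail either the 5-event or
the 3-repeat arm of the rule; ear scans are drawn to match the recorded
favourite category.

## Validation strategy and problem sizes

The test suite checks every operation against an independent oracle where one
exists: closed-form centroid size, an exhaustive rotation grid search,
`vegan::procrustes` for the two-shape case, a hand-assembled five-point TPS
system, a 1D grid search for a single sliding point, exact enumeration of
2×2 tables for the Monte Carlo chi-square, and the rank-sum formula for
Kruskal–Wallis. Simulation suites use 500 null replicates for the mixed
ANOVA's size (rejection rate expected in [0.02, 0.09] at α = 0.05), 200
replicates for its power at a 1.5-SD effect with 40 individuals × 10 photos
(expected ≥ 0.8), and 100 full-pipeline replicates at the default population
spec for end-to-end recovery, run with and without neck stabilization. These
sizes give simulation standard errors of about 1–4 percentage points, small
enough for the bands tested.

At the default conditions the recovery rate saturates near 100% in both
stabilization modes, so the benefit of stabilization is not visible as a
power difference there; it is visible — and tested — as the collapse of
within-individual neck variance to the jitter level once the swing is
removed.

## Degenerate inputs and numerical choices

* Coincident points (zero centroid size), rank-zero rotations, collinear TPS
  references and zero-margin contingency tables raise informative errors.
* A sample of identical shapes has zero shape variance; `shape_pca()` refuses
  it rather than returning all-zero scores.
* GPA tolerance `1e-8` on consensus change and sliding tolerance `1e-6` on
  energy drop sit far below landmark noise; both are exposed as arguments.
* All-tied Kruskal–Wallis input returns a flagged degenerate result
  (`statistic = NA`, `p = 1`) instead of dividing by zero in the tie
  correction.

## Known limitations

* 2D only; no curve re-projection during sliding; no allometric or
  phylogenetic corrections.
* The containment denominator df is exact for balanced between-subject
  designs and conservative-to-approximate otherwise; Satterthwaite or
  Kenward–Roger approximations are deliberately out of scope.
* The mixed scheme's default fixed-landmark indices are a documented
  convention, not a measured fact about any digitizing protocol; override
  them when yours differs.
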