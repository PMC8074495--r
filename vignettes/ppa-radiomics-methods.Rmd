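---
title: "Optic-disc-region radiomics for myopic maculopathy: models and methods"
author: "ppaRadiomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optic-disc-region radiomics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Pathologic myopia remodels the posterior pole: the optic disc tilts and
rotates, the peripapillary atrophy (PPA) crescent widens and brightens,
and the chorioretinal texture around the disc coarsens. Myopic
maculopathy (MM) is graded on the META-PM scale (C0 no lesions, C1
tessellated fundus, C2 diffuse atrophy — split into peripapillary PDCA
and macular MDCA — C3 patchy atrophy, C4 macular atrophy); eyes graded
MDCA or worse, or showing plus lesions (lacquer cracks, myopic CNV,
Fuchs' spot), form the *severe* group. This package quantifies the
optic-disc region of a color fundus photograph with a fixed bank of
radiomic features and mines the bank for features that separate severe
from non-severe MM.

## Coordinates and ROI geometry

All image coordinates are 0-based with x = column, y = row, y increasing
downward, and **integer coordinates at pixel centres** (so pixel
`[r, c]` of an R matrix has centre `(c-1, r-1)`). This convention makes
the left-eye mirror map `x -> (W-1) - x` an exact involution on both
pixels and landmarks, which the orientation canonicalization relies on.
Rasterization assigns a pixel to a region iff its centre is inside the
polygon under the even-odd rule, implemented as a deterministic
half-open scanline. Manual contours are smoothed with the interpolating
periodic cubic spline (the unique C² closed cubic through the points,
parameterized by cumulative chord length) and resampled at uniform
parameter spacing, by default at 4x the input density. Zero smoothing is
deliberate: annotation vertices are trusted, only the polygonal kinks
between them are removed. One known consequence: at an exact 90° corner
(never produced by anatomical contours) the interpolant overshoots, and
an 8-point square's enclosed area changes by ~6.7%; for convex contours
with 12 or more points the area change stays under 5%.

The PPA mask is defined as fill(PPA outer contour) minus fill(disc
contour), so disc and PPA masks are disjoint by construction; an eye
without PPA carries an empty PPA mask, and every PPA-dependent feature
is emitted as 0 with a flag rather than NA.

## The feature bank (322 columns)

* **Clinic features (6).** `AreaPPA` and `AreaDisc` are mask pixel
  counts. The disc ellipse is the *moment-equivalent* ellipse (centroid,
  2·sqrt of the coordinate-covariance eigenvalues, principal-axis
  orientation) — robust on rasters, unlike boundary least squares.
  `Tilt` = short/long axis in (0, 1]. `Torsion` is the signed acute
  angle between the disc long axis and the perpendicular to the
  macula–disc-centre line; positive when the long axis is rotated
  counter-clockwise (y-down screen frame) from that perpendicular, folded
  to (−90°, 90°]. `Dist_MD` is the macula–disc-centroid distance in px;
  `Angle_MD` the signed acute angle of that line from horizontal,
  positive when the macula sits below the horizontal. Signs are
  conventions of this package (a signed convention is required, its
  direction is not dictated by anatomy) and are documented here.
* **Morphologic bank (151).** A fixed roster: the clinic ingredients
  re-emitted under `shape_*` names (10); signed Menger curvature at 16
  equally spaced arc-length stations per contour, anchored at the
  +x-extreme point, plus magnitude mean/SD/max (2 × 19); perimeter,
  area/perimeter ratio, circularity, solidity, extent, eccentricity and
  convex-hull area per region (2 × 7); central moments, normalized
  moments and the 7 Hu invariants per region (2 × 21); Fourier harmonic
  magnitudes |c_k|/|c_1|, k = 1..10, and Fourier circularity
  |c_1| / Σ|c_±k| per contour (2 × 11); symmetric Hausdorff, mean and
  minimum nearest-point and centroid distances between the contours (4);
  broadwise PPA width statistics over 72 rays (5); the `PPAweight_u{10,20,30}{R,G,B}`
  family (9); and 7 derived ratios. Curvature uses the
  circumscribed-circle (Menger) construction over a wide stencil because
  finite differences on resampled polylines are unstable; Menger is
  exact on circles at any sampling density.
* **PPAweight.** The operator casts 72 rays from the disc centroid;
  along each ray's intersection with the PPA mask the chosen channel is
  resampled at u equally spaced stations, and the feature is the mean
  over rays of the mean absolute successive station difference — a
  broadwise intensity-fluctuation rate. It is linear in intensity
  contrast and zero on constant regions. The construction (rays,
  stations, mean |Δ|) is this package's concrete operator for a
  qualitatively described quantity; alternatives (e.g. gradient
  projections) would order eyes similarly but are not implemented.
* **Intensity bank (54).** 18 standard first-order statistics × 3
  channels over the PPA region. Entropy and uniformity are computed on a
  32-bin equal-width histogram of the in-mask range. `TotalEnergy`
  equals `Energy` under unit pixel spacing and is kept to preserve the
  18-statistic roster.
* **Texture bank (111).** Per channel: 8 GLCM features (contrast,
  dissimilarity, homogeneity, ASM, entropy, correlation, cluster shade,
  cluster prominence) at each of the four angles 0/45/90/135°, distance
  1, kept separate because angle-specific features (e.g. cluster shade
  at 135°) are first-class citizens of the analysis; plus 5 NGTDM
  features (coarseness, contrast, busyness, complexity, strength) with
  8-neighborhoods restricted to in-mask pixels. Quantization is
  equal-width into 32 levels over the in-ROI range — self-contained and
  reproducible, where external toolkits default to fixed bin *widths*.
  Coarseness uses ε = 1e-6 and a 1e6 cap so constant regions are finite
  and testable.

The 151/54/111 rosters are a **contract of this package**: the
literature constrains only the totals, so the roster composition is
fixed, named, and covered by tests rather than inferred.

## The mining cascade

Normalization is z-score with *population* SD, fitted on the training
split only and applied unchanged to validation (no leakage; zero-SD
features map to 0 and are flagged). The mutual-information filter uses a
plug-in estimator on 10 equal-frequency bins, in bits, with threshold
0.2; the t-test filter is the pooled-variance two-sided Student test at
α = 0.05; candidates are the intersection, in original column order.

SFFS adds, at each step, the candidate maximizing the criterion — the
mean ROC AUC of a random-forest classifier over stratified fivefold
cross-validation on the training eyes — then conditionally removes any
included feature whose removal strictly improves the best score recorded
at the smaller cardinality. Ties break by column order; a single seed
governs folds and forests. The wrapper's scoring forest uses 50 trees:
selection needs stable *ranking* of candidate subsets, not calibrated
probabilities, and 50 trees halves the search cost at no measurable
ranking loss; the final decision model uses 100 trees. The forward
search is capped at 30 features and additionally stops once the running
best score has not improved by more than `tol` (0.005) for 6 consecutive
cardinalities — the stopping rule below never chooses cardinalities that
far past the plateau, so the truncation cannot change the final set
(`patience = Inf` restores the plain algorithm).

The final cardinality is the **rise-plateau rule**: the smallest k such
that no larger cardinality improves the mean CV score by more than
`tol` = 0.005 — an operationalization of trading classification
performance against model refinement. Whether the CV "score" is AUC or
accuracy is configurable (`criterion`); AUC is the default because the
evaluation battery is AUC-based throughout.

## Evaluation

The 70/30 split takes ceiling(0.3·n) validation eyes, stratified by
severity with largest-remainder allocation (457 eyes give exactly
319/138). ROC AUC is computed by the rank (Mann–Whitney) formula with
ties counted ½ — identical to trapezoidal integration — and
cross-checked in the tests against both a brute-force pair count and
pROC. Univariate feature performance is the mean ± SD over stratified
fivefold CV of a single-covariate logistic regression's held-out AUC
(the SD is across folds). Correlation between new and clinic features is
Pearson's r with two-sided p from the t transform (n − 2 df) and stars
at 0.05/0.01/0.001; zero-variance columns yield r = 0 with a flag.
Subclass profiles tabulate mean ± SD per META-PM grade for every feature
whose univariate mean AUC exceeds 0.75, and test each adjacent-grade
transition with Welch's t-test, flagging transitions at p < 0.01 —
Welch rather than pooled because grade subgroups differ in size and
spread.

## The phantom generator

Each phantom renders, on a 128×128 frame: a tessellated background
(smooth Gaussian random field), a bright elliptical disc (semi-major
axis ~16 px, tilt and orientation drawn per eye), an enclosing PPA outer
ellipse offset toward the macula (crescent geometry), a dark macula spot
43 px temporal, and PPA-zone intensity = brightness + a textured field.
Texture is controlled by separable Gaussian smoothing of white noise —
the correlation length gives monotone, testable control of NGTDM
coarseness. Histogram complexity is controlled *orthogonally to the
first two moments*: the texture field's marginal is blended through its
copula from Gaussian toward uniform (`x -> (1-λ)·x + λ·√12·(Φ(x)-½)`,
re-standardized), which raises the binned intensity entropy while
leaving mean, variance and the spatial correlation essentially
unchanged — so entropy-family statistics, not tail or dispersion
statistics, carry that axis.

Grade schedules (C0, C1, PDCA, MDCA, C3, C4) shift four planted axes —
PPA extent, PPA brightness, marginal shape λ (histogram complexity) and
texture correlation length (coarseness) — with the two largest jumps at
C0→C1 and PDCA→MDCA, so the subclass-profile analysis has a recoverable
signal at the clinically reported transition points. Disc tilt follows
the per-grade means and spread reported for clinical cohorts
(0.78 → 0.66 with SD ≈ 0.12). The shift magnitudes were chosen once so
that (i) each planted axis alone yields a univariate AUC near 0.75 —
inside the range reported for such cohorts (≈0.56–0.85) — and (ii) the
four axes carry comparable, partially complementary signal, so that a
wrapper search genuinely needs all four families; per-eye parameter
jitter (lognormal or additive, 10–30%) provides the within-class
overlap. A 3%
plus-lesion rate among mild grades renders those eyes with severe-grade
appearance, consistent with their pathology.

What the phantoms deliberately do **not** model: vessel trees, optic cup,
illumination gradients, camera vignetting, or any real chorioretinal
texture statistics. Passing tests on phantoms therefore demonstrates
that the *pipeline machinery* (geometry, feature arithmetic, filters,
wrapper, evaluation) is correct and recovers planted structure — not
that the specific features would transfer to any particular clinical
cohort.

## Numerical choices and degenerate inputs

* Constant ROI: quantization collapses to a single level; GLCM gives
  contrast 0, ASM 1, correlation 1 by convention; NGTDM coarseness hits
  the 1e6 cap; first-order entropy is 0.
* No valid GLCM pair (e.g. a one-pixel mask): all-zero feature block
  with a flag.
* Zero pooled variance in the t filter: equal means → p = 1 (dropped),
  unequal → p = 0 (retained).
* Isotropic regions: moment-ellipse orientation defined as 0 by
  tie-break.
* Angles are folded to (−90°, 90°]; at exactly ±90° the positive sign is
  taken.
* Problem sizes used by the test-suite and acceptance computations —
  300-eye cohorts on 128×128 frames, 10 master seeds for the cascade
  recovery, 20 seeds for the tabular SFFS recovery, n = 2000 for the
  binormal closed form — were chosen as the smallest sizes at which the
  statistical assertions have comfortable margins.

## Known limitations

* Radiomic features are entangled readouts of the underlying physical
  parameters: region energy reflects both area and brightness,
  co-occurrence entropy reflects both correlation length and marginal
  shape, NGTDM busyness scales with region size. In the planted-axis
  recovery experiment the parsimonious rise-plateau rule therefore
  selects small sets (4–7 features) that carry the *information* of all
  four planted axes through such composite features, while a dedicated
  representative of every feature family (shape, intensity location,
  intensity histogram, texture) is present only in a subset of seeds;
  the recovery test measures and documents exactly this behaviour.

* The PPAweight and curvature-station constructions are documented
  stand-ins for qualitatively described quantities; different concrete
  operators would produce different (though correlated) values.
* The roster composition inside the 151/54/111 totals is this package's
  contract, not a reconstruction of any particular historical feature
  list.
* Performance estimates come from a single 70/30 split as in the study
  design this mirrors; nested cross-validation would be required for
  unbiased performance estimation and is out of scope.
* Physical units (mm²) are not derived from dpi; all measurements are in
  pixels.
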