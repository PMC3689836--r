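---
title: "Methods: comparative morphometrics of the bony labyrinth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative morphometrics of the bony labyrinth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otomorph)
```

## The data and the measurement model

The bony labyrinth is measured on digital endocasts as a small set of
linear, angular and volumetric quantities per taxon: whole-labyrinth volume
(mm³) and length (mm); cochlear volume, coiling (degrees), canal length,
aqueduct length, spire aspect ratio, and the angle between the basal turn
and the lateral canal plane; vestibular aqueduct length, stapedial ratio,
sagittal labyrinthine index, and the three inter-canal plane angles; and,
per semicircular canal, arc radius of curvature, slender-portion length,
lumen diameter, total linear deviation from the canal plane, angular
deviation, and arc aspect ratio. The packaged fixture
(`load_measurements()`) holds one row per taxon for 36 therians: one
marsupial outgroup, four Mesozoic stem eutherians stored as the published
per-taxon averages (`is_average = TRUE`), and 31 placentals. Missing cells
stay missing; nothing is imputed.

One transcription correction: the printed per-taxon table gives the human
body mass as 8000 g. The same source's text puts the adult human average at
74–86 kg, and its normalized canal radius for the human (0.004 per gram,
×100) back-computes to roughly 70–80 kg, so the printed value lost a
digit. The fixture stores 80000 g. This matters: with 80 kg the ln–ln
correlation between labyrinth length and body mass is 0.94; with 8 kg it
would be 0.92.

## Derived indices

All indices are pure functions of the measurement columns:

* **Arc radius of curvature** `R = (height + width) / 4` — half the average
  of the in-plane extents of the canal arc; a circle of diameter d gives
  d/2.
* **Angular deviation.** The published protocol converts a canal's total
  linear deviation from its plane into an angle "trigonometrically" without
  printing the formula. We use the chord-subtended angle
  `θ = 2 arcsin(ld / 2R)`: the angle at the centre of a circle of radius R
  under a chord of length ld. The choice is empirical as well as
  geometric: applied to the published (R, ld) pairs it reproduces 95 of 96
  published angular deviations for non-averaged taxa within 0.6°, where
  alternatives such as `arctan(ld / R)` do not. The one mismatch (the
  opossum's lateral canal, 24.9° computed vs 23.7° printed) is consistent
  with rounded inputs and is tolerated, not forced.
* **Substantial deviation.** `ld / lumen diameter ≥ 1`. The threshold is
  inclusive: a deviation exactly one lumen diameter counts as substantial.
  The flag is descriptive, with no physiological claim.
* **Volumetric contributions.** Cochlear percent of total labyrinth volume
  and its exact complement, the vestibular percent; they sum to 100 by
  construction because the vestibular compartment is defined as everything
  that is not cochlea.
* **Discrete characters.** The spire-shape threshold is 0.55 (a ratio of
  exactly 0.55 is "low"/flattened); coiling bins break at 720° and 1080°
  with the left edge excluded (720° is still "1–2 turns"); contribution
  bins break at 50% and 75%. Ties for the largest canal radius are reported
  as a slash-joined polymorphic state, never silently resolved.

Report-level rounding follows the printed tables (two decimals for ratios,
one for angles, whole percent for contributions); all internal computation
is full precision.

## Geometry over centerlines

Centerlines are ordered n×3 point matrices in mm, consumed as given — no
resampling or smoothing, because the operators must be deterministic
functions of their input.

* **Plane fit** is total least squares (smallest principal component),
  which is rotation- and translation-invariant; the original endocast
  protocol oriented planes by eye. Collinear input is rejected. The fit is
  exact (residual < 10⁻⁹ mm) iff the points are coplanar.
* **Arc extents** are ranges along the two in-plane principal axes (width =
  major). The anatomical protocol anchors these axes on the ampullar
  apertures; principal axes are the deterministic surrogate and coincide
  for near-elliptical arcs. A consequence is that measured arc aspect
  ratios never exceed 1, while anatomically anchored published values
  occasionally do.
* **Linear deviation** is the range (max − min) of signed orthogonal
  distances. A symmetric sinusoidal warp of amplitude A yields 2A; a
  one-sided bump of height A yields ≈ A. The range is the only single
  statistic that treats both shapes commensurately.
* **Inter-plane angles** orient each normal toward the side containing a
  reference point (the labyrinth centroid) before taking the angle, which
  is what allows obtuse published angles such as 109°.
* **Cochlear coiling** unwraps the azimuth of the points about the rotation
  axis from the basal point's azimuth (the published "reference line") to
  the apex; reversal of point order changes only the sign.
* **Sagittal index** is the percentage of the posterior arc's orthogonal
  span below the lateral canal plane, with "below" fixed by a caller-
  supplied dorsal direction.

## The synthetic generator

`generate_canal()`, `generate_cochlea()` and `generate_labyrinth()` emulate
the measured properties of endocast centerlines — elliptical arcs of known
radius, aspect and plane; a single-frequency sinusoidal out-of-plane warp
(amplitude A ⇒ true linear deviation 2A); conical helices with prescribed
coiling, taper and height; canal triples installed at prescribed mutual
plane angles via the symmetric square root of the cosine Gram matrix
(infeasible triples are rejected); optional isotropic Gaussian noise,
seeded and bit-reproducible. Presets named for exemplar taxa (opossum-,
guinea-pig- and dolphin-like) span the measured ranges.

The generator makes no claim to anatomical realism beyond those measured
quantities: no ampullae, no lumen surfaces, no asymmetric warps, no
spatially correlated segmentation noise. Passing recovery tests therefore
demonstrates the correctness of the measurement operators, not robustness
to every artefact of real CT segmentation.

For a tapered helix the maximal first-turn diameter is not twice the basal
radius but `2·r₀ − taper/2` (basal point to half-turn point); the recorded
ground truth uses this value so that recovery tests are exact rather than
taper-biased.

## Allometry and the habitat contrast

Correlations are Pearson on natural logs with pairwise deletion, and
two-tailed p from the t distribution on n−2 df; `critical_r(28, 0.05)` =
0.374, the threshold the study rounds to 0.38. The body-mass regression is
OLS of ln(length) on ln(mass) over the 28 extant taxa with a recorded mass
(the dog is excluded by having none, as are fossils). Refit to the
printed-precision table this gives slope 0.151 and intercept 0.814; the
published intercept 0.8212 evidently comes from pre-rounding spreadsheet
values, so mass predictions through the published equation are reproduced
exactly (4.5 kg dog, 2.5 kg oreodont) while the refit intercept differs in
the third decimal.

The habitat contrast compares vestibular percent contributions between the
four aquatic taxa (manatee, sea lion, dolphin, balaenopterid) and the
non-volant, non-aquatic taxa outside the Mesozoic stem group (n = 24,
including fossil terrestrial taxa and the marsupial; this set reproduces
the published terrestrial mean of 44% and range 28–69%). Bats are excluded
as volant. Following the published procedure the headline test is the
Welch unequal-variance two-tailed t, with the F test for variance equality
reported alongside. On these data the aquatic group is small (n = 4) and
wide-spread (variance 348 vs 96), so the Welch test is weak: t ≈ 2.30 at
df ≈ 3.3, p ≈ 0.10, versus the published p = 0.007 — which is not
recoverable from the printed volumes under any defensible Welch grouping
(a pooled-variance t gives p ≈ 0.001). The default grouping is therefore
reported as computed, and alternative terrestrial sets are exposed as an
argument rather than tuned.

## Ancestral states

Discrete characters use uniform-cost Sankoff dynamic programming, which
handles multistate characters and polytomies directly (no resolution of
multifurcations). An up-pass computes subtree costs; a down-pass adds
outside costs, so each node's reported set is exactly the states attained
in some globally most-parsimonious labeling — nodes with more than one are
"equivocal". The implementation is verified against exhaustive enumeration
over all internal labelings on random small trees. Missing and polymorphic
tips contribute zero cost over their allowed states.

Continuous traits use Brownian-motion generalized least squares,
equivalently the minimizer of Σ(Δx)²/ℓ over branches. The normal equations
form a weighted graph Laplacian with observed tips as boundary values and
are solved directly — exact, iteration-free, and missing tips are simply
left free (marginalized). On a star tree with equal branches the root is
the tip mean; simulation tests confirm an unbiased root estimator.

The composite cladogram carries topology only; every branch length defaults
to 1 because the source supertree's lengths are unpublished. Continuous
reconstructions are therefore comparable to the published Mesquite values
only approximately, and tests assert tolerances (±8 percentage points on
the therian cochlear contribution), not equality. In practice the
unit-length reconstruction lands very close to the published node values,
which suggests the original analysis also used unit lengths. One
qualitative difference is expected: at the hyrax+manatee node the
most-parsimonious largest-canal state is the singleton "posterior" on this
topology, where the published trace reports an equivocal node; the tests
assert the weaker shared claim (the anterior canal is ancestral nearly
everywhere, with that node the exception).

Unresolved parts of the source tree are encoded as polytomies rather than
arbitrarily resolved: the basal placental trichotomy, the basal afrotherian
trichotomy, the ungulate/ferae/bat polytomy, and a trichotomy within
Euarchontoglires (no tree-shrew placement is lettered in the source
cladogram, and its text treats a tree-shrew+Glires clade as hypothetical).

## Problem sizes and determinism

The test suite runs entirely from code-built fixtures: synthetic canals use
33–1024 points; brute-force parsimony checks enumerate 4–6-tip trees;
Brownian unbiasedness uses 200 seeded replicates on 32-tip trees; the
Monte-Carlo plane-residual check uses 20 replicates of 200 points. These
sizes give sub-minute runs while keeping Monte-Carlo standard errors well
inside the asserted tolerances. Every stochastic test is seeded, and the
pipeline is byte-deterministic for a fixed configuration.

## Known limitations

* No extraction of centerlines from CT volumes or meshes, and no surface
  file I/O: the package starts from measured centerlines or tables.
* Principal-axis arc extents understate anatomically anchored aspect
  ratios that exceed 1.
* No phylogenetically corrected regression (independent contrasts): the
  replicated analysis used ordinary correlations, and so does the package.
* The discrete reconstructions depend on the composite topology; with only
  one or two representatives per major clade, single-taxon reversals (dog,
  aardvark) strongly shape the inferred ancestral states.
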