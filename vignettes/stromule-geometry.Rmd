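---
title: "Modeling plastid-stromule interaction capacity in a quasi-2D cytoplasm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling plastid-stromule interaction capacity in a quasi-2D cytoplasm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stromules)
```

## The scientific setting

In leaf epidermal cells the large central vacuole presses the cytoplasm into a
layer roughly 100 nm thick against the cell wall. Organelles embedded in this
layer — plastids, mitochondria, peroxisomes — therefore meet each other in what
is effectively a plane. Plastids extend stroma-filled tubules (stromules,
0.4–0.8 µm thick and microns long) whose role is widely believed to include
enlarging the plastid's surface available for inter-organelle exchange.

This package quantifies that idea geometrically. A plastid is a disc of radius
R (default 2 µm, the measured scale of an epidermal plastid in projection) and
its stromules are zero-width polylines of conserved total length l (default
10 µm). Two complementary quantities describe interaction capacity:

* **Interaction region** — the area of the plane within a proximity d of the
  plastid boundary, excluding the plastid interior. It measures how much
  cytoplasm the plastid can touch.
* **Plastid access** — for a point in the cytoplasm, the fraction of ray
  directions from that point that encounter plastid material within a reach D.
  It measures how much of the perimeter of a small organelle parked at that
  point could be in contact with the plastid.

Stromule arrangements are compared at matched total length: a bare body
(`none`), one radial stromule (`single`), two stromules of length l/2 rooted
on opposite sides (`double`), and a Y-shaped stromule (`branched`) whose stem
of length l/3 splits into two l/3 branches with all three junction arms 120°
apart.

## Simulation machinery

`compute_distance_field()` partitions a window of the plane into square pixels
and stores the exact Euclidean distance from each pixel center to the nearest
plastid element (0 inside a body). Discretization therefore enters only
through area integration: `interaction_area()` counts pixels with
0 < distance ≤ d and multiplies by the pixel area. At the default 0.05 µm
pixels the bare-body area agrees with the closed-form annulus
π((R+d)² − R²) to well within 2%, and to about 0.5% at 0.02 µm.

`compute_access_field()` casts rays at angles 0, 0.1, 0.2, … rad strictly
below 2π (63 rays) from each pixel center and records the encountered
fraction. Conventions that matter numerically:

* The intersection test is closed — rays exactly tangent to a body circle
  count as encounters — which makes the access fraction stable at region
  boundaries.
* Pixels farther than D from every element are assigned access 0 without
  raytracing (no ray of length D can reach anything), so cost scales with the
  reachable band rather than the window.
* Pixels inside a body have access 1 (every ray starts on material).

Pixel grids are laid out symmetrically about the window center, so
mirror-symmetric scenes produce exactly mirror-symmetric fields; this is also
why reflecting a geometry across a grid axis reproduces its area to the pixel.

Default resolutions are 0.05 µm pixels for area work and 0.1 µm for access
fields (raytracing is ~63× more expensive per pixel); the default window is a
40 µm square, large enough to hold every default arrangement plus the largest
default proximity with room to spare. Windows that would clip an interaction
region trigger a warning, and geometries that stick out of an explicit window
are an error. Default proximities are d ∈ {0.5, 1, 2, 5} µm and the default
access reach is D = 1 µm, the scale of a mitochondrion's radius.

## What the comparisons show

At matched stromule length the interaction area always orders
`single ≥ branched ≥ none`: a branch point "double counts" dilated area near
the junction, so a single prolonged stromule reaches more cytoplasm than a
branched one. Branching instead pays in access: near a junction an organelle
is surrounded by three arms rather than flanked by one.

One subtlety is worth stating precisely, because it constrains how the
branched-vs-single access comparison can be tested. For any reach D smaller
than the stem length l/3, the neighborhoods within D of the stromule root are
congruent between `single` and `branched` (both are a body plus a radial
segment longer than D), so the *maximum* access over the plane ties exactly;
a point beside a 120° junction attains access ≈ 1 − 120°/360° = 2/3, slightly
below the root value. The branched advantage at small D lives in the amount
of high-access area (the upper tail of the access distribution), which is
substantially larger for `branched` at every reach. Only when D exceeds the
body–junction distance — so that junction-adjacent points integrate body and
branches together — does the strict maximum for `branched` exceed `single`
(e.g. 0.78 vs 0.70 at D = 5 µm). The package's tests therefore assert the
tail comparison at D = 1 µm and the maximum comparison at D = 5 µm.

### Branch angle

`branch_angle_scan()` varies the angle between the stem arm and each branch
over a grid (default 60–180° in 5° steps) and reports the angle maximizing
the interaction region at d = 1 µm. All candidate angles are measured on one
shared pixel grid covering the union of the candidate geometries: the body
and stem then contribute identical pixels at every angle, so the flat optimum
is not obscured by grid-alignment noise. The optimum is 120° — the equal
three-way split minimizes the overlap of the three arms' dilations — and the
area surface is very flat within ±15° of it, consistent with branch angles
observed in cells scattering around 120°. Ties are broken toward 120°. At the
default resolution the scan resolves the optimum exactly; the comparison is
meaningful to about one 5° grid step.

### Plastid pairs

`pair_separation_scan()` places two plastids at center separations of 5–25 µm
(the range implied by measured plastid densities) and measures the union
interaction region on a single distance field, so overlap is never double
counted. Extension angles are randomized per instance; the same per-instance
angles are reused at every separation (common random numbers), which removes
resampling noise from the separation trend and makes the monotonicity of the
union area testable with a modest number of instances (the default is 100).
Separations below 2R would overlap the body discs; they are permitted but
flagged. The union area rises from little more than a single plastid's region
at 5 µm toward twice it beyond ~15 µm: closely spaced plastids gain little
from stromule extension, well-spaced ones gain fully — and the spacings cells
actually exhibit (8–15 µm, from the density analysis below) sit in the
high-gain range.

## Closed-form model with membrane or volume conservation

Extruding a stromule is not free: the tubule's membrane (or volume) comes out
of the body, shrinking it. `conservation_budget()` books this on 3D
primitives — a sphere body and an open cylinder stromule of radius r_s
(default 0.3 µm, the midpoint of the observed 0.4–0.8 µm thickness) — even
though interaction is scored in the 2D projection, because the envelope
really is a 3D surface. A pure-2D perimeter budget is rejected as infeasible
at realistic parameters: a 2 µm disc has only ~12.6 µm of perimeter, less
than the two sides of a 10 µm stromule.

The shrunken radius solves 4πR0² = 4πR′² + 2π r_s L (membrane) or
(4/3)πR0³ = (4/3)πR′³ + π r_s² L (volume). The relative interaction gain then
compares stromule-plus-shrunken-body against the original body, using
annulus/stadium formulas in 2D and shell/capsule formulas in 3D, with the
junction overlap ignored (the closed forms are upper bounds; the pixel
simulator supplies overlap-corrected 2D values, and stays within ~10% of the
bound for the single arrangement). Two conventions are worth noting:

* With L = 0 the gain is exactly 1: the dilation term is dropped rather than
  evaluated at L = 0, where a literal zero-length segment would still dilate
  to πd².
* In 3D at small d the zero-width gain can dip slightly below 1 (membrane
  budget, d = 0.5 µm gives 0.93): the segment's capsule shell is O(d²) while
  the body loses O(d) of shell. This is an artifact of scoring a zero-width
  stromule and disappears for any finite tubule radius; it does not affect
  the headline comparison, which is that the 2D gain exceeds the 3D gain at
  every proximity examined — stromules pay off most exactly where the
  cytoplasm is flattest.

## Distribution models of the measurements

Three statistical regularities of stromule populations are modeled, fitted by
maximum likelihood, and used to parameterize the synthetic generator:

* **Counts**: stromules per plastid are Poisson — initiation events are
  independent with a characteristic rate λ. `fit_poisson_counts()` uses the
  sample mean (the MLE), reports `1 − exp(−λ̂)` as the implied stromule
  frequency (SF%, the proportion of plastids with at least one stromule), and
  runs a chi-square goodness-of-fit with the tail pooled so every expected
  count is at least 5 (df = categories − 2).
* **Lengths**: stromule lengths are log-normal, the signature of growth by
  independent multiplicative increments. The MLEs are the mean and population
  standard deviation of log lengths; fitted quartiles are
  exp(µ ∓ z₀.₇₅σ), so their geometric mean equals the fitted median by
  construction; sample quartiles (linear-interpolation convention) are
  reported alongside. A Kolmogorov–Smirnov test against the fitted
  distribution is attached. The GOF choices are labeled in the fit objects
  and deliberately simple; they are descriptive checks, not model-selection
  machinery.
* **Density**: plastid density (count/area) falls with cell area roughly as a
  power law a·areaᵇ toward an asymptotic packing density.
  `fit_powerlaw_density()` regresses log density on log area and reports R²
  on that scale — the scale on which the model is linear — because over a
  limited multiplicative range of areas a power law is an empirical summary
  to be read cautiously, not a mechanism.

`density_to_separation()` converts a density to the side of the square "box"
of cytoplasm holding one plastid, 1/√density: the measured density range
0.014–0.004 µm⁻² corresponds to characteristic separations of 8.5–15.8 µm,
which is what links the density measurements to the pair-separation scan.

## The synthetic generator

`generate_stromule_table()` and `generate_cell_table()` stand in for the
microscopy measurement tables. Two presets carry the fitted condition
parameters: `"stressed"` (λ = 0.69 stromules/plastid; lengths with median
3.5 µm, quartiles 1.7/7.7 µm) and `"unstressed"` (λ = 0.12; median 1.0 µm,
quartiles 0.6/1.4 µm). The log-normal σ is matched to the upper quartile,
σ = (log Q3 − log median)/z₀.₇₅, because the measured quartiles are slightly
asymmetric on the log scale (the geometric mean of 1.7 and 7.7 is 3.62, not
3.50) and a single σ cannot match both; the median — the quantity the
recovery simulations target — is unaffected by this choice. Counts and
lengths are drawn independently: no count–length coupling is assumed.

Cell areas are log-uniform on 10³–10⁵ µm², a realistic pavement-cell range.
The density coefficients default to a = 0.0904 µm⁻², b = −0.27, chosen so the
density is 0.014 µm⁻² at 10³ µm² and 0.0040 µm⁻² at 10⁵ µm², matching both
ends of the measured range. Expected counts are a·areaᵇ·area with
multiplicative log-normal noise of sd 0.11 on the rate before Poisson
realization; 0.11 was derived analytically as the dispersion at which the
log-log R² of the fitted power law falls near 0.8, the regime the real
density data occupy (fitted values on generated tables land at ~0.75–0.82).

Everything is seeded: a given seed reproduces tables bit-for-bit, and the
provenance (generator name, version, parameters, seed) rides along in the
dataset object and its JSON sidecar.

What the generator does *not* emulate — and hence what passing recovery tests
do and do not show: there is no spatial placement of plastids within cell
outlines, no measurement error or length censoring at the image border, no
per-leaf or per-image batch structure (the observed between-sample spread of
λ, roughly 0.57–0.88 stressed, is not simulated), and no count–length
dependence. Recovery tests demonstrate that the estimators are correct and
well-calibrated for the assumed data-generating process, not that the
process captures every feature of real tissue.

## Determinism, seeds and problem sizes

Every stochastic entry point takes an explicit seed and restores the caller's
RNG state afterwards. `run_reproduction()` derives per-stage seeds
arithmetically from one global seed, so stages can be rerun independently;
its manifest records MD5 hashes of every output, and identical configurations
reproduce identical hashes.

The package's tests and the acceptance script run at deliberately moderate
sizes chosen to estimate each quantity comfortably within its tolerance:
10,000 plastids for rate recovery (standard error ~0.008 at λ = 0.69), 50,000
lengths for median recovery (relative error ~0.7%), 200 cells for exponent
recovery, 5°/0.05 µm grids for the branch-angle optimum, and a handful of
common-random-number instances for the pair trend. Coarser grids (0.1–0.2 µm)
are used where only orderings or monotonicity are at stake.

## Known limitations

* Plastid bodies are discs; the measured slight ellipticity (6.3 × 5.0 µm in
  projection) is not modeled.
* Stromules are straight, static and zero-width in the spatial simulations;
  width enters only the conservation budgets, and kinking, curvature and
  extension dynamics are out of scope.
* The 3D side of the comparison is analytic only; no voxel simulation is
  provided.
* Closed-form gains ignore junction/root overlap and are upper bounds by
  construction.
* The access maximum is reported over pixel centers; its supremum over the
  continuum is 1 trivially close to any zero-width segment, which is another
  reason the distribution of access, not its pointwise extreme, is the robust
  summary.
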