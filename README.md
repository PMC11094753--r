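# stromules

Geometric models of how plant plastids use stromules — stroma-filled tubular
extensions of their envelope — to regulate interactions with other organelles
in the thin, effectively two-dimensional cortical cytoplasm of leaf epidermal
cells.

The package is for quantitative cell biologists who want to reason about
organelle geometry with numbers: it pairs a pixel-grid simulator of spatial
interaction capacity with maximum-likelihood models of stromule morphology
statistics, and a seeded synthetic-data generator that stands in for
microscopy measurement tables.

## The model

A plastid is a disc of radius *R* (default 2 µm) plus zero-width stromule
polylines of conserved total length *l* (default 10 µm), arranged as `none`,
`single`, `double` (two *l*/2 stromules on opposite sides), or `branched`
(an *l*/3 stem splitting into two *l*/3 branches, junction arms 120° apart).
Two quantities score interaction capacity:

* **Interaction region** — area of the plane within proximity *d* of the
  plastid boundary (interior excluded), measured by counting pixels of a
  distance field: `compute_distance_field()` + `interaction_area()`.
* **Plastid access** — for each pixel, the fraction of 63 ray directions
  (0 to 2π in 0.1-rad steps) that encounter plastid material within reach
  *D*: `compute_access_field()`.

Closed forms back the simulator: annulus π((R+d)² − R²) and stadium 2ld + πd²
in 2D, shell and capsule in 3D. `conservation_budget()` and
`relative_interaction_gain()` compare stromule extension against the bare
body while conserving envelope membrane (4πR₀² = 4πR′² + 2πr_s l) or volume —
showing the gain is far larger in 2D than in 3D. Grid scans cover plastid
pairs at 5–25 µm separations (`pair_separation_scan()`) and stromule branch
angles (`branch_angle_scan()`), whose interaction-area optimum is 120°.

Measurement statistics are modeled as: per-plastid stromule counts
~ Poisson(λ) (so the stromule frequency is 1 − e^−λ), stromule lengths
~ log-normal, and plastid density ~ a·areaᵇ decaying toward an asymptote
(`fit_poisson_counts()`, `fit_lognormal_lengths()`, `fit_powerlaw_density()`,
with broom-style `tidy()`/`glance()` methods).

## Worked example

Generate a stressed-tissue plastid population, refit it, and scan branch
angles:

```r
library(stromules)

ds <- generate_stromule_table(10000, preset = "stressed", seed = 1)
fit_poisson_counts(ds$plastids)
#> <poisson_fit> lambda = 0.6929 (se 0.0083), n = 10000, implied SF = 50.0%
#>   GOF chi-square, tail pooled to expected >= 5: X² = 10.94, df = 4, p = 0.0273

fit_lognormal_lengths(ds$lengths)
#> <lognormal_fit> mu = 1.2391, sigma = 1.1612, n = 6929
#>   median 3.45 µm (fitted quartiles 1.58, 7.56 µm)
#>   GOF Kolmogorov-Smirnov vs fitted log-normal: D = 0.0068, p = 0.909

branch_angle_scan(angles = seq(100, 140, by = 10))
#> # A tibble: 5 × 3
#>   angle_deg area_um2 optimum
#>       <dbl>    <dbl> <lgl>
#> 1       100     35.1 FALSE
#> 2       110     35.2 FALSE
#> 3       120     35.2 TRUE
#> 4       130     35.2 FALSE
#> 5       140     35.1 FALSE
```

The recovered rate λ̂ = 0.693 (a stressed plastid averages ~0.7 stromules;
the implied stromule frequency of 50% says half the plastids carry at least
one), the fitted length median of 3.45 µm sits at the generating 3.5 µm
scale, and the branch-angle scan puts the interaction-area optimum at 120°.
Analytic gains at d = 1 µm under membrane conservation are 2.31× in 2D
versus 1.14× in 3D (`interaction_gain_table(d = 1)`): stromules pay off most
in flattened cytoplasm.

`run_reproduction(reproduction_config(out_dir = "runs/full", seed = 1))`
drives the whole campaign (geometry summaries, pair scan, branch-angle scan,
analytic gains, synthetic tables and fits) into CSVs with a hash manifest;
`inst/scripts/reproduce.R` wraps it for the shell. `autoplot()` on the field
objects and `plot_pair_scan()`/`plot_branch_angle_scan()` give quick-look
figures.

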