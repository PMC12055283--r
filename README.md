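# leafsettle

Leaf outline morphometrics and settling-speed analysis in R.

Deciduous leaves are conspicuously symmetric and only subtly lobed. One
mechanistic explanation is aerodynamic: symmetric, unlobed blades settle
fast, land near the parent tree, and recycle their nutrients locally,
while asymmetric shapes fall 15–30% slower and disperse. Probing that link
computationally needs a chain of tools: shape statistics that quantify
symmetry and lobedness, in-silico "digital mutations" of blade margins,
generators for comparison shapes, and a robust terminal-speed estimator
for tracked falling trajectories. `leafsettle` provides that chain, plus a
fully synthetic study generator so every stage can be validated end to end
against a known ground truth.

## The core quantities

All shapes are closed simple polygons in millimetres, standardised to a
constant blade area A = 100 mm² so that shape — not size — is the variable.

* **Symmetry number** S ∈ (0, 1]: the maximum, over mirror axes through
  the area centroid, of the intersection-over-union between the outline P
  and its reflection,
  `S = max_θ |P ∩ R_θP| / |P ∪ R_θP|`.
  S = 1 iff the blade has a reflection axis.
* **Lobedness number** L ∈ [0, 1): the hull deficit `L = 1 − A / A_hull`
  (one minus solidity); 0 for convex blades.
* **Digital mutation magnitude** ε = ΔA/A₀: the symmetric-difference area
  between a blade and its sinusoidally perturbed version, as a fraction of
  the original area (computed before re-normalising the mutant back to
  100 mm²).
* **Terminal settling speed** V_S: the robust (Theil–Sen) slope of depth
  vs time over the automatically detected steady window of a trajectory;
  trials aggregate to a mean ± SEM, reported relative to a circular disc
  control of equal area, with Reynolds number Re = V_S·D/ν.

Shapes split into two regimes at S = 0.75: above it, settling is on par
with the disc (within ±10%, decreasing with lobedness); at or below it,
settling is substantially slower and insensitive to lobedness.

## Worked example

```r
library(leafsettle)

# a five-lobed, mildly asymmetric parametric leaf
leaf <- parametric_leaf(lobe_count = 5, lobe_depth = 0.4, asymmetry = 0.25)
morphometrics(leaf)
#> # A tibble: 1 x 9
#>   label           provenance     S     L best_axis_angle area_mm2 perimeter_mm
#> 1 parametric_leaf parametric 0.924 0.122            2.50      100         41.7
```

The asymmetry term pulls S below 1 (0.92), and the lobes give a hull
deficit of L = 0.12 at exactly 100 mm² of blade area.

```r
# digitally mutate a disc: full-boundary sinusoid, 0.5 mm amplitude
mut <- digital_mutate(ideal_forms()[["disc"]], mutation_spec(amplitude = 0.5))
mut
#> <mutation_result> amplitude 0.5 mm, epsilon 0.112 (delta area 11.2 / 100 mm^2)
```

ε = 0.112 matches the small-amplitude estimate 4aR/A₀ = 0.113 for the
100 mm² disc (R = 5.64 mm).

```r
# a small synthetic settling study, fully seeded
res <- run_study(n_random = 4, trials_per_shape = 10, seed = 0)
res$results[c(1, 7, 13, 18:21),
            c("shape_id", "S", "L", "VS_mm_s", "relative_speed", "regime")]
#>        shape_id     S     L VS_mm_s relative_speed        regime
#> 1  disc_control 1.000 0.000   10.74          1.000 high_symmetry
#> 2 ideal_octagon 1.000 0.000   10.56          0.984 high_symmetry
#> 3       leaf_02 1.000 0.168    8.92          0.830 high_symmetry
#> 4        rw_001 0.574 0.395    8.08          0.752  low_symmetry
#> 5        rw_002 0.667 0.297    7.79          0.726  low_symmetry
#> 6        rw_003 0.363 0.545    6.90          0.642  low_symmetry
#> 7        rw_004 0.328 0.622    7.78          0.724  low_symmetry
```

Symmetric shapes (disc, octagon) settle at the control speed; the
asymmetric random-walk blobs (S < 0.75) fall 25–35% slower regardless of
their lobedness. The attached report summarises the regime envelopes:

```r
cat(res$report, sep = "\n")
#> # Settling study report
#>
#> Shapes analysed: 21 of 21 (0 excluded)
#> Control mean settling speed: 10.74 mm/s
#> Symmetry range: 0.328 - 1.000; lobedness range: 0.000 - 0.622
#>
#> ## Regimes (threshold S = 0.75)
#> - high symmetry (n = 17): relative speed min 0.830, q25 0.918, median 0.935, q75 0.970, max 1.000
#> - low symmetry (n = 4): relative speed min 0.642, q25 0.704, median 0.725, q75 0.732, max 0.752
```

Outlines move in and out of the package as plain-text formats:
`read_mask_outline()` traces binary mask images at sub-pixel precision,
`write_outline_csv()`/`read_outline_csv()` round-trip vertex lists, and
`export_svg()` writes millimetre-scale, stroke-only SVG suitable for a
laser cutter. `write_results_csv()` emits the study table byte-stably.

See the methods vignette (`vignettes/leafsettle-methods.Rmd`) for the
model details, calibration constants and numerical choices.

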