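---
title: "Methods: shape metrics, digital mutations and settling analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shape metrics, digital mutations and settling analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafsettle)
```

## The problem

Deciduous leaves are strikingly symmetric and only subtly lobed. One
mechanistic hypothesis is aerodynamic: a leaf that settles quickly lands
near its parent tree and returns its nutrients to the local soil, whereas a
slow, fluttering leaf is carried away. Testing that idea requires a
quantitative chain from *blade shape* to *settling speed*: shape statistics
that capture symmetry and lobedness, a way to perturb shapes in silico
("digital mutations"), comparison shapes spanning the space of
two-dimensional forms, and a robust estimator of terminal speed from
tracked falling trajectories. `leafsettle` implements that chain, together
with a synthetic-data generator so the whole pipeline can be exercised and
validated end to end without any experimental input.

Throughout, a shape is a closed simple polygon in millimetres (an
`outline`), and every shape is standardised to a constant blade area of
100 mm^2 — holding area fixed is what isolates *shape* as the experimental
variable. Settling happens at Reynolds numbers of order 100–300 (blades of
roughly 1 cm falling at roughly 1 cm/s in water), which the
`reynolds_number()` bookkeeping records.

## The two shape statistics

**Symmetry number S.** `symmetry_number()` scores the blade's best mirror
symmetry as the maximum, over axis angles through the area centroid, of the
intersection-over-union between the outline and its reflection:

$$ S = \max_{\theta \in [0, \pi)} \,
   \frac{|P \cap R_\theta P|}{|P \cup R_\theta P|}. $$

$S = 1$ exactly when the shape has at least one reflection axis, and falls
towards 0 as no axis fits. The maximisation scans 180 coarse angles and
refines the best one by golden-section search to $10^{-4}$ rad. The IoU is
piecewise-smooth in $\theta$, so this two-stage search agrees with a dense
3600-angle brute-force scan to well within $10^{-3}$ (the test suite pins
this on batches of irregular shapes).

**Lobedness number L.** `lobedness_number()` uses the hull deficit
$L = 1 - A / A_{\mathrm{hull}}$, i.e. one minus the solidity. It is 0 for
any convex blade and grows as lobes deepen; a plus-sign shape (area 5
inside a hull of area 7) scores exactly $2/7$.

Both statistics are resolved through a *name registry*
(`register_symmetry_metric()`, `register_lobedness_metric()`), so an
alternative definition — for example a different published mass-distribution
statistic — can be swapped in without changing any call site. The search
over axis *angle only* (not offset) is a deliberate choice: the axis is
anchored at the area centroid, which any exact mirror axis must pass
through; for strongly asymmetric blades an offset search could only raise S
slightly, at quadratic cost.

All metrics are computed on outlines resampled to 512 vertices by uniform
arc length and normalised to 100 mm^2, making values reproducible across
input digitisation densities. Reported values are rounded to two decimals
only for presentation, never internally.

## Digital mutations

`digital_mutate()` displaces the vertices of chosen boundary segments along
the local outward normal by
$a \sin(2\pi s / \lambda + \phi)$, with $s$ the arc length from the segment
start. Segment ends are cosine-tapered over 5% of the segment length so the
perturbed boundary stays $C^1$-ish and does not kink; a full-boundary
mutation is instead closed periodically by snapping $\lambda$ to an integer
number of waves. The default wavelength is perimeter/24 — "short" relative
to the blade — and is exposed as an argument.

The mutation magnitude is the modified-area fraction
$\varepsilon = \Delta A / A_0$, where $\Delta A$ is the **symmetric
difference** between the original and mutated polygon, computed *before*
the mutant is rescaled back to 100 mm^2. Two properties motivate this
definition. First, under the constant-area protocol a net signed area
change is compensated away by the rescale, so a net definition would sit
near 0 and could not grow with mutation strength. Second, the symmetric
difference has a clean small-amplitude limit: for displacement
$a \sin(2\pi s/\lambda)$ along a boundary of perimeter $P$,

$$ \varepsilon \;\to\; \frac{1}{A_0} \oint |a \sin| \, \mathrm{d}s
   \;=\; \frac{2}{\pi} \frac{a P}{A_0}, $$

which for the 100 mm^2 disc is $4 a R / A_0$. The implementation matches
this limit within a few percent at small amplitude and an independent
boolean-xor oracle at all amplitudes. Mutations that would self-intersect
fail loudly, naming the offending segment. Whether real margin
irregularities displace inward, outward or both is not determined by the
phenotype; the signed sinusoid used here does both symmetrically.

## Comparison shapes

* `ideal_forms()` returns ten mirror-symmetric reference shapes: disc,
  regular 3/4/5/6/8-gons, ellipses of aspect 1.5/2/3, and a stadium. The
  set composition is a documented package choice (only "regular polygons"
  plus a count of ten is externally fixed) and is overridable.
* `parametric_leaf()` is a radial family
  $r(\theta) = r_{\mathrm{ellipse}}(\theta)\,[1 + 0.45\,d\cos(k\theta) +
  \alpha\,(0.25\sin 2\theta + 0.18\sin(3\theta + 1))]$ with lobe count $k$,
  lobe depth $d$ and asymmetry $\alpha$. At $\alpha = 0$ the outline has an
  exact mirror axis; the two odd harmonics with incommensurate phases share
  no common mirror, so $S$ decreases strictly with $\alpha$ — this family
  provides controllable (S, L) fixtures.
* `random_walk_shape()` thickens a 2000-step Gaussian random walk
  (step σ 0.5 mm) to a 1 mm-wide ribbon, rasterises it at a quarter of the
  path width, and extracts the largest closed 0.5-level iso-contour of the
  lightly blurred occupancy field at sub-pixel precision, then smooths
  (circular moving average, window 9) and resamples. These irregular blobs
  populate the asymmetric regime (typically $S \approx 0.35$–$0.8$,
  $L \approx 0.2$–$0.6$ under the defaults). The exact construction recipe
  of such shapes is underdetermined; the parameters here are declared
  defaults, chosen so the generated set reaches well below the $S = 0.75$
  regime boundary while remaining simple, cuttable polygons.

All generators are pure functions of their seed and parameters.

## Terminal-speed estimation

A tracked trajectory is time-stamped centroid positions: lateral $x(t)$ and
depth $z(t)$ (positive downward), in mm. `estimate_terminal_speed()`:

1. computes rolling ordinary-least-squares slopes of $z$ vs $t$ over 1 s
   windows;
2. takes the longest terminal run of windows whose slopes all lie within 5%
   of the run's median — the *steady window* (an initial acceleration
   transient is thereby excluded); a record with no such run (e.g. constant
   $z$) raises a non-terminal error;
3. reports the Theil–Sen slope (median of pairwise slopes) over the steady
   window, which is exact on affine records and robust to occasional
   tracking outliers.

`aggregate_trials()` turns repeated drops of one shape into a mean speed
with SEM $= s/\sqrt{n}$ and, given the disc control's mean, a relative
speed. With a per-trial coefficient of variation of 15%, 25 trials pin the
mean within about 3% relative error — the rationale for a 20–30-trial
protocol. The 15% per-trial CV is a documented calibration constant of the
synthetic generator, not a derived quantity.

## The synthetic study and what it validates

`settling_speed_model()` is a deliberately simple piecewise map from shape
to expected relative settling speed, encoding the observed envelopes as
*calibration constants*: above a symmetry threshold of 0.75 the relative
speed is $1 - 0.5\,L$ clipped to $[0.9, 1.1]$ (on par with the disc,
decreasing with lobedness); at or below the threshold it is 0.775
(the midpoint of a 15–30% slowdown), independent of lobedness. The
discontinuous switch mirrors the description of two regimes; a logistic
blend is available behind a flag but off by default, since smoothing would
add parameters nothing constrains. Whether the 15–30% span reflects
shape-to-shape variation or measurement spread is not determinable from
the envelopes alone; the model treats it as shape-to-shape with a fixed
midpoint.

`make_synthetic_study()` assembles control + ideal forms + parametric
leaves + random-walk shapes, computes (S, L), draws per-trial speeds
$\mathcal{N}(\mu_i, (0.15\,\mu_i)^2)$ (truncated at $0.2\,\mu_i$) around
the model mean, and simulates every trial as a full trajectory —
exponential approach to terminal speed (τ = 0.5 s), sinusoidal flutter
(2 mm at 1.5 Hz) and 0.1 mm Gaussian tracking noise at 50 samples/s for
10 s. All randomness flows from one master seed through a fixed splitting
scheme (per-shape base seeds `(seed*100003 + 1009*i) mod 2^31-1`,
incremented per trial), so studies are bit-reproducible.

`run_study()` then runs the analysis blind to the truth: metrics per shape,
per-trial speed estimation, aggregation against the control, regime
classification (the boundary value $S = 0.75$ is assigned to the
low-symmetry regime; a strict inequality convention is required and this
one is documented), and a report with min/quartile/max envelopes per
regime (the spread measure behind published envelope statements is not
fixed, so both extremes and quartiles are printed).

Passing the end-to-end tests shows the *plumbing* recovers a known truth
through simulated measurement noise. It does not validate the biology or
fluid dynamics: the synthetic model is calibrated to reported envelopes by
construction, the trajectory model ignores rotation, tumbling and
Reynolds-number dependence, and real tracked data carry outliers and drift
the simulator does not emulate beyond Gaussian noise.

## Numerical choices

* Polygon booleans go through the Clipper library (`polyclip`), which
  snaps coordinates to a fine integer grid; identities such as
  $|P \cap P| = |P|$ hold to ~1e-8 relative, and tests assert them at
  1e-6. Area normalisation is pure scaling (no clipping) and meets its
  1e-9 relative target exactly.
* Degenerate inputs: outlines need ≥ 3 distinct vertices and positive
  area; clockwise input is silently reversed (digitisers emit either
  orientation); self-intersecting input is rejected by default, with an
  opt-in zero-distance boolean repair (`repair = TRUE`) that keeps the
  largest ring — silent repair would corrupt the area bookkeeping that
  $\varepsilon$ depends on.
* Metric resolution: 512 vertices balances boolean-op robustness against
  discretisation error (< 0.1% in area on smooth shapes); symmetric shapes
  score $S = 1$ within 5e-3 at this resolution.
* Ties and boundaries: the symmetry search returns the first maximising
  angle of the coarse grid refined locally; `classify_regime(0.75)` is
  `"low_symmetry"` by the strict-inequality convention.
* Test and validation problem sizes: oracle-equivalence runs use 50
  irregular shapes against a 3600-angle scan; end-to-end recovery uses a
  study of 47 shapes (10 ideal + 6 parametric + 30 random + control) at
  25 trials per shape under the default study seed 0; estimator accuracy
  uses 200 simulated trajectories. These sizes are the package's
  validation choices and are stated here so they can be scaled up.

## Known limitations

* S maximises over axis angle only (axes through the centroid), and L is
  hull-deficit; other published definitions can be registered but are not
  bundled.
* The digital-mutation operator is the package's own geometric realisation
  of sinusoidal margin perturbation; segment choices applied to any
  particular real leaf are not reproduced.
* A per-shape "within 2·SEM" recovery count sits exactly at the nominal
  coverage of a 2σ band (~95%), so single-seed verdicts of a "≥ 95% of
  shapes" count are inherently variable; the estimator's z-scores being
  unbiased with unit scale is the stronger, stable property, and the
  recovery tests also pin the median relative error (< 2%).
* Trajectories are analysed in physical mm; camera calibration, raw video
  tracking, and flow-field analysis are out of scope.
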