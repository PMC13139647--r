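---
title: "Canopy space filling, four ways: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canopy space filling, four ways: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its own methods: the quantities
it computes, the conventions it fixes where the field leaves them open, the
synthetic stands it tests itself on, and what those tests do and do not
demonstrate about real data.

## 1. From point cloud to voxel grid

A plot is a 45 × 45 m square. Before any structural metric is computed, a
2 m buffer at the plot boundary is removed to suppress edge effects, and
the 41 × 41 m interior is divided into four equal quadrant subplots
(SW, SE, NW, NE). All spatial membership tests — buffer clipping, quadrant
assignment, voxel binning — use half-open intervals `[lo, hi)`, with ties
on a midline going to the eastern/northern side. This makes the partition
exact: no point is lost or counted twice, clipping is idempotent, and
translating cloud and geometry together changes nothing.

Each subplot cloud is binned into cubic voxels of edge *e* = 0.40 m, a
grain coarse enough to be robust to occlusion in dense canopies yet fine
enough to resolve crown-scale structure. The grid's horizontal dimensions
are `ceiling(footprint / e)` — edge voxels may overhang the footprint
slightly, but the per-layer voxel count is then the constant `nx · ny`,
which keeps the per-layer occupancy fraction well defined. The vertical
dimension is `ceiling(max z / e)` with the grid base at ground (z = 0).
A voxel is *occupied* when it holds at least `min_points` returns
(default 1: any return fills a voxel, the binary occupied/empty voxel
model standard in this literature). Points outside the grid are dropped
and tallied, never fatal: upstream clipping makes them rare, and a batch
run should not die on a stray return.

Heights are assumed ground-relative. An optional normalisation
(`normalize_heights()`) subtracts the per-cell minimum z on a 1 m
horizontal grid — a deliberately simple lowest-point terrain model whose
residual error is bounded by the relief across one cell. It is off by
default: the synthetic generator produces ground-relative clouds, and
real-data users should decide explicitly how to reference their terrain.

## 2. Boundary heights and the four canopy-space definitions

Three heights are detected per subplot from the layer occupancy profile
*o_k*:

* **H_max** — the top face of the highest occupied layer;
* **h10** — scanning from the top layer *downward*, the top face of the
  first layer with *o_k* ≥ τ (default τ = 0.10). The downward scan
  matters: it finds the boundary below which the canopy is consistently
  filled, skipping sparse emergent crowns. If no layer reaches τ, h10 is
  undefined and the definitions that need it are flagged invalid;
* **LGB** (lowest green branch) — either a field-measured override, or the
  bottom face of the lowest occupied layer whose bottom lies at or above a
  0.3 m ground-exclusion height (default), falling back to 0. The
  exclusion keeps residual ground returns from masquerading as foliage.

The four definitions are then slabs: total `[LGB, H_max]`, top
`[⅔ H_max, H_max]`, mid `[⅓ H_max, h10]`, main `[LGB, h10]`. The height
fractions use the subplot's own H_max — all four definitions are
subplot-local. A layer belongs to a slab when its *centre* lies in the
closed interval: a simple, deterministic way to snap fractional boundaries
(H_max/3 is rarely a lattice plane) to whole layers. Degenerate slabs —
inverted bounds (h10 at or below H_max/3 makes the mid slab empty) or an
undefined h10 — produce flagged invalid records rather than errors, so a
sweep over many subplots always completes and reports what it skipped.

Two conventions here are genuinely open in the field and are therefore
explicit, configurable choices: the comparison with τ is non-strict (≥),
and the 10 % rule is evaluated per layer on a top-down scan rather than on
any cumulative profile.

## 3. Productivity

Stem volume uses the taper-corrected cylinder
`V = π (D/100)²/4 · H · f` with form factor f = 0.4; D is in cm
(converted internally to m), H in m, V in m³. Subplot annual wood
productivity is the sum over trees *alive at both censuses* of
`(V₂ − V₁)/(t₂ − t₁)`, scaled to cm³ yr⁻¹. Trees that died during the
interval contribute nothing — their terminal volume is unobserved — which
is a declared choice; with the low inter-census mortality this design
emulates (5 %), it moves subplot AWP little. Negative per-tree increments
(measurement noise) are kept, so a subplot AWP can in principle be
non-positive; because the gamma response requires AWP > 0, such rows are
excluded from model fits and counted in the run manifest.

## 4. The gamma mixed model and marginal R²

Per canopy definition, `AWP ~ CSFI + (1 | plot)` with a gamma response and
log link, fitted by Laplace-approximate maximum likelihood (glmmTMB). The
log link keeps predictions positive and makes the CSFI coefficient a
proportional effect; the plot random intercept absorbs the nesting of four
subplots per plot. Fixed-effect starting values come from the
corresponding gamma GLM without the random effect, making the optimisation
reproducible; Wald z-tests on the link scale give SEs and p-values, with
no multiple-testing correction. Stratified fits (mixtures only,
monocultures only) drop the mixture factor; the across-subplots fit used
for the reported CSFI effect omits the interaction, which is fitted
separately to supply the CSFI × mixture-type interaction p-value. Rank
deficiency (e.g. constant CSFI) and other non-convergence produce a
flagged fit object, not an exception.

Marginal R² follows the variance-decomposition approach for GLMMs:
`var(Xβ) / (var(Xβ) + σ²_plot + σ²_resid)`, with the observation-level
gamma variance on the log scale taken as `trigamma(ν)` — the exact
variance of log Y for a gamma with shape ν — and a lognormal
approximation `log(1 + 1/ν)` available as an alternative. The trigamma
form is the default because it is exact for the fitted family; the two
differ noticeably only at small shape.

One caveat worth stating: with a plot-level variance truly equal to zero,
maximum likelihood at the boundary estimates a spuriously positive σ_plot
in a sizeable fraction of small samples, and the mixed fit then differs
slightly from the fixed-effects GLM. This is a property of boundary ML,
not of the implementation; the package's reduction check therefore runs in
the large-sample regime (500 plots), where the collapse to the GLM is
exact to optimiser tolerance.

## 5. What the synthetic stands emulate — and what they do not

The generator reproduces the *design* of a classic tropical BEF
plantation: 45 × 45 m plots on a 3 m planting grid (15 × 15 = 225 stems),
two monoculture plots per species over six species spanning three growth
guilds (pioneer, intermediate, shade-tolerant), six three-species mixtures
constrained to one species per guild, six six-species mixtures, and the
removal of one pioneer's monocultures (emulating early mortality) to give
22 plots and 88 subplots.

Trees get first-census sizes from guild-level normal distributions and
grow by guild rates with lognormal noise over the five-year interval;
5 % die. Crowns are plain vertical ellipsoids — semi-axes and crown-base
height as fixed fractions of tree height per guild — sampled uniformly
with Poisson point counts at ~50 points per m³ of crown, plus a sparse
stem line. Guild stratification (tall thin pioneer crowns high up, deep
wide shade-tolerant crowns low down) is what makes the four definitions
diverge realistically: the mid slab catches the dense crown core, the top
slab the patchy emergent layer.

Deliberately absent: occlusion and beam geometry (every crown interior is
uniformly visible, unlike real TLS), branch architecture, terrain,
understorey, allometry fitted to any real species, and any calibration to
measured CSFI or AWP values. Passing tests on these stands therefore
demonstrates that the *computational chain* is correct and that the
statistical machinery recovers known effects under the design's structure
— not that any particular field result would be reproduced. In mechanistic
mode the CSFI–AWP association arises only implicitly (shared dependence on
tree size) and is weak; generative mode exists precisely to inject a known
effect (β₁, σ_plot, ν) through the measured CSFI so recovery, coverage and
type-I error can be checked against ground truth.

Default generative magnitudes are chosen for scale realism, not mimicry:
β₀ = 12 puts subplot AWP in the 10⁵–10⁶ cm³ yr⁻¹ range of a young
plantation subplot, β₁ = 3 is the order of link-scale CSFI effects such
studies report, σ_plot = 0.3 gives plots ±35 % around the mean, ν = 5 a
~45 % coefficient of variation. The driver CSFI for pure recovery studies
is Beta(2.5, 5) (mean 0.33), with an optional per-mixture-type spread
multiplier used to study stratum-wise explained-variance contrasts.

## 6. Numerical and testing choices

* Voxel counts are exact integer tallies (`tabulate` on linear indices);
  equality with a brute-force all-pairs assignment is asserted exactly,
  not within tolerance.
* CSFI aggregation identities (union of layer ranges = voxel-weighted mean
  of parts) hold to 1e-12 relative and are tested at that tolerance.
* The fixed reference grid used across tests (10 × 10 × 10 voxels, bottom
  five layers full, top five at 5 % occupancy) has hand-derivable bounds
  (H_max = 4 m, h10 = 2 m) and CSFI values (0.525 / 0.05 / 1.0 / 1.0 for
  total/top/mid/main), all cross-checked against a cell-by-cell count.
* Simulation-based checks run at deliberately chosen sizes: the recovery
  study uses the full 22-plot design with 200 replicates (CI coverage) and
  500 replicates (type-I error); the explained-variance contrast 100
  replicates; the reduction-to-GLM check one 500-plot sample. All seeds
  are fixed; every stage is deterministic given its seed.

## 7. Known limitations

* No occlusion correction: on real TLS data the index inherits whatever
  occlusion bias the scan design leaves; comparisons should be restricted
  to data scanned under one protocol.
* The lowest-point terrain model is crude on steep or sparsely-sampled
  ground; pre-normalised heights are preferred.
* LAS/LAZ input is not parsed; convert binary point clouds to ASCII XYZ
  upstream.
* The h10 boundary is sensitive to τ near sparsely filled canopies; the
  per-layer top-down convention is one of several defensible readings and
  is configurable.
* Marginal R² values under different residual-variance formulations are
  not comparable; the package reports the trigamma form unless asked
  otherwise.
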