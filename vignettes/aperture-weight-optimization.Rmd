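---
title: "Aperture-weight optimization by exact elimination: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aperture-weight optimization by exact elimination: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abiplan)
```

## The planning problem

In aperture-based inverse planning (ABIP) for intensity-modulated
radiotherapy, the deliverable multileaf-collimator shapes are fixed *before*
optimization: for each beam, a field conformal to the target's beam's-eye-view
(BEV) projection, plus fields that additionally block each organ at risk (OAR)
lying in front of or behind the target. Only the scalar weight of each
aperture is optimized. This trades some dosimetric freedom for plans that are
directly deliverable, with far fewer segments and monitor units than
beamlet-based plans.

`abiplan` implements the weight optimization as a single exact linear solve,
plus everything needed to exercise it end to end without a commercial
planning system: a synthetic phantom and dose-kernel simulator, dose-volume
evaluation, penalty-trial replanning and aperture-count sweeps.

## The objective and its linear surrogate

Plan quality is scored by a one-sided quadratic penalty cost over all dose
sample points $i = 1, \dots, N$:

$$F(\mathbf d) = \sum_{i=1}^{N} p_i\, \big(D_i - \mathrm{PD}_i\big)^2
  \quad \text{counted one-sidedly,}$$

where a target point is penalised when it falls above its $D_\max$ or below
its $D_\min$, an OAR point only when it exceeds its $D_\max$, and $p_i$ is
the penalty of the structure containing point $i$ (`plan_cost()`).

The dose is linear in the aperture weights through the dose-influence matrix
$D_0$ (entry $(m, n)$: dose at point $m$ per unit weight of aperture $n$),
so the ideal plan solves $D_0 \mathbf w = \mathbf d_p$ for a prescribed
per-point dose vector $\mathbf d_p$. With $N \gg n$ this system is
overdetermined; the package forms the weighted normal equations

$$\big(D_0^{\mathsf T} P D_0 + \lambda I\big)\, \mathbf w
   = D_0^{\mathsf T} P\, \mathbf d_p,$$

with $P = \mathrm{diag}(p_i)$, and solves the $n \times n$ system exactly by
its own Gaussian elimination with partial pivoting and back-substitution
(`gaussian_eliminate()`). No iteration is involved; a system of 1200
equations in 30 unknowns solves in about a hundredth of a second on one CPU
core.

The one-sided cost $F$ is *not* what the linear solve minimises — an exact
non-iterative solve is only available for a symmetric least-squares
objective. The two are reconciled by how $\mathbf d_p$ is built
(`prescribed_dose_vector()`), from the reference doses computed at uniform
weights ($w_n \equiv 1$):

* **target points** are anchored at the prescription dose, which drives
  homogeneous coverage at the prescribed level;
* **OAR points** are anchored at $\min(\text{reference dose}, D_\max)$: a
  point already below its limit keeps its current dose as the anchor, so the
  symmetric pull cannot push a compliant OAR *up* to its limit, while a
  violating point is pulled down to the limit.

The reported `cost_initial` and `cost_final` are always the one-sided $F$ at
uniform and at optimized weights. Descent of $F$ on the packaged presets is
regression-tested; it is not a theorem (only the surrogate is guaranteed to
decrease), which mirrors how the underlying one-sided problem is non-convex
and the method finds a good local plan rather than a global optimum.

## Non-negative weights

Negative aperture weights are unphysical. The solver clamps negative
components to zero and re-solves the reduced system; by default
(`nnls = TRUE`) this clamp-and-refit repeats until all weights are
non-negative — an active-set non-negative least-squares scheme that
terminates after at most $n$ exact elimination passes. A cheaper single-pass
variant (`nnls = FALSE`) is available, but on strongly concave geometries a
refit can introduce fresh negative weights that a single pass then merely
truncates, and we have observed the truncated plan landing far from the
constrained optimum (every structure overdosed). The iterated clamp is
therefore the default.

## Smoothing

The elimination is exact, so ill-conditioning in $D_0^{\mathsf T} P D_0$
(near-duplicate apertures) surfaces directly as wild weight vectors.
A Tikhonov term $\lambda \lVert \mathbf w \rVert^2$ is folded into the
normal system; the default
$\lambda = 10^{-6}\,\mathrm{tr}(D_0^{\mathsf T} P D_0)/n$ scales with the
system and is small enough to leave well-posed solves essentially unchanged
(`lambda = 0` reproduces the unsmoothed solution exactly). As
$\lambda \to \infty$ the weight norm shrinks monotonically to zero.

## The phantom simulator

The simulator replaces the planning-system dose calculation with the
simplest model that still produces realistic dose gradients:

* **Geometry** — voxel grids with parametric structures (spheres, cylinders,
  boxes, elliptical cylinders, and a horseshoe/annular-sector shape for
  concave targets). Coordinates are voxel-centred mm with the isocenter at
  the grid centre; gantry angles are measured clockwise from $+y$ in the
  axial plane; beams are parallel (no divergence) and the collimator is
  fixed at 0.
* **Apertures** — per beam: the target BEV projection dilated by a margin
  (default 5 mm), one OAR-blocked field per OAR overlapping the target BEV,
  and sub-field splits up to the requested count. Splits are deliberately
  *not* complementary halves: a left half plus a right half would sum
  exactly to the conformal field and make dose-matrix columns linearly
  dependent.
* **Dose kernel** (`dose_kernel()`) — primary photons only:
  $\Phi_0 \exp(-\mu\,\mathrm{depth})\,T$, with $\Phi_0 = 2$ Gy per unit
  weight at zero depth, $\mu = 0.05\ \mathrm{cm}^{-1}$ (about right for
  6 MV), and $T$ the open mask blurred by an isotropic Gaussian penumbra of
  $\sigma = 3$ mm. Depth is ray-marched (1 mm steps) through the body mask.
  There is no scatter, no heterogeneity, no divergence: the simulator's job
  is to give the optimizer matrices with realistic structure, not clinical
  dosimetry. Tests passing on these phantoms say nothing about dosimetric
  accuracy on real CT data.
* **Sample points** (`place_sample_points()`) — per structure,
  $\max(1, \mathrm{round}(\rho V))$ points uniformly at random inside the
  mask, seeded and reproducible, at a default density of
  $\rho = 1$ point/cc — the density at which the cost function has
  converged in clinical experience with this class of optimizer. The body
  label covers unclassified normal tissue (body minus target and OARs), so
  spillage participates in the objective like any other structure.

## Packaged presets

Two presets ship with the package. `case_a` is a concave head-and-neck-like
geometry: a horseshoe target (about 68 cc at 2 mm voxels) wrapped around a
central cord-like cylinder, lateral parotid-like spheres, seven coplanar
6 MV-style beams at 0°, 45°, 100°, 150°, 210°, 260°, 315°, 3–5 apertures
per beam, 50.4 Gy prescription with a 45 Gy cord maximum. `case_b` is a
brain-like geometry: a spherical target beside a brainstem-like cylinder and
a chiasm-like sphere, 50 Gy prescription, coplanar beams (the package keeps
the couch at 0; with parallel-beam BEV projections a couch rotation adds
nothing the optimizer would notice). Both are deliberately smaller than
clinical cases — roughly 600 sample points at $\rho = 1$ — so the whole
suite, including full-resolution presets, runs in seconds; solver-scale
checks use synthetic 1200-equation, 30-aperture systems instead, the size
regime the method targets.

Preset penalties (target 1, cord/brainstem/chiasm 5, parotids 1, body 0.1)
were chosen once as a typical clinical weighting — serial OARs dominate,
spillage is lightly penalised — and are the starting point the replanning
loop is meant to edit, not a tuned endpoint.

## Replanning and the aperture sweep

`plan_session()` / `run_trial()` drive the interactive loop
programmatically: each trial applies a penalty edit, re-solves, evaluates
Table-style dose-volume goals (inclusive thresholds) and appends an
immutable record. Sessions serialise to JSON (costs at 17 significant
digits, so replays verify bit-exactly against the file).

`aperture_sweep()` re-optimizes over an ascending number of apertures per
beam. Two design choices make its trend a provable property rather than an
empirical accident: aperture sets are nested (the $k$-aperture set per beam
is a prefix of the $k+1$ set), and a single prescribed-dose vector —
anchored at the full set's uniform-weight reference — is used for every
count. The unconstrained weighted least-squares minimum is then
non-increasing in $k$. The sweep therefore defaults to `nonneg = FALSE`
and `lambda = 0`; the clamped solve does not carry the same guarantee.

## Numerical choices

* Pivoting: partial (max-magnitude) pivoting, ties to the lowest row index;
  singularity is declared when a pivot falls below $10^{-12} \max |A|$.
* The normal matrix is symmetrised as $(A + A^{\mathsf T})/2$ before the
  solve to remove accumulation asymmetry.
* DVH curves (`dvh()`) use 0.1 Gy bins over sample points (the optimizer's
  native resolution) and treat a dose exactly on a bin edge as covered,
  with a $10^{-9}$ relative guard against floating-point edge drift.
* Apertures with weight below $10^{-6} \max(w)$ are reported as dropped
  from the deliverable plan (`plan_metrics()`).
* Monitor units are proportional to aperture weight through one calibration
  constant (default 1 MU per weight unit); no output-factor model is
  attempted.
* Dose matrices exchange as wide CSV with 15 printed significant digits
  (round trips verified to 12); specifications, objectives, results and
  manifests are JSON.

## Limitations

The dose model is a primary-photon caricature; absolute doses are not
clinical. The one-sided cost is only evaluated, never directly minimised,
so a trial can in principle raise $F$ even though the surrogate fell.
Dose-volume (partial-volume) constraints, biological objectives, beam-angle
optimization and MLC sequencing are out of scope. The method finds a good
local plan quickly; it does not claim the global optimum of the non-convex
one-sided problem.
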