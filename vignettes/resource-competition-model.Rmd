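---
title: "A resource-competition model of multi-spine structural plasticity"
author: "SpineCompete"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{A resource-competition model of multi-spine structural plasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SpineCompete)
```

## The model and its assumptions

`SpineCompete` implements a minimal dynamical account of how dendritic
spines that are potentiated together compete for the molecular resources
needed to express structural plasticity. Two resource fields live on a
one-dimensional dendrite coordinate (µm): a fast potentiating resource $C$
— calcium and the molecules it immediately engages — and a slow dual-role
resource $P$ that is generated from an inactive precursor $P_{in}$ wherever
$C$ is present. The normalised spine size $S$ (baseline $=1$) integrates
both: $C$ always promotes growth, while the effect of $P$ switches sign at
a size threshold $\nu$ through the smooth decision function
$F(S) = -\tanh(\phi\,(S - \nu))$. This sigmoidal switch deliberately avoids
an abrupt potentiation/depression border: near $S=\nu$ there is a regime of
weak net change, between clear growth (small spines) and clear shrinkage
(large spines).

Key structural assumptions, inherited from the biology the model
abstracts:

* **Stimulation is instantaneous at $t=0$.** The uncaging train itself
  (about one minute) is not modelled; $t=0$ is its end, and model output is
  compared with data from $+2$ min onward. Snapshots inside the first two
  minutes are outside the model's validity window.
* **Resources are neither produced nor imported after stimulation.** All
  dynamics redistribute, convert or degrade the amounts fixed by the
  initial conditions; late robust growth in very large clusters must
  therefore come from the uncontested spine-specific store $C_s$.
* **Competition acts only through the initial allocation.** Each
  stimulation site receives $C_s + C_d D_i$ of the fast resource, where the
  allocation factor $D_i = (1 + d_i)/(N + \hat N)$ shares the dendritic
  pool $C_d$ among the $N$ stimulated spines and the $\hat N$ unstimulated
  spines lying within 2 µm of at least two stimulation sites. The proximity
  sum $d_i = \sum_{j \ne i} (r_{ij}/(1+r_{ij}))^{\lambda}$ releases the
  competition as distances grow. The inactive pool is correspondingly
  depleted by $1 - D_i$ at each site (clamped at zero where depletion
  kernels of tight clusters overlap — concentrations cannot be negative).
* **An effective, population-average description.** One parameter set
  describes the average spine; spine-to-spine parameter heterogeneity is
  not modelled.

Sham stimulations carry no initial resources, so the exact solution is
$S \equiv 1$; the package returns that analytically rather than
integrating.

## Parameters

| name | meaning | units | default |
|------|---------|-------|---------|
| `C_s` | spine-specific fast-resource store | a.u. | 0.003 |
| `C_d` | shared dendritic fast-resource pool | a.u. | 1 |
| `lam` | competition exponent $\lambda$ | — | 3 |
| `g_eff` | initial-kernel coefficient | µm⁻² | $-4\ln 2$ |
| `alpha1` | $C$ diffusion | µm²/min | 0.2 |
| `alpha2` | $C$ degradation | min⁻¹ | 0.25 |
| `beta1` | $P$, $P_{in}$ diffusion | µm²/min | 0.1 |
| `beta2` | activation of $P$ by $C$ | (a.u.·min)⁻¹ | 6 |
| `gamma` | $P$ degradation | min⁻¹ | 0.30 |
| `rho` | baseline inactive pool | a.u. | 1.35 |
| `phi` | switch steepness $\phi$ | — | 2 |
| `nu` | size threshold $\nu$ | normalised size | 1.42 |
| `zeta1` | size susceptibility to $C$ | a.u.⁻¹ min⁻¹ | 0.177 |
| `zeta2` | size susceptibility to $P$ | a.u.⁻¹ min⁻¹ | 0.45 |

Concentrations are in arbitrary units fixed by the fit; only ratios and
products such as $\zeta_1 C$ are meaningful. `g_eff` deserves comment: the
initial profile of each stimulation is a narrow Gaussian
$\exp(g_{\mathrm{eff}}(x-x_i)^2)$, and the default $-4\ln 2$ µm⁻² gives a
kernel with full width at half maximum of exactly 1 µm — a spine-head
length scale. The width is configurable because the mapping between a
dimensionless kernel constant and physical micrometres is a unit
convention, not an empirical quantity.

### The reference parameter set

The original imaging data are not shipped with the package and the source
study prints no fitted parameter values, so `referenceParameters()` is a
*reference* set — chosen once so that the model sits in the empirically
reported qualitative regime, and used as the ground truth of the synthetic
generator and the default starting point of fits:

* an isolated spine rises quickly, peaks a few minutes after stimulation
  and decays toward a sustained size above baseline (its abundant local
  $P$ first accelerates growth past $\nu$, then brakes it);
* co-located clusters potentiate less at $+2$ min the more spines share
  the site, because the inactive pool is depleted over a wider region and
  early $P$-driven growth is progressively lost (the $1/N$ trend);
* in 7- and 15-spine clusters the outermost spines receive larger
  allocation factors, generate more local $P$ while $C$ is still alive,
  and keep a persistent size advantage over the middle spines at 30–40
  min;
* 7 spines spaced by ≥30 µm behave like isolated spines (decoupling);
* reducing the $P$ susceptibility (as under calcineurin block) slows the
  post-peak decay; increasing it while lowering $\nu$ (as under CaMKII
  block) shrinks the peak.

Two compromises are worth stating plainly. First, the reference
potentiation magnitudes (peaks around 1.4–1.5) are smaller than typical
experimental peaks (1.8–2.0): the set prioritises reproducing the
*orderings* above, which all have to hold simultaneously under one
parameter vector. Second, the effective lifetime of $P$
($1/\gamma \approx 3$ min) is at the short end of the plausible range for
a slow protein resource; with much slower degradation every cluster
trajectory converges onto $\nu$ within the 40-min window and the
edge/middle structure collapses to a tie. Both are properties of this
reference point, not of the model: fits are free to move all 13 constants
(only `g_eff` stays fixed).

## Numerical scheme

The coupled system is integrated by Strang splitting: half a step of the
pointwise reactions (explicit midpoint rule), one step of diffusion
(Crank–Nicolson), half a step of reactions again — formally second order
in `dt`. Diffusion uses a conservative zero-flux (Neumann) stencil whose
columns sum to zero, so with $\gamma = 0$ the total $P_{in} + P$ is
conserved to rounding (the activation term only converts one into the
other, and the midpoint rule preserves the sum exactly). The grid extends
20 µm beyond the outermost spine on each side, keeping the boundaries
several diffusion lengths away over 40 min; spacing must resolve the
initial kernel with at least eight nodes per FWHM (0.125 µm at the
default width), which `initialC()` enforces. $S$ is integrated as a field
and read out at the grid node nearest each spine (a ±0.5 µm window average
is available via `window=`).

Defaults `dt = 0.02` min and `spacing = 0.125` µm satisfy the package's
convergence contract: halving `dt` changes any reported trajectory value
by well under $10^{-4}$ (measured $\sim 6\times10^{-7}$ at the reference
point) and doubling the grid density by under $10^{-3}$ (measured
$\sim 6\times10^{-4}$). Fitting and synthesis default to `dt = 0.05`
(fits use `dt = 0.1` in the recovery studies), trading a $\sim10^{-4}$
trajectory perturbation for speed. Non-finite field values abort the
integration with the offending time, which is how reaction rates beyond
the explicit step's stability limit surface.

## Fitting

The cost is the plain sum of squared differences between simulated and
target normalised sizes over stimulated spines and the $+2$ to $+40$ min
snapshots (pre-stimulation snapshots are excluded: the model is not valid
there, and after normalisation their mean is 1 by construction). The
fitted target is the cohort-mean trajectory, matching the effective
(average-spine) character of the model.

Gradients come from a **discrete adjoint** of exactly the scheme above:
one backward sweep applies the transposes of the Crank–Nicolson solves and
of the midpoint-rule Jacobians, accumulating sensitivities to the nine
dynamical constants, and the initial-condition adjoint fields are chained
analytically to `C_s`, `C_d`, `lam` and `rho` (the clamp in $P_{in}(x,0)$
contributes a subgradient of zero where active). Because the adjoint
differentiates the discretisation itself, it agrees with central finite
differences to $\sim10^{-6}$ relative error; the test suite asserts
$10^{-3}$ at ten random parameter points, and a central finite-difference
mode is available as a first-class alternative (`gradient = "fd"`).

Positivity is enforced by optimising in log-parameter space inside a
bounds box; L-BFGS-B runs from `nRestarts` (default 10) starting points —
the supplied start plus log-uniform seeded draws — and the best restart
wins. Start draws are prefix-stable in the restart count, so adding
restarts can only improve the best cost at a fixed seed. Identifiability
is *not* assumed: on synthetic cohorts the fitted trajectory reproduces
the generating trajectory (NMSE ≈ 1.02, sup-norm ≈ 0.016 in the shipped
recovery test) while individual constants can land far from the generating
values; parameter values are reported, trajectory recovery is what the
tests assert. Drug-condition refits (`fitDrugVariant()`) free only the
susceptibilities — plus the threshold for the CaMKII-block condition —
with the reported directions of change imposed as bounds.

## Statistics

The snapshot-averaged NMSE divides the squared prediction error at each
snapshot by the observations' squared deviation from their snapshot mean
and averages the ratios; its analytic minimum, attained exactly when every
prediction equals the snapshot mean, is 1. The weighted $R^2$ compares
predictions with snapshot means, weighted by inverse per-snapshot
variance, against a constant predictor at the grand mean. Snapshots with
zero observation variance carry no information for either metric and are
excluded with a warning. Both metrics use post-stimulation snapshots only
(a flag away from including all snapshots), consistent with the model's
validity window.

Decay structure is summarised by least squares of $a e^{-bt} + c$ with
$b \ge 0$. For fixed $b$ the model is linear in $(a, c)$, so the package
profiles: an inner linear solve per candidate $b$ and a deterministic
grid-plus-golden-section search over $b$ — no random starting values. Two
degeneracies are flagged rather than hidden: near-constant data leave $a$
(and $b$) unidentified, and $b = 0$ confounds $a$ with $c$, in which case
only their sum is determined and is reported through $c$. The
cohort-level bootstrap draws half of the experiments (rounded up) *with
replacement*, averages their mean trajectories, refits, and repeats 1000
times; replicate failures are excluded and counted. Between-paradigm
comparisons use Kruskal–Wallis followed by Dunn's pairwise rank test (with
the tie correction) and Benjamini–Hochberg adjustment — the procedure used
everywhere a false-discovery-rate correction is called for. Cohort means
are compared by Welch's unequal-variance $t$ test under the same
adjustment, and means carry studentised (bootstrap-$t$) 95% intervals.

## The synthetic-data generator

`generateCohort()` emulates the *structure* of the imaging datasets: per
spine, three pre-stimulation snapshots (−6, −4, −2 min) and
post-stimulation snapshots every 2 min to +40; cluster geometries whose
span statistics match the reported ones (3-spine spans uniform on
2.2–4.2 µm, mean 3.2; 7-spine spans log-normal with quartiles 5.6 and
14.1 µm; distributed-7 spacing three times the clustered draw; 15-spine
spans on 20–30.6 µm with mean 28.3); unstimulated spines as a Poisson
process at 0.66 µm⁻¹ (which reproduces the reported ≈7 competing
neighbours for a mean 7-spine cluster); and cohort sizes mirroring the
published experiment table (7 three-spine, 25 seven-spine, 13
fifteen-spine experiments, ...). Raw fluorescence is
`baseline × S × exp(ε)` with i.i.d. Gaussian log-noise (σ = 0.05 by
default — the true measurement-noise magnitude is unknown, so σ is a
knob) and log-normal per-spine baselines; normalising by a 3-snapshot
baseline then inflates the coefficient of variation to
$\sigma\sqrt{1 + 1/3}$, which the tests check.

What the generator does **not** emulate: spine-to-spine parameter
heterogeneity (the model is an effective average), temporal drift or
correlated noise, unequal spine counts per experiment, raw image stacks,
and any failure/exclusion process. Tests passing on synthetic cohorts
therefore demonstrate that the pipeline recovers what the model family can
express under idealised noise — not that the model is correct for real
dendrites.

## Design choices on open points

* $\hat N$ is a single global count entering every $D_i$ (the allocation
  formula carries no per-site subscript on it), and "close to multiple
  sites" means within the 2 µm radius of at least two distinct sites;
  both the radius and an explicit `nHat` override are exposed.
* Distances enter the proximity metric in µm through $r/(1+r)$, which is
  already bounded in $[0,1)$; no additional rescaling.
* Edge/middle splits follow the published convention — 1, 2 and 4 edge
  spines per side for 3-, 7- and 15-spine clusters — by sorted position,
  ties broken by spine id.
* `referenceLayout()` fixes deterministic mean-geometry layouts; its
  competing-neighbour counts are 2, 7 and 13 for the 3-, 7- and 15-spine
  paradigms (the 7-spine value is the reported estimate; the others scale
  with cluster length).
* Problem sizes in the shipped tests are desk-scale by design: recovery
  fits use the 7-experiment three-spine cohort with 10 restarts at
  `dt = 0.1`, bootstrap analyses use 1000 replicates, and property loops
  use 10–25 seeded random cases.

## Known limitations

* The 1-D dendrite has no branch points, spine necks or 3-D geometry, and
  resources are conserved quantities — no synthesis, import or transport
  beyond diffusion.
* Reflection symmetry of trajectories is exact only up to the
  nearest-grid-node readout (about $10^{-4}$ at default resolution for
  off-grid mirrors).
* JSON round-trips of fitted parameters are accurate to ~15 significant
  digits (CSV interchange uses 17 and is bit-exact for doubles).
* The reference parameter set underestimates absolute potentiation
  magnitudes (see above); quantitative work on real data should refit.
* With strongly persistent $P$, all trajectories converge to the
  threshold $\nu$ and between-spine structure vanishes; fits in that
  regime are poorly identified in $\phi$ and $\zeta_2$.
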