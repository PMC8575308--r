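---
title: "Methods: spatial GLV metacommunities in metaglv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial GLV metacommunities in metaglv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`metaglv` simulates generalised Lotka-Volterra (GLV) communities coupled by
nearest-neighbour dispersal on a periodic lattice. The local (well-mixed)
dynamics of species $i$ are

$$\frac{d\phi_i}{dt} \;=\; \phi_i r_i\Big(1 - \frac{\phi_i}{K_i}\Big)
  \;+\; \sigma\,\phi_i \sum_{j=1}^N A_{ij}\phi_j ,$$

with abundance $\phi_i$, intrinsic growth rate $r_i$, carrying capacity
$K_i$, an $N \times N$ interaction matrix $A$ and an overall
interaction-strength scale $\sigma$ (the standard deviation of interaction
strengths, the usual proxy for community complexity). On the lattice, every
grid point carries a copy of this community and species additionally hop to
their nearest neighbours:

$$\frac{\partial \phi_{i,\alpha\beta}}{\partial t}
 = \underbrace{\phi_{i,\alpha\beta} r_i (1 - \phi_{i,\alpha\beta}/K_i)
 + \sigma \phi_{i,\alpha\beta} \textstyle\sum_j A_{ij}\phi_{j,\alpha\beta}}_{\text{local GLV}}
 + D_i\, \Delta_h \phi_{i,\cdot} \big|_{\alpha\beta},$$

where $\Delta_h$ is the discrete Laplacian (three-point stencil on a ring,
five-point on a torus) with periodic wrap and patch spacing $h = 1$, and
$D_i$ is the per-species dispersal rate, identical at all grid points.

A note on the discretisation: the consistent second-difference operator
divides by $h^2$ in any dimension, and that is what both
`discrete_laplacian()` and the compiled right-hand side use. (One sometimes
sees the one-dimensional stencil quoted with a bare $h$ denominator; at the
default $h = 1$ the numbers coincide, but we treat the $h^2$ form as the
correct one and apply it uniformly.)

## The random ensemble

`sample_interaction_matrix(N, c, mu, seed)` draws the classic random
ensemble: each off-diagonal entry is independently non-zero with probability
$c = 0.5$ (connection density) and non-zero entries are
$\mathcal{N}(\mu, 1)$ with $\mu = -0.5$, so competitive and amensalistic
links dominate but all interaction types occur. Three choices deserve
comment because the ensemble definition does not fix them:

* **Diagonal.** $A_{ii} = 0$. Self-regulation is carried entirely by the
  logistic $r, K$ term; a non-zero diagonal would double-count it. The
  constructor enforces this (you can pass any matrix with zero diagonal if
  you want other conventions for the off-diagonal part).
* **Zero-pattern symmetry.** Whether $A_{ij} \neq 0$ implies
  $A_{ji} \neq 0$ is a modelling choice; we use independent Bernoulli draws
  per ordered pair, the simplest reading.
* **Rates and capacities.** $r_i = K_i = 1$ for all species by default.
  This fixes the time unit ($1/r$) and the abundance unit ($K$), so that
  $\sigma$ alone tunes complexity; both are configurable everywhere.

`sample_diffusion_rates(N, mu_D, b, seed)` draws $D_i$ i.i.d. uniform with
mean $\mu_D$ and standard deviation $b\,\mu_D$, i.e. on
$[\mu_D(1-\sqrt3 b),\, \mu_D(1+\sqrt3 b)]$. Restricting $b \in (0.3, 0.4]$
keeps the supports of consecutive decade means $10^a$ and $10^{a+1}$
disjoint, so "diffusion magnitude" is well defined per run. We admit the
boundary value $b = 0.4$ (where the supports are still disjoint:
$1.693\cdot10^a < 3.07\cdot10^a$) because the canonical showcase setting
$\sigma_D = 0.4\,\mu_D$ sits exactly there. $\mu_D = 0$ yields exact zeros:
the disconnected, non-spatial limit. When `b` is not fixed by the caller it
is drawn once per system uniformly from $(0.3, 0.4)$, seeded.

All samplers are pure functions of their arguments including the seed; a
master seed splits deterministically into matrix / spread / diffusion /
initial-condition streams (`derive_seeds()`), so any component can be
regenerated independently.

## Integration

The lattice ODE system (up to $M \times N$ = a few thousand equations) is
integrated by a compiled adaptive Dormand-Prince 5(4) stepper
(`src/glv_integrate.cpp`), with relative tolerance $10^{-8}$ and absolute
tolerance $10^{-10}$ by default and PI-free step control clamped to
$[0.2, 5]\times$ per step. The pre-installed environment offers no ODE
solver package, which is why the integrator is part of the package; a test
verifies that halving the tolerances changes test trajectories by less than
$10^{-5}$ relative, i.e. results are converged rather than
tolerance-limited. Explicit stepping is adequate here: the stiffest terms
are the diffusive couplings, whose eigenvalues are bounded by
$4 D_{\max} d / h^2 \lesssim 14$ at the largest diffusion level used, well
within the stability region at the step sizes the error control selects.

Defaults the model text does not fix, and how we chose them:

* **Initial conditions.** The interior fixed point $\phi^*$ (component-wise
  absolute value if infeasible), perturbed multiplicatively per grid point
  and species by lognormal noise with `sdlog = 0.2`, seeded. Per-point
  perturbation is essential: the spatially homogeneous manifold is exactly
  invariant (a property we test), so an unperturbed lattice could never
  desynchronise. A `"uniform"` preset (i.i.d. uniform on $(0,1]$) is also
  provided and is what the non-spatial regime scan uses.
* **No extinction floor.** Abundances are never clamped to zero during
  integration (solver undershoots beyond $-10^{-9}$ flag the run as
  diverged; smaller ones are clipped). Near-extinct species can therefore
  re-grow, which is deliberate: the oscillatory regimes of interest show
  species dipping to tiny abundances and returning. Extinction is decided
  at measurement time by threshold.
* **Horizon.** Default `t_end = 2000` with the first half discarded as
  transient. This matters: just above the feasibility boundary the
  community relaxes through a weakly damped focus, and with short windows
  those decaying ringing transients are easily misread as oscillations.
  Tests that need many runs shorten the horizon explicitly and say so.
* **Geometry.** A ring of $L = 50$ patches by default (two-dimensional
  tori are fully supported and tested); one-dimensional lattices carry the
  same phenomenology at much lower cost.

## Measurements

After discarding the transient, each grid point is classified as
`fixed_point` or `oscillation`: a point is a fixed point when every locally
extant species' relative fluctuation range $(\max-\min)/\max(\text{mean},
\text{floor})$ stays below `rel_tol` $= 10^{-3}$. The extinction floor is
$10^{-4}$ (in units of $K = 1$); both are configurable in
`measure_config()` because the underlying cut-offs are conventions, not
model facts.

Oscillation amplitude is half the peak-to-peak range. Spectral quantities
use a mean-removed, Hann-windowed discrete Fourier transform; the dominant
frequency is the non-DC bin of maximal amplitude. The synchronisation index
of a run is computed per species at that species' own dominant bin (the bin
with the greatest summed windowed power over the grid points where the
species is locally extant): the phases at that bin are compared between all
grid-point pairs exactly ($M \le$ a few hundred makes $O(M^2)$ cheap), each
difference wrapped into $[0, \pi]$, and the index is the mean over extant
oscillating species of the maximum pairwise shift. Zero means the lattice
oscillates in unison; $\pi$ means some pair is in perfect anti-phase. At a
lattice-wide fixed point the index is undefined and reported as missing,
never as 0.

Diversity is global, "extant anywhere": a species counts as extant when its
time-averaged abundance exceeds the floor in at least one grid point. This
matches the recolonisation narrative (a species rescued by one patch is not
extinct); the per-point extant masks are kept alongside. Whether the
"average amplitude" statistic should average over species only or over
species $\times$ grid points is likewise a convention; we average over
locally extant species at oscillating grid points and also report the
per-species marginal.

## Regime structure in $\sigma$

For the non-spatial model, increasing $\sigma$ takes a random community
through three regimes: a feasible phase (the interior equilibrium
$(\mathrm{diag}(r/K) - \sigma A)\phi^* = r$ is positive and linearly
stable), a structurally unstable phase (stable equilibria exist only with
some species extinct), and collapse (no stable many-species equilibrium;
persistent oscillations or a crash to a much smaller community).

`feasibility_boundary()` bisects the predicate "feasible and linearly
stable" in $\sigma$. `stability_scan()` operationalises the rest by
simulation: at each $\sigma$ it integrates from several seeded random
starts (default 5; the structurally unstable region can hold multiple
alternative equilibria, so one restart under-samples), verifies any
apparent fixed point by solving the exact equilibrium of the surviving
subcommunity and checking the full Jacobian (which includes the invasion
rates of the excluded species), and labels the $\sigma$ `feasible`,
`structurally_unstable`, or `collapsed`. Two refinements keep finite
horizons honest near bifurcations, where modes decay at rates of
$10^{-3}$ and slower: species on a clear downward trend (tail-window mean
below half the previous window's) are treated as prospective extinctions
and excluded from the settledness assessment, and a tail that is still
ringing but has shrinking, moderate amplitude is resolved by the exact
equilibrium-plus-Jacobian check rather than by waiting for the trajectory
— a genuine limit cycle keeps its amplitude and its extant-set equilibrium
is not stable, so the two cases separate cleanly. Exhaustive fixed-point enumeration
over $2^N$ subcommunities is intractable and is not attempted. A stable
equilibrium that lost more than half the pool counts as collapsed; the
one-half fraction is a package convention for "substantially smaller
community" and is configurable.

Empirically — and this shaped several defaults — random communities at
$\mu = -0.5$ hold on to trimmed stable equilibria for a long stretch of
$\sigma$ (often several times the feasibility boundary) before genuinely
losing all stable fixed points, and near that onset the surviving
oscillations can be nearly critical (tiny amplitudes). The
`preset_stabilisation_example()` search therefore walks $\sigma$ upward in
multiples of the feasibility boundary (default factors 1.5-6) and stops at
the first collapse.

## What the synthetic world does and does not establish

The generator *is* the stated study system: there is no external data. A
green test therefore establishes that the implementation reproduces the
mathematical consequences of that stated world — the ensemble moments, the
fixed-point algebra, diffusion conservation, the homogeneous invariant
manifold, phase/amplitude recovery on planted signals, and the directional
trends (spatial rescue of diversity, amplitude damping at intermediate
dispersal, synchronisation growing with dispersal) on scaled-down
ensembles. It does not establish anything about real ecosystems: the
ensemble has no trophic structure, no spatial heterogeneity in parameters,
dispersal only between nearest neighbours, and every patch is identical by
construction.

Scaling notes for the test suite: the acceptance tests run the full stated
system sizes ($N = 20$, $L = 50$) but shorten horizons (500-1500 time units
instead of 2000) and use ensembles of 5-20 communities so the whole suite
fits in a desktop-scale budget; each file states its scaling where it
deviates from the package defaults.

## Known limitations

* Long weakly-damped transients near bifurcations can still be classified
  as oscillatory at short horizons; the classifier is a threshold rule, not
  a spectral test of sustainedness.
* The Fourier phase at a single bin is a biased lag estimator for
  non-sinusoidal or drifting cycles; the planted-signal tests quantify the
  error only for clean tones (one bin, $2\pi/W$).
* The collapse label depends on the restart budget: a stable equilibrium
  missed by all restarts mislabels the $\sigma$ as collapsed. Five restarts
  were chosen as a compromise; raise `n_restarts` for tighter scans.
* Explicit stepping would become inefficient (not incorrect) for diffusion
  rates far above the $\mu_D = 10$ decade.
* On a 50-patch ring at $\mu_D = 10^{-2}$, weak (near-onset) oscillations
  tend to phase-lock across the lattice, while strongly incoherent
  oscillation persists only at violent amplitudes. "Nearly constant global
  abundances alongside large local swings" is therefore a matter of degree:
  the local-to-global variability separation approaches the incoherence
  bound $\sqrt{2M}$, but per-species global CVs in the incoherent regime
  remain at the 0.1-0.5 level. `preset_stabilisation_example()` reports
  per-candidate diagnostics so the degree achieved is always visible.

## A worked example

```{r example, eval = FALSE}
library(metaglv)

sys <- build_system(N = 20, sigma = 0.3, mu_D = 1e-2, b = 0.4, seed = 5)
tr  <- integrate_system(sys, t_end = 1000)
summarise_run(tr)
spatial_regime(summarise_run(tr))
```
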