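# metaglv

Simulation and analysis of **random generalised Lotka–Volterra (GLV)
metacommunities**: many-species communities with random interaction
networks, replicated over a periodic lattice (a ring or a torus) and coupled
by per-species nearest-neighbour dispersal.

The package is aimed at theoretical ecologists studying stability,
feasibility and synchronisation in large model ecosystems. The well-mixed
question — *how much interaction strength can a random community bear before
it loses feasibility, sheds species, and finally collapses?* — acquires a
spatial twist once local communities can differ: out-of-phase local
oscillations can average into nearly constant global abundances, letting the
spatial system hold more species, and hold them beyond the classical
stability boundaries of the non-spatial model.

## Model

Local dynamics at every grid point follow the GLV equations

    dφ_i/dt = φ_i r_i (1 − φ_i/K_i) + σ φ_i Σ_j A_ij φ_j

with interaction matrix `A` (connection density `c = 0.5`, non-zero entries
Normal(μ = −0.5, 1), zero diagonal) and interaction-strength scale `σ`.
On the lattice each species additionally diffuses to nearest neighbours with
its own rate `D_i`, drawn uniformly with mean `μ_D = 10^a` and s.d.
`b·μ_D`, `b ∈ (0.3, 0.4]`:

    ∂φ_{i,α}/∂t = [local GLV] + D_i · Δφ_{i,·}|_α        (periodic Laplacian, h = 1)

Key statistics computed per run: the number of oscillatory grid points, the
**synchronisation index** (mean over extant species of the maximum
between-patch Fourier phase shift at the species' dominant frequency; 0 =
synchronised, π = fully anti-phase), mean oscillation amplitude, global
diversity (species extant anywhere), and global (spatial-mean) abundances.
`feasibility_boundary()` and `stability_scan()` locate the σ-regimes of the
non-spatial system; `run_sweep()` maps the (diffusion magnitude × σ) plane.

## Worked example

```r
library(metaglv)

# a 20-species community on a 50-patch ring, moderate dispersal
sys <- build_system(N = 20, sigma = 0.8, mu_D = 1e-3, b = 0.35, seed = 5)
tr  <- integrate_system(sys, t_end = 1500)
summarise_run(tr)
#> Run summary: 50/50 grid-points oscillating, diversity 15/20,
#>   sync index = 3.139 rad, mean amplitude = 1.18

# same community, strong dispersal: the lattice synchronises
sys2 <- build_system(N = 20, sigma = 0.8, mu_D = 1, b = 0.35, seed = 5)
summarise_run(integrate_system(sys2, t_end = 1500))
#> Run summary: 50/50 grid-points oscillating, diversity 14/20,
#>   sync index = 0.005 rad, mean amplitude = 0.988
```

At weak dispersal every patch oscillates but the phases are spread across
the ring (index ≈ π: unsynchronised), so the *global* abundances barely
fluctuate and 15 of 20 species persist. At strong dispersal the same
community oscillates in unison (index ≈ 0): global abundances swing with
full local amplitude and one more species is lost. That contrast — and its
systematic mapping over the (μ_D × σ) plane — is what the package is for.

Other entry points:

* `preset_stabilisation_example(seed)` — searches seeded communities for
  the showcase phenomenology: σ beyond the non-spatial fixed-point range,
  unsynchronised local oscillations, near-constant global means, no
  diversity loss.
* `preset_diffusion_scan(seed)` — one community at four diffusion decades.
* `metaglv_cli()` / `inst/cli/metaglv.R` — `generate`, `simulate`,
  `measure`, `scan-regimes`, `sweep`, `preset` subcommands for scripted use.
* `write_system()` / `read_system()` — JSON + text array container with
  bit-exact round-trips.

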