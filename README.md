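# woundabc

Simulation-based inference of cell motility and cell–cell adhesion
parameters from wound-healing (scratch) assays, and simulation-based
comparison of experimental designs for that inference.

## Who this is for

Quantitative cell biologists and modellers who (a) represent a scratch
assay as a lattice exclusion-process agent-based model (ABM), (b) want
posterior distributions — not point estimates — for the motility and
adhesion parameters of that model, and (c) want to know *which
experimental design* (more replicates? a wider microscope field of view?)
makes those parameters identifiable.

## The model

Agents (cells) live on an `Lx × Ly` square lattice, at most one per site
(volume exclusion). Columns are indexed `i = 1..Lx`, rows `j = 1..Ly`;
the y direction is periodic, the x boundaries are either reflecting
(`no_flux`) or open (`flux`). Movement attempts occur at rate `P_m` per
agent per minute (simulated exactly with the Gillespie algorithm); a
selected agent moves to a neighbouring site with per-direction transition
probability

- model A: `T_A = (1 − nα) / 4` (linear in the occupied-neighbour count `n`),
- model B: `T_B = (1 − α)^n / 4` (multiplicative),

where `α` is the adhesion parameter: `α > 0` means adhesion (crowded
agents move less), `α < 0` repulsion. Admissibility of the summed
transition probabilities bounds `α` to `[−1/3, 1/4]` (A) and `[−1/3, 1]`
(B); see `admissible_alpha_range()`.

Three summary statistics reduce a simulation `D` to `S(D)`: the average
horizontal displacement of agents, the per-column density profile
`C_t(i)`, and a pair-correlation function (PCF)
`q_t(m) = c_t(m) / ĉ_t(m)` — observed over expected horizontal pair
counts at separation `m`, the expectation being that of `N` agents placed
uniformly at random (`ĉ_t(m) = L_y²(L_x − m)ρρ̂`). ABC (rejection and
MCMC variants) compares ensemble-averaged statistics of observed and
simulated data with the L1 distance
`d = Σ_t Σ_r |S(D)_{r,t} − S(D̃)_{r,t}|`, and the information gained by an
experiment is measured by the Kullback–Leibler divergence of the
discretised posterior from the uniform prior.

## Worked example

Simulate the idealised double-sided wound, infer its parameters back from
its own synthetic data, and measure the information gain:

```r
library(woundabc)

design   <- design_unrealistic(Lx = 50, Ly = 50)   # scaled-down wound assay
truth    <- abm_params(pm = 0.5, alpha = 0.1, model = "A")
observed <- generate_synthetic_data(design, truth, seed = 1000)

post <- abc_rejection(design, abc_prior("A"), observed,
                      distance_spec("pcf"),
                      n_sims = 500, n_accept = 25, seed = 1)
posterior_mode(post)
#> # A tibble: 1 × 3
#>      pm  alpha    prob
#>   <dbl>  <dbl>   <dbl>
#> 1 0.398 0.0285 0.00390
posterior_kld(post, n_bins = 16)
#> [1] 3.123556
```

The mode sits close to the generating parameters `(0.5, 0.1)`; the KLD of
about 3.1 nats (on a 2⁴ × 2⁴ grid — appropriate for a 25-sample accepted
set) quantifies how much the PCF data narrowed the prior. An accepted set
re-ranked by the displacement statistic (`accept_top(post,
"displacement")`) gives a lower KLD: displacement trades `P_m` against
`α` along a ridge and identifies neither well.

Plotting: `autoplot()` works on occupancy states, summary datasets,
posteriors and grids; `tidy()`/`glance()` return tibbles for all fitted
objects.

A command-line interface with the same functionality is installed at
`inst/cli/woundabc` (subcommands `simulate`, `synth`, `abc-reject`,
`abc-mcmc`, `kld`, `variance`, `compare-designs`).

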