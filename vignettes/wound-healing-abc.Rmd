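---
title: "Inferring motility and adhesion from scratch assays: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring motility and adhesion from scratch assays: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its science: the
agent-based model and its assumptions, the summary statistics, the
approximate Bayesian computation (ABC) machinery, the design-comparison
apparatus, and — importantly — the numerical and statistical choices made
where the problem left the design open. Code chunks are illustrative and
not evaluated at build time; everything shown is exercised by the test
suite and `scripts/acceptance.R`.

## The agent-based model

Cells are agents on an `Lx × Ly` square lattice with at most one agent
per site (an exclusion process). A site is `(i, j)` with column
`i = 1..Lx` and row `j = 1..Ly`, 1-based everywhere in the interfaces.
Time is continuous: each agent carries a movement *attempt* rate `P_m`
(min⁻¹), and sample paths are generated exactly with the Gillespie
algorithm. When an agent is selected it directs probability

* model A: `T_A = (1 − nα)/4`
* model B: `T_B = (1 − α)^n / 4`

at each eligible neighbouring site, where `n` is its occupied-neighbour
count. With probability `1 − Σ T` the attempt lapses. Attempts into
occupied sites are aborted, which is statistically identical to lapsing,
so the implementation assigns probability mass only to empty targets.
`α > 0` is adhesion (crowding suppresses movement), `α < 0` repulsion.
Requiring the summed probability over free sites to stay in `[0, 1]` for
every `n` bounds `α`: `[−1/3, 1/4]` for model A, `[−1/3, 1]` for model B
(`admissible_alpha_range()`); the default priors `[−0.2, 0.25]` (A) and
`[−0.2, 1]` (B) are strict subsets.

**Boundaries.** The y direction is always periodic (cells drift through
the top and bottom of a microscope field at roughly equal rates). The x
direction never wraps: `no_flux` edges reflect (the off-domain direction
receives no probability; the denominator stays 4), `flux` edges are open
— an agent selecting the off-domain direction leaves the simulation and
is dropped from the registry, with its record retained for bookkeeping.
Off-lattice positions are not sites: they contribute 0 to `n`.

**Replenishment.** With an open left boundary the column-1 monolayer
would drain. After every event that vacates a column-1 site, agents are
added to empty column-1 sites chosen uniformly at random until the
column's density is at or above a target (default: the initial column-1
density, which is 1 under the default initial profile). Added agents get
fresh ids with `init_col = 1`. A lapse at a full column cannot trigger
replenishment — only successful vacating moves do.

**Tiny-lattice convention.** The four movement directions are treated as
distinct even if the periodic wrap maps both vertical directions to the
same site (`Ly = 2`: that site counts twice in `n` and receives `T`
twice); a direction mapping to the agent's own site (`Ly = 1`) is
dropped. Production lattices have `Ly ≥ 23`, where the convention is
vacuous; it only pins down the semantics of the miniature lattices used
in the exact-CTMC validation tests, whose independently enumerated
generators use the same stated convention.

**Event engine.** Since every agent has the same attempt rate, the total
rate is `N·P_m` and inter-event times are `Exp(N·P_m)`; the acting agent
is chosen uniformly. When `N` cannot change during a sampling interval
(no-flux, no replenishment), the number of attempts in the interval is
drawn once as `Poisson(N·P_m·Δt)` — an exact equivalent that skips the
per-event exponential clock. With open boundaries `N` varies and the
per-event clock is used, with the total rate updated immediately on
removal or addition. The hot loop draws from an internal xoshiro256++
stream seeded from R's RNG at each call, so `set.seed()` makes every
simulation, sampler and study bit-reproducible while keeping the loop at
tens of millions of events per second.

## Initial conditions

Two generators emulate the two experimental settings:

* `initialize_unrealistic()` — the idealised double-sided wound: columns
  1–10 and `Lx−9`–`Lx` fully occupied, the space between is the wound.
  Deterministic; `N = 2·10·Ly` (2000 at the default 100 × 100). Its
  uniformity is unattainable in a real assay — that is the point of the
  companion setting.
* `initialize_from_column_densities()` — single-sided: column `i`
  receives `round(density_i · Ly)` agents placed uniformly at random
  within the column. The default profile
  (`default_column_densities()`: 6 fully occupied columns, a linear ramp
  0.75/0.5/0.25 over the next 3, then empty) is a stand-in for an
  averaged experimental initial frame, chosen to mimic a confluent band
  with a diffuse leading edge on the 23-column field of view
  (23 × 23 sites of 26 µm ≈ a 597 µm field). Measured profiles can be
  supplied as a numeric vector or ingested from a 0/1 occupancy CSV.

What the generator does *not* emulate: proliferation, cell-size
variation, sub-lattice positioning, imaging noise, and any correlation
between neighbouring columns of the initial frame. Passing tests
therefore validate the inference machinery on data whose generative
model is exactly the ABM — they show the method recovers parameters when
the model is right, not that the model is right for any particular cell
line.

## Summary statistics

All three statistics are computed per sampling time (defaults
`t = 240, 480, 720` min, i.e. 4, 8, 12 h):

* **Average horizontal displacement** — mean `|i_k(t_i) − i_k(t_f)|`
  over agents present at both times, in site units. `t_i` defaults to 0;
  agents that exited through an open boundary or were added by
  replenishment are excluded (both positions are required). Repulsion
  raises it, adhesion lowers it.
* **Density profile** — occupied fraction per column, length `Lx`.
* **Pair-correlation function (PCF)** — `q_t(m) = c_t(m)/ĉ_t(m)` for
  horizontal separations `m = 1..Lx−1`, where `c_t(m)` counts unordered
  agent pairs at column distance `m` (never wrapping the x boundary,
  same-column pairs excluded but exposed via `same_column_pairs()`), and
  `ĉ_t(m) = Ly²(Lx−m)·ρ·ρ̂` with `ρ = N/(LxLy)`,
  `ρ̂ = (N−1)/(LxLy−1)` is the expectation under uniform-random
  placement, so `q ≡ 1` means no horizontal structure beyond exclusion.

Ensemble averages over replicates are arithmetic means; variances are
unbiased (n−1), because replicate counts are as small as 5.

## ABC

The distance between two datasets is the L1 norm of the difference of
their *ensemble-averaged* statistics, summed over sampling times
(optionally over several statistics with weights; when combining, each
statistic can be scaled by a pilot-run median to balance magnitudes).

`abc_rejection()` draws parameters from the uniform prior box, simulates
one dataset per draw — with the same replicate protocol as the observed
data, so like is compared with like — and accepts the `n_accept`
smallest distances. Per-statistic distances for all three statistics are
stored for every draw, so `accept_top()` re-derives the accepted set
under a different statistic without re-simulation.

`abc_mcmc()` is a Marjoram-style chain: Gaussian random-walk proposals,
independent per coordinate, default scales 5% of each prior width;
out-of-box proposals are rejected outright (with a uniform prior and a
symmetric kernel the in-box Metropolis ratio is 1); otherwise the
proposal is accepted iff its simulated distance is at most `ε`. The
default `ε` is a pilot-run quantile (`choose_epsilon()`, nearest-rank;
1% by default). With `ε = ∞` no simulation is needed and the chain
targets the prior — a property the tests exploit.

## Posteriors, KLD, and two estimator caveats

Posterior samples are histogrammed onto `2⁶ × 2⁶` equal-width bins
spanning the prior box (half-open bins, last bin closed; the prior grid
is the analytic uniform `1/4096`, not a sampled histogram), and the
information gain is `D_KL(p‖π) = Σ p log(p/π)` with `0·log 0 = 0`.
Natural logarithms by default; `base = "2"` reports bits for
sensitivity.

Two small-sample caveats drove design choices, both visible in the
package's own desk-scale studies (hundreds of simulations, tens of
accepted samples) rather than the full-scale campaigns (10⁴ simulations,
100 accepted, days of CPU):

* **Histogram-KLD saturation.** When the accepted count `k` is far below
  the bin count `K`, almost every sample lands in its own bin and the
  plug-in KLD collapses to `log(K/k)` *regardless of the statistic*.
  Desk-scale comparisons therefore use a `2⁴ × 2⁴` grid (`n_bins = 16`),
  where bins are shared and the estimator discriminates; the `2⁶` grid
  remains the default for full-scale work.
* **Mode estimation.** The argmax bin of a 25-sample histogram on 4096
  bins is a count-1 bin chosen almost arbitrarily. `posterior_mode()`
  therefore smooths with a Gaussian kernel before taking the argmax
  (bandwidth 5% of each prior width — the same fraction as the MCMC
  proposal scale; `smooth = FALSE` recovers the raw mode).

A related scientific observation: at strongly reduced scale (a 50 × 50
wound, 500 simulations) all three summary statistics share a nearly flat
`P_m`–`α` valley — higher motility compensated by stronger adhesion —
and the PCF's advantage over the density profile is within seed noise.
At the full 100 × 100 geometry the PCF's advantage re-emerges even at
the reduced simulation budget. The package's tests assert the ranking at
the scale they run at; the acceptance script reports it at the full
geometry.

## Design comparison and variance

`compare_designs()` scores experimental designs by the KLD of the
posterior obtained from synthetic data generated under each design (plus
the posterior mode and its distance to the truth); independent seed
streams per arm derive from one master seed. `scale_design()` grows `Ly`
by an integer factor while keeping the initial column densities — the
simulation analogue of widening the field of view; the preset pair
23 × 23 / 23 × 184 differs in area by exactly 8.

`variance_study()` reports, per statistic element, the across-replicate
sample variance within each dataset (`var_within`) and the ensemble
average per dataset; the variance of the latter across regenerated
datasets falls like `1/n_replicates` (a property the tests check with a
log–log slope within ±0.2 of −1). The observed ordering — five
replicates on the 8×-larger domain beat even 100 replicates on the
small domain for the PCF at `t = 720` — reflects the pair-count budget:
the PCF is built from `N(N−1)/2` pairs (minus same-column pairs), which
grows quadratically with domain size but only linearly with replicates.

## Problem sizes used by the shipped studies

Chosen as the smallest sizes at which each effect is statistically
stable: recovery and ranking use 500 simulated datasets with 25 accepted
(10-replicate protocol) over 3 seeds; the design comparison uses 150
datasets per arm with 15 accepted (arms: 23 × 23 with 50 replicates vs
23 × 92 with 5) over 3 seeds; the variance ordering uses 100 vs 5
replicates; the exact-CTMC validation uses 10⁴ runs (total-variation
tolerance 0.02, ≈ 4 Monte-Carlo standard errors); CSR calibration of the
PCF uses 10³ draws at 3 standard errors.

## Degenerate inputs and numerical details

* `P_m = 0`, a fully occupied lattice, and an empty domain all
  short-circuit to frozen snapshots.
* The PCF requires `N ≥ 2` (`ρ̂` is undefined below that) and errors
  otherwise; displacement errors when no agent is present at both times.
* Replenishment tops up to `⌈density·Ly⌉` (computed with a 10⁻⁹ slack
  against floating-point roundoff of products like `0.8·10`).
* Distance ties in rejection are broken by draw order; the accepted set
  is exactly the `n_accept` order statistics.
* Grid normalisation is checked to `10⁻⁸` before a KLD is computed, and
  posterior mass on a zero-prior bin is an error rather than an `Inf`.
* Serialisation uses full-precision floats (`digits = NA` JSON, readr
  CSV), so config → run → provenance → re-run round-trips bit-identically.

## Known limitations

* No proliferation, death (beyond flux exit), cell-cycle state, or
  directed motility; constant parameters across the population.
* Horizontal-only PCF and displacement: appropriate for wound-front
  geometry (the initial conditions are translation-invariant vertically),
  uninformative for radially structured data.
* The single-sided default initial profile is a synthetic stand-in, not
  a measured profile; supply measured column densities for real work.
* Desk-scale ABC budgets identify the `P_m`–`α` ridge but localise along
  it only weakly; full-scale budgets (10⁴ simulations) are required for
  posteriors comparable to the original study's, and nothing in the
  shipped tests asserts otherwise.
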