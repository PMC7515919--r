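---
title: "Modelling range-selective multivalent adsorption"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling range-selective multivalent adsorption}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rangebind)
```

## The model

A multivalent particle — a nanoparticle, polymersome or virus carrying
`N_L` ligands in its contact region — adsorbs on a surface carrying `N_R`
receptors. Its occupation probability of an adsorption site follows a
Langmuir-like isotherm

$$\theta = \left\langle \frac{z\,q}{1 + z\,q} \right\rangle, \qquad
q = v_\mathrm{bind}\, e^{-\beta F_\mathrm{tot}}, \qquad
v_\mathrm{bind} = \pi R^2 L,$$

where `z` is the bulk activity (number density), `R` the effective
particle radius and `L` the binding range, set to the ligand tether's
gyration radius `R_g`. The angle brackets average over Poisson-distributed
counts (spatial inhomogeneity of grafting) and, optionally, the particle
size distribution. All energies are dimensionless (units of `kT`), lengths
in nm, so `z` in nm^-3 makes `zq` dimensionless.

`F_tot` has an attractive part from ligand-receptor bond formation and a
repulsive part from excluded volume. The attraction is bracketed by two
binding topologies:

* **indifferent** (`f_att_indifferent()`): at most one bond at a time,
  `beta F = -ln(1 + N_L N_R chi)` with bond strength
  `chi = exp(-beta dG)`. We evaluate the full logarithm rather than its
  large-argument expansion so that zero-count systems give exactly zero.
* **radial** (`f_att_exact()`): every ligand can reach every receptor,
  one bond per binder per configuration,
  `beta F = -ln sum_k C(N_L,k) C(N_R,k) k! chi^k`. The sum is accumulated
  in the log domain (log-sum-exp over log-factorials); counts of order
  10^3 stay finite.

The radial case is also solved in a self-consistent mean field
(`solve_bonds()`): the unbound probabilities obey
`p_L + N_R p_L p_R chi = 1` and its mirror, with
`beta F = sum_i N_i (ln p_i + (1 - p_i)/2)`. The closed-form root is
rearranged through its conjugate whenever the leading coefficient is
non-negative, avoiding catastrophic cancellation as `N chi -> 0`. The
mean field accepts real-valued (averaged) counts, which the combinatorial
sum cannot. An arbitrary bipartite topology version
(`solve_bonds_network()`) uses damped fixed-point iteration (damping 0.5,
tolerance 1e-12, at most 1e5 iterations) and reproduces the closed form on
complete bipartite graphs.

### Accuracy of the mean field

The saddle-point free energy tracks the exact sum closely in asymmetric or
moderately bonded systems (well under 1 kT). At full bond saturation on
the balanced diagonal (`N_L = N_R = n`, strong bonds) it misses the
Gaussian-fluctuation correction and the gap approaches `0.5 ln(2 pi n)` —
about 2.4 kT at `n = 20` — which the test suite asserts as the true
structure. Inside the adsorption averages this regime is rarely visited
(the Poisson mixtures are dominated by asymmetric pairs), but users
pushing balanced, strongly bonded systems should prefer
`f_att_exact()`.

## Repulsion

Receptors inserting into the particle's protective brush pay
`A(delta) kT` each (`repulsion_coefficient()`): the curved-surface brush
insertion expression with brush height
`h0 = N (nu a^2 / 3 sigma0)^{1/3}` and curvature exponent `gamma = 3` for
`h0/R_np > sqrt(3) - 1`, else `(1 + h0/R_np)^2` (continuous at the
boundary). `A` vanishes at `delta = 1` (particle at the brush edge) and is
`V_R sigma0^{-3/2}` at full compression. Ligands confined against the
target surface pay `B kT` each; `B` either comes directly from
configuration or from the Gaussian-chain-near-wall fit
`B(r) = a exp(-b (r/R_g - c))` with `a = 3.1995`, `b = 4.1662`,
`c = 0.4996`, giving `B = 0.40` at `r = R_g`.

Both contributions are linear in their counts. That linearity against the
asymptotically logarithmic growth of the attraction
(`f_att_limiting()`: `-N_L ln(1 + N_R chi)` at high receptor excess) is
the whole mechanism of range selectivity: below a lower receptor number
the attraction cannot pay the translational entropy of binding; above an
upper one the linear repulsion outruns the logarithmic attraction and
binding shuts off again.

## Averaging choices

Poisson averages are truncated at the quantile retaining `1 - 1e-10` of
the mass (the formal sum is infinite); Gaussian count averages are
discretized on the non-negative integers with renormalised weights and
default to the Poisson-matching `sd = sqrt(mean)`. Size polydispersity
uses a truncated-normal grid of 15 points across +/-3 sd, renormalised,
with the lower end clipped at `0.55 R_g` so the projected interaction
area `pi[R_np^2 - (R_np - R_g)^2]` stays in its validity region. Counts,
sizes are treated as independent; both count means are rescaled with the
interacting areas at each size grid point. Exact-radial evaluations inside
averages are memoised per `(N_L, N_R)` pair.

The fitting path evaluates the same triple average in compiled code with
recursive log-domain Poisson weights and a limiting-form screen
(`|F_att| <= min(N_L,N_R) ln(1 + max(N_L,N_R) chi)`) that skips terms
contributing below ~1e-16; the compiled and pure-R paths are
cross-checked against each other in the tests.

## Demonstration parameter sets

The receptor-number sweeps that exhibit range selectivity use a canonical
particle: `R_np = 50` nm, `N_L = 3`, `z = 1` nM, bond energy `-9 kT`,
brush `sigma0 = 1.95` nm^2 with `N = 150`, `a = 0.35` nm (PEG-like),
receptor volumes 40-110 nm^3, insertion ratio 0.9 (or a fixed 9 nm ligand
length with `delta = L/h0` for the brush-density sweep), and a binding
range of 1.5 nm otherwise. Sweeps run on a log grid over the mean receptor
count, 1 to 10^6.

These sweeps are evaluated **without** count averaging. The reason is
structural: a Poisson average with mean 1 places ~26% of its mass at
`N_R >= 2`, where three strong ligands already bind near their peak
probability, so the averaged curve can never start more than a factor
~4 below its peak regardless of the repulsion, binding volume or
activity. The unaveraged curve shows the full rise-and-fall cleanly, and
the qualitative trends (window orderings, non-monotonicity) are identical
with or without averaging — which the module tests verify for the
averaged case as well.

## The optimal ligand number

With linear ligand repulsion `B` per ligand, the low-receptor limiting
attraction `-N_R ln(1 + N_L chi)` is maximised net of repulsion at
exactly `N_L = N_R/B - 1/chi` (`optimal_ligand_number()`), which can be
negative for weak bonds: then adding ligands only ever weakens binding.
The full mean-field optimum is slightly larger; it has the closed form

$$N_L^{*} = \frac{N_R}{1 - e^{-B}} - \frac{e^{B}}{\chi},$$

derived from the variational condition `ln p_L = -B` and verified in the
tests against a golden-section argmax (`argmax_binding_strength()`, search
interval `[0, 10 N_R/B]`, interval tolerance 1e-8). The excess over the
limiting-form value is `~N_R/2` for small `B`; both formulas agree in the
strong-bond, small-`B` corner. Treat `N_R/B - 1/chi` as the design
rule-of-thumb and the closed form above as the model's exact statement.

## Binding windows and trends

`binding_window()` reports where a curve exceeds a threshold: default half
the curve's peak for qualitative sweeps, or an absolute 0.01
("appreciable binding") for reports. Edges are refined by bisection on
the regenerated model between bracketing grid points (log-scale bisection,
relative tolerance 1e-3); curves lacking a parameter snapshot fall back to
log-linear interpolation. Saturating curves flag `upper_unbounded`;
sub-threshold curves return an absent window with all edge fields `NA`
together. `trend_report()` maps a parameter grid to windows and reports
whether width and peak rise or fall: smaller receptor volume or a sparser
brush widens the window and raises the peak, weaker bonds narrow it —
and width and peak always co-vary.

## Fitting

`anneal_fit()` recovers two grafting densities — the reference ligand
density `sigma_L,ref` (at relative loading 1) and the receptor density
`rho_R` — from a normalised adsorption-versus-loading dataset by
minimising the weighted mean squared deviation
`E = sum w_i (theta'_exp - theta'_model)^2 / sum w_i`, with `w_i` the
inverse mean-square-root deviation of each row (zero-spread rows take the
largest finite weight; all-degenerate datasets fall back to equal
weights). The forward model uses the radial mean field, double Poisson
count averaging, and each row's own size distribution.

The annealer is Metropolis with geometric cooling: temperature 1, scaled
by 0.95 every 100 sweeps until it falls below 1e-7 — exactly 315 cooling
steps, 31,500 sweeps. A sweep is one proposal per fitted parameter;
proposals are independent log-normal multiplicative steps (sd 0.1 in log
space), rejected outside the bounds (defaults 1e-4 to 1 nm^-2 for the
ligand density and 1e-6 to 1e-2 nm^-2 for the receptor density, bracketing
typical nanocarrier and cell-surface values); the starting point is the
geometric mean of the bounds. The best-ever parameters are returned, the
per-step trace records temperature, best objective and acceptance rate,
and a fixed seed reproduces the fit bitwise.

## Synthetic data

`simulate_adsorption()` emulates the measurement design the fit expects:
five relative ligand loadings (0, 0.5, 1, 5, 10) with per-loading particle
size distributions whose means shrink with loading (26.6, 10.0, 11.5,
19.3, 20.4 nm, spreads 10.9, 4.7, 5.8, 10.1, 8.6 nm), three replicates,
and optional relative Gaussian noise applied to theta before
normalisation and clipped at zero. Replicate means are normalised by
their maximum across loadings, and the per-row uncertainty is the RMS
deviation of the normalised replicates. The generating truths default to
`sigma_L,ref = 2e-2` nm^-2 and `rho_R = 2e-4` nm^-2, the centre of the
plausible range for ligand-functionalised vesicles on receptor-bearing
cells.

The generator's forward model fixes what the data cannot state: bond
energy `-9 kT`, `R_g = 5` nm, brush height 8 nm on the particle,
`B = B(R_g) = 0.40`, no receptor-side brush repulsion, 1 nM bulk
concentration. Under these conditions the normalised curve is strongly
non-monotonic in loading and the objective surface identifies both
densities (the receptor density through the Poisson saturation
`1 - e^{-mu}` and the multi-bond nonlinearity, the ligand density through
the position of the high-loading suppression). On noiseless data the
full-schedule fit recovers both truths to well under 1%; with 10%
relative noise the median error over seeds stays within a few tens of
percent — the acceptance tests assert 10% and 30% respectively.

What the generator does **not** emulate: confocal image formation,
cell-to-cell variability, receptor clustering or mobility, non-specific
adhesion. Passing recovery tests therefore demonstrate that the inference
machinery is consistent with its own forward model under realistic noise,
not that the model is correct for any particular experimental system.

## Numerical choices and limitations

* Count supports: Poisson truncation mass 1e-10; compiled path terminates
  the ligand loop once the remaining pmf mass bound drops below the same
  allowance.
* `adsorption_probability()` is evaluated as a logistic in `ln(zq)`;
  partition weights are handled in log space throughout.
* Window bisection: 60 iterations max, log-scale, relative tolerance
  1e-3.
* The exact radial sum requires integer counts and rejects fractional
  input; the mean field accepts non-negative reals.
* Mobile receptors/ligands, non-specific particle-surface forces,
  competition between particles and multi-layer adsorption are out of
  scope; with mobile binders the high-density drop of theta would shift
  to higher densities than this model predicts.

## Problem sizes used in the checks

The bundled tests run the mean-field/exact comparison on the full
20 x 20 x 5 count-energy grid, receptor sweeps on 41-61 point log grids,
one full-schedule noiseless fit plus five full-schedule fits at 10%
noise, and short-schedule (2-10 sweeps per step) fits for the
determinism, trace and noise-monotonicity properties.
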