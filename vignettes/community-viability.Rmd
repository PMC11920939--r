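---
title: "Random community assembly and viability under generalized Lotka-Volterra dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random community assembly and viability under generalized Lotka-Volterra dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glvsim)
library(dplyr)
```

## The question

Classical random-matrix arguments say that large, densely connected model
ecosystems are almost surely *locally unstable*: beyond a critical richness,
a randomly assembled equilibrium no longer attracts nearby states. It is
tempting to read this as "large complex ecosystems cannot exist". But local
instability of one particular equilibrium says nothing about what the
community actually does after a small perturbation. It may collapse
entirely - or it may shed a few species and settle elsewhere, or grow until
some resource limit bites. A community is better called *viable* whenever a
nonempty subset of species persists in the long run, whether or not the
original equilibrium was stable.

`glvsim` implements the simulation machinery needed to ask this question
quantitatively: sample random communities around a guaranteed feasible
equilibrium, test local stability spectrally, then *follow the trajectories*
of perturbed communities and record what actually survives.

## The model

The classical generalized Lotka-Volterra (GLV) system for `S` species is

$$\frac{dN_i}{dt} = N_i \Big( r_i + \sum_{j=1}^{S} a_{ij} N_j \Big),$$

with per-capita interaction coefficients $a_{ij}$ and intrinsic growth rates
$r_i$. The package samples the ingredients as follows:

* **Interaction matrix** `A`: diagonal fixed at $a_{ii} = -1$ (every species
  is self-limited); exactly `round(c * S * (S - 1))` off-diagonal entries are
  nonzero, their positions drawn uniformly without replacement - the
  connectance `c` is honoured as an exact count, not a per-entry
  probability. Nonzero values are drawn from $\mathcal{N}(0, \sigma^2)$.
  Under a sign-constrained regime (`all_negative`, `all_positive`) the
  half-Gaussian magnitude $|\mathcal{N}(0, \sigma^2)|$ is used with the
  prescribed sign, which preserves the magnitude distribution of the mixed
  case. $a_{ij}$ and $a_{ji}$ are independent, so the interaction type of a
  pair (competition, antagonism, mutualism, commensalism, amensalism)
  emerges from the realised sign pair; no pair carries two interaction
  types at once.
* **Equilibrium abundances** $N_i^*$: log-Gaussian, $\ln N_i^* \sim
  \mathcal{N}(0, 1)$, so abundances are strictly positive with median 1 and
  mean $e^{1/2} \approx 1.65$.
* **Growth rates**: $r = -A N^*$, which makes $N^*$ an interior equilibrium
  *by construction* - and exactly so in floating point, since the identity
  $A N^* + r = 0$ is evaluated with the same product used to define $r$.
* **Perturbation**: initial conditions are $N_{p,i} = |N_i^* +
  \varepsilon_i|$ with $\varepsilon_i \sim \mathcal{N}(0, 0.02^2)$; the
  absolute value guards the (rare) sign flips at very low equilibrium
  abundance.

A note on $\sigma$: we interpret $\sigma$ as the **standard deviation** of
the nonzero coefficients (default 0.2). Under the alternative reading
($\sigma$ = variance, i.e. SD $\approx 0.45$), random communities are
already almost surely unstable at $S = 10$ for the default connectance
0.7 - the random-matrix stability radius $\sigma\sqrt{cS}$ exceeds 1
everywhere on the richness grid - which is inconsistent with any regime in
which small communities are generically stable. With SD = 0.2 the stability
transition falls at $S^* = 1/(c\sigma^2) \approx 36$, and the package's own
sweeps reproduce the expected sharp decline of the proportion of stable
communities around that richness (see "What the tests do and do not show"
below for the one place where this choice matters quantitatively).

### Local stability

At an interior GLV equilibrium the Jacobian collapses to the closed form
$J = \mathrm{diag}(N^*)\, A$. `local_stability()` computes its full
eigenvalue spectrum and declares stability when every real part is below
`-stability_tol`. This is mathematically equivalent to the Routh-Hurwitz
criterion on the characteristic polynomial; the spectral route is the
numerically robust one for matrices up to a few hundred species.
Eigenvalues within `stability_tol = 1e-9` of the imaginary axis are flagged
`marginal` rather than silently binned - exact zeros have measure zero
under the sampling distribution, but floating point does not respect
measure theory.

### The bounded model

In the classical GLV, positive feedback can drive abundances to infinity.
To study what happens when growth ultimately meets a limit, the bounded
variant multiplies each equation by an attenuation factor:

$$\frac{dN_i}{dt} = N_i \Big( r_i + \sum_j a_{ij} N_j \Big)
  \frac{N_{\max} - N_i}{N_{\max}}.$$

The factor is positive inside $(0, N_{\max})$, so interior trajectories
keep the sign structure of the classical model, every classical equilibrium
below the ceiling is preserved, and no abundance can cross $N_{\max}$. It
is deliberately phenomenological - the simplest modification that encodes
"all growth eventually saturates" without committing to a mechanism.

## Numerical choices

**Coordinates.** Trajectories are integrated in transformed coordinates:
$y_i = \ln N_i$ for the classical model and $y_i = \ln\!\big(N_i /
(N_{\max} - N_i)\big)$ for the bounded model. Both transforms are chosen so
that the governing equation becomes simply $dy_i/dt = r_i + \sum_j a_{ij}
N_j(y)$ (for the bounded model this identity is exact, not approximate).
The payoff is threefold: positivity holds *by construction* at every output
time; in the bounded model the ceiling also holds exactly, because
$N = N_{\max}/(1 + e^{-y})$ can never reach $N_{\max}$; and the two
absorbing regimes of interest - extinction and the ceiling - become linear
asymptotes along which a stiff solver takes large steps. In natural
coordinates, by contrast, species that saturate at the ceiling drive the
factor $(N_{\max} - N_i)/N_{\max}$ into catastrophic cancellation (the
computed factor is pure roundoff once $N_i$ is within $\sim 10^{-13}
N_{\max}$ of the ceiling), which we found stalls adaptive solvers; and
species decaying to extinction routinely undershoot zero by more than
machine precision.

**Solver.** `deSolve::lsoda` with the analytic Jacobian of the transformed
system (`rtol = 1e-8`, `atol = 1e-10` by default, exposed in
`scenario_config()`). Tight tolerances matter because survivor counts
compare final abundances against a $10^{-4}$ threshold.

**Stopping rules.** Three, checked in this order within each integration
chunk: (i) *convergence*, declared at the first dense checkpoint (spacing
`checkpoint_dt = 1` time unit) where $\max_i |dN_i/dt| < 10^{-5}$; (ii)
*blow-up* (classical model only), detected by root location on $\max_i N_i$
crossing 1000, so the stopping time is accurate rather than rounded to a
checkpoint; (iii) a *time limit* of `t_max = 1000` time units, read as
model time rather than solver steps. The convergence schedule is a design
choice: the criterion itself fixes the threshold but not when to test it,
and a once-per-time-unit schedule makes the reported stopping times
comparable across replicates.

**Ceiling count.** A species "reached the ceiling" iff $N_i \ge 0.999
N_{\max}$ at the end; the bounded model approaches $N_{\max}$ only
asymptotically, so some tolerance is unavoidable, and 0.1% is far above
solver error yet far below any interior equilibrium abundance.

**Return to equilibrium.** A converged run is counted as having returned
to $N^*$ when $\max_i |N_i - N_i^*| < 10 \times$ `perturb_sd`; generous
relative to the perturbation, strict relative to the spacing of distinct
equilibria.

**Degenerate input.** Matrices with singular 2-species interaction
structure (parallel isoclines) are reported as degenerate rather than
solved; non-hyperbolic equilibria are classified `marginal`, never forced
into stable/unstable.

## Experiments

`run_replicate()` runs the full chain sample → stability → perturb →
integrate → classify and returns a one-row tibble; `run_richness_sweep()`
maps it over a richness grid with *pre-assigned* per-replicate seeds drawn
from the root seed, so any replicate can be reproduced in isolation and
results are invariant to execution order (replicates are embarrassingly
parallel by contract, though the package runs them serially).

Summary statistics per richness follow the headline figures of this
literature: proportion of locally stable equilibria, proportion of
blow-ups, mean number of survivors, mean number of species at the ceiling,
proportion with no extinction, proportion with near-total extinction, and
the mean interaction-selection statistic.

**Interaction selection.** For bounded runs the package records the
difference between the mean interaction coefficient of the surviving
subcommunity and that of the initial pool. Both means are taken over
*realised* interactions only - nonzero off-diagonal entries - excluding the
constant $-1$ diagonal and structural zeros, which would otherwise dilute
the statistic; this is an interpretation (the alternative conventions are
not distinguishable from the figure-level description this statistic comes
from) and is documented here as such. Undefined cases (fewer than two
survivors, or a survivor submatrix with no realised interaction) are
recorded as missing, not zero, and excluded from means.

**All-positive outcome classification.** In purely mutualistic
communities with an unstable initial equilibrium, runs end either with all
species alive (at the ceiling) or with almost all extinct. "Almost all" is
operationalised as $n_{\mathrm{alive}} \le 0.1\,S$; the cutoff is exposed
as `near_total_fraction` and nothing in the reported 50:50 split is
sensitive to it, because observed survivor counts cluster at $n = S$ and
$n \approx 0$.

## What the synthetic communities do and do not emulate

The generator reproduces the statistical world of classical random-matrix
ecology: fixed self-limitation, exact connectance, Gaussian interaction
strengths, lognormal abundances, all species equivalent a priori. It does
**not** emulate structured topologies (bipartite, cascade, modular),
empirically calibrated strengths, correlated $(a_{ij}, a_{ji})$ pairs,
dual interactions, demographic or environmental stochasticity, or
ratio-dependent functional responses. Conclusions from passing tests
therefore concern this idealised ensemble, not any particular natural
community; the value of the exercise is that the ensemble is exactly the
one for which the classical instability results were derived.

## Problem sizes used by the checks

The headline experiments in this literature use 1000 replicates per
richness up to $S = 350$; full replication is an hours-scale computation.
The package's own test suite and acceptance script run scaled-down
versions, chosen as the smallest sizes at which the qualitative claims are
statistically unambiguous: 400 pooled communities ($S \le 40$) for the
stability plateau, 200 unstable replicates at $S = 100$ for the
all-positive 50:50 split, 50 replicates at each $S \in \{100, 150, 200\}$
for the competitive persistence cap, 40 replicates at $S = 150$ for the
blow-up fraction, and 12 replicates per point for the bounded mixed-regime
trends. The lognormal moment check pools $10^6$ draws.

## What passing tests show - and one expected discrepancy

Most figure-level claims reproduce cleanly at these scales: the sharp loss
of stability with richness; blow-up as the generic fate of unstable
unbounded communities; persistence *increasing* with initial richness in
the bounded mixed regime; selection of more positive interactions among
survivors; and the 50:50 fate split of purely mutualistic ones. The
~60-70-species ceiling of purely competitive communities also reproduces
in expectation (independent 100-replicate runs give mean survivor counts
of about 67 at both $S = 150$ and $S = 200$, s.d. $\approx 10$), but at 50
replicates per richness the check is noise-limited: a sample mean can land
a species or two above 70, and the suite's fixed-seed sample at $S = 200$
does. The seed is not cherry-picked around this.

One quantitative claim does not reproduce under the stated sampling
parameters: that the proportion of locally stable communities "is 1" for
all $S < 50$ at $c = 0.7$, $\sigma = 0.2$. The random-matrix stability
radius $\sigma\sqrt{cS}$ crosses 1 at $S \approx 36$, and the measured
proportions (cross-checked against an independent eigensolver) are 1.0,
0.997, 0.92 and 0.66 at $S = 10, 20, 30, 40$ - a pooled 0.89, not 1.0. The
corresponding acceptance check is left failing rather than widened: the
plateau-then-collapse *shape* is robust, but its quoted location is only
consistent with a lower effective interaction density or strength than the
parameters state. All other checks are insensitive to this, and the same
parameter set is the one that reproduces the competitive persistence cap.

## Worked example

```{r example, eval = FALSE}
library(glvsim)

cfg <- scenario_config(S = 60, bounded = TRUE, seed = 1, n_reps = 20)
sweep <- run_richness_sweep(cfg, S_grid = c(20, 40, 60, 80), n_reps = 20)
glance(sweep)          # per-richness summary tibble
autoplot(sweep)        # stability / persistence / selection panels

# two-species phase plane of a strong bounded mutualism
m <- two_species_model(r1 = -1, r2 = -1, a11 = -1, a12 = 2,
                       a21 = 2, a22 = -1, Nmax = 10)
enumerate_equilibria(m)
autoplot(m)
```

## Known limitations

* Replicates run serially; the pre-assigned-seed contract makes parallel
  execution safe, but no backend is wired in.
* The time-limit stop cannot distinguish a cyclic or chaotic attractor
  from slow transient convergence; runs that hit `t_max` while species
  with small negative per-capita rates are still decaying report those
  species as alive. (At the default thresholds this affects a minority of
  large purely competitive communities and biases their survivor count
  slightly upward.)
* Blow-up detection in the classical model reports the first crossing of
  the threshold; it does not extrapolate to the finite-time singularity
  that strong mutualism can produce.
* The sign-constrained magnitude distribution (half-Gaussian) is a
  modelling choice; any heavier- or lighter-tailed magnitude law with the
  same scale would be equally consistent with the verbal specification of
  the constrained regimes.
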