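---
title: "Evolutionary game dynamics on activity-driven temporal networks"
author: "tegt package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary game dynamics on activity-driven temporal networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tegt)
```

## The model

`tegt` studies symmetric n-strategy pairwise games in a large population
whose interaction structure is an *activity-driven temporal network*. Each
individual u carries an activity potential a_u drawn once from a density
f(a) on (0, 1]. In every instantaneous snapshot, u activates with
probability a_u and creates m undirected links to uniformly chosen
distinct partners; self-links and multi-edges are forbidden, and all edges
are discarded after the snapshot. One evolutionary step spans a window of
delta snapshots: individuals play the game with every neighbour on the
*integrated* (union) graph G_delta, accumulate payoffs, and then each
individual with at least one neighbour picks one uniformly at random and
imitates its strategy with the Fermi probability
F(dP) = 1 / (1 + exp(-beta dP)), where dP is the payoff of the role model
minus the focal player's and beta is the selection intensity.

The package implements the model twice and checks the two against each
other:

* a stochastic agent-based simulator (`run_abm()`, with the granular
  operations `generate_instantaneous()`, `integrate_window()`,
  `accumulate_payoffs()`, `update_strategies()` exposed individually), and
* the deterministic weak-selection theory below
  (`transformed_matrix()`, `integrate_trajectory()`, `ess_temporal()`).

## The weak-selection theory

For beta -> 0 the mean strategy frequencies obey replicator-like
equations driven not by the payoff matrix A but by

$$A' = \alpha_1 A + \alpha_2 B, \qquad B = A - A^{\mathsf T},$$

with weights

$$\alpha_1 = \tfrac{\beta}{2}\left(3 m \delta \langle a\rangle^2 +
  m \delta \langle a^2\rangle - 2\langle a\rangle\right), \qquad
  \alpha_2 = \beta \langle a\rangle .$$

B is antisymmetric: it is a zero-sum *local competition* (spite) term that
never changes the population mean payoff (x'Bx = 0). Since positive
rescaling of the driving matrix only rescales time, the single beta-free
number
$\bar\alpha_2 = \alpha_2 / (\alpha_1 + \alpha_2) =
2\langle a\rangle / (m\delta(3\langle a\rangle^2 + \langle a^2\rangle))$
determines the phase portrait: heterogeneous activity distributions or
large m*delta push $\bar\alpha_2$ down and the dynamics towards the
well-mixed replicator limit, while homogeneous, sparse interaction makes
the local-competition term dominant.

A strategy i is evolutionarily stable on the temporal network iff
$\alpha_1 a_{ii} + \alpha_2 a_{ij} > (\alpha_1 + \alpha_2)\, a_{ji}$ for
every rival j. Equality margins are ungeneric; `ess_temporal()` returns a
three-valued verdict (`ESS` / `not-ESS` / `undecided`) so such cases
cannot be silently coerced to a boolean. With `alpha2 = 0` the condition
reduces to the strict clause of the classical well-mixed ESS condition,
and the well-mixed taxonomy is reproduced by the same code paths.

## Activity moments and the slow manifold

The mean-field state is the joint activity-strategy density; the
observables are its moments I^k_si (I^0 is the strategy frequency). At
neutrality the moments obey a linear hierarchy that relaxes fast — at a
rate independent of beta — onto the *slow manifold*
I^k = ⟨a^k⟩ I^0, while frequencies move only at O(beta). On the slow
manifold the O(beta) imitation balance reduces exactly to the
replicator-like equations with the weights above; the package verifies
the reduction symbolically-numerically rather than assuming it.

Two integration routes are provided:

* `moment_hierarchy_rhs()` / `integrate_moment_hierarchy()`: the moment
  ladder truncated at k_max, with two top closures (`slow-manifold-top`,
  which applies the stationarity identity of the neutral hierarchy at the
  top order, and `truncate-top`). **Caveat:** truncating the ladder
  introduces spurious weakly unstable modes (growth rates around 0.1 for
  k_max near 8 under the benchmark uniform density), although the
  untruncated dynamics is provably contracting — the truncation, not the
  model, is the culprit. The ladder is therefore suitable for short
  horizons and structural checks only.
* `integrate_activity_density()`: the same dynamics in its density
  representation on a discrete activity measure
  (`discretize_activity()`). This is the *untruncated* hierarchy — every
  moment order is implied simultaneously and no closure is needed — and
  is the route used for quantitative work. For a discrete measure it is
  exact up to integrator tolerance; a 101-atom discretization of the
  benchmark uniform density reproduces the transformed-replicator
  frequency dynamics at beta = 1e-3 to ~1e-5 absolute error over a
  horizon in which frequencies move by ~0.17, and halving beta at fixed
  horizon quarters the discrepancy, the expected O(beta^2) signature.

## Deterministic integration and fixed points

`integrate_trajectory()` wraps an adaptive stiff/non-stiff integrator
(deSolve's lsoda) at rel. tol. 1e-10 / abs. tol. 1e-12. Output states are
clipped at zero and renormalized, with the largest pre-renormalization
simplex drift reported (typically < 1e-12 over the horizons used here);
integrator failures are surfaced as errors, never truncated silently.
Vertex absorption is logged when a trajectory passes within 1e-6 of a
vertex. An optional uniform mutation term eps (1/n - x_i), default off,
serves as a stress test for boundary-supported attractors.

`classify_fixed_point()` uses the closed-form Jacobian of the replicator
field (finite-difference checked in the tests), projected onto the
(n-1)-dimensional tangent space of the simplex — the orthogonal
complement of the all-ones vector, which the linearized flow preserves on
the simplex. Eigenvalues within a tolerance band (default 1e-7) of zero
count as neutral; the classification distinguishes stable, unstable,
saddle, and "non-isolated/neutral-direction" (exactly one neutral
eigenvalue, the rest negative — the signature of a line of rest points),
with anything else reported as undecided rather than forced.

## The mini-ultimatum game

With offer/acceptance levels 0 < l < h < 1/2, the four strategies are
R = [l, l] (reasonable), G = [h, l] (generous), F = [h, h] (fair) and
I = [l, h] (immoral); `mug_matrix()` builds the payoff matrix from the
two-role ultimatum payoffs. Classical replicator dynamics stabilizes the
unfair R outcome. On temporal networks the picture flips: R loses
evolutionary stability exactly when l < alpha2 / (alpha1 + 2 alpha2)
(`critical_offer()`), with the immoral strategy I the binding rival, and
fairness F becomes the attracting pure state.

Every row of A' satisfies a'(s,R) + a'(s,F) = a'(s,G) + a'(s,I), which
makes K = (x_R x_F)/(x_G x_I) a constant of motion
(`constant_of_motion()`): interior trajectories live on invariant
surfaces, and there is no interior fixed point. The boundary rest points
have closed forms (`edge_fixed_points()`): a bistable basin boundary on
the R-F edge (existing iff h exceeds the critical offer), an unstable
point on the G-I edge (existing iff h - l < alpha1/(alpha1 + 2 alpha2)),
and a line of rest points on the G-F edge that splits into a stable and
an unstable segment at a computed endpoint. Existence is decided by
strict interior membership of the closed-form coordinates, and each
existing point is verified to be a root of the dynamics to 1e-12; the
tests additionally confirm that the membership test is equivalent to the
analytic inequalities.

One nuance: F is the attracting pure state, but its ESS margin against G
is exactly zero (the G-F direction is neutral), so `ess_temporal()`
reports F as `undecided` rather than a strict ESS; the Jacobian
classification with its explicit neutral-direction category carries the
full information. Relatedly, interior trajectories need not end at the F
vertex itself: with K fixed they land on the stable part of the G-F
segment (from the barycentre of the simplex, at x_G ≈ 0.28 for
h = 0.3, l = 0.2, alpha-ratio 2). `phase_diagram()` classifies the
(alpha2/alpha1, l) plane by the R-stability verdict; cells on the
boundary are labelled as such, never forced into a phase, and the verdict
is checked per cell to be independent of the representative h.

## The simulator and the study conditions

The synthetic benchmark conditions follow the study design throughout:
uniform activity density f(a) = 1000/999 on [0.001, 1], m = 4, delta = 2,
beta = 1e-6, the 2x2 coordination game diag(1, 0.5), initial frequencies
0.2/0.8, and the measurement protocol of 250 recorded steps after 750
relaxation steps. Population size and replicate counts are run at desk
scale (N = 4000, 50 replicate initial conditions) — chosen so the
full-protocol agreement check completes in seconds while the
across-replicate standard deviations still resolve the k = 8 moments; the
agreement between stationary I^k and ⟨a^k⟩ x then holds within 3
estimated standard deviations for all k up to 8 and both initial
conditions (observed z-scores are below about 0.5).

Design choices fixed in the simulator (and exposed as switches where a
reasonable alternative exists):

* **Synchronous updating** — all individuals decide from the pre-update
  state, matching the global game-then-update step structure; an
  asynchronous random-order variant is available
  (`scheme = "asynchronous"`). At weak selection the mean-field dynamics
  is insensitive to this choice.
* **Accumulated (not degree-normalized) payoffs**; isolated nodes hold
  payoff 0 and skip updating.
* **Collision handling**: an active node draws its m partners uniformly
  without replacement (draw-level rejection); an edge drawn in several
  snapshots of one window enters the simple union graph once
  (`multigraph = TRUE` preserves multiplicities for sensitivity checks).
  Collisions vanish as 1/N, so the finite-N simple-graph union matches
  the thermodynamic-limit theory.
* **Reproducibility**: one master seed; per-replicate streams are split
  deterministically, and identical seeds give identical edge sets. The
  ABM kernels are implemented in C++ but draw from R's RNG, so
  `set.seed()` governs everything.
* **Mean degree**: at finite N the expected integrated degree of an
  activity-a node is N(1 - exp(-a m delta / N)) + ⟨a⟩ m delta
  exp(-a m delta / N), which tends to (a + ⟨a⟩) m delta; the finite-N
  form was verified against brute-force simulation at small N before
  adoption, and the empirical mean degree at N = 1e4 matches the
  asymptotic law within 2%.

What the generator deliberately does *not* emulate: heavy-tailed activity
distributions with structural cutoffs, burstiness, memory kernels, and
topological correlations of real temporal networks. Agreement of the
simulator with the theory therefore validates the weak-selection
reduction under the activity-driven mechanism, not the behaviour of any
empirical contact network.

## Numerical choices and known limitations

* Weak selection means beta times payoff differences of order the mean
  degree must be small; at beta near or above ~0.1/⟨degree⟩ the O(beta^2)
  terms neglected by the theory become visible.
* The deterministic description needs N large: at small N, demographic
  noise causes extinctions/fixations that the ODEs cannot show (the
  simulator exhibits them; the moment-sanity invariants still hold).
* Trajectory endpoints on the G-F rest-point line are only neutrally
  stable transversally; stochastic perturbations (or the mutation stress
  term) slowly drift along the line, which is why the mutation stress is
  reported separately and defaults to off.
* The truncated moment ladder is for structure, not quantitation (see
  above); the density route is exact for discrete activity measures, and
  continuous densities enter through a controlled discretization
  (the benchmark checks use 101 atoms).
* Phase-diagram cells exactly on l = alpha2/(alpha1 + 2 alpha2) are
  reported as `boundary`; the undecided band is zero-width by default.

## A worked call

```{r example}
d <- activity_uniform(0.001, 1)
w <- selection_weights(1e-6, m = 4, delta = 2, d)
unlist(w)
critical_offer(1, 2)
fp <- edge_fixed_points(0.45, 0.2, 1, 2)[[1]]
fp$location
ess_temporal(mug_matrix(0.3, 0.2), 1, 2, i = 1)$verdict
```
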