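---
title: "Quantifying and reducing energy landscapes of multistable gene networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and reducing energy landscapes of multistable gene networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model class

`drlandscape` works with gene regulatory networks whose deterministic
dynamics follow Hill kinetics,

$$
f_i(x) \;=\; \sum_j A_{ji}\,\frac{x_j^n}{S_{ji}^n + x_j^n}
 \;+\; \sum_j B_{ji}\,\frac{S_{ji}^n}{S_{ji}^n + x_j^n}
 \;-\; k\,x_i \;+\; g_0 ,
$$

where $A_{ji}$ and $B_{ji}$ are activation and inhibition strengths of
regulator $j$ on target $i$, $S$ is the regulation threshold, $n$ the Hill
coefficient (steepness), $k$ first-order degradation and $g_0$ an optional
basal synthesis rate. Gene-expression noise is modelled as additive Gaussian
white noise with a constant, homogeneous diffusion coefficient $d$:
$\dot x = f(x) + \Gamma(t)$, $\mathbb E[\Gamma_i(t)\Gamma_j(t')] =
2d\,\delta_{ij}\,\delta(t-t')$. The steady-state probability density
$P_{ss}$ of this process defines the energy landscape $U = -\ln P_{ss}$:
attractors are basins, depth measures stability.

Solving the stationary Fokker–Planck problem directly is impractical beyond
a couple of dimensions, so the package uses a Gaussian moment closure
("truncated moment equations"): around each stable fixed point $\mu_j$ the
mean follows the ODE and the covariance obeys
$\dot\Sigma = J\Sigma + \Sigma J^\top + 2dI$ with $J$ the drift Jacobian.
At a stable fixed point the stationary covariance solves the algebraic
Lyapunov equation $J\Sigma + \Sigma J^\top = -2dI$; `stationary_covariance()`
solves it directly by Kronecker vectorization (a time-integrated variant is
available and agrees to integration tolerance, so the algebraic route is the
default — identical limit, no integration error). A multistable density is
the weighted mixture $p(x) = \sum_j \phi_j\,\mathcal N(x;\mu_j,\Sigma_j)$,
where the weight $\phi_j$ is the fraction of random initial conditions whose
deterministic relaxation lands in basin $j$ (`find_stable_states()`, default
1000 starts; the count is configurable and the seed is recorded so weights
are reproducible). Components are never pruned, so shallow basins remain
visible on the landscape.

## Dimension reduction

The global mixture moments are
$\mu = \sum_j \phi_j \mu_j$ and
$\Sigma = \sum_j \phi_j(\Sigma_j + \mu_j\mu_j^\top) - \mu\mu^\top$.
`compute_basis()` eigendecomposes $\Sigma$; the orthonormal eigenvectors
$w_1, \dots, w_N$ (eigenvalues $\lambda_1 \ge \dots \ge \lambda_N$) are the
maximal-variance directions of the steady-state density, and
$100\,\lambda_i/\sum_k \lambda_k$ is the contribution rate of component $i$.
Under $Z = W^\top X$ every mixture component stays Gaussian
($\mu_z = W^\top\mu_j$, $\Sigma_z = W^\top\Sigma_j W$), and marginalizing to
the first $C$ coordinates just truncates means and covariance blocks
(`project_mixture()`). The reduced landscape is $U_C = -\ln p_{z_C}$ on a
regular grid (`grid_landscape()`).

Numerical conventions:

* **Eigenvector signs** are fixed by making the largest-magnitude entry of
  each eigenvector positive; ties in eigenvalues keep the stable order
  returned by the symmetric eigensolver.
* **Degenerate directions**: eigenvalues below $10^{-12}\lambda_1$ are
  reported as 0% contribution; projection remains defined.
* **Grid**: 200 points per axis by default, spanning the component means
  ±3 component standard deviations per axis; $U$ is capped at `u_cap`
  (default 50) where the density underflows. Both raw $-\ln p$ and a
  min-shifted variant are available; the mode is recorded in the object.
* **Minima** are grid cells lower than all neighbours (8-connected in 2D);
  exact ties — which arise on even grids under perfect symmetry — are broken
  by linear index so a plateau yields exactly one minimum.

## Landscape quantification

`find_saddle()` computes the minimax saddle between two basins by
sorted-cell union-find flooding: cells are added in order of increasing
$U$ and merged with flooded neighbours; the level at which the two basins'
sublevel sets join is the saddle. This equals the minimax over all
8-connected grid paths (the suite cross-checks it against an independent
threshold-plus-flood-fill oracle). Barrier height is
$BH = |U_{saddle} - U_{stable}|$; the relative barrier height between two
basins is the signed difference of their minima.

A reference landscape can be estimated by long Langevin simulation
(`simulate_langevin()`, Euler–Maruyama, per-step variance $2d\,\Delta t$,
many trajectories advanced in parallel from uniformly sampled initial
conditions) followed by `histogram_landscape()`. Two estimates are compared
by the mean relative deviation over jointly valid cells,
$\mathrm{mean}\,|U_1 - U_2|/U_2$ (the plain sum is also reported). Both
landscapes are first placed on the probability-*mass* scale
($-\ln$ of per-cell mass) so the denominator is strictly positive; on a
uniform grid this differs from the density scale only by the constant
$\ln(\text{cell area})$. Cells capped in either estimate (zero sampled
density) are excluded — a ratio against a cap is meaningless.

Two choices here deserve emphasis. First, the comparison simulation is run
*unclamped* (`clamp = FALSE`): the Gaussian closure lives on the unbounded
domain, and when a low-expression state sits within a fraction of a
standard deviation of zero (the MISA low state is at $0.23\sigma$ for
$d = 0.02$), a zero-clamped reference piles that component's sub-zero mass
at the boundary and the comparison would measure the boundary convention,
not the closure. Clamping remains the default for biological simulation.
Second, the histogram bins equal the landscape grid, with no smoothing.

## Transition paths

Between attractors $x_i, x_j$, the package minimizes the Freidlin–Wentzell
action
$S = \tfrac12\int_0^T \|\dot x - f(x)\|^2\,dt$
over discretized paths with fixed endpoints (`minimize_action()`). The
discretization is frozen so actions are reproducible bit for bit: $K$
points on a uniform time grid ($K = 101$ by default), midpoint velocities
$(x_{m+1}-x_m)/\Delta t$, drift at segment midpoints, and
$S = \tfrac{\Delta t}{2}\sum_m \|v_m - f_m\|^2$. The optimizer is L-BFGS-B
on the flattened interior points with the analytic gradient obtained by the
chain rule through the discretization (box-constrained at zero for
gene-network models); the straight line between the endpoints initializes
the search, plus seeded smooth-bump restarts (3 by default, best action
kept). Endpoints are the Newton-polished fixed points, not grid cells.

The terminal time $T$ trades accuracy for conditioning: the quasipotential
limit is approached from above as $T$ grows, while at fixed $K$ the
discretization coarsens. `t_scan()` warm-starts successive $T$ values from
the previous optimum and reports the action-vs-$T$ table. The whole
machinery is validated end to end on the 1D double well
$V = x^4/4 - x^2/2$, a gradient system where the uphill action must equal
$2\,\Delta V = 0.5$; the suite requires agreement within 2% and observes
~0.1% at $T = 20$, $K = 201$.

Indirect paths through an intermediate attractor are built from two
independently minimized legs concatenated at the shared attractor and
resampled (`concat_paths()`). Paths are compared by the Euclidean path
distance $\mathrm{Dis} = \tfrac1N\sum_{i=1}^K \|x_i - y_i\|_2$ (resampling
to a common point count first), and visualized after per-component min–max
normalization to $[0,1]$ (constant components map to 0.5).

## Robustness and sensitivity

`perturb_and_collect()` multiplies every nonzero link strength by an
independent uniform factor (default range 75–125%), re-finds all stable
states per parameter set, pools them, and clusters the pooled matrix
(per-node z-score, Euclidean distance, average linkage) — the contract is
group recovery, not reproduction of any particular dendrogram layout.
`robust_paths()` repeats the analysis in a tight range (default 95–105%,
larger perturbations provoke phase changes), matching endpoints to the
reference attractors by nearest relative-L2 state and projecting every
path onto the PCA basis of the pooled states. `global_sensitivity()`
perturbs each nonzero entry of $A$ and $B$ individually by ±10%
(thresholds, Hill coefficient, degradation and diffusion are left fixed,
so a network with $L$ links yields $2L$ records), recomputes both
transition actions at fixed $T$ and $K$, and ranks links by the difference
of the two percent changes; perturbations that lose an endpoint (or make
the nearest-match ambiguous within 10%) are flagged as phase changes and
excluded from the ranking.

Uniform sampling within the fractional range is the minimal assumption for
"randomly sampled" perturbations; all ensemble randomness flows through a
single recorded seed.

## Bundled fixtures and the study conditions

* `fixture_misa()` — the mutual-inhibition self-activation switch
  ($a = b = 0.5$, $S = 0.5$, $n = 4$, $k = 1$), bistable at
  $(0.033, 0.967)$ and its mirror. The fixture carries the package's frozen
  diffusion coefficient $d = 0.02$, calibrated once so that the leading
  contribution rate of the two-component mixture is 95.8%: the contribution
  is a smooth, monotone function of $d$ (within-component variance grows
  linearly in $d$ while the between-state separation is fixed), so a
  one-dimensional root solve determines $d$ and it is not revisited.
* `fixture_synthetic_multistable(n_nodes)` — self-activating genes on a
  ring, each inhibiting its two neighbours ($a = 1$, $b = 0.5$, $S = 0.5$,
  $n = 4$, $k = 1$; the 2-node ring is exactly the MISA topology). The
  frozen parameters give 3/4/7/11/18 stable states for 2–6 nodes; at four
  nodes the seven attractors are four single-high states, two
  opposite-pair states and the all-intermediate state.
* `fixture_emt_synthetic()` — a *synthetic* quadrastable stand-in for
  metabolism–EMT crosstalk: two toggle switches (a metabolic pair and an
  EMT pair) weakly coupled by an activation from the metabolic driver to
  the EMT driver. It exercises state classification (E/A/H/M marker
  patterns), clustering and path analysis end to end. It is a constructed
  network, not a transcription of any published parameterization — node
  names carry an `s` suffix as a reminder — so conclusions about the real
  metabolism–EMT system cannot be drawn from it.

The attractor search samples initial conditions in
$[0, x_{\max}]^N$ with
$x_{\max,i} = (\sum_j A_{ji} + \sum_j B_{ji} + g_0)/k \times 1.2$. Both
Hill terms are bounded by their link strength — the inhibition term is a
*production* term that saturates at $B_{ji}$ when the inhibitor is absent —
so every steady state lies inside this box; for MISA a bound ignoring the
inhibition strengths would exclude the high attractor itself.

## What the synthetic generators do and do not emulate

The fixtures reproduce the qualitative phenomena the method targets —
multistability, symmetry orbits, intermediate states on transition
corridors — under exactly known conditions, which is what makes the
oracle-style tests sharp. They do not emulate features of real expression
data: no intrinsic (copy-number) noise, no parameter heterogeneity between
cells, no unmodelled regulators, and noise is state-independent by
assumption. A passing suite therefore certifies the numerics and the
contracts, not biological fidelity of any particular network.

## Problem sizes used by the tests

The suite runs on two- to six-node networks; stochastic checks use
$10^5$–$10^6$ retained Langevin samples, attractor searches 100–1500
starts, perturbation ensembles 8–30 parameter sets, and action
minimizations $K = 31$–201 points. These sizes were chosen so every
stochastic assertion sits several standard errors away from its threshold
while the whole suite stays interactive; the acceptance sweep uses
$10^6$ samples per parameter value, matching the scale at which the
histogram estimator resolves the barrier region.

## Known limitations

* **Corridor overestimate of the closure.** The mixture's inter-basin
  potential comes from Gaussian tails, i.e. from the *quadratic*
  expansion of the quasipotential around each attractor. The true
  stationary occupancy of the transition corridor is governed by the
  Freidlin–Wentzell quasipotential, which the quadratic form overestimates
  whenever the saddle lies outside the linear neighbourhood of the
  attractors — for the MISA fixture by roughly a factor two (closure
  barrier ≈ 8.6 vs. quasipotential $S/2d$ ≈ 3.9 at $b = 0.5$,
  $d = 0.02$; the package's own action solver and the Arrhenius slope of
  simulated transition rates agree on the latter). The ratio is independent
  of $d$. Consequently, landscape comparisons against *equilibrated*
  simulations that do sample the corridor show mean relative errors of
  10–20% concentrated there, while basin cores agree to ~1% (exact for
  linear dynamics, verified on an Ornstein–Uhlenbeck process). Barrier
  *rankings* and parameter *trends* are preserved (barrier-series
  correlations ≈ 0.97–0.99 across the MISA inhibition sweep); absolute
  corridor depths are not. Reduced-dimension landscapes inherit this
  property from the mixture.
* **Weights are basin-volume fractions.** $\phi_j$ measures the size of
  the deterministic basin under the sampling measure, not the Boltzmann
  occupancy; at small $d$ the two can differ for asymmetric systems.
* **Small-noise validity.** The closure assumes well-separated components;
  `mixture_overlap_diagnostic()` reports the spread-to-separation ratio
  but no hard cutoff is imposed.
* Limit cycles and other non-point attractors are not handled: the
  attractor search reports an explicit error when relaxations fail to
  converge.
* The minimum action method fixes $T$; no geometric ($T$-free)
  reformulation is provided, and forward/backward paths legitimately
  differ for non-gradient drift.
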