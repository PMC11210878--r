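---
title: "Threshold-aware optimal policies for adaptive cancer therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold-aware optimal policies for adaptive cancer therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(thresholdtx)
```

## The control problem

Adaptive therapy prescribes the drug dose from the *current* state of a tumor
rather than from a fixed schedule. `thresholdtx` works with controlled models
of a heterogeneous tumor whose reduced state is a pair $(q, p) \in [0,1]^2$
and whose dynamics are a controlled drift–diffusion

$$dX = a(X, d)\,dt + \Sigma(X, d)\,dW, \qquad d(t) \in [0, d_{\max}],$$

where $d$ is the dose rate and $d_{\max}$ the maximum tolerated dose (MTD).
Therapy terminates when $p$ crosses one of two barriers: *success* when
$p < \gamma_r$ (stabilization or remission) and *failure* when $p > \gamma_f$
(loss of the patient). Barrier hits are classified with strict inequalities;
on a grid the distinction is measure-zero, but it keeps the terminal-region
definitions literal. The cumulative cost of a course of therapy is

$$J = \int_0^T K(X(t), d(t))\,dt, \qquad K(x, d) = d + \delta,$$

a weighted combination of total drug delivered and total treatment time; the
time penalty $\delta > 0$ both expresses that treatment time is undesirable
and keeps $K$ bounded away from zero, which the threshold-aware equation
needs (see below).

Three layers of analysis are built on this:

1. **Deterministic optimum.** With the noise switched off, the minimal cost
   $u(q, p)$ to reach success satisfies the stationary first-order HJB
   equation $\min_d \{K + \nabla u \cdot f\} = 0$ with $u = 0$ on the
   success barrier. Because $f$ and $K$ are affine in $d$, the optimal
   feedback is *bang-bang*: only $d = 0$ and $d = d_{\max}$ ever need to be
   compared. `solve_deterministic_hjb()` computes $u$ and the policy
   $d_\star(q, p)$.
2. **Cost distributions under noise.** Under stochastic dynamics the cost of
   any fixed feedback policy is random. `run_ensemble()` simulates therapy
   courses by Euler–Maruyama integration and returns tidy per-path records
   from which empirical cost CDFs $\hat F(s) = \hat P(J \le s)$ are built
   (failed and censored courses count as infinite cost, so $\hat F$ is the
   probability of *success* within cost $s$).
3. **Threshold-aware optimum.** The quantity a patient may actually care
   about is the probability of succeeding *without exceeding a cost budget*
   $\bar s$. The value $v(q, p, s) = \sup_{d(\cdot)} P(J \le s)$ satisfies a
   parabolic HJB equation in which the remaining budget $s$, which decreases
   at the strictly positive rate $K$, plays the role of time:
   $$\max_d \Big\{ -K \partial_s v + a \cdot \nabla v
     + \tfrac12 \mathrm{tr}(\Sigma\Sigma^\top D^2 v) \Big\} = 0 .$$
   `solve_threshold_hjb()` marches this equation upward from $v(\cdot, 0)$
   and returns $v$ together with the budget-dependent bang-bang policy
   $d^*(q, p, s)$ — for *every* budget in $(0, \bar S]$ simultaneously.

The central consistency property, which the test suite checks directly, is
that the Monte-Carlo success-within-budget frequency under the extracted
policy matches the PDE prediction $v(q_0, p_0, \bar s)$.

## The two bundled models

**EGT competition model.** Three phenotypes compete in a public-goods game:
glycolytic cells (GLY, fraction $p$) acidify the environment to every cancer
cell's benefit; among the aerobic cells, VEGF-overproducers (VOP, fraction
$q$ of aerobic cells) pay a cost $c$ to improve vasculature while defectors
(DEF) free-ride. Each cell interacts with $n$ neighbours; the benefit per
unit acidification is $b_a$ and per unit vascularization $b_v$. The drug
targets GLY fitness. Coexistence (cycling) requires
$b_a/(n+1) < b_v - c < c\,n$, which `heterogeneous_regime()` checks. The
constructor defaults — $b_a = 2.5$, $b_v = 2$, $c = 1$, $n = 4$,
$d_{\max} = 3$, $\delta = 0.05$, $\gamma_r = 1 - \gamma_f = 10^{-2}$ and
uniform fitness volatilities $\sigma = 0.15$ driven by three independent
Brownian channels — are the study conditions under which all quantitative
checks in this package run. The stochastic drift includes the Itô
corrections that arise when the raw subpopulation SDEs are reduced to
$(q, p)$, and every diffusion entry carries a $q(1-q)$ or $p(1-p)$ factor,
so the state cannot diffuse out of the unit square.

**Sensitive–resistant model.** Drug-sensitive ($S$) and fully resistant
($R$) cells share a carrying capacity; resistant cells are $m$ times larger,
sensitive cells suppress them through a competition term
$\beta C z_S z_R$, and the drug kills sensitive cells at rate
$\alpha z_S d$. The reduced state is the effective tumor size
$p = z_S + m z_R$ and the sensitive share $q = z_S / p$; a single Brownian
motion perturbs both intrinsic growth rates. The goal here is eradication
($p < \gamma_r$). The published experimental calibration of this model is
not redistributable, so `sr_params()` has no numeric defaults;
`sr_params_synthetic()` provides a clearly-labelled synthetic set (hours as
time unit, $m = 30$ chosen so that a tumor 96% sensitive by cell number at
90% of capacity sits at $(q, p) \approx (0.45, 0.9)$, growth rates
$g_S = 0.031 > g_R = 0.026$, strong competition $\beta C = 2.75$, kill rate
$\alpha d_{\max} \gg g_S$) that reproduces the qualitative regime — initial
tumor shrinkage from competitive release, then regrowth — and is used only
for structural and invariant tests, never for quantitative claims.

During the reduction of the two models to $(q,p)$ coordinates we
re-derived all drift corrections from the raw subpopulation systems; for
the SR model the correction in the $q$-equation is
$(1-p)^2\,[\sigma_R^2 (1-q) - \sigma_S^2 q + \sigma_S \sigma_R (2q-1)]$,
which vanishes when $\sigma_S = \sigma_R$ — as it must, because equal
volatilities silence the composition noise entirely.

## Numerical choices

**Deterministic solver.** Semi-Lagrangian value iteration: each node is
relaxed to $\min_d \{\tau K(d) + u(x + \tau f(x, d))\}$ with a local step
$\tau = h / \max(|f|, 10^{-12})$ and bilinear interpolation, swept
Gauss–Seidel style in four alternating orderings until the sup-norm residual
falls below $10^{-6}$. This scheme is robust for the cycling replicator flow
field, where causal (fast-marching) orderings do not exist. The infinite
cost of failure is realized as a large finite cap
$U_{\max} = 10 (d_{\max} + \delta) T_{\mathrm{scale}}$ pinned on the failure
row; equilibrium nodes from which success is unreachable inherit it. Ties
between the two doses are broken toward $d = 0$ (less toxicity at equal
cost). The scheme is first-order: the value at a point converges roughly
linearly in the grid spacing, while the *cost of the integrated closed-loop
trajectory* converges much faster because the policy's switching curve is
what matters; quantitative checks therefore integrate the trajectory.

**Threshold solver.** Because $K \ge \delta > 0$, the equation is rewritten
as $\partial_s v = \max_d [a \cdot \nabla v + \frac12 \mathrm{tr}(B D^2 v)] /
K(d)$ and marched explicitly from the $s = 0$ data. Drift terms use
first-order upwind differences (direction per node and dose), diffusion uses
central differences, and the mixed derivative the standard 7-point
monotone-leaning stencil. All stencil weights are $s$-independent and
precomputed, so each budget level is a sparse matrix–vector product. The
budget step is set from the explicit-scheme stability bound
($\Delta s \cdot \max |w_{\mathrm{center}}| \le 0.9$, computed and recorded
in the output); a user-supplied step that violates the bound is refused with
the required value. Values are clipped to $[0, 1]$ after each level and the
largest clip is reported — machine-epsilon clips are normal, large ones
indicate instability. On the faces $q \in \{0, 1\}$ all $q$-coefficients
vanish identically, so the march solves the induced 1-D dynamics there
without artificial boundary data. Value and policy slices are stored on a
subsampled budget grid (default spacing 0.01 cost units); the marching grid
itself is orders of magnitude finer.

One practical detail deserves mention: the stored policy on the two barrier
rows is inherited from the adjacent interior row. The rows themselves are
Dirichlet data, but a simulated state sitting marginally above the success
barrier looks up its dose at the nearest node — the barrier row — and a
conventional zero dose there would let drift push the state away from the
barrier, stalling the course indefinitely while the budget drains.

**Simulator.** Euler–Maruyama with the dose re-evaluated every step from the
current $(q, p)$ (and remaining budget $s$, tracked by $\dot s = -K$);
nearest-node policy lookup preserves the bang-bang structure (interpolating
a binary field would create spurious intermediate doses). Barrier crossings
inside a step are refined by linear interpolation, which removes the leading
$O(dt)$ bias in the terminal cost. Once $s$ hits zero the course continues
under a caller-chosen fallback policy (conventionally $d_\star$); since cost
keeps accruing identically, the fallback can only shift probability mass
*above* the budget, a property the tests assert path-by-path. Paths are
seeded with counter-based per-path sub-seeds from one master seed, so any
single path can be replayed independently of the ensemble size, and normal
draws use an explicit Box–Muller transform so replays are bit-identical
across platforms. States are clamped to the unit square (excursions are
numerical only, since the diffusion vanishes on the faces); clamp counts are
returned per path.

**Problem sizes.** The quantitative checks in the test suite use spatial
grids of $161^2$–$401^2$ and $10^4$ Monte-Carlo paths at $dt = 10^{-3}$
(binomial standard error $\approx 0.5\%$ near $p = 0.5$); the acceptance
script uses $481^2$. These sizes were chosen so that the remaining
discretization error, estimated by Richardson comparison of successive grid
refinements, is comparable to the Monte-Carlo noise at $10^4$ paths.
Reference values quoted from the study were computed with $10^5$ paths;
at $10^4$ the comparison tolerances include 3 binomial standard errors.

## What the checks do and do not show

The consistency checks validate the solver–simulator pair *under the bundled
models at the study parameter values*: PDE-predicted success probabilities
match simulated frequencies within the combined discretization and binomial
tolerance; the noise-free simulator collapses onto the deterministic
integrator; value cubes respect their probability bounds, boundary
conditions and budget monotonicity; and the analytic bang-bang switch
condition agrees with the discrete argmax away from the switching curve.
They do not validate either tumor model against data — both are stylized
models of cell-line dynamics, without mutation, demographic stochasticity,
spatial structure, or partial observability — and policies computed here are
method demonstrations, not clinical guidance.

## Known limitations

* Both solvers are first-order; success probabilities read directly off a
  coarse cube can be biased upward by several percentage points in regions
  where $v$ has steep gradients (near level curves of the deterministic
  value $u$). Refine the grid, or validate by simulation, before quoting a
  number.
* The explicit budget march needs $O(10^4$–$10^5)$ levels at the stability
  bound; runtime grows like $n_q n_p \bar S / \Delta s$. The cube for the
  EGT study conditions at $481^2$ takes a few minutes on one core.
* The tie-break toward $d = 0$ makes the stored policy conservative in
  regions where $v$ is numerically flat (success nearly certain or nearly
  impossible); this is harmless for the value but means the policy map is
  only meaningful where $v$ has gradient.
* `sr_params_synthetic()` is synthetic. Quantitative statements about the
  sensitive–resistant system require the experimentally calibrated
  coefficients, which must be supplied by the user.

## A worked example

```{r example, eval = FALSE}
pars <- egt_params() # study conditions
u <- solve_deterministic_hjb(pars, nq = 321, np = 321)
tr <- integrate_optimal_trajectory(pars, u, c(0.26, 0.665), dt = 1e-3)
attr(tr, "cost") # ~ 5.13

cube <- solve_threshold_hjb(pars, s_bar = 5, nq = 321, np = 321)
autoplot(cube, s = c(1.5, 3, 5), what = "policy")

e <- run_ensemble(pars, cube, c(0.27, 0.4), s_bar = 4.71,
                  dt = 1e-3, n = 10000, seed = 1, fallback = u)
summarize_ensemble(e, thresholds = c(4.35, 4.71))
```
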