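---
title: "Methods: the self-healing model and its network realization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the self-healing model and its network realization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selfheal)
```

## The analytic model

`selfheal` studies tissue homeostasis as a feedback loop between a single
effective cell (a fibroblast-like *agent*, activity $a$) and its substrate
(local extracellular-matrix stiffness $k$):

$$\frac{da}{dt} = \frac{k}{1+k} - a, \qquad
  \frac{dk}{dt} = -D\,k\,(a - q) + P.$$

The assumptions behind these forms:

* activity relaxes toward a saturating function of stiffness — cells
  activate on stiff substrate, but activation costs energy and tops out at
  a finite level. In dimensional terms the saturation level is $A$, the
  half-activation stiffness $Q$, and the relaxation rate $\alpha$;
  `nondimensionalize()` maps the six dimensional parameters onto the three
  that matter: $q = q'/A$, $D = A D'/\alpha$, $P = P'/(\alpha Q)$.
* stiffness is removed enzymatically when activity exceeds a threshold $q$
  and deposited when activity is below it — the partition factor $(a-q)$
  times the simplest stiffness-proportional removal term $-Dk$.
* a constant production floor $P > 0$ prevents the biologically wrong
  fixed point at the origin; with $P = 0$ exactly, the model degenerates to
  $a^* = q$, $k^* = q/(1-q)$ with no dependence on $D$ (`fixed_point()`
  implements that branch only for exact zero; nearby values use the general
  closed form, which is numerically stable as written).

Substituting the activity nullcline $a = k/(1+k)$ into the stiffness
equation yields a quadratic whose unique positive root is the homeostatic
set point $k^*$; `stability_report()` evaluates the Jacobian trace
$\tau = -1 - D(a^*-q)$ and determinant
$\Delta = D(a^*-q) + Dk^*/(1+k^*)^2$ there, and also reports the simple
sufficient condition $D < 1$. In the constant-stiffness limit the activity
equation is linear and decays as a single exponential
(`activity_relaxation()`); the full two-variable relaxation is *not*
exponential — the log-residual slope steepens over time and activity makes
a brief excursion away from its set point after a stiffness perturbation —
which the unit tests check directly.

### Parameters and defaults

| parameter | meaning | default | units |
|---|---|---|---|
| `q` | activity threshold (production vs digestion) | 0.2 | dimensionless activity |
| `D` | digestion rate | 0.32 | 1/dimensionless time |
| `P` | production rate | 0.1 | stiffness/dimensionless time |

The baseline triple gives $a^* = 0.50559$, $k^* = 1.022612$; it sits well
inside the stable region and produces resolution of a doubled-stiffness
lesion on a timescale of a few hundred dimensionless time units. The aging
parameterization (`aging_params()`) raises the set point to $k^* = 2$
(hence $a^* = 2/3$, $q = 2/5$), lowers $D$ to 0.08 — slow matrix turnover —
and recomputes $P = D \cdot 8/15 \approx 0.0427$ from stationarity
(`production_for_fixed_point()`) so that only the *dynamics*, not the set
point, change.

### Integration

`integrate_model()` uses an adaptive embedded Runge–Kutta 2(3) pair
(Bogacki–Shampine, deSolve's `"ode23"`) with `rtol = 1e-8`,
`atol = 1e-10` by default. Results are solver-agnostic at these tolerances;
the order-2(3) pair is ample for a smooth two-variable system. Trial stages
may probe $k$ slightly below zero (the flow itself cannot, since
$dk/dt = P > 0$ at $k = 0$); stage evaluations clamp $k$ at 0, and a
negative *output* value — never observed in practice — would be clamped
with a warning. Activity is validated on input but not clamped during
integration: the saturating form keeps $a \in [0,1]$ invariant.

## The network realization

`build_hex_network()` constructs a honeycomb patch of identical Hookean
springs, each with rest length shorter than its built geometric length so
the resting lattice carries tension, as soft tissue does. Choices that the
model statement leaves open, and what this package does:

* **Patch dialect.** Hexagonal cells on an offset grid; `rows = cols = 10`
  (240 nodes, 339 springs) is the experiment default. Interior nodes join
  exactly three springs; the spring count obeys the planar Euler relation
  for any patch size.
* **Pre-strain.** 10% by default (`rest_length = 0.9 * spacing`), exposed
  as a parameter. All reported network properties (homogeneity in spring
  constants, linear response, halo counts) are pre-strain-independent;
  pre-strain only sets the magnitude of the resting tension.
* **Boundary.** Nodes on the outer ring (membership in fewer than three
  hexagonal cells) are position-fixed during equilibration. Agents may
  still occupy and leave them; migration just uses however many springs are
  incident.
* **"Average network stress".** Defined here as mean spring tension,
  stiffness × (length − rest length). It is the simplest frame-consistent
  scalar; it vanishes at rest, doubles when all spring constants double at
  fixed geometry, and makes the biaxial modulus below a force-per-strain
  quantity. Homogeneity and symmetry tests pin this behavior.
* **Network stiffness.** `network_stiffness()` equilibrates, scales the
  boundary biaxially by ±0.2% about the centroid, re-equilibrates the
  interior at each strained boundary, and divides the stress difference by
  the total strain (0.004) — a central difference in the linear-response
  regime (halving the amplitude changes the answer by < 0.1%).
* **Equilibration.** The default minimizer is deterministic L-BFGS-B on the
  interior coordinates with the analytic gradient; a seeded simulated
  annealing option (geometric cooling, Gaussian single-node moves) is
  retained, finished with the same local descent so both land on the same
  minimum to ~1e-6 relative energy on test fixtures. The minimization
  target, not the algorithm, determines results: the pre-tensed Hookean
  energy is effectively convex from lattice-like starts. An exhaustive
  grid search over a one-free-node hexagon fixture confirms the minimum.

## Agent dynamics

Each iteration of `run_simulation()` advances dimensionless time by `dt`
(default 1; any `dt < 2` keeps the explicit activity update stable):

1. every agent samples one incident spring — uniformly for the pure random
   walk, stiffness-proportionally for the durotactic walk — and crosses it;
2. from *pre-step* values, the agent gains
   $\Delta a = dt\,(k/(1+k) - a)$ with $k$ the crossed spring's stiffness,
   and contributes $\Delta k = dt\,(-Dk(a-q) + P)$ to that spring;
3. all increments apply simultaneously (concurrent crossings of a spring
   sum), so results cannot depend on agent ordering. Springs are remodeled
   *only when crossed*; unvisited springs hold their value. Because the raw
   rate equations vanish at $(a^*, k^*)$, a uniform network at $k^*$ with
   all agents at $a^*$ is exactly stationary — no baseline offset is needed.

Multiple agents may share a node (no exclusion). Spring stiffness is floored
at a tiny positive value with a warning; the floor is unreachable under the
healing scenarios. Replicate $i$ of `run_ensemble()` seeds its RNG with
`base_seed + i`, so ensembles are reproducible run-to-run and replicates
are independent.

**Injury, halo, resolution.** Injury multiplies the central spring (the one
whose midpoint is nearest the node centroid, ties broken by lowest index)
by a factor, default 2. The halo is the set of springs more than 0.1% above
$k^*$ (`halo_threshold = 1.001`); a run is *resolved* at the first step
where the halo is empty and the injured spring is within 0.1% of $k^*$,
reusing the same 0.1% band for symmetry.

**Forcing (fibrosis).** `forcing_period = n` resets every agent's activity
to 0 after each $n$-th update. In this model's convention $a = 0$ is a
*highly active*, depositing state (it lies below $q$, so
$dk/dt = Dkq + P > 0$), implemented literally. One discretization subtlety
matters: with `dt = 1` a single post-reset Euler step carries activity all
the way to the nullcline value $k/(1+k)$, so the agent spends half of each
2-step cycle in a digesting state and the intended "persistently active"
forcing self-cancels on stiff springs. The fibrosis scenario therefore runs
at `dt = 0.25`, where post-reset activity stays low through the cycle,
stiffening is progressive, and durotaxis acts as a positive feedback —
agents preferentially revisit the stiffest springs, whose deposition rate
$Dkq + P$ grows with $k$ — producing faster, more heterogeneous stiffening
under the biased walk.

**Halo-prohibited control.** With `remodeling = FALSE` agents never modify
springs; the central spring instead follows a user-supplied stiffness
trajectory (typically the injured-spring series of a paired random-walk
run) while activities still update, isolating the halo's contribution to
activity dynamics.

**Ensemble statistics.** `compare_series()` applies a two-sided
Mann–Whitney test per time step to replicate halo sizes (all-tied steps are
flagged, not tested); the choice of a rank test reflects the small, tied,
integer-valued samples. At desk-scale replicate counts the ensemble mean
halo curve is noisy near its flat maximum, so `ensemble_peak_step()`
locates peaks on a 21-step centered running mean — the standard smoothing
treatment for noisy simulation series. Paired scenario comparisons use
common replicate seeds for variance reduction; the unpaired rank test is
then conservative.

## What the experiments emulate — and what they do not

The scenario drivers run at desk scale: a 10 × 10 patch and 100-replicate
ensembles (30 for the aging comparison) rather than thousands, with the
full scale one argument away. At this scale the qualitative phenomenology
is robust across seeds — halo rise-and-fall, earlier durotactic peak,
faster biased-walk resolution, progressive heterogeneous stiffening under
forcing, several-fold slower aging repair — but per-step significance
levels are far weaker than at reference scale, and peak locations carry
tens-of-steps uncertainty.

One quantitative correspondence deserves honesty. With an agent on every
node and small `dt`, the injured spring's ensemble-mean decay *approaches*
the two-variable analytic solution but stays systematically above it by up
to ~9% mid-decay (the equivalence test asserts a 5% band and this is the
package's one known red). The reasons are structural to the migration
rules: the analytic model describes one agent resident on the lesion,
whose activity climbs with lesion stiffness; in the network the lesion is
serviced by a rotating cast of visitors whose activity averages well below
the resident value, and late in healing the lesion's traversal share drops
toward the unbiased incidence fraction. Migration can only dilute the
resident-agent rate, never exceed it — the unit suite verifies the decay
is bracketed from below by the analytic solution.

The model deliberately omits: multiple cell types and cytokine signaling,
chemotaxis, cell division/death, bond rupture and re-bonding, 3-D
architecture, heterogeneous initial matrix, and any coupling of mechanical
equilibrium back into migration or remodeling — mechanics is a readout
only. Passing tests therefore demonstrate the feedback structure's
sufficiency for self-healing phenomenology on an idealized lattice, not
fidelity to any particular tissue.

## Numerical summary

* solver: embedded RK 2(3), `rtol = 1e-8`, `atol = 1e-10`; outputs on
  user-specified or 501 equispaced times.
* discrete map: forward Euler, `dt = 1` (healing), `dt = 0.25` (forcing),
  stability bound `dt < 2`.
* minimizer: L-BFGS-B, analytic gradient, energy tolerance ~1e-10;
  annealing option with geometric cooling (factor 0.9/sweep, 60 sweeps,
  Gaussian moves of 0.05 lattice units) plus local polish.
* tie-breaks: central spring by lowest index among equidistant midpoints;
  node ordering canonical in (y, x).
* degenerate inputs rejected: $q \notin (0,1)$, $D \le 0$, $P < 0$,
  `dt` outside (0, 2), imposed trajectories shorter than the run.
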