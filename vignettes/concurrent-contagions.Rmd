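---
title: "Modelling concurrent contagions on networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling concurrent contagions on networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multicontagion)
```

## The model

`multicontagion` implements a discrete-time stochastic process for an
arbitrary number *m* of contagions — pathogens, rumors, innovations —
spreading concurrently on an undirected simple graph (single- or
multi-layer). Each node holds exactly one of the *m* states (1-of-m
coding). Every time step, synchronously and reading only the step-start
configuration, each node undergoes two mutually exclusive mechanisms:

1. **Spontaneous state change.** A draw from the node's row of the matrix
   `Delta`: `delta[k, l]` is the probability that a node in state *k*
   spontaneously moves to *l*; the diagonal `1 - sum(off-diagonal)` is the
   probability that nothing happens spontaneously. This generalises the
   curing/recovery mechanism of classical epidemic models.
2. **Contact-induced state change** (only if the spontaneous draw left the
   state unchanged). The process is *reactive*: every neighbor *j* attempts
   a transmission on its link with probability `gamma[k, s_j]`, where *k*
   is the receiver's state and `s_j` the neighbor's state, independently
   across links (and directions — contacts are directed, as in the rumor
   model). If one or more links become *infectious*, the node picks one of
   them uniformly at random; if that link transmitted state *r*, the node
   adopts the state *l* with `theta[k, r, l] = 1`. The stimulation tensor
   `Theta` covers processes in which exposure to one state triggers
   adoption of a *different* one (a spreader exposed to another spreader
   becomes a stifler); its default is the identity, `l = r`.

Because time steps have finite length, several transmissions can succeed
simultaneously — the central difficulty this model addresses head-on
instead of assuming infinitesimal steps or asynchronous updates.

## The adoption probability and its approximation

For a node in state *k* whose neighbors occupy fixed states with per-state
counts `n_l`, write `s_l ~ Binomial(n_l, gamma[k, l])` for the number of
infectious links carrying state *l* and `S` for their total. The
probability that the uniformly chosen transmission carries state *l* is

$$ q_l = E\left[\frac{s_l}{S};\, S \ge 1\right], \qquad
   h = \prod_l (1 - \gamma_{kl})^{n_l}, \qquad \sum_l q_l + h = 1 . $$

The package evaluates this **exactly** by two interchangeable backends:

* enumeration of all $2^n$ infectious-link events (the defining sum), used
  up to `enumGuard = 20` links;
* the polynomial-integral identity
  $E[s_l/S; S \ge 1] = \int_0^1 n_l \gamma_l (1-\gamma_l+\gamma_l x)^{n_l-1}
  \prod_{j \ne l}(1-\gamma_j+\gamma_j x)^{n_j}\,dx$, a degree-$(n-1)$
  polynomial integrated exactly by Gauss–Legendre quadrature with
  $\lfloor n/2 \rfloor + 1$ nodes, valid for degrees in the thousands.

The identity follows from $1/S = \int_0^1 x^{S-1}dx$ and independence of
the per-link Bernoulli draws. The two backends agree to machine precision
and serve as mutual oracles in the test suite, with Monte-Carlo
frequencies as a third corner.

For the deterministic solver the neighbor states are themselves random
(probability vectors `p_j`), and the exact value requires a sum over all
$m^k$ neighbor configurations crossed with the $2^k$ events — intractable
beyond small degrees. The package's tractable path applies a **one-point
(midpoint) quadrature** to the tie-breaking integral and renormalises so
that the exactly computed no-adoption probability
$h = \prod_j (1 - v_j)$, $v_j = \sum_r \gamma_{kr} p_j^r$, is preserved:

$$ q^*_l = (1 - h)\,\frac{u_l}{\sum_r u_r}, \qquad
   u_l = \gamma_l \sum_j \frac{p_j^l}{1 - v_j/2} , $$

which for integer counts collapses to
$u_l = n_l\gamma_l/(1-\gamma_l/2)$. The construction makes the
approximation **exact** in three regimes: when only one state is
transmissible (the classical product form), when all transmission
probabilities are equal (symmetry forces $q_l \propto$ expected exposure),
and for nodes of degree at most one. Outside these regimes its worst
absolute error over all count vectors with $n \le 10$ is about $6\times
10^{-3}$ for transmission probabilities up to 0.3 and about $8\times
10^{-2}$ up to 1.0 (measured against the exact backends; the test suite
asserts 0.02 and 0.1). The error is systematically signed: states with
high transmission probability competing against weakly transmitting states
tend to be overestimated. A plain ratio-of-expectations weight
($u_l = n_l\gamma_l$) satisfies the same exactness limits but is roughly
twice as inaccurate at high transmission probabilities, which is why the
tilted weight is used.

## Deterministic counterpart and continuous time

Taking expectations of the stochastic update under the assumption that
nodes' states are independent yields a nonlinear dynamical system on the
per-node probability vectors: a field `P` (N x m, rows summing to 1)
evolves by the three-term composition *spontaneous in* + *contact-induced
in, given no spontaneous move* + *stay*. `stepField()` offers the
approximate backend at any scale and the exact configuration-sum backend
behind a cost guard (`m^k 2^k` elementary terms per node, budget 1e7 by
default, overridable for deliberate brute-force runs on 6–9-node graphs).
`iterateFixedPoint()` iterates to an L-infinity tolerance of 1e-10 (cap
1e5 iterations) and reports non-convergence honestly — oscillatory
systems are flagged, not errors. Note one caveat: dynamics that creep
along slow manifolds (e.g. heteroclinic-type cycles approaching
monomorphic corners) can momentarily satisfy a step-change criterion; the
residual history is exposed for diagnosis.

Substituting probabilities by rates (`gamma = rate * dt`) and letting `dt
-> 0` gives the continuous-time equations. In that limit at most one
transmission event occurs per instant, so the contact gain of state *k*
depends only on the neighbors' state-*k* components — the equations
simplify structurally, and the package verifies this both symbolically
(structural perturbation test) and numerically: the discrete solver's
endpoint deviation from a fixed-step RK4 reference shrinks linearly in
`dt` (first-order consistency). RK4 with fixed step (default `dt = 0.01`,
via `deSolve`) is used precisely so that consistency-order measurements
are clean; adaptive stepping is a possible extension.

## Model zoo

Presets cover the standard reductions, each validated against an
independently hand-coded transcription of its printed update equations
(agreement to 1e-12 over 100 steps in the test suite):

| preset | states | mechanism summary |
|---|---|---|
| `presetSIS(beta, delta)` | S, I | infection + spontaneous recovery |
| `presetSIR(beta, delta)` | S, I, R | permanent immunity |
| `presetSIRS(beta, delta, xi)` | S, I, R | temporary immunity |
| `presetMakiThompson(lambda, alpha, sigma)` | I, S, R | rumor spreading; spreader-spreader contact stimulates stifling via `Theta`; `sigma = 0` recovers the original model |
| `presetSI1I2S(b1, b2, d1, d2)` | S, I1, I2 | two competing SIS-type contagions |
| `presetSI1I2SContactOnly(...)` | S, I1, I2 | recovery by contact with susceptibles instead of spontaneously |
| `presetThreeInnovations(G)` | A, B, C | cyclic contact-only competition, full 3x3 `Gamma` incl. diagonal |
| `presetMultiplexSI1I2S(...)` | S, I1, I2 | two layers, each contagion confined to its own layer |

The three-innovation default matrix is **synthetic**
(`threeInnovationsGammaSynthetic()`): a stand-in chosen once with the
structural features the example calls for — relatively large values,
meaningful diagonal, row maxima forming the cycle A→B→C→A, which drives
cyclic spreading waves in stochastic lattice runs. With this matrix the
*deterministic* field damps its oscillation after a few hundred
iterations on small lattices; sustained cycling is a property of the
stochastic spatial dynamics, which the deterministic independence
approximation does not capture indefinitely.

For the multiplex case a node has one state across all layers, but each
layer carries its own transmission matrix; links from all layers compete
in a single uniform tie-break, and the no-adoption probability multiplies
across layers. When each transmissible state lives on exactly one layer
this reduces to per-layer product forms, checked against an independent
implementation.

## Stochastic engines

`simulateRun(method = "exact")` simulates every link event — it *is* the
model. `method = "approx"` is the approximated stochastic version: each
node samples its next state directly from the closed-form adoption
distribution given its neighbors' counts (with `h` exact). Comparing
ensemble averages of the two versions measures the approximation's
trajectory-level accuracy on systems too large for the exact
deterministic backend; on a 32x32 periodic lattice with the
three-innovation model (200 runs each, 50 steps) the macroscopic
fractions differ by at most about 0.012 — the same order as the
single-node approximation error, concentrated at the oscillation onset.
Because this bias is systematic, it is resolvable by a statistical test
at large ensemble sizes even though the trajectories visually coincide.

The deterministic solver tracks the stochastic ensemble mean only as far
as the independence assumption holds. On lattices, spatial correlations
make the ensemble-averaged oscillations decohere while the deterministic
field keeps a coherent phase, so the two diverge on oscillatory systems
regardless of ensemble size; this is a property of the mean-field
closure, not an implementation artifact, and the package therefore
assesses the approximation stochastically (above) where fixed-point
comparison is uninformative.

## Experiment scale and defaults

* Fixed-point scans (`scanCompetition`): grid step 0.05 over
  $[0,1]^2$, recovery parameters fixed at `delta1 = delta2 = 0.2`
  (defaults, overridable), on complete/star graphs of 6 nodes and the
  3x3 periodic lattice — sizes at which the exact backend is feasible.
  Initial states are random assignments redrawn until every state is
  present (a competition with an absent contagion is vacuous); three per
  cell, error = worst Euclidean norm of the difference between the two
  backends' macroscopic fixed points.
* Trajectory comparison: 32x32 lattice, 200 runs per engine, 50 steps —
  a desk-scale rendition of the large-lattice experiment (128x128, 1000
  runs), which remains available by passing those sizes explicitly.
* The RNG contract: the simulator consumes R's global RNG stream inside
  a single synchronous C++ kernel that reads only the step-start state,
  so results are reproducible given `set.seed()` and structurally
  independent of node iteration order; ensembles seed run *r* with
  `baseSeed + r`.

## Numerical choices

* Conservation: every exact adoption computation satisfies
  `sum(q) + h = 1` to 1e-12; deterministic steps keep rows of `P`
  stochastic to 1e-9 (asserted in tests); the approximation preserves it
  by construction.
* Degenerate inputs: zero-degree nodes have `h = 1`; all-zero `gamma`
  rows short-circuit; `v_j = 1` (certain transmission) is handled exactly
  (`h = 0`); tie-breaks among equally probable successful links are
  uniform by reservoir sampling.
* The enumeration backend refuses degrees beyond 25 outright (memory);
  the exact field backend refuses nodes whose configuration sum exceeds
  the term budget rather than silently approximating.
* Probability/rate forms are distinct modes: converting a rate model with
  `toProbabilities(model, dt)` rejects any entry with `rate * dt > 1`,
  naming it; simulators and the discrete solver accept only probability
  form, the continuous-time functions only rate form.

## What the synthetic experiments do and do not show

All networks and parameter sets here are generated in code: canonical
graph topologies, preset parameter matrices, seeded random initial
assignments. They exercise the mathematical contracts — exactness limits,
conservation, reduction identities, backend agreement, consistency orders
— under conditions chosen to be representative of the small-graph and
lattice experiments the model family is used for. They do not validate
the independence (mean-field) closure on networks with strong degree
heterogeneity or community structure, nor parameter inference on observed
spreading data; both are applications the machinery supports (the
deterministic solver yields per-node likelihoods) but which require real
data beyond this package's scope. Node-dependent parameters and
fractional (weighted) `Theta` entries are deliberately unsupported.
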