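---
title: "Topology-driven idiotypic network modelling with idionet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topology-driven idiotypic network modelling with idionet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idionet)
```

## The model

`idionet` models the antigen-free idiotypic network: antibodies that
stimulate or suppress one another's production in the absence of any
external antigen. Each antibody carries a binary concentration
$c_i \in \{0,1\}$ ("produced" / "suppressed"), and the network acts on
antibody $i$ through a mean field

$$h_i = S + \sum_{k \ne i} J_{ik}\, c_k, \qquad c_i = \Theta(h_i),$$

where $J_{ik} = J_{ki}$, $J_{ii} = 0$ measures the influence of antibody
$k$ on antibody $i$ (stimulatory when positive, suppressive when
negative), $S$ is a global threshold, and $\Theta$ is the Heaviside step.
The couplings are conventionally drawn from $[-1, 1]$; the package treats
that interval as the sampling convention of its generators and enforces it
as a hard constraint only in an optional strict mode.

The package's core extension makes the field *multilinear*: the coupling
graph $\mathcal{G}$ (support of the non-zero $J_{ik}$) is completed to its
clique complex $\mathcal{C}$, and any simplex
$\sigma = \{\ell_1, \dots, \ell_{n+1}\}$ of $\mathcal{C}$ may carry a
coupling $J_\sigma$ contributing

$$J_\sigma \prod_{j \in \sigma,\, j \ne i} c_j$$

to $h_i$ for every $i \in \sigma$. A cell's contribution vanishes as soon
as one of its *other* members is suppressed, which is exactly what makes
these couplings genuine $n$-body interactions: they cannot be decomposed
into pairwise effects. With only pairwise couplings the multilinear field
reduces identically to the linear one (the $n = 1$ case), which the test
suite verifies on random states.

The product is taken over the simplex's vertices *other than* $i$. This is
the one reading of the $(n+1)$-vertex cell product under which the
pairwise case reduces exactly to the classical field, and it is the
convention used throughout.

The global cost function is $E(c) = \sum_i h_i(c)\, c_i$ with $h$ the
multilinear field evaluated on the same configuration. $E$ is defined on
*all* $2^N$ binary configurations; the threshold self-consistency
$c_i = \Theta(h_i)$ characterizes fixed points of the dynamics, not the
support of the statistical ensemble. (The binary state space is used
throughout; a continuous relaxation $c_i \in [0,1]$ admits several
inequivalent semantics and is deliberately not guessed at.)

Two further conventions are fixed once:

* $\Theta(0) = 1$, so that a zero field counts as stimulatory and the
  update is a deterministic map into $\{0,1\}^N$; the alternative
  $\Theta(0) = 0$ is available via `zero_value`.
* Each cell of $\mathcal{C}$ carries at most one coupling value, attached
  by its sorted vertex tuple.

## Dynamics

The update $c_i(t+\tau) = \Theta[h_i(t)]$ is iterated either
synchronously (all antibodies from the same snapshot — the default, as the
parallel reading of the update rule) or as an asynchronous index-order
sweep, provided for robustness checks; outputs are labelled with the mode
because the two schedules can disagree. There is no randomness anywhere in
the dynamics; all stochasticity lives in the data generators.

`attractors()` enumerates all $2^N$ initial states (default cap
$N \le 16$), finds every cycle by functional-graph decomposition, and
reports basin sizes, which must and do sum to $2^N$. For synchronous
dynamics of symmetric pairwise models the test suite checks the classical
property that all cycles have length $\le 2$; this is verified
empirically over random model batches, not assumed, and is *not* asserted
for multilinear models.

## Exact statistical mechanics

The partition function

$$Z(x) = \sum_{\{c_\ell\}} e^{-x E(\{c_\ell\})}, \qquad x \ge 0,$$

is computed by exact enumeration (cap $N \le 20$), never by sampling.
Weights are accumulated in log space (log-sum-exp) so large $|xE|$ cannot
overflow, and the final sum is evaluated in a peak-scaled form that is
exact at $x = 0$, where $Z = 2^N$. Correlation functions

$$\Gamma_k(x) = \frac{1}{Z} \sum_{\{c_\ell\}} c_{\ell_1} \cdots c_{\ell_k}
  e^{-x E}$$

are ensemble probabilities that $k$ given antibodies are simultaneously
active: they lie in $[0,1]$, equal $2^{-k}$ at $x = 0$, and can only
decrease when indices are added. `observable_sweep()` tabulates $Z$, the
mean concentration $m(x)$ and its ensemble variance over an $x$-grid and
flags the steepest finite-difference slope of $m$ as the crossover
candidate — a symmetry-breaking scale, if the model has one.

Two points the interface makes explicit rather than resolving silently:

* The ensemble sums over all $2^N$ valuations. Folding configurations by
  the global flip $c \mapsto 1 - c$ (which halves the count to $2^{N-1}$)
  is available as `identify_global_flip` for exploratory use, since both
  counting conventions appear in discussions of this model family.
* The package computes both the Poincaré polynomial of a complex and
  $Z(x)$ and reports them side by side; it does not assert a variable
  mapping identifying one with the other, because no explicit dictionary
  is fixed by the model.

## Homology, persistence, and the data comparison

The clique complex is built by clique enumeration (via igraph) with a
default dimension cap of 4; capping truncates Betti numbers above the cap,
which is why the inference routines raise the cap to one above the target
vector's length. Boundary matrices follow the lexicographic simplex order,
making them reproducible bit for bit. Betti numbers are ranks of boundary
maps, by Gaussian elimination over GF(2) (the default field — fast, and in
keeping with the model's $\mathbb{Z}_2$ degrees of freedom) or by rational
rank for torsion checks; the two agree on every torsion-free fixture in
the suite, and the Euler characteristic identity
$\sum (-1)^n b_n = \sum (-1)^n \#\text{cells}_n$ is property-tested on
random Erdős–Rényi complexes.

Empirical topology comes from a Vietoris–Rips filtration over GF(2),
implemented as compiled boundary-matrix reduction. For antibody time
series the default metric is the signed correlation distance
$d_{ij} = 1 - \rho_{ij}$, chosen so that *anti*-correlated antibodies are
maximally far; $1 - |\rho|$ is available by flag since no proximity notion
is canonical for these data. Zero-variance (constant) trajectories get
$\rho := 0$ with a warning instead of an error. Points represent
antibodies (antibody-as-point convention); the dual sample-space analysis
is left open.

A persistence diagram is reduced to a single Betti vector by the
**plateau rule**: among the finite filtration scales, take the longest
interval on which the whole Betti vector is constant and read the vector
there (ties go to the smallest scale; the scan stops at the last finite
event because a complete Rips filtration is eventually contractible
forever). The plateau rule was preferred to total-persistence
maximization for interpretability — the answer is literally "the topology
you see at most scales" — and the supporting interval is always reported
next to the vector. Model and data vectors are compared by L1 distance
after zero-padding.

## The S[B] adaptation loop

The S[B] view couples a behavioural machine $B$ (here: the attractor
states and transitions of the network dynamics) with a structural
controller $S$ whose states are contexts labelled by Betti-vector
constraints, observed through $O(q)$ = the Betti vector of the current
model's complex. The well-formedness invariants — $O$ defined on all of
$Q$, and $q_0 \models L(r_0)$ — are checked by `check_sb()` and
re-established after every adaptation.

Adaptation compares the model's Betti vector with the data's. On mismatch
the package must solve an inverse problem — find a coupling support whose
clique complex has prescribed Betti numbers — which in general is a system
of nonlinear algebraic conditions with no stated solution method. The
package realizes it as seeded simulated annealing over single-edge
toggles with the L1 Betti mismatch as cost, initialized (when the vertex
budget allows) at a constructed witness: a wedge of cross-polytope graphs,
one $(k{+}1)$-partite $K_{2,\dots,2}$ gadget per unit of $b_k$, whose flag
complex is a $k$-sphere, plus isolated vertices for extra components and
homotopy-irrelevant pendants for leftovers. The constructed start
typically verifies immediately, making the common recovery cases
deterministic; annealing remains the engine for targets the construction
cannot reach within $N$. Every returned graph is re-verified through the
homology engine before being returned, and budget exhaustion raises a
typed error carrying the best graph found — a declared failure, never a
silent one. No uniqueness is claimed: the first verified witness is
returned and the evaluation count recorded.

Coupling values for an adapted support follow the geometric rule
$J_\sigma = -(a V_n + b \kappa_n W_n)$: minus a weighted sum of the
regular unit-edge $n$-simplex volume and the total volume of its
$(n-2)$-faces, curvature-weighted. Since no curvature formula is fixed
for abstract cells, $\kappa_n = 1$ by default with per-dimension
overrides. Larger cells thus couple more negatively, and monotonicity in
$a, b$ is property-tested. Contexts accumulate across adaptations — prior
S-states are never deleted — and adaptation is idempotent once the
topologies match. Transition invariants constraining the adaptation path
are exposed only as the recorded S-transition history, not as implemented
checking logic.

## The Z2 Regge toy

The same binary degrees of freedom admit a geometric reading: on a closed
triangulated surface, squared edge lengths restricted to two values
$q_\ell = 1 + \mathfrak{l}\sigma_\ell$, $\sigma_\ell = 2c_\ell - 1 = \pm 1$.
The package implements the two-dimensional case only — the minimal
dimension where the discretized action

$$A(q) = x\Big(\sum_{\text{triangles}} V^{(2)}
  - \zeta \sum_{\text{vertices}} \mathfrak{d}(v)\, V^{(0)}\Big)$$

is fully exercisable and independently checkable: areas come from Heron's
formula, deficit angles $\mathfrak{d}(v) = 2\pi - \sum \text{angles at } v$
from the law of cosines, and every valid configuration must satisfy
combinatorial Gauss–Bonnet $\sum_v \mathfrak{d}(v) = 2\pi\chi$, which the
suite verifies to $10^{-9}$ on sphere and torus fixtures. The point
volume $V^{(0)}$ is set to 1 (a convention the model leaves open). The
state sum

$$Z = \sum_{\sigma \in \{\pm 1\}^{\mathcal{N}}} \mathcal{F}(q)
  \prod_\ell q_\ell^{-\alpha}\, e^{-A(q)}$$

discretizes the simplicial path-integral measure: the continuum weight
$dq_\ell / q_\ell^\alpha$ becomes the per-edge factor $q_\ell^{-\alpha}$,
and $\mathcal{F}$ is the indicator of the triangle inequalities. It is
enumerated exactly (cap: 24 edges) with per-triangle lookup tables over
the 8 sign patterns, and matches a naive nested-loop oracle to machine
precision on the tetrahedron. The $\sigma \leftrightarrow c$ conversion
helpers document the structural correspondence with the immune model's
states; no full coupling–geometry dictionary is asserted, because none is
fixed by the model.

The 16-triangle torus fixture is built by subdividing one edge of the
7-vertex Möbius torus (giving $V{=}8$, $E{=}24$, $F{=}16$, $\chi = 0$),
keeping the enumeration cap honest while exercising a genus-1 surface.

## Synthetic data and what the tests do (and do not) show

All inputs are generated in code from seeds: Erdős–Rényi coupling models
with uniform $[-1,1]$ values (the model's stated sampling interval),
planted topological fixtures with known Betti vectors (4-cycle
$\to (1,1)$, octahedron $\to (1,0,1)$, two triangles $\to (2,0)$), noisy
binary trajectories (deterministic dynamics plus i.i.d. Gaussian
observation noise — a generic choice, as no data-noise model is
specified), jittered circles and two-cluster clouds for the persistence
pipeline. Default sizes are the study conditions of the test suite:
$N \le 12$ for enumeration batches, 40-point circles with jitter 0.05,
clusters separated by ten times their spread. Generators are pure
functions of their configuration (same seed, same bytes) and leave the
caller's RNG stream untouched.

These fixtures emulate the *topological* features of real concentration
data — loops, components, voids at a dominant scale — but not its
biological texture: no birth–death population dynamics, no
antigen-driven excursions to large concentrations, no measurement
heteroscedasticity. A green suite therefore shows that the machinery
(enumeration, homology, persistence, recovery loop) is correct on spaces
with known answers, not that any particular biological dataset has these
topologies.

## Numerical choices and limitations

* Exact enumeration everywhere, by design: $2^N$ configurations
  ($N \le 20$), $2^{\mathcal{N}}$ sign assignments
  ($\mathcal{N} \le 24$). Beyond the caps the functions refuse and
  advise sampling, which is out of scope.
* Problem sizes in the tests (batches of 25–100 random models at
  $N \le 12$, 20–40-point clouds, budgets of 500–2000 annealing
  evaluations) were chosen so the whole suite runs in well under a minute
  while still exercising every property at non-trivial scale.
* GF(2) ranks by dense Gaussian elimination — adequate for the complex
  sizes at these $N$; no sparse or persistent-cohomology optimizations.
* The Rips engine enumerates all $\binom{n}{k}$ simplices up to
  `max_dim + 1` (default `max_dim` 2: $H_0$–$H_2$ cover the comparisons
  the model calls for); practical up to ~60 points at dimension 2.
* Tie-breaks: $\Theta(0) = 1$; plateau ties go to the smallest scale;
  simplices and boundary columns are ordered lexicographically.
* The annealer's witness construction needs $1 + \sum_k b_k(2k+1)$
  vertices in the main component; below that it falls back to random
  initialization, where success within budget is genuinely stochastic and
  failure is reported as such.
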