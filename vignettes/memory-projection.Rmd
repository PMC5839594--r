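---
title: "Memory functions for subnetworks of thermodynamic gene-regulation models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Memory functions for subnetworks of thermodynamic gene-regulation models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnmem)
```

## The model class

`grnmem` works with thermodynamic state-ensemble models of transcriptional
regulation. Each gene $j$ is described by the set of binding conformations
of its cis-regulatory DNA. A conformation is an occupancy vector
$\mathbf{n}$ (how many copies of each transcription factor are bound), an
affinity weight $w_{(j,\mathbf{n})}$ and a production rate
$\alpha_{(j,\mathbf{n})}$. The probability of a conformation follows the
ensemble form

$$x_{(j,\mathbf{n})} =
  \frac{w_{(j,\mathbf{n})} \prod_i x_i^{n_i}}
       {\sum_{\mathbf{n}'} w_{(j,\mathbf{n}')} \prod_i x_i^{n_i'}},$$

and protein concentrations evolve as production averaged over
conformations minus first-order decay,

$$\partial_t x_j = \sum_{\mathbf{n}} x_{(j,\mathbf{n})}
  \alpha_{(j,\mathbf{n})} - \beta_j x_j.$$

All quantities are treated as dimensionless: weights carry units of
concentration$^{-\sum n_i}$ so every weighted term in the ensemble sum is
commensurate, and time is naturally measured in units of inverse decay
rates. Clamped inputs (for instance a morphogen effector) are species with
a fixed concentration that appear in occupancy vectors but have no dynamics
of their own; their level is the natural scan parameter for
position-dependent models. Decay rates must be strictly positive — a zero
decay rate would leave a species without a restoring timescale and the
memory analysis below undefined — so $\beta = 0$ is rejected at model
construction.

## The projection

Given a steady state $y$ (located by damped Newton iteration seeded from a
user grid plus long-time endpoints of the full dynamics), the deviation
dynamics $\delta x = x - y$ are Taylor-expanded. At linear order this gives
a matrix $L$; we use the row = source, column = target orientation
throughout ($\partial_t \delta x^T = \delta x^T L$), fixed once package-wide
to eliminate transposition mistakes between modules. At quadratic order the
expansion also carries coefficients $Q_{(jk)i}$ of the canonical products
$\delta x_j \delta x_k$ ($j \le k$), with $Q_{(jj)i}$ equal to half the
second partial derivative. Both are computed analytically by the quotient
rule over the ensemble sums and are validated against central finite
differences in the test suite.

Choosing a subnetwork $S$ (the tracked species) and a bulk $B$ (the rest),
the projected equations for the subnetwork deviations are

$$\partial_t \delta x_i = \sum_j \delta x_j \Omega_{ji}
  + \int_0^t \sum_j \delta x_j(t') M_{ji}(t - t')\, dt' + r_i(t),$$

with the rate matrix $\Omega = L^{S,S}$ and the memory matrix

$$M(\Delta t) = L^{S,B}\, e^{L^{B,B} \Delta t}\, L^{B,S}.$$

The random forces $r_i$ encode uncertainty about the initial bulk state and
vanish when the bulk starts at its steady state; the package adopts that
convention, making the projected equations closed. At quadratic order the
observable vector is enlarged with all canonical products; products
involving at least one bulk species belong to the bulk block, and the
quadratic-to-quadratic block of the extended matrix follows from the
product rule applied to the linear dynamics, discarding the cubic terms
that the quadratic coefficients would generate (a second-order truncation
in the deviations). Because the linear-to-quadratic block is exactly zero,
the linear memory functions computed at quadratic order coincide with those
of the linear-order projection.

## Why the projection needs only the thermodynamic equations

The ensemble production rates are rational functions of the concentrations,
so a truncated Taylor expansion is a heuristic. The mathematical
justification implemented in `expand_network()` proceeds by making every
DNA conformation an explicit mass-action species. Binding and unbinding
rate constants are constrained by detailed balance: their ratio must equal
the corresponding affinity-weight ratio. Only ratios are fixed, so the
package sets every unbinding rate to one by default and exposes the
convention (`kminus`) so users can verify that projected quantities do not
depend on it — the test suite re-runs the equivalence check with
randomised unbinding rates in $[0.5, 2]$.

All DNA reactions are scaled by a fast rate factor $\gamma$; DNA
concentrations scale as $1/\gamma'$ and production rates as $\gamma'$, so
that binding consumes a negligible amount of protein. We take
$\gamma' = \gamma$, the simplest choice consistent with both factors being
large (they play different roles — reaction speed versus concentration
scale — and the implementation keeps them as separate arguments with equal
defaults). The finite-$\gamma$ simulations include the net binding drain on
free protein, which vanishes as the DNA approaches its quasi-steady state;
trajectories of the expanded network converge monotonically to the
thermodynamic ones over $\gamma \in \{10, 100, 1000\}$ in the shipped
checks, at roughly first order in $1/\gamma$.

Linearising the expanded network and eliminating the fast DNA block with a
quasi-steady-state (QSS) condition,

$$L_\mathrm{eff} = L^{\mathrm{slow},\mathrm{slow}}
  - L^{\mathrm{slow},a} (L^{a,a})^{-1} L^{a,\mathrm{slow}},$$

reproduces the direct linearisation of the thermodynamic equations exactly
(machine precision in the tests, required to $10^{-8}$). One numerical
subtlety arises here: the DNA fractions of each gene sum to one at all
times, so the raw fast block $L^{a,a}$ is singular along each gene's
conservation direction. `effective_protein_L()` therefore eliminates one
reference conformation per gene first — its deviation is minus the sum of
the others — which makes the fast block invertible without changing the
dynamics. With that reduction the equivalence is an identity, independent
of $\gamma$ and of the unbinding-rate convention, which is why
`project_subnetwork()` can work from the thermodynamic equations alone.

## Memory analysis

The memory amplitude is the memory function at zero time difference,
$M(0) = L^{S,B} L^{B,S}$, and the decay of $M(\Delta t)$ is governed by the
spectrum of the bulk block — for the two-gene cross-repression example the
self-memory is a single exponential decaying at the bulk protein's decay
rate. Memory is decomposed into channels attributed to individual bulk
species. The package uses *entry attribution*: a signal's channel is the
bulk observable it first enters, which makes the channels a column
partition of $L^{S,B}$ and hence exactly additive (channel sums equal the
total at machine precision). This is our stated reading of the
channel-decomposition idea; exit attribution (the bulk observable from
which the signal re-enters the subnetwork) is provided as an option for
comparison. Products of two different bulk species are split half and half
between the two channels and reported separately so users can re-aggregate
under a different convention.

Matrix exponentials of the bulk block are computed densely
(scaling-and-squaring); on uniform time-difference grids a single
exponential of the step is taken and accumulated by multiplication, which
is both faster and consistent with the semigroup property.

## Integrating the projected equations

`integrate_projected()` solves the closed Volterra integro-differential
equations on a uniform grid: the history is stored on the integrator grid,
the convolution uses trapezoidal quadrature (second order), and each step
is a Heun predictor–corrector. Halving the step changes trajectories at
$O(h^2)$, so the step is chosen to keep quadrature error below the accuracy
being tested; the shipped checks use steps between $10^{-2}$ and
$2.5\times 10^{-3}$ in units of the decay time. Three modes are exposed:

* `memoryless` — bare linear rate-matrix term $\delta x\, \Omega$,
* `linear` — adds the linear memory integral,
* `nonlinear` — quadratic rate-matrix and memory terms as well.

Our reading of the "no memory" baseline is the bare linear rate-matrix
term: it is what remains when the bulk's action is dropped entirely, and it
makes the three modes strictly nested. On a fully linear network with the
bulk initially at steady state, the `linear` mode is exact up to quadrature
error; over ensembles of random models with small (5%) initial subnetwork
perturbations, median trajectory errors order as nonlinear ≤ linear ≤
memoryless. A perturbation-scaling check separates the modes more sharply:
the memoryless error divided by the perturbation size approaches a nonzero
constant while the linear-memory ratio vanishes with the perturbation. The
two-gene cross-repression motif is *not* suitable for that particular
check, because its bulk production does not depend on the bulk species
itself, making the linear projection exact at linear order; random
three-gene models are used instead.

With memory present, the current subnetwork state no longer determines the
velocity — two histories passing through the same state move at different
speeds, which is what makes trajectories cross in the subnetwork plane.
On the bistable fixture (one-dimensional subnetwork) the package tests
exactly this signature, since genuine curve crossings need at least two
subnetwork dimensions.

## Effective drift

The effective drift summarises the instantaneous tendency of the projected
system. The closure used is a first-order-in-time expansion of the history,
$\delta x(t-\tau) \approx \delta x(t) - \tau\, \partial_t \delta x(t)$, with
the upper integration limit sent to infinity. Writing
$M_0 = \int_0^\infty M(\tau)\,d\tau = -L^{S,B}(L^{B,B})^{-1}L^{B,S}$ and
$M_1 = \int_0^\infty \tau M(\tau)\,d\tau = L^{S,B}(L^{B,B})^{-2}L^{B,S}$
(closed forms valid for a stable bulk block and verified against numerical
quadrature), the drift $d$ solves the linear system
$d = \delta x\,\Omega + z\,M_0 - (\partial_t z)\,M_1$, where $z$ collects
the subnetwork observables. At quadratic order the time derivative of a
product observable is $d_j \delta x_k + \delta x_j d_k$ — linear in $d$ —
so the closure remains a single linear solve. This self-consistent
construction is the package's stated reading of the first-order drift
expansion; it reduces to $\delta x\, \Omega$ when memory is dropped and
vanishes at the steady state for every order.

## Shipped fixtures and what they do (and do not) show

* `cross_repression` — two genes, each repressing the other through a
  single binding site, with production $\alpha_1/(w_1 + w_{p2} x_2)$ for
  gene 1 and conversely. The ensemble encoding uses an unbound conformation
  (weight $w_1$, rate $\alpha_1 / w_1$) and a repressor-bound conformation
  (weight $w_{p2}$, rate 0), the unique two-conformation reading that
  reproduces that rational production law. Parameters:
  $\alpha_1 = \alpha_2 = 1$, $w_{p1} = 1$, $w_{p2} = 2$, $w_1 = w_2 = 2$,
  $\beta_1 = \beta_2 = 1/2$. The motif is monostable; its unique steady
  state solves $x_1^2 + 3 x_1 - 2 = 0$.
* `cross_repression_bistable` — the same motif with two binding sites per
  gene (weights $1, w_p x, w_p^2 x^2$ with $w_p = 3$; production only from
  the unbound state, $\alpha = 1$, $\beta = 1/4$), which is verified
  bistable in the tests (two stable states and a symmetric saddle).
* `neural_tube_like` / `neural_tube_family(sig)` — a synthetic four-gene
  circuit copying the topology of the ventral neural-tube network: mutual
  repressions among the factors N, O, P, I and an activating clamped input
  on N and O. It is explicitly *not* the published parameterisation of that
  network (those parameter values are not reproduced here); parameters are
  round numbers chosen once, by the design analysis below, and frozen.
  Design goals: (i) the signal scan shows three dominant-factor regions
  (P/I at low signal, O at intermediate, N at high); (ii) the full-signal
  end is monostable; (iii) removing the O→P repression lets P stay high in
  the O-dominant state, which holds N down and creates a competing stable
  O-branch at high signal. Two-site (quadratic-weight) repressions provide
  the necessary steepness; N requires two bound effector copies so its
  response is sharper in the signal than O's single-site response; and P —
  not O — is the decisive repressor of N, which is exactly what makes the
  O→P link a robustness element: with the link intact, an O-dominant state
  cannot hold N down at full signal because O shuts P off.

The seeded random-model generator (`random_grn_model`) draws log-uniform
weights in $[0.1, 10]$, production rates in $[0.5, 2]$ and decay rates in
$[0.2, 2]$, with each bound conformation repressing (zero production) with
probability one half. These ensembles exercise the machinery across
parameter scales, but they remain small (3–4 genes), noise-free,
well-stirred ODE models: passing tests say nothing about stochastic
copy-number effects, spatial coupling, or parameter regimes far outside
those ranges.

## Numerical choices

* Steady-state roots: damped Newton with analytic Jacobians, acceptance
  residual $10^{-10}$, deduplication at $10^{-6}$ in max-norm (ties keep
  the smaller residual), deterministic lexicographic output order.
* Stiff integration: `deSolve::lsoda` with analytic Jacobians for both the
  thermodynamic and the expanded systems; expanded-network tolerances
  default to $10^{-9}$ relative so DNA conservation holds to $10^{-9}$ or
  better.
* Continuation: natural parameter stepping with previous-point seeding; no
  arclength continuation — the fixtures are low-dimensional and folds are
  recovered by the seed grid.
* Basin scans: endpoints after 50 slowest decay times, Newton-polished,
  classified to the nearest steady state within $10^{-5}$ (ten times the
  dedup tolerance); starts exactly on a separatrix correctly converge to
  the saddle and are labelled as such.
* Degenerate inputs: an all-zero ensemble denominator raises an error
  naming the gene; an ill-conditioned fast block in the QSS elimination
  warns with the condition number and the near-null conformation
  combination; an unstable bulk block still evaluates the memory but warns
  that it will not decay.

## A worked example

```{r example}
m <- make_fixture("cross_repression")
ss <- find_steady_states(m, rbind(c(0, 0), c(2, 2)))
y <- ss[[1]]$y
round(y, 5)

proj <- project_subnetwork(m, y, "g1", order = "quadratic")
proj

# memory amplitudes: linear self-memory positive, quadratic negative
round(memory_amplitude(proj)[, "g1"], 5)

# the projected trajectory tracks the full dynamics near the steady state
cmp <- compare_to_full(m, proj, unname(0.9 * y["g1"]), seq(0, 15, 0.01))
cmp$errors
```

## Known limitations

The projection is built around one steady state; accuracy degrades away
from it, and multistable systems must be analysed state by state. Random
forces are set to zero, so initial bulk deviations from steady state are
outside the closed equations. Cubic and higher observable couplings are
truncated. The Volterra integrator stores the full history
($O(n^2)$ work in the number of steps), which is ample for the fixture
sizes here but would need a dedicated scheme for very long horizons.
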