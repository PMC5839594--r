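# grnmem — Zwanzig-Mori projection and memory functions for gene regulatory networks

Gene regulatory network (GRN) models quickly grow past the point where
their behaviour is intuitive: even four mutually repressing transcription
factors under a morphogen gradient produce multistability, basins of
attraction and transient dynamics that are hard to attribute to individual
links. `grnmem` is for systems biologists who want to *reduce* such a model
to a chosen subnetwork — the species they care about or can measure — while
keeping a quantitative, interpretable account of everything that was
removed.

## The method

The package works with thermodynamic state-ensemble models, where the
production rate of gene *j* is an average over the binding conformations
**n** of its regulatory DNA,

    dx_j/dt = sum_n x_(j,n) alpha_(j,n) - beta_j x_j,
    x_(j,n) = w_(j,n) prod_i x_i^(n_i) / sum_n' w_(j,n') prod_i x_i^(n_i'),

with affinity weights *w*, conformation production rates *alpha* and decay
rates *beta*. Around a steady state *y* the deviation dynamics are expanded
to linear (or quadratic) order, giving a matrix **L** in the row = source
orientation. For a partition into subnetwork S and bulk B, the Zwanzig-Mori
projection yields closed equations for the subnetwork deviations,

    d(dx_i)/dt = sum_j dx_j Omega_ji
                 + int_0^t sum_j dx_j(t') M_ji(t - t') dt',

with the rate matrix `Omega = L^{S,S}` and memory functions

    M(dt) = L^{S,B} exp(L^{B,B} dt) L^{B,S}.

Memory functions quantify how the subnetwork reacts to its own past via the
bulk; their amplitudes `M(0)` and channel decomposition (contributions
flowing through individual bulk species) measure the dynamical importance
of specific regulatory links. The expansion of the thermodynamic model into
a mass-action network of DNA-conformation species with detailed-balance
rates, followed by quasi-steady-state elimination of the fast DNA block, is
implemented as well, and reproduces the direct linearisation exactly — the
mathematical result that justifies computing projections from the
thermodynamic equations alone.

The package covers:

* model construction, validation, JSON serialisation (`grn_model`,
  `read_grn_model`, `write_grn_model`), full nonlinear simulation and
  steady-state location with stability;
* analytic linear and quadratic Taylor expansions (`linearize`,
  `quadratic_expansion`);
* mass-action expansion, stiff simulation at finite fast-rate factor gamma,
  and QSS elimination (`expand_network`, `simulate_expanded`,
  `effective_protein_L`);
* the projection itself: rate matrix, memory functions, amplitudes,
  entry/exit channel decomposition (`project_subnetwork`,
  `memory_function`, `memory_amplitude`, `channel_decomposition`);
* Volterra integration of the closed projected equations in memoryless,
  linear and nonlinear modes, comparison against the full dynamics, and the
  first-order effective drift (`integrate_projected`, `compare_to_full`,
  `effective_drift`, `kernel_moments`);
* bifurcation scans, memory-amplitude profiles along a parameter, basin
  scans and link removal (`continuation_scan`, `amplitude_profile`,
  `basin_scan`, `link_removal`);
* fixtures (a cross-repression motif, a bistable two-site variant, a
  synthetic four-gene neural-tube-like circuit) and a seeded random-model
  generator.

## Worked example

The minimal worked example is a cross-repression motif: two genes, each
repressing the other through one binding site, with production
`alpha_1 / (w_1 + w_p2 x_2)` for gene 1 and conversely
(`alpha = 1`, `w_p1 = 1`, `w_p2 = 2`, `w_1 = w_2 = 2`, `beta = 1/2`).

```r
library(grnmem)

m <- make_fixture("cross_repression")
y <- find_steady_states(m, rbind(c(0, 0), c(2, 2)))[[1]]$y
round(y, 5)
#>      g1      g2
#> 0.56155 0.78078

proj <- project_subnetwork(m, y, subnetwork = "g1", order = "quadratic")
proj
#> Zwanzig-Mori projection (quadratic order)
#>   subnetwork: g1
#>   bulk: g2
#>   rate matrix Omega (row = source):
#>      g1
#> g1 -0.5

round(memory_amplitude(proj)[, "g1"], 5)
#>       g1  (g1,g1)
#>  0.02403 -0.00938
```

Reading the output: the unique steady state is (0.56155, 0.78078) — the
positive root of `x1^2 + 3 x1 - 2 = 0`. Tracking only protein 1, the rate
matrix is its bare decay `-beta_1 = -0.5`; everything protein 2 does is in
the memory. The linear self-memory amplitude 0.02403 is *positive* — a
protein repressing its own repressor effectively promotes itself — and the
memory decays as `exp(-0.5 dt)`, the decay rate of the bulk protein: the
effect lasts only as long as the repressor persists. The quadratic
self-memory amplitude -0.00938 is negative, correcting the linear terms for
the saturating nonlinearity. Integrating the projected equations
(`integrate_projected`, `compare_to_full`) shows the memory terms tracking
the full dynamics closely near the steady state and degrading further away.

The four-gene fixture (`neural_tube_family`) demonstrates the analysis
workflow on a multistable patterning circuit: `continuation_scan` maps the
stable branches along the signal gradient, `amplitude_profile` follows the
memory amplitudes and their bulk channels along each branch, and
`link_removal` plus `basin_scan` show that deleting one repressive link
(O to P) enlarges the region with a competing stable branch and sharply
shrinks the basin of the previously monostable high-N state — a robustness
role for a link that barely matters for maintaining the steady states.

A thin command-line front end over the same functions ships in
`inst/cli/grnmem.R`
(`Rscript inst/cli/grnmem.R simulate --model model.json --out out/`).

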