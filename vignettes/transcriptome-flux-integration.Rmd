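---
title: "From transcriptome to flux: context-specific metabolic modeling with contextflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From transcriptome to flux: context-specific metabolic modeling with contextflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Bulk RNA-seq of exposed versus control animals tells us which genes move,
but not what the tissue's metabolism does with them. Constraint-based
modeling closes that gap: a genome-scale metabolic model (GEM) encodes every
annotated reaction with its stoichiometry, flux bounds, pathway ("subsystem")
label, and a gene-protein-reaction (GPR) rule linking it to the genes whose
products catalyze it. `contextflux` implements the full inference chain from
a raw count matrix and a GEM to subsystem-level activation/suppression
calls:

1. normalize counts and test differential expression (NB Wald + BH);
2. discretize expression into low / moderate / high per gene;
3. map gene levels onto reactions through the GPRs;
4. solve the iMAT mixed-integer program per sample and prune the
   switched-off low reactions into a *context-specific model* per animal;
5. characterize each context model by flux balance analysis (FBA), flux
   variability analysis (FVA), and hit-and-run flux sampling;
6. aggregate |flux| by subsystem, difference against the control group,
   t-test, and classify subsystems as activated or suppressed.

A synthetic-data module generates toy GEMs and count matrices with known
injected perturbations so that the complete chain is testable end to end
without any external data.

## Models and statistics

**FBA.** Fluxes `v` (mmol/gDW/h) satisfy steady-state mass balance
`S v = 0` and box bounds `lb <= v <= ub`; FBA maximizes the biomass
reaction's flux by linear programming. A reaction is *inactive* when
`|v| < 1e-6`; the absolute value matters because reversible fluxes are
signed. FVA minimizes and maximizes each reaction's flux under the same
constraints, by default with the objective held at its optimum (the
objective reaction's lower bound is raised; `fraction_of_optimum = 0`
explores the whole polytope).

**Differential expression.** `nb_wald_test()` is a deliberately simple
negative-binomial Wald test: median-of-ratios size factors, group means with
pseudocount 0.5, `log2fc = log2(mean_test / mean_ref)`, gene-wise dispersion
by the method of moments (floored at 1e-8; no shrinkage, no Cook's
filtering, no independent filtering), delta-method standard errors, and a
two-sided normal tail. DEGs require `|log2FC| > 0.25` and BH-adjusted
`p < 0.05`, both strict. The simplifications relative to a full DE engine
are intentional — the pipeline's subject is what happens *downstream* of the
DE table — and the null calibration and power of the test are themselves
part of the test suite (type-I error within [0.025, 0.075] at n = 10/group,
power ≥ 0.8 at log2FC = 2, n = 8/group).

**iMAT.** Expression states are mapped to reactions by evaluating the GPR
with `and` = min, `or` = max over `{-1, 0, 1}` (a complex is only as
available as its scarcest subunit; isozymes take the best one). Genes
without data, and reactions without GPRs, are moderate (0): absence of
evidence must not switch a reaction off. The MILP then maximizes the number
of expression-consistent reactions: each high-state reaction gains a point
if it carries `|v| >= eps` (binaries y+ / y- for the two directions, big-M
linking, `y+ + y- <= 1`), each low-state reaction gains a point if its flux
is forced to zero (binary y0 with `-M(1-y0) <= v <= M(1-y0)`). Defaults
`eps = 1`, `M = 1000` match the conventional bound magnitude of 1000; both
are arguments. The solver returns the first optimal incumbent; alternate
optima exist in principle and are not enumerated.

**Context extraction.** Only low-state reactions whose `y0 = 1` in the
optimum are removed — a moderate reaction that happens to carry no flux is
retained, because iMAT provides evidence of absence only for low states. If
the pruned model cannot reach a biomass flux of 1e-6, removed reactions are
restored greedily (the one that raises the attainable biomass most, then
repeat); this guard exists because the downstream analyses optimize the
biomass reaction and need a growing model.

**Flux sampling.** `sample_fluxes()` is an artificially-centered hit-and-run
sampler with FVA warmup points. The chain runs in null-space coordinates
(`v = v0 + N t`, `N` an orthonormal basis of `null(S)` from a QR
decomposition), so mass balance holds to machine precision at every step —
the usual periodic re-projection of drifting chains is replaced by a
parameterization that cannot drift. Directions go through the running
center (refreshed every 100 steps); one point is recorded every `thinning`
steps (default 100). The sampled polytope carries the objective constraint
at `fraction_of_optimum = 1` by default, matching the way the rest of the
package interrogates context models; 0 gives the unconstrained polytope.
A fixed seed gives bitwise-reproducible output, and the sampler name is
recorded in the result.

**Subsystem scoring.** Per sample, subsystem mean flux is the mean of
`|v|` over reactions at or above the inactivity threshold (signed means are
available via `use_abs = FALSE` but cancel across reversible reactions). A
cell whose subsystem has no active reaction is *missing* in the table; when
differencing against control, missing cells enter as zero flux — a
subsystem pruned from a context model genuinely carries nothing, and
activation-from-silence / suppression-to-silence are exactly the calls of
interest. Group deltas are exposed minus control (positive = activated),
tested by unpaired two-tailed pooled-variance t-tests over the per-animal
values, significant at raw p < 0.05 (BH across rows is available but off by
default). `projective_rescale()` provides a scale-invariant biproportional
RMS normalization of the subsystem x condition matrix for cross-condition
comparison — a deliberately simple stand-in for projective decomposition,
invariant to independent positive row/column scalings, not a re-derivation
of that method.

## The discretization choice

The package discretizes **per gene across samples** by default: a gene is
high (+1) in the samples where its normalized expression is strictly above
its own 75th percentile, low (-1) strictly below its 25th. This is the
relative-expression reading of the iMAT input — "highly expressed" means
*running above its typical level in this context* — and it is the form in
which condition contrasts can reach the flux side at all. The alternative,
quantiles across genes within each sample (`by = "sample"`), tiers genes by
absolute abundance; it is invariant to any monotone per-sample distortion,
but in a compact gene panel the between-gene spread (orders of magnitude)
dominates the within-gene, between-condition signal, so every sample
produces nearly the same states and the integration step becomes blind to
the exposure. Both modes are exposed; the quantile pair (0.25, 0.75) is an
argument. Ties at a threshold are moderate, and a degenerate distribution
(all values equal) yields all zeros with a warning.

## The synthetic study design

`make_toy_gem()` builds one substrate exchange feeding `n_subsystems`
parallel linear pathways that converge on a biomass precursor. Each pathway
is a subsystem; every internal reaction carries a GPR over fresh genes
(1-3 genes, random `and`/`or`). The exchange is non-limiting (bound 1000)
and each pathway's entry reaction is capacity-bounded at 10 mmol/gDW/h, so
the biomass optimum is `10 x (number of intact pathways)` and every intact
pathway saturates at a unique flux. That uniqueness is deliberate: with a
shared limiting substrate, the LP optimum is degenerate (any split among
intact pathways is optimal) and pathway usage would reflect solver
tie-breaking and mechanical share dilution rather than expression.

`simulate_counts()` emulates a multi-dose exposure design: ordered groups
(control first) with `n_per_group` replicate animals, log-normal baseline
means (meanlog 5, sdlog 1.5 — the dynamic range of bulk liver RNA-seq),
NB dispersion 0.1, a log-normal per-sample depth factor, and log2 fold
changes injected only into the genes of chosen subsystems, scaled per group
to mimic dose response. Effects are injected at the *transcript* level, not
the flux level, so recovering the perturbed subsystem as "activated" from
the flux side is a genuine end-to-end test of the whole chain. The matrix
also contains 500 unperturbed background genes by default: real studies
normalize genome-wide before subsetting to the model's genes, and without
background mass a perturbed subsystem is a large enough fraction of the
panel that median-of-ratios normalization picks up a systematic composition
bias (group-coherent size-factor shifts of ~20% in our measurements), which
masquerades as suppression of every unperturbed subsystem.

What the generator does **not** emulate: GC/length bias, batch effects, sex
chromosomes, dispersion trends, correlated gene programs, or any kinetic
realism in the toy network. Passing the end-to-end test therefore shows the
chain is sound — that injected transcriptional signal propagates through
normalization, discretization, the MILP, pruning, the LP, and the
subsystem statistics to the right call — not that it would recover effects
in any particular real tissue.

## Which subsystems get tested

Activation/suppression calls are made only for subsystems containing at
least one gene-associated reaction (`test_subsystems = "genic"`, the
default). Boundary exchanges and the biomass sink have no GPRs, so no
transcriptomic evidence can bear on them, and in the toy topology their
totals mechanically track the number of intact pathways; they appear in the
means table but receive no call. `"all"` restores full testing.

## Numerical choices

* **LP/MILP solver.** All programs are solved by a package-internal
  bounded-variable two-phase primal simplex (dense tableau, Dantzig pricing
  with a Bland's-rule fallback against cycling, pivot tolerance 1e-9) and a
  depth-first branch-and-bound with most-fractional branching and
  floor-based pruning for the integral iMAT objective. Finite bounds on all
  variables — natural for flux models — keep the formulation simple and
  exclude unboundedness. The iMAT indicator constraints use the tightest
  per-reaction big-M coefficients rather than one global constant; the
  integer solutions are identical but the relaxation gap (and with it the
  branch-and-bound effort) shrinks by an order of magnitude on the toy
  models. Solutions are deterministic given input ordering.
  The solver is validated in the test suite against an independent
  vertex-enumeration oracle on random networks and, for iMAT, against
  brute-force enumeration over all indicator assignments.
* **Tolerances.** Mass-balance residual ≤ 1e-6 and bound violation ≤ 1e-9
  on every returned flux (asserted in tests); reaction inactivity at
  |v| < 1e-6 with the boundary value counting as active; FVA objective
  constraint applied with a 1e-9 slack against round-off; MILP integrality
  tolerance 1e-6.
* **Ties and degeneracy.** Discretization ties are moderate; constant
  samples/genes discretize to all-moderate with a warning; a pooled t-test
  over two equal constant groups is 1 by convention (0 when constant but
  different); empty subsystems are missing cells, zero-imputed only at the
  delta stage.
* **Seeds.** Every stochastic component (toy GEM wiring, count simulation,
  sampler chain) takes an explicit integer seed and restores the caller's
  RNG state; pipeline per-sample sampler seeds are derived as
  `config seed + sample index`.
* **Problem sizes.** The validation suite runs desk-scale problems: random
  networks of ≤ 8 reactions for the vertex-enumeration comparisons, iMAT
  fixtures with ≤ 10 indicator binaries against brute-force enumeration,
  2000-gene null and 1200-gene power simulations for DE calibration, and
  five replicate end-to-end designs (5 subsystems x 4 reactions, 4 groups
  x 5 animals). These sizes make exhaustive oracles feasible; the
  implementation itself has no hard-coded size assumptions, but the dense
  simplex is not intended for genome-scale (10^4-reaction) models.

## Limitations

* The DE test is unshrunk; at very small n its dispersion estimates are
  noisy and its type-I error runs slightly above nominal (within the tested
  band). It is a documented simplification, not a DESeq2 replacement.
* iMAT alternate optima are not enumerated; a consensus over forced on/off
  re-solves would tighten per-sample state calls.
* The hit-and-run sampler is single-chain; no cross-chain convergence
  diagnostics are computed beyond the distributional checks in the tests.
* Loopless constraints are not implemented; fully reversible parallel
  routes can in principle carry thermodynamically infeasible cycles
  (rare in the generated toys, impossible to rule out in arbitrary models).
* Subsystem p-values are uncorrected by default (BH is an option), matching
  the analysis convention the pipeline reproduces rather than a
  recommendation.
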