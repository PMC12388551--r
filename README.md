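# contextflux

Transcriptome-guided context-specific metabolic flux analysis in R.

`contextflux` is for systems biologists who have bulk RNA-seq of treated
versus control animals (multi-dose exposure designs, gene knockouts) and a
genome-scale metabolic model (GEM) of the organism, and who want to know
which metabolic **subsystems** (pathways) the condition activates or
suppresses — not just which genes move. It implements the complete
inference chain as a tested R package: differential expression, tri-state
discretization, iMAT integration into per-sample context-specific models,
flux balance / variability analysis and flux sampling, and subsystem-level
differential flux calls. A synthetic-data module generates toy GEMs and
negative-binomial count matrices with known injected perturbations, so the
whole chain is validated end to end with no external data.

## The method

A GEM defines fluxes `v` (mmol/gDW/h) constrained by steady-state mass
balance and bounds:

    S v = 0,   lb <= v <= ub

**FBA** maximizes the biomass flux `v_bio` over this polytope (LP);
**FVA** reports `[min v_i, max v_i]` per reaction, by default with
`v_bio` fixed at its optimum; reactions with `|v| < 1e-6` are inactive.

**iMAT** turns a sample's transcriptome into a subnetwork. Normalized
expression is discretized per gene into low (-1) / moderate (0) / high (+1)
against the gene's own quantiles across samples, mapped onto reactions
through the gene–protein–reaction rules (`and` = min, `or` = max), and the
MILP

    max  sum_{r in High} (y_r+ + y_r-)  +  sum_{r in Low} y_r0
    s.t. S v = 0,  lb <= v <= ub
         v_r >=  eps - M (1 - y_r+)   (high, forward)
         v_r <= -eps + M (1 - y_r-)   (high, backward),  y+ + y- <= 1
         -M (1 - y_r0) <= v_r <= M (1 - y_r0)   (low)

maximizes the number of expression-consistent reactions (`eps = 1`,
`M = 1000`). Low reactions switched off in the optimum are pruned, with a
biomass-feasibility guard, giving one **context-specific model** per
animal. Context models are characterized by FBA (and optionally by 1000
hit-and-run flux samples); per subsystem, the mean `|v|` over active
reactions is differenced against the control group, tested with unpaired
two-tailed t-tests, and classified **activated** (positive, p < 0.05) or
**suppressed** (negative, p < 0.05).

All LPs and MILPs run on a package-internal bounded-variable simplex and
branch-and-bound, validated in the test suite against vertex-enumeration
and brute-force-indicator oracles.

## Worked example

The `analysis/` directory is a five-stage workflow over the package. Stage
1 simulates the study: a 5-pathway toy GEM and a 4-group x 5-animal count
matrix with a log2FC = 2 perturbation injected into the genes of
`pathway_03` (half strength at the lowest dose):

```sh
Rscript analysis/01_simulate_data.R
Rscript analysis/02_differential_expression.R
```

```
dose1 vs control: 11 up, 4 down (of 540 genes)
  top enriched subsystem: pathway_03 (overlap 7, padj 9.94e-11)
dose2 vs control: 10 up, 3 down (of 540 genes)
  top enriched subsystem: pathway_03 (overlap 8, padj 3.78e-14)
dose3 vs control: 13 up, 6 down (of 540 genes)
  top enriched subsystem: pathway_03 (overlap 8, padj 2.22e-12)
```

The DE stage already points at the right genes; stages 3–5 carry the signal
to the flux side — iMAT context models per animal, FBA/FVA/sampling, and
the subsystem delta table:

```sh
Rscript analysis/03_context_models.R
Rscript analysis/04_flux_analysis.R
Rscript analysis/05_subsystem_deltas.R
```

```
    subsystem group delta       p     class
7  pathway_03 dose1     6 0.03997 activated
8  pathway_03 dose2    10 0.00000 activated
9  pathway_03 dose3    10 0.00000 activated
...
recovery vs truth: recall 1.00, precision 1.00 (1 called, 1 correct)
```

`delta` is the subsystem's mean |flux| difference versus control in
mmol/gDW/h: in control animals the perturbed pathway is pruned from the
context models (zero flux), at the full doses it carries its entire
10 mmol/gDW/h capacity in every animal, and the dose-response is graded at
the low dose. All other subsystems stay `unchanged`, so the one injected
perturbation is recovered with no false positives.

The same chain is available programmatically:

```r
library(contextflux)
tg  <- make_toy_gem(seed = 1)
sim <- simulate_counts(...)                       # see analysis/01
cfg <- pipeline_config(tg$model, sim$counts, sim$metadata,
                       control = "control", seed = 1)
rep <- run_pipeline(cfg)
score_recovery(rep, sim$truth)
```

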