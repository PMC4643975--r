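# fbascreen

Comparative flux-balance screens of genome-scale metabolic models in R.

## The problem

Genome-scale metabolic models of the same organism — yeast alone has a
dozen published reconstructions — disagree in scope, annotation and
predictions, and much of the disagreement comes not from the reconstructed
biochemistry but from tunable model parameters: the simulated medium, the
biomass objective function, and the reference list of "essential" genes
used for benchmarking. Comparing reconstructions fairly requires
standardizing those parameters and re-running the same screens across all
models. `fbascreen` packages that workflow for anyone evaluating or
curating constraint-based models: systems biologists benchmarking a new
reconstruction, curators hunting for reconstruction errors, and method
developers who need screens with known ground truth.

## What it computes

At the core is flux balance analysis (FBA): maximize the flux *v*<sub>bio</sub>
through a biomass reaction subject to steady-state mass balance and flux
bounds,

```
max  v_bio   s.t.   S v = 0,   lb <= v <= ub
```

where `S` is the stoichiometric matrix over non-boundary metabolites.
On top of that LP (solved by a built-in bounded-variable simplex):

- **Deletion screens.** Boolean gene–protein–reaction (GPR) rules map gene
  deletions to disabled reactions (`and` = complex, `or` = isozymes). A
  gene is predicted essential when the mutant optimum falls below 1e-6
  flux units; a gene pair is synthetic lethal when neither gene is
  individually essential but the double mutant's flux is at most 10% of
  wild type.
- **Scoring.** Predictions against a reference list are summarized by the
  Matthews correlation coefficient,
  `MCC = (TP·TN − FP·FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`,
  with the growth-screen polarity (positive = viable). Cross-condition
  aggregation pools the counts, never averages coefficients.
- **Standardization.** Media are sets of exchange uptake bounds (YAML
  serializable, with per-model supplements); biomass definitions are
  precursor drains substituted for each model's own objective.
- **Network structure.** Blocked reactions (flux variability analysis with
  all exchanges open), dead-end metabolites (only-produced /
  only-consumed / single-reaction), and one-norm-minimized FBA for
  diagnosing unrealistic high-flux internal loops.
- **Scope comparison.** Binary gene and ChEBI-metabolite incidence
  matrices across models, pairwise distances, hierarchical clustering
  (Newick export) and classical MDS.
- **Growth correlation.** FBA maxima under measured uptake constraints
  (single or joint), Pearson correlation with observed growth rates, and a
  remove-reaction-and-rescan workflow for confirming suspect reactions.
- **Synthetic models.** `generate_toy_model()` builds toy networks whose
  essential genes, synthetic-lethal pairs, dead ends and blocked reactions
  are known *by construction*, so every pipeline stage can be validated
  with no external data.

Models load from SBML (Level 2 COBRA dialect or Level 3 + FBC) or from a
plain-text flat dialect (sections `[objective]`, `[metabolites]`,
`[reactions]`, `[gpr]`; see `?read_flat_model`).

## Worked example

```r
library(fbascreen)

tm <- generate_toy_model(toy_model_spec(
  n_linear_pathways = 3, pathway_length = 4, n_isozyme_pairs = 2,
  n_complexes = 1, n_dead_ends = 1, n_blocked = 1, seed = 42))
tm$model
#> <metabolic_model> toy_seed42
#>   genes:        15
#>   metabolites: 18 (0 boundary)
#>   reactions:   20 (3 exchange)
#>   objective:   biomass

screen <- single_deletion_screen(tm$model)
screen
#> <single_screen_result> toy_seed42 [medium: Default, biomass: Default]
#>   wild-type flux: 10
#>   genes evaluated: 15 (10 predicted essential)

tidy(build_confusion_single(screen, tm$truth$essential_genes))
#> # A tibble: 1 x 9
#>   model_id   medium  biomass reference          TP    TN    FP    FN   mcc
#> 1 toy_seed42 Default Default essential_genes     5    10     0     0     1

dbl <- double_deletion_screen(tm$model)
mcc(classify_synthetic_lethality(dbl$singles, dbl,
                                 tm$truth$synthetic_lethal_pairs))
#> [1] 1

blocked_reactions(tm$model)
#> [1] "R_de1"    "R_blk1_a" "R_blk1_b"
dead_end_metabolites(tm$model)$metabolite_id
#> [1] "m_de1"      "m_blk1_tip"
```

The screen recovers the 10 planted essential genes (one per undecorated
pathway step plus two for the `and`-complex) with no false calls, hence
MCC = 1; the two `or`-isozyme pairs are individually viable but pair
lethal; the planted side branches surface as blocked reactions and
dead-end metabolites. For a grid of models x media x biomass definitions
use `run_comparison()`, which returns tidy tables of per-cell MCCs, pooled
per-model MCCs, per-gene prediction classes, model summary statistics and
the scope-comparison objects (plus TSV/Newick/JSON exports when an output
directory is given).

## Package layout

- `R/` — model container and I/O, GPR logic, simplex LP core, FBA/FVA,
  standardization, screens, scoring, scope comparison, growth
  correlation, synthetic generator, grid driver, plots.
- `inst/extdata/` — small text fixtures: a 5-reaction SBML model, a flat
  dialect model, YAML medium/biomass definitions.
- `vignettes/model-benchmarking.Rmd` — the methods vignette: model,
  assumptions, parameter choices and limitations.
- `tests/testthat/` — unit, property and acceptance tests with
  independent oracles (vertex enumeration for LPs, R's own parser for
  GPR rules, sign-pattern scans for dead ends).
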