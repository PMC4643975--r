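---
title: "Benchmarking metabolic network models with standardized flux-balance screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking metabolic network models with standardized flux-balance screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbascreen)
```

## The model and its assumptions

A constraint-based metabolic model consists of a stoichiometric matrix
$S$ (rows: metabolites, columns: reactions), flux bounds
$lb \le v \le ub$, boolean gene–protein–reaction (GPR) rules, and a
biomass pseudo-reaction that drains precursor metabolites in
growth-mimicking proportions. Flux balance analysis (FBA) assumes the
cell is at steady state ($S v = 0$ over non-boundary metabolites) and that
evolution has tuned metabolism to maximize growth, so the maximum biomass
flux is taken as a proxy for growth rate:

$$\max_v \; v_{\text{bio}} \quad \text{s.t.} \quad S v = 0, \; lb \le v \le ub.$$

These assumptions are deliberately minimal: no kinetics, no metabolite
concentrations, no regulation. What FBA predicts well under them is the
*binary* outcome — growth or no growth — which is why every screen in this
package makes binary calls rather than quantitative fitness predictions.
Mutant growth rates depend on parameters (ATP maintenance, uptake
kinetics) that binary essentiality calls largely cancel out.

A deletion screen works through the GPR layer: deleting a gene set turns
each GPR leaf for a deleted gene FALSE; a reaction whose rule evaluates
FALSE is closed (bounds 0, 0). `and` encodes a protein complex — one
missing subunit disables the reaction — while `or` encodes isozymes, so a
single isozyme deletion changes nothing but the joint deletion is a
candidate synthetic-lethal interaction. Reactions with no GPR
(spontaneous, or of unknown catalyst) are never disabled.

## Decision thresholds

Two thresholds drive all classifications; both live in `screen_config()`
and are echoed into report provenance headers.

* **Essentiality threshold, 1e-6 flux units.** A gene is predicted
  essential when the mutant optimum falls below this value. Flux units
  are model-relative (mmol/gDW/h by convention); at the usual bound
  magnitude of 1000 this separates numerical noise from genuine growth by
  about nine orders of magnitude. An infeasible mutant LP is scored as
  zero flux, hence essential — with a closed uptake or broken biomass path
  the LP has no feasible flux distribution, which *is* "no growth" in this
  formalism.
* **Synthetic-lethality fraction, 10% of wild type.** A pair (of
  individually viable genes) is called lethal when the double mutant
  reaches at most 10% of the wild-type biomass flux. The strict reading
  defines *non-lethal* as exceeding 10%, so the boundary case is assigned
  to lethal. The fraction is arbitrary but strict; it is a config field
  precisely because reasonable analyses may move it.

Scoring polarity follows the growth-screen convention: **positive means
viable**. A true positive is a gene predicted viable and annotated
viable; a gene correctly predicted essential is a true negative. The
Matthews correlation coefficient is computed with the denominator as a
product of four square roots so genome-scale pair counts (order $10^7$,
products order $10^{28}$) never leave the exactly-representable integer
range of doubles; the result is clamped to $[-1, 1]$ because
`sqrt(x)^2` can overshoot by an ulp. When a denominator factor is zero
the MCC is defined as 0 and a message notes it. Aggregation across
conditions pools the four counts and recomputes — the mean of
per-condition MCCs is a different statistic and is deliberately not
offered.

For double-knockout scoring, reference pairs that fail the
neither-gene-individually-essential gate are counted as "other errors"
and excluded from the MCC: the underlying mistake was already charged to
the single-gene screen. Reference pairs naming genes outside the model
are out of scope and tallied separately, since a metabolic model cannot
be wrong about a gene it never claimed to cover.

## Standardization: media and biomass

Published models embed their authors' choices of medium and objective, so
raw comparisons confound the reconstruction with its parameterization.
`apply_medium()` closes every exchange uptake and reopens exactly the
listed components; `set_biomass()` replaces the objective with a common
precursor drain and *closes* the old objective reaction, so the
substituted objective fully replaces it (leaving the old drain open would
let it leak flux in variability analyses). Substitution fails loudly,
listing all missing precursors, when a model cannot satisfy the common
definition — silent partial substitution would quietly change what is
being compared.

Numeric conventions: "unconstrained" exchange is $\pm 1000$, the COBRA
magnitude convention; the default constrained glucose uptake is 10
(negative lower bound $-10$). Both are parameters, not constants, because
neither has a canonical value — they are echoed in every report header.
Media are YAML files with per-model key maps and supplements because real
model collections use incompatible exchange identifiers; keys resolve by
exchanged-metabolite id, then ChEBI id, then exchange-reaction id, and an
unresolvable key is a hard error listing the model's exchanged
metabolites.

## Network structure statistics

**Blocked reactions** are those that cannot carry flux under the network
structure. They are detected by flux variability analysis (per-reaction
minimization and maximization) with *all exchanges opened* to $\pm 1000$,
so that medium choice cannot masquerade as structural blockage; the
biomass definition still matters, which is why summaries report blocked
counts under both the model's own and a common biomass. The blocked
cutoff $\varepsilon_{block} = 10^{-6}$ matches the essentiality threshold
scale; the simplex feasibility tolerance is $10^{-9}$. FVA deliberately
does not fix biomass at its optimum (an `objective_fraction` argument
exists but defaults to none): blockage here is a property of the
reconstruction, not of one optimal flux state.

**Dead-end metabolites** are detected purely structurally, by two clauses
reported side by side rather than collapsed: (a) the metabolite
participates in exactly one reaction; (b) accounting for reaction
reversibility it can only ever be produced, or only ever be consumed.
The two clauses capture subtly different reconstruction defects (an
orphan leaf vs. a directional imbalance), and a metabolite in a single
*reversible* reaction satisfies (a) but not (b) — collapsing them would
hide that distinction.

**One-norm-minimized FBA** re-solves with biomass fixed at its optimum
(to within $10^{-8}$) and minimizes $\sum_j |v_j|$ via the standard
positive/negative split. Alternate optima in FBA are the rule, not the
exception; only objective values and the minimal one-norm are
contractual outputs, while individual fluxes are unique only on
constructed fixtures. The l1-minimal solution zeroes any internal cycle
that carries no objective benefit, so internal reactions that *still*
carry large flux after minimization are the signature of erroneous
shortcuts — `diagnose_high_flux_reactions()` ranks internal reactions by
$|v|$ (ties by id) and `remove_reaction_and_rescan()` closes a suspect
(bounds 0, 0 — provably equivalent to deleting the column) and repeats a
constrained growth scan to see whether correlations recover.

## Scope comparison

Models are compared as binary vectors: 1 if an ORF annotates any reaction
(gene scope), or 1 if a ChEBI identifier annotates any metabolite
(metabolite scope). A metabolite carrying several ChEBI identifiers —
database redundancy — contributes only its *first* identifier, and
unannotated metabolites are excluded, making the metabolite comparison
intentionally less comprehensive than the gene comparison rather than
silently guessing identities. Reaction-level comparison is a non-goal:
no external reaction reference identifier is shared across model
generations, so any mapping would be invented.

Distances default to Euclidean-on-binary and clustering to average
linkage — the defaults of the MATLAB `pdist`/`clustergram` pair that this
kind of analysis historically used — with Hamming and Jaccard, single and
complete linkage available since nothing canonical forces the choice.
Classical MDS is the standard double-centered eigen-decomposition
(`stats::cmdscale`); negative eigenvalues (non-Euclidean input) are
truncated with a warning, and cluster-count statements are treated as
cut-height-dependent observations, not contracts of this package.
Compartment naming across models is *not* canonicalized: published models
disagree, and guessing equivalences would corrupt the comparison — ids
are opaque, case-sensitive strings throughout, with no gene nomenclature
translation either.

## The synthetic-data generator

`generate_toy_model()` builds linear substrate-to-biomass pathways and
decorates steps with motifs whose phenotypes are known by construction:

| motif | GPR | planted truth |
|---|---|---|
| plain step | single gene | essential |
| isozyme pair | `(a or b)` | synthetic-lethal pair, each viable |
| complex | `(a and b)` | both essential |
| parallel route | gene + GPR-less duplicate | gene viable, no interaction |
| dead-end branch | — | 1 dead-end metabolite, 1 blocked reaction |
| blocked stub | — | 2 blocked reactions, 1 dead-end tip |

The truth is derived from the wiring during generation, never from the LP
machinery under test — that independence is what makes it an oracle.
Generation is a pure function of the spec (same seed, byte-identical
files), and the generator restores the caller's RNG state. Default scale
is tens of genes and a few hundred reactions so that exhaustive double
screens finish in seconds. What the toys emulate: compartments, isozymes,
complexes, parallel routes, dead ends, blockage, exchange/biomass
structure. What they do not: the degree distribution, cofactor coupling
and loop structure of real metabolic networks. Passing tests on toys
therefore demonstrates correctness of the algorithms, not predictive
accuracy on any real organism.

`generate_reference_lists()` emulates imperfect literature-derived
references by flipping each truth label independently with a configurable
rate; the expected MCC of a perfect predictor against such a list has an
exact expression under the two binomial flip counts, which the test-suite
evaluates by summation over the joint probability mass (the plug-in MCC
of expected counts carries an $O(1/n)$ bias that is detectable at the
tested scale). `generate_growth_observations()` perturbs FBA optima with
multiplicative Gaussian noise truncated at zero — a deliberately simple
error model for chemostat growth tables.

## Numerical core

No LP solver ships with the R distribution in use, so the package
includes a dense bounded-variable two-phase simplex (`solve_lp()`):
equality constraints over shifted variables, upper-bound flips, Dantzig
pricing with smallest-index tie-breaking, and an automatic switch to
Bland's rule after a run of degenerate pivots to guarantee termination on
the heavily degenerate LPs metabolic networks produce. Pivoting is
deterministic, so identical programs return identical vertices — the
basis of all byte-reproducibility guarantees. Metabolic LPs here are
small (hundreds of rows and columns) and dense tableau updates are
entirely adequate; unboundedness is reported as a status, never clamped,
because the growth-correlation module uses it as a loop symptom.
Correctness is established in the test-suite against an independent
vertex-enumeration oracle on randomly generated programs.

The double screen enumerates unordered pairs lexicographically, streams
records to a checkpoint file for resumable campaign-scale runs, and by
default applies a skip rule that reuses an already-computed flux only
when the pair's *jointly* disabled reaction set is empty or equal to one
single mutant's set — a provably neutral shortcut whose equality with the
exhaustive path is asserted on fixtures. Whether to skip at all is
exposed because the equivalence deserves to be checkable, not assumed.

## Problem sizes

The shipped tests and the acceptance script run single screens on models
of 12–30 genes, exhaustive double screens on 12–20 genes (66–190 pairs),
a 28-cell standardized grid (2 models × 7 media × 2 biomass definitions),
noisy-reference simulations on a ~500-gene truth over 50–200 replicate
lists, and growth scans of 20 points over 50 noise replicates. These
sizes were chosen so that the full validation battery, including the
brute-force oracles, completes in a few minutes on a single core while
still exercising every code path at non-trivial scale; the algorithms
themselves have no size-specific logic.

## Known limitations

* No regulatory or condition-specific constraints; conditionally
  essential genes in rich-vs-minimal comparisons are out of reach of pure
  FBA and are expected error sources.
* No loopless-FBA MILP or thermodynamic constraints; l1-minimization
  suppresses, but cannot forbid, flux through stoichiometrically balanced
  cycles.
* No quantitative mutant fitness — binary calls only, by design.
* No automatic minimal-supplement search for non-growing model/medium
  pairs; supplements are declared per model in the medium file.
* The flat dialect and SBML reader/writer cover the constraint-based
  subset (species, reactions, bounds, GPRs, objective, ChEBI
  annotations), not kinetic SBML.
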