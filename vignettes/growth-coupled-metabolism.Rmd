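---
title: "From omics tables to growth-coupled regulators: the gemflux methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From omics tables to growth-coupled regulators: the gemflux methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Stem-like tumour subpopulations — for instance CD133-expressing
hepatoma cells — proliferate faster than their counterparts, and the
metabolic rewiring behind that proliferation is of direct therapeutic
interest.  gemflux implements a systems pipeline that starts from three
routine data types (a gene-expression table with duplicate samples per
cell type, a metabolite concentration table, and a universal
genome-scale metabolic model) and ends with a ranked list of
transcription factors whose targets operate the metabolic reactions
most tightly coupled to biomass production.  The stages are:

1. **Differential expression** under the raw-p rule: equal-variance
   Student's t-test per gene plus a strict linear fold-change gate.
2. **Rank scoring** of the model's genes per cell-type sample, feeding
3. **context-specific model extraction** — a mixed-integer program that
   selects the reaction subnetwork most consistent with the expression
   evidence while provably producing the detected metabolites and
   passing a set of metabolic tasks;
4. **gap-filling**, adding a minimum number of universal-model
   reactions so the extracted model grows on the configured medium;
5. **flux response analysis** — the biomass flux is pinned at a grid of
   fractions of its optimum, the attainable flux range of every
   reaction is measured at each step, and the Pearson correlation of
   the range midpoint with biomass flux flags growth-coupled reactions;
6. **TF ranking** by the number of growth-coupled metabolic genes
   (via gene–protein–reaction rules) each factor targets in a curated
   regulatory network.

# The models and their assumptions

## Constraint-based core

A `MetabolicModel` is a stoichiometric matrix with flux bounds
(mmol·gDW⁻¹·h⁻¹ by convention), boolean gene associations, and a
designated biomass drain.  Flux balance analysis assumes steady state
(`S v = 0`) and optimises one reaction's flux; flux variability
analysis reports each reaction's attainable `[min, max]` under an
objective constraint.  Exchange reactions are written in the secretion
direction (`met →`), so uptake is negative flux and a `Medium` is just
a vector of maximal uptake magnitudes; applying it sets every exchange
reaction's lower bound to `-uptake` (absent exchanges are closed).
Reversibility is encoded purely by a negative lower bound.

All linear programs are solved by a dense two-phase primal simplex
written for this package (no LP solver binding is part of the package's
dependency footprint).  It uses Dantzig pricing with a switch to
Bland's rule after 2000 iterations, which guarantees termination on the
degenerate programs that subnetwork selection produces.  Constraint
satisfaction uses a 1e-9 tolerance; fluxes below 1e-6 are classified as
zero (blocked-reaction calls).  Unbounded directions are reported as
`±Inf`, never truncated.  The dense tableau limits practical problem
size to a few hundred reactions, which covers the package's validation
scale (all shipped fixtures and synthetic bundles are ≤ 100 reactions);
swapping in an industrial solver behind `fba()`/`fva()` would be the
first step toward genome-scale data.

## Differential expression

The test is the classic pooled-variance Student's t — with duplicate
arrays per group it is the only defensible choice, and it is applied to
the intensities as provided (linear scale), with the fold change
computed on linear-scale group means.  Calls are `up` iff
`p < 0.05` **and** `FC > 1.5`, `down` symmetrically (`FC < 1/1.5`);
both gates are strict inequalities.  No multiple-testing correction
gates the calls; a Benjamini–Hochberg column is emitted for information
only.  Degenerate genes (zero pooled variance) get `p = 1` when the
group means agree and `p = 0` otherwise.  Whether absolute fold change
should be read symmetrically, and whether the test should run on a log
scale, are genuinely open readings; both choices are isolated in
`differentialExpression()` and documented here — the symmetric linear
reading is the default.

## Rank scores and reaction weights

Within one cell-type sample, the model's genes are ranked by expression
(most expressed gene = rank N); the score divides the rank by `0.3·N`,
so the 30th-percentile gene scores exactly 1 and the bottom 30% score
below 1.  Ties break lexicographically by gene id so that fixture data
with repeated values stay deterministic.  Scores flow through GPR rules
with max over OR (best isoenzyme) and min over AND (weakest complex
subunit), and the aggregate minus 1 becomes the reaction's inclusion
weight: sub-pivot genes actively discourage inclusion.  This score→
weight mapping is this package's design choice; it is what makes the
"0.3 = bottom 30%" calibration operative in the MILP.  Reactions
without gene association get weight 0, and the extraction objective
carries a 1e-6 per-inclusion penalty so that among weight-equal optima
the smallest network wins deterministically (too small to override any
real weight).

## Extraction MILP

Binary `y_r` per reaction, maximising `Σ w_r y_r` subject to a single
certifying flux vector: reversible fluxes are split into nonnegative
forward/backward parts, every included reaction must carry activity of
at least ε = 1e-4 (`p + q ≥ ε·y`), excluded reactions none
(`p, q ≤ M·y`, big-M = 1000), and each required metabolite (those
detected in the metabolome and mapped into the model) receives a
production slack of at least ε in the mass balance.  This is a
deliberately simplified, single-flux-vector variant of task-driven
subnetwork selection: faithful reproduction of the published
genome-scale formulations is out of scope, but the contract — omics
consistency maximisation under required production and task constraints
— is the same, and on small instances the selected set is certified
against exhaustive subset enumeration in the test suite.

Metabolic tasks ("produce X at ≥ r given only inputs Y"; negative
controls marked *should fail*) are enforced by iterative cut
generation rather than one monolithic MILP: solve, check the tasks on
the extracted model, then (a) for a failing must-pass task require one
of the currently excluded *task-relevant* reactions — those able to
carry flux in that task's environment on the full model; restricting
the cut this way is valid because task feasibility is monotone in the
reaction set, and it is what makes convergence fast — or (b) for a
passing should-fail task forbid the full set of reactions active in its
certificate.  Task checking itself closes every exchange (and the
biomass drain), opens temporary supply reactions for the allowed
inputs, and maximises a temporary demand for each required output.

Branch-and-bound details that matter for correctness: incumbents whose
relaxed binaries merely round to integers are re-verified with the
binaries fixed — under big-M couplings a `y` parked at 1e-7 passes any
reasonable integrality tolerance while still leaking real flux — and
branching is depth-first on the most fractional variable with a fixed
order, so results are bit-reproducible.

## Gap-filling and flux response

Gap-filling minimises the number of universal-model reactions added so
the biomass flux reaches `min_growth` (default 1e-3 flux units — the
contract is "demonstrates growth", so any strictly positive floor
works; the value only needs to exceed the zero-flux tolerance).
Minimal cardinality is certified against brute force on small fixtures.

The flux-response scan uses 11 evenly spaced fractions from 0.90 to
1.00 of the biomass optimum (the range is the method's; the step is a
package default, and doubling it moves no correlation by more than
1e-6 on linear-response fixtures).  The default constraint mode pins
the biomass flux to `f·μmax` exactly ("fixed"), reading "forced to" as
pinning; a `lower_bound` mode is retained for sensitivity analysis.
The per-step summary is the FVA midpoint `(min+max)/2` — the only
computable "mean flux" given min/max data — and the association
statistic is the Pearson correlation of that series with the enforced
biomass series.  A constant series carries no evidence of coupling and
receives the sentinel `r = 0` rather than `NA`.  Selection is strict
and signed (`r > 0.7`): anti-correlated competing pathways are not
growth-associated.

## TF ranking

Growth-associated genes are the union of GPR leaves over the selected
reactions.  Each TF's statistic is the *distinct* overlap count between
its target set and that gene set — duplicate edges can never change a
count — with zero-overlap TFs omitted and ties ordered
lexicographically.  No enrichment p-value is computed: the replicated
procedure ranks by raw target counts, and a hypergeometric column would
change the method.  Gene identifiers must share a namespace between the
model's GPRs and the network file; a synonym table is accepted for
metabolites, but no automatic gene-identifier conversion is attempted.

# The synthetic study

`syntheticSpec()` pins the emulated study conditions: duplicate samples
per cell type, planted 2-fold expression effects under multiplicative
lognormal noise (sdlog 0.1), a linear biomass pathway of 6 reactions
(the growth-coupled ground truth), 4 decoy reactions that are
flux-feasible but capped independently of biomass (own substrate, own
sink, rate ≤ 5), a gene pool of 240 with 20 planted up / 10 planted
down (the generator plants both directions; the coupled-pathway
genes are a subset of the planted-up set), a metabolome with planted
fold changes plus one dropout of every detection category, and a
regulatory network whose master TF targets exactly the coupled genes
while 7 decoy TFs target only decoy genes.  Everything is a pure
function of the seed, and generators restore the caller's RNG state.

What the bundle does *not* emulate: genome-scale network size,
correlated gene noise, probe-level artefacts, batch effects,
compartmentalisation beyond a minimal scheme, or identifier mapping
noise.  Passing the recovery tests therefore shows the pipeline's
logic is sound end to end, not that it is robust to real microarray
or CE-TOFMS pathology.

Under these fixed conditions the planted coupled pathway is recovered
exactly by the flux-response scan (and no decoy is ever selected), and
the master TF ranks first, in 20/20 seeded bundles.  Mean differential-
expression recovery of planted genes sits near 89% with zero false
calls among the null genes — consistent with the noncentral-t power of
a two-sample test at n = 2 per group, 2-fold effect and ~10%
multiplicative noise, which is the binding constraint of the emulated
duplicate-array design.  These numbers are recomputed, not quoted, by
`scripts/acceptance.R` and the test suite.

# Pipeline and reproducibility

`runPipeline()` is driven by a YAML configuration (an established
structured-text format with a maintained parser was preferred over a
bespoke INI dialect) holding the paths, the thresholds (p 0.05,
fc 1.5, rank fraction 0.3, r 0.7), the fraction grid, the scan mode and
the extraction ε/big-M.  Unknown keys and missing files abort before
any computation.  Extraction runs once per replicate sample of the
target group (the duplicate-array reading of the study design; pooled
ranking is available by calling `rankGeneScores()` on group means),
the growth-associated sets are unioned across replicates, and every
stage writes its table to the output directory, so a rerun with
`resume = TRUE` loads finished stages and identical inputs yield
byte-identical outputs.  `inst/scripts/gemflux` exposes the stages as
shell subcommands over exactly these functions.

# Known limitations

* Dense simplex and exhaustive-style branch-and-bound limit problem
  size; the package validates the method, it is not tuned for
  genome-scale reconstructions.
* The extraction MILP certifies activity through one flux vector; it
  does not reproduce the published multi-condition formulations and is
  not intended to.
* Task environments close all boundary reactions; tasks whose biology
  requires partial medium access must encode it in their input list.
* SBML support covers the constraint-based subset (species, reactions,
  flux-bound parameters, gene-product associations, one maximisation
  objective); kinetic laws, annotations and other SBML packages are not
  preserved.
* With duplicate samples the t-test has limited power (see above);
  recovery rates below ~90% under the default noise model reflect the
  emulated design, not an implementation artefact.
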