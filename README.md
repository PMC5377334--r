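# gemflux

Constraint-based analysis of cell-type-specific metabolism, built for
studies that compare a stem-like and a non-stem-like cell population
(e.g. CD133-positive vs CD133-negative hepatoma cells) using
transcriptome and metabolome data together with a genome-scale
metabolic model (GEM).  It is aimed at systems-biology practitioners
who want the full chain — from omics tables to a ranked list of
candidate master regulators of proliferation — as tested, reproducible
R functions rather than a one-off analysis script.

## What it computes

Given a universal model with stoichiometry `S`, flux bounds
`lb ≤ v ≤ ub` and gene–protein–reaction (GPR) rules:

* **FBA / FVA** — flux balance analysis `max c'v  s.t.  S v = 0,
  lb ≤ v ≤ ub` and per-reaction flux variability
  `[min v_i, max v_i]` under an objective constraint, on a built-in
  dense simplex (no external solver required).
* **Differential expression** — per gene, an equal-variance two-sample
  Student's t-test plus a strict linear fold-change gate:
  call *up* iff `p < 0.05` and `FC > 1.5` (symmetric for *down*).
* **Gene scores** — rank genes by expression within a sample; the score
  is `rank / (0.3·N)`, so the 30th-percentile gene scores exactly 1.
  GPR aggregation (max over OR, min over AND) minus 1 gives each
  reaction an inclusion weight.
* **Context-specific extraction** — a MILP selecting the reaction set
  that maximises `Σ w_r y_r` while a certifying flux vector keeps every
  included reaction active (`|v_r| ≥ ε`), produces every metabolite
  detected in the metabolome, and satisfies a list of metabolic tasks.
* **Gap-filling** — a minimum-cardinality set of universal reactions
  restoring growth on the configured medium.
* **Flux response analysis** — pin the biomass flux at fractions
  0.90…1.00 of its optimum, record each reaction's FVA midpoint per
  step, and call a reaction growth-associated when the Pearson
  correlation of its midpoint series with the biomass series exceeds
  0.7 (strict, signed).
* **TF ranking** — map growth-associated reactions to genes through the
  GPRs and rank transcription factors from a RegNetwork-style edge
  table by the number of distinct growth-associated targets.
* **Synthetic data** — a seeded generator producing a coherent bundle
  (toy model + medium + tasks, duplicate-sample expression with planted
  fold changes, metabolome with detection dropouts, regulatory network
  with a planted master regulator) so the whole pipeline is testable
  end to end with known ground truth.

## Worked example

```r
library(gemflux)

bundle <- generateBundle(syntheticSpec(seed = 42))
dir <- file.path(tempdir(), "bundle42")
writeBundle(bundle, dir)                      # model, TSVs, config.yaml

report <- runPipeline(file.path(dir, "config.yaml"),
                      file.path(dir, "results"), quiet = TRUE)

table(report$de$call)
#> down   ns   up
#>    7  215   18

report$growthReactions
#> [1] "BIOMASS" "R_C1" "R_C2" "R_C3" "R_C4" "R_C5" "R_C6"

head(report$tfRanking, 3)
#>   rank        TF count                             overlap
#> 1    1 TF_master     6 g0049,g0065,g0074,g0153,g0228,g0229
```

Reading the output: the differential-expression rule calls 18 of the
20 planted up-regulated genes and 7 of the 10 planted down-regulated
genes (the rest fall to the limited power of a duplicate-sample
t-test), with no false calls among the 210 null genes.  The
flux-response scan selects exactly the planted growth-coupled pathway
(`R_C1`–`R_C6` plus the biomass reaction) and none of the decoy
reactions — the decoys' flux ranges do not move as biomass is forced
up, so their correlation takes the sentinel value 0:

```r
scan <- fluxResponseScan(applyMedium(bundle$model, bundle$medium))
round(scan@r[c("R_C1", "BIOMASS", "R_D1", "EX_M0")], 3)
#>    R_C1 BIOMASS    R_D1   EX_M0
#>       1       1       0      -1
```

Finally the planted master regulator — the only TF whose targets are
the coupled-pathway genes — ranks first with 6 growth-associated
targets, while the decoy TFs (targets among decoy genes only) have no
overlap and are excluded from the ranking.

A thin shell interface over the same functions ships in
`inst/scripts/gemflux` (`simulate`, `run`, `de`, …).

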