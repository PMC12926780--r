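# rasflux

Transcriptomics-constrained metabolic flux analysis, sampling and
enrichment maps for R.

Constraint-based models describe a metabolism as a stoichiometric matrix
*S* with flux bounds per reaction; any feasible flux state *v* satisfies
the steady-state condition *S·v = 0* within those bounds. `rasflux` is for
researchers who want to ask how that feasible space *differs between
biological conditions* — tumor vs. normal tissue, treatment vs. control —
using ordinary bulk or single-cell expression matrices, without leaving R.

The workflow, end to end:

1. **Model I/O** — read SBML (Level 3 + fbc), COBRA-style JSON, YAML or a
   flat tabular schema (optionally gz/bz2/zip-compressed); flatten models
   to one-row-per-reaction tables and write them back out.
2. **Reaction Activity Scores (RAS)** — evaluate each reaction's
   gene-protein-reaction (GPR) boolean rule on each sample's expression:
   `OR` becomes a **sum** (isoenzymes add capacity), `AND` a **minimum**
   (complex subunits co-limit). Genes missing from the data drop out of
   sums and minima; a rule with no measured gene is scored missing.
3. **Bounds** — normalize each reaction's RAS by its maximum across
   samples, then shrink that reaction's flux bounds by the normalized
   score, per sample; a medium table (metabolite, maximal uptake) clamps
   exchange-reaction lower bounds first.
4. **Flux analysis and sampling** — FBA, parsimonious FBA, flux
   variability analysis and single-reaction deletions on a built-in
   bounded-variable simplex; corner-based sampling (random-objective
   vertices) and artificial-centering hit-and-run sampling of the flux
   polytope, with batching and summary statistics.
5. **Enrichment** — per-reaction two-sample tests (Kolmogorov–Smirnov by
   default) between groups, the bounded fold change

   *fc = (avg₁ − avg₂) / (|avg₁| + |avg₂|)* ∈ [−1, 1],

   a Welch z-score, and significance gating at p ≤ 0.05 **and** at least a
   20% mean difference (fold-change threshold 1.2), with `1v1`, `1vAll`
   and `1vControl` comparison modes.
6. **Maps** — paint the results onto an SVG metabolic map: orange/sky-blue
   arrows for up/down regulation, red/blue for reversible reactions whose
   direction flips between groups, arrow width proportional to |fc| (or to
   flux magnitude in per-group mean/median maps).

## Worked example

Two parallel routes from A to B, each gated by a GPR, scored on a
two-sample expression matrix:

```r
library(rasflux)

tm <- make_toy_model(2L, c(1L, 1L), 10, path_ub = 10,
                     gpr_assignment = list(P1_1 = "g1 and g2",
                                           P2_1 = "g3 or g4"))
model <- tm$model
model
#> metabolic_model: 2 metabolites, 4 reactions (2 exchange), 4 genes in GPRs
#> objective: EX_B

expr <- matrix(c(8, 6, 2, 1,
                 2, 9, 4, 3), nrow = 4,
               dimnames = list(c("g1", "g2", "g3", "g4"),
                               c("tumor", "normal")))
ras <- expression_to_ras(model, expr)
ras
#>      tumor normal
#> EX_A    NA     NA
#> P1_1     6      2
#> P2_1     3      7
#> EX_B    NA     NA
```

`P1_1` scores `min(8, 6) = 6` in the tumor sample (`AND` = minimum) and
`P2_1` scores `2 + 1 = 3` (`OR` = sum); exchanges have no GPR, so they
stay missing and keep their bounds. Normalizing per reaction across
samples and scaling bounds (medium applied first):

```r
nr <- normalize_ras(ras)
round(nr, 3)
#>      tumor normal
#> P1_1 1.000  0.333
#> P2_1 0.429  1.000
bounds <- build_sample_models(model, nr, medium = c("A[e]" = 10))
bounds$tumor
#>   reaction_id lower_bound upper_bound
#> 1        EX_A         -10 1000.000000
#> 2        P1_1           0   10.000000
#> 3        P2_1           0    4.285714
#> 4        EX_B           0 1000.000000

fl <- t(vapply(names(bounds), function(s) pfba(model, bounds[[s]])$fluxes,
               numeric(4)))
round(fl, 3)
#>        EX_A   P1_1  P2_1 EX_B
#> tumor   -10 10.000 0.000   10
#> normal  -10  3.333 6.667   10
```

The tumor sample routes all flux through the highly expressed `P1_1`;
the normal sample, capped at `10 × 0.333` on that route, spills the rest
through `P2_1`. With sampled or per-sample flux matrices,
`compare_groups()` produces the per-reaction comparison table
(`reaction_id, p_value, fold_change, z_score, avg1, avg2, style_class`)
and `style_comparison_map()` renders it onto an SVG map.

A command-line interface with subcommands (`importmodel`, `ras`,
`ras2bounds`, `fluxsim`, `fluxsample`, `fluxenrich`, `fluxmap`,
`fixtures`) is installed under `exec/rasflux`.

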