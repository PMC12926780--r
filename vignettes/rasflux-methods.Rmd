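---
title: "rasflux: methods, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rasflux: methods, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rasflux)
```

This vignette is the package's own account of what it computes and why
each default is what it is. It states no empirical result that the test
suite and `scripts/acceptance.R` do not themselves compute.

## The model

A metabolic network is a stoichiometric matrix $S$ (metabolites ×
reactions) with per-reaction flux bounds $l \le v \le u$ in mmol·gDW⁻¹·h⁻¹.
Feasible flux states satisfy the steady-state condition $S v = 0$: no
internal metabolite accumulates or is depleted. Exchange reactions —
detected purely structurally as reactions touching exactly one metabolite
— connect the network to the environment; negative exchange flux is
uptake, positive is secretion (the dominant sign convention in the
field, adopted here).

Two assumptions frame everything downstream: (i) the cell is at a
metabolic steady state over the measurement window, and (ii) enzyme
expression constrains the *capacity* of a reaction, not its realized
flux — which is why expression enters through the bounds rather than
through the objective.

## Reaction Activity Scores

A GPR rule is a boolean expression over genes. We score it on a sample's
expression vector with `or` → sum (isoenzymes provide redundant,
additive capacity) and `and` → minimum (complex subunits are
co-limiting). `and` binds tighter than `or`; operators are
case-insensitive; parentheses override precedence.

Policies where the scoring rule alone does not decide:

* **Missing genes** are dropped from sums and minima; a node whose
  operands are all missing is itself missing, and a reaction whose score
  is missing later keeps its original bounds. This is the
  least-destructive reading: partial data stay usable, and reactions we
  know nothing about are left unconstrained rather than silently closed.
  The alternative (score 0, closing the reaction) would frequently make
  whole cohorts infeasible on sparse single-cell data.
* **Gene matching** is exact string equality after trimming whitespace.
  Symbol/Ensembl conversion is a data-preparation concern with its own
  failure modes and belongs upstream of this package.
* **Duplicate gene rows** in the expression table are an error, not an
  average: silent averaging would corrupt scores invisibly.
* **Repeated occurrences** of a gene inside one rule are evaluated
  independently, mirroring the literal boolean expression.

## From scores to bounds

Each reaction's scores are divided by that reaction's **own maximum
across samples**, giving values in $[0,1]$ with the most active sample at
1. The maximum is per reaction, not global: a single global maximum would
make scores incomparable across reactions whose absolute expression
differs by orders of magnitude. A reaction whose maximum is 0 carries no
signal; by default its row becomes missing (bounds untouched) rather
than 0, with `zero_ras_closes = TRUE` restoring the harsher reading.

Both bounds are then multiplied by the normalized score, preserving
reversibility direction and never widening a bound. Exchange reactions
are exempt by default even when they carry a GPR: the medium, not enzyme
expression, governs uptake, and scaling both would constrain the same
flux twice (`scale_exchanges = TRUE` overrides).

A medium table sets each listed metabolite's exchange lower bound to
minus its maximal uptake rate and closes (lower bound 0) uptake of every
unlisted metabolite; secretion is untouched. The medium is applied
**before** RAS scaling in `build_sample_models()`; the two operations
commute whenever the GPR-bearing and exchange reaction sets are disjoint
(asserted on fixtures), so the ordering only matters under
`scale_exchanges = TRUE`, where medium-first means the medium defines
the envelope that expression then shrinks.

## The linear-programming core

FBA maximizes the objective $c^\top v$ over the polytope; pFBA then
minimizes total absolute flux $\sum_i |v_i|$ subject to retaining a
fraction (default 1) of that optimum, with each flux split into
non-negative forward and reverse parts so the objective is linear; FVA
minimizes and maximizes each flux under the same optimum floor (at
fraction 0 the floor is omitted entirely and the ranges describe the raw
polytope); single-reaction deletion re-solves with one reaction clamped
to $(0,0)$.

The solver is a two-phase primal simplex on bounded variables written
for this package (no LP backend is assumed), with Dantzig pricing, a
switch to Bland's rule after a streak of degenerate pivots (so cycling
is impossible), and artificial variables that tolerate redundant
stoichiometric rows. Numerical contract: pivot tolerance $10^{-9}$
internally; the public invariants — steady-state residual
$\lVert S v\rVert_\infty$ and bound violations — are asserted at
$10^{-6}$. The optimum floor is applied as
$c^\top v \ge f \cdot z^* - 10^{-6}\max(1, |z^*|)$ to absorb round-off,
which is why reported pFBA objectives can sit $\sim 10^{-5}$ below the
FBA optimum. Because the solver returns basic solutions, alternative
FBA optima are resolved arbitrarily; tests and users should rely on
objective values, or on pFBA when a reproducible representative
distribution matters. The test suite validates the solver against an
independent brute-force vertex-enumeration oracle on every fixture with
at most 10 reactions (and the pFBA split-polytope enumeration on
5-reaction fixtures, where exhaustive enumeration of the doubled
variable space is still tractable).

## Sampling

**Corner-based sampling** draws a random objective per sample —
coefficients i.i.d. uniform on $[-1,1]$, the natural uninformative
choice over directions, exposed as a parameter — and records the optimal
vertex. Every point therefore carries a vertex certificate: at least
$n - \operatorname{rank}(S)$ bounds are active. The method characterizes
the corners of the feasible space, not its volume.

**Hit-and-run** is a single-chain artificial-centering walk: warmup
points are the FVA extreme solutions (one optimal vertex per reaction
per direction, no objective floor), chord directions are a stored point
minus the running center, and the step is uniform on the feasible
segment. Every `thinning`-th iterate (default 100) is kept. Two
numerical choices matter: directions are projected onto an orthonormal
null-space basis of $S$ each step, so rounding can never walk the chain
off the steady-state hyperplane (without the projection, near-zero
direction vectors amplify float noise after normalization); and
direction candidates with norm below $10^{-8}$ are rejected as
degenerate. The published parallel-chain sampler this stands in for is
not reproduced chain-for-chain; a single self-tuning chain with FVA
warmup is an honest, simpler member of the same family and is named
neutrally (`sample_hit_and_run`).

Bounded feasibility is a precondition: infinite bounds are a hard error
telling the user to close open exchanges, never silently clipped —
sampling an unbounded polytope is ill-defined. Batches use seed
`base + i` (0-based), so one batch reproduces the direct call and
batches are independent streams; sizes differ by at most one.

## Group comparison

For each reaction the two groups' flux values are compared with a
two-sided two-sample test — Kolmogorov–Smirnov by default (exact
small-sample null when sizes permit and ties are absent),
Mann–Whitney and Welch's t available. The reported effect size is the
bounded fold change $(avg_1 - avg_2)/(|avg_1| + |avg_2|) \in [-1,1]$,
antisymmetric, 0 by convention when both means are 0, and ±1 exactly
when the means have equal magnitude and opposite signs. The z-score
column is the Welch standardized mean difference
$(\bar v_1 - \bar v_2)/\sqrt{s_1^2/n_1 + s_2^2/n_2}$ — the named
statistic is not given a formula in the literature this implements, so
the package defines it explicitly and documents it as its own choice.

Significance requires **both** gates: p ≤ 0.05 and the fold-change
criterion. The user-facing threshold 1.2 means "at least a 20%
difference between the group means", which we implement as the ratio
criterion $|avg_1 - avg_2| \ge (t-1)\min(|avg_1|,|avg_2|)$ — equivalent
to $\max/\min \ge t$ for same-sign means. The bounded statistic is what
is *reported*; the ratio is what *gates*, because a threshold of 1.2
applied literally to a statistic bounded in $[-1,1]$ would mark nothing
significant. `fc_on_eq1 = TRUE` instead applies
$|fc| \ge (t-1)/(t+1)$ to the bounded statistic directly. Sign-discordant
mean pairs that pass the p-gate are always classified as a direction
flip (`sign_flip_up`/`sign_flip_down`): a reversible reaction running
backwards in one condition is qualitatively significant whatever the
ratio. Reactions with zero variance in both groups are never flagged.

No multiple-testing correction is applied by default — the raw 0.05
threshold is the convention this workflow follows — with
`correction = "bh"` available. `1vAll` pools all other groups' samples
into group 2 (rather than averaging pairwise comparisons), which keeps
the test a plain two-sample problem.

## Maps

Comparison maps color each matched arrow by style class (defaults:
orange `#FFA500` up, sky blue `#87CEEB` down, red/blue for flips, grey
`#BEBEBE` otherwise — named colors pinned to hex values as a package
choice) and set stroke width `width_min + (width_max − width_min)·|fc|`
with defaults 2–12 SVG units; linear is the simplest monotone map.
Magnitude maps rescale width by $|statistic|/\max$, so doubling every
flux changes nothing. Arrows are located by element id through the
template `R_{reaction_id}` (the common convention of community-exported
maps), configurable because hand-drawn maps vary. Flux *direction* is
not encoded in magnitude maps: maps rarely provide paired direction
elements, so sign information is left to the comparison maps. Styling
is idempotent and touches nothing outside the matched elements and the
package's own legend group.

## Synthetic data: what it does and does not emulate

The generators produce chain/parallel-route toy models (3–20 reactions)
with matching SVG maps, and expression matrices with multiplicative
lognormal noise (CV default 0.2 — non-negative and right-skewed like
real expression data; the value is a package choice and configurable)
around a baseline, with planted per-(group, gene) fold effects. Ground
truth for which reaction scores shift, and in which direction, is
derived **symbolically** by evaluating each GPR at the noise-free group
means — valid because the scoring rule is monotone in every gene — so
the oracle is independent of the code under test.

The two-group fixture uses two *disjoint* chains so that a planted 3×
effect on one chain's genes shifts exactly that chain's fluxes (the
gene-capped reaction binds; its exchanges carry the same flux, the
uptake becoming more negative, hence "down" on the signed scale) while
the other chain stays exchangeable between groups. The null fixture
uses six disjoint gene-gated chains with 20 samples per group: each
chain contributes one independent null statistic, and 50 seeded runs ×
6 chains give the type-I fraction a standard error small enough for the
nominal band to be a meaningful check (with discrete exact-KS p-values
at $n = 20$, the effective level at the 0.05 gate is ≈ 0.034).

What these fixtures deliberately do **not** emulate: genome-scale
network structure (loops, cofactor coupling, compartments), count noise
and dropout of real single-cell data, correlated genes within rules,
and batch effects. Passing tests therefore demonstrate that the
machinery is correct and the statistics calibrated under the stated
noise model — not that biological signal of a given size is recoverable
from any particular real dataset.

## Problem sizes and degenerate inputs

The checked configurations (chosen as the package's own test design):
vertex-oracle battery on ≤ 10-reaction networks; sampler validity on
300–500 points; hit-and-run convergence on a 1-D uniform fixture with
2000 kept points (3-standard-error band around the interval midpoint);
planted-effect recovery with 25 samples per group; null calibration
over 50 seeded runs. Degenerate inputs have defined behavior
throughout: empty medium closes all uptakes; identical constant samples
give p = 1; both-zero means give fold change 0; a both-groups-constant
reaction is never significant; all-zero magnitude summaries render at
minimum width; infeasible/unbounded LPs return a status, never throw.

## Known limitations

MATLAB `.mat` models are rejected (binary format, no R reader in the
dependency set) — convert to SBML or JSON first. SBML support covers
the Level 3 + fbc subset described above plus legacy GENE_ASSOCIATION
notes (fbc wins when both are present), not full SBML validation,
groups, or annotations beyond a SUBSYSTEM note. Gene-level deletions,
loopless FVA, thermodynamic constraints, pathway-level aggregation
statistics and paired tests are out of scope. The simplex is tuned for
the tool's intended toy-to-medium scale, not for genome-scale
performance engineering.
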