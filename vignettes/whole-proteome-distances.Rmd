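---
title: "Whole-proteome distances from average sequence similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-proteome distances from average sequence similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prophy)
```

## The statistic

prophy reconstructs phylogenies from whole proteomes without choosing
genes, building multiple alignments, or calling orthologs. The unit of
information is the E-value of a directed best hit: every ORF `x` of
organism X is searched against all ORFs of organism Y by local alignment,
and the E-value `E` of its single best match is recorded — including
best matches with no detectable homology, which enter at the reporting
ceiling. The same query searched against its own proteome returns its
identical copy, whose E-value `E_best` is the best value that query could
ever achieve.

The per-gene similarity ratio is

    T = log10(E) / log10(E_best),

which is 1 when the best match is the query itself (E = E_best) and falls
towards 0 as the best match decays into the noise (E near the ceiling,
log10 E near 0). Because E-values are probabilities of chance occurrence,
log-transforming them yields additive information scores, and the ratio T
measures how much of the query's self-information survives in the target
genome — the same logic by which log-odds substitution matrices turn
residue substitution probabilities into additive alignment scores. The
ratio deliberately includes non-orthologous and undetectable pairs: a
genome is *not* just its conserved core, and the fraction of queries whose
information has vanished is itself signal.

A directed proteome-level average is estimated by plotting
`(log10 E_best, log10 E)` for all queries of X and fitting a straight
line **through the origin** by least squares; the slope (closed form
`sum(xy) / sum(x^2)`, clamped into [0, 1]) is the directed average
`T_xy`. The line must pass through the origin because a query with no
self-information (`log10 E_best = 0`) can retain none. A 14-bin profile
of mean `log10 E` across the `log10 E_best` range is attached to every
fit as a linearity diagnostic; it never influences the slope. Fits with
the two directions exchanged generally differ (`T_xy != T_yx` — proteome
sizes differ), and the symmetric distance is their average:

    D = 1 - (T_xy + T_yx) / 2,

zero for identical proteomes, approaching 1 when homology is
undetectable in both directions. Distance matrices over many organisms
feed neighbor joining or BioNJ.

```{r tslope-demo}
X <- synth_root_proteome(40, 200, seed = 1, organism_id = "X")
Y <- mutate_proteome(X, 0.35, seed = 2)
Y$organism_id <- "Y"
fit <- fit_T_slope(directed_best_hits(X, Y))
fit
head(fit$bin_profile, 4)
```

## The search engine and its E-values

The package delegates nothing: an internal Smith–Waterman engine with
affine gaps (a length-k gap costs `gap_open + k * gap_extend`; defaults
11/1 with BLOSUM62) computes raw scores, striped SSE2 where the CPU
supports it and plain dynamic programming otherwise; both paths are
verified against an independent brute-force DP oracle in the test suite.
Raw scores become E-values through the Karlin–Altschul formula
`E = K * m * n * exp(-lambda * S)` with the conventional gapped
BLOSUM62/11/1 constants `lambda = 0.267`, `K = 0.041`, raw (uncorrected)
lengths, and `n` equal to the total residue count of the target
proteome. Users with precomputed search results can instead supply the
standard 12-column tabular layout via `parse_tabular_hits()`; both routes
produce the same best-hit table structure.

Numerical choices, all visible in `search_params()`:

* **E-value clamps.** E is clamped into `[1e-180, 10]`. The floor keeps
  `log10 E` finite when searches report 0; the ceiling is the
  conventional reporting cutoff. Queries whose best pre-clamp E exceeds
  the ceiling are *no-hit* rows: they keep an absent target and enter the
  slope fit at `(log10 E_best, 0)`, i.e. as evidence of total decay.
  The floor has a scientific side effect worth knowing: for very similar
  proteomes, long genes reach the floor in both `E` and `E_best`, so
  their per-gene T saturates at 1 slightly early. This compresses
  distances near 0 and is one reason a saturation correction exists at
  the other end of the scale.
* **Eligibility.** Queries with `E_best >= 1` carry no usable
  self-information (log10 E_best >= 0) and are excluded from fits; only
  pathologically short ORFs trigger this in practice.
* **Tie-breaking.** Best hits are chosen by smallest E, then largest raw
  score, then lexicographically smallest target ID, making every search
  deterministic.
* **Ambiguity codes.** B, Z, X, J, U, O are accepted on input and scored
  at the substitution matrix's mismatch floor (-4 for BLOSUM62) against
  everything; `*` stop characters are stripped with a warning. No
  low-complexity filtering is applied — the knob exists in real search
  tools, and leaving it off is a documented choice, not an oversight.

In `reciprocal` mode only best hits confirmed by the reverse search
(Y's best hit of X's best hit is the original query) enter the fits,
reproducing the classical reciprocal-best-hit restriction; the point set
is provably a subset of the directional one. Directional mode is the
default and the method's point: comparisons on simulated clades show the
directional statistic recovers topology at least as well while using all
genes.

## Tree building

`neighbor_joining()` and `bionj()` implement the standard agglomerations
in-package (BioNJ adds Gascuel's variance-weighted reduction with the
lambda weight that minimizes the variance of the reduced matrix), with
two determinism rules: exact ties in the join criterion go to the
smallest row-index pair, and negative branch estimates are clamped to
zero with the deficit absorbed into the sibling edge so path lengths are
preserved. Both recover any additive matrix exactly; the installed `ape`
implementations serve as independent cross-checks in the tests, never as
the implementation. Robinson–Foulds comparison (`rf_distance()`) wraps
`phangorn::RF.dist` after verifying leaf sets.

## The in-silico evolution model

The simulator exists to validate the distance, so its mutation model is
deliberately the simplest thing whose expectations are computable in
closed form:

* `synth_root_proteome()` draws i.i.d. sequences from Robinson–Robinson
  background frequencies with log-normal lengths (default mean 300,
  `sdlog` 0.35, floor 40) — the scale of a small bacterial proteome.
* `mutate_proteome()` redraws exactly `round(fraction * total_residues)`
  positions per round, selected uniformly across the whole proteome (no
  per-gene quota), each replaced uniformly over the 20 standard residues.
  Self-replacement is allowed, so one round changes `fraction * 19/20`
  of positions in expectation, and g rounds leave a site unchanged with
  probability `(1 - fraction * 19/20)^g` ignoring back-mutation. Twelve
  rounds at 10% therefore replace `1 - 0.905^12 = 69.8%` ≈ 70% of
  positions. The alternative 19-residue draw (every selected site
  changes) is exposed as `exclude_self = TRUE`.
* `evolve_lineages()` doubles the population each generation (default
  20% mutation per generation), returning all `2^g` leaves and the true
  balanced genealogy; leaf IDs encode the lineage path so
  `mrca_generation()` is exact. `inject_lgt()` copies a random fraction
  of donor genes over the recipient's genes at the same index positions
  (genome size conserved; an additive append mode also exists, matching
  experiments where foreign genes are added rather than swapped).

What the simulator does *not* model — and therefore what green tests do
not certify about real data: insertions/deletions, gene gain/loss and
paralogy, composition bias and rate heterogeneity across sites or
lineages, and any selection. It isolates exactly one question: does the
average-similarity statistic recover a known genealogy generated by
uniform substitution?

## Validation experiments and the saturation correction

Three desk-scale experiments (runtimes on one CPU, sizes chosen so the
full suite stays in minutes):

1. **Topology recovery.** 16-leaf clades (4 generations, 20% mutation,
   100 proteins x 300 aa) are reconstructed perfectly (RF = 0 to the true
   tree) across seeds, rerunning the headline validation at reduced
   scale; `recipe_insilico_validation()` automates it.
2. **D against divergence depth.** In 5-generation clades, pairs whose
   most recent common ancestor is at generation 3 or later stay below
   D ≈ 0.85–0.88 while generation-2 pairs sit above 0.97, reproducing
   the working rule that D < 0.85 marks the reliable regime.
3. **LGT robustness.** `recipe_lgt_robustness()` transfers 10–50% of
   genes between two descendants (default: opposite halves of the root
   split) and rebuilds the tree. At the full 32-leaf clade scale the
   topology survives 40% transfer and breaks at 50%; at the reduced
   8-leaf scale used in the automated suite the boundary shifts one grid
   step down (survives 30%, breaks at 40%) because each leaf has fewer
   correctly-placed neighbors anchoring it — the smaller the clade, the
   cheaper it is for one corrupted leaf to be pulled across the root.
   An idealized mixture model of the directed averages predicts exactly
   this shift, so the suite documents the 8-leaf boundary rather than
   borrowing the full-scale one.

Because uniform substitution saturates (a site re-mutated g times
retains only a 1/20 chance of matching), D compresses at large
divergence. `build_saturation_curve()` calibrates this empirically:
mutate a reference proteome cumulatively at 10% per round, record
D(reference, mutant-at-g) averaged over replicate chains, force
monotonicity by isotonic regression, and invert piecewise-linearly.
`correct_distance()` maps D to C in units of 10%-mutation rounds; C < 12
(~70% replacement) marks the approximately linear regime, and anything
beyond D = 0.85 or the curve grid is flagged unreliable rather than
extrapolated. The unit interpretation ties back to the closed form
above: C = 12 corresponds to `1 - 0.905^12` ≈ 70% replacement.

```{r curve-demo}
ref <- synth_root_proteome(40, 150, seed = 5, organism_id = "ref")
curve <- build_saturation_curve(ref, max_generations = 13, replicates = 2,
                                seed = 6)
round(correct_distance(curve$mean_D_iso[c(3, 7, 13)], curve), 2)
```

## Design notes and limitations

* **Desk-scale only by default.** All-vs-all local alignment is
  quadratic in proteome count and size; the compiled engine covers
  simulation-scale studies (tens of organisms x hundreds of proteins) in
  minutes. Real multi-megabase proteome sets should be searched with a
  production tool and imported via `parse_tabular_hits()` — the module
  boundary exists precisely so the statistic is independent of the
  search backend.
* **Fixed E-value statistics.** lambda and K are constants, not fitted
  per matrix, and lengths are raw. This keeps the statistic deterministic
  and documented; absolute E-values differ from production search tools
  (which apply effective-length corrections), but T is a *ratio* of log
  E-values of the same query, which cancels most of the discrepancy.
* **E_best from self-alignment.** In a full self-search the best match
  of a query is its identical copy, so E_best is computed from the
  self-alignment score directly, at linear rather than quadratic cost;
  `directed_best_hits(X, X)` verifies the equivalence in the tests. A
  guard enforces `E_best <= E` per row after clamping, which can only
  act under pathological database-size mismatches.
* **Multiple queries may share one target.** The statistic deliberately
  allows many-to-one best hits; whether that is ideal for distance
  estimation is an open question of the method itself, inherited here.
* **Saturation inverse is empirical.** No functional form is assumed for
  the curve; a flat stretch after isotonic pooling maps through
  `approx(ties = mean)`. C is only as good as the reference proteome
  used to train the curve resembles the organisms being corrected.
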