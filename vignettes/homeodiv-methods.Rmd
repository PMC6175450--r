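---
title: "Methods: ensemble-SOM divergence classification of homologue families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble-SOM divergence classification of homologue families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homeodiv)
```

## The model and its assumptions

The package asks, for each family of duplicated genes in an allopolyploid,
whether the copies are co-regulated across a developmental time course. The
unit of analysis is one gene's FPKM trace in one tissue together with a
per-timepoint uncertainty (as produced by transcript quantifiers such as
Cufflinks). Three assumptions shape the method:

1. **Shape, not level.** Regulatory similarity is judged on z-normalized
   traces (mean 0, unit variance across timepoints), so two copies expressed
   at very different absolute levels but with the same dynamics count as
   co-regulated. Level differences are handled separately by the two-fold
   expression-bias tables.
2. **Measurement uncertainty matters.** Whether two traces are "the same" is
   decided by resampling each trace under its stated uncertainty and asking
   how often the draws land on the same prototype (SOM node), not by a fixed
   distance cutoff.
3. **Map ambiguity is informative.** A single self-organizing map imposes one
   arbitrary quantization of trace space; training an ensemble of maps and
   averaging the co-mapping probability turns "how robustly do these two
   genes co-cluster across reasonable quantizations" into the similarity
   statistic.

The pipeline around the core classifier (copy-number retention statistics,
expression filtering at 2.0 FPKM inclusive, Pearson chi-square tissue
specificity, reciprocal-best-hit pair calling, the lightweight co-expression
module detector, and the sliding-window conservation scanner) follows the
field's standard constructions; their parameters are listed below.

## The classifier, step by step

1. **Filter and normalize.** Genes with maximum FPKM below the threshold
   (default 2.0, inclusive) are removed per tissue; survivors are
   z-normalized with population (1/n) variance. Constant traces cannot be
   normalized and are excluded with a warning.
2. **Size the grid.** The node count S is the smallest whose trained-map
   variance-explained ratio (node assignments as clusters, between/total sum
   of squares) reaches `target_ratio` (default 0.85); the rectangle's aspect
   follows the ratio of the first two principal-component eigenvalues. The
   search doubles S and then binary-refines downward; the ratio is monotone
   in S on all data we have examined, and the refinement re-verifies the
   returned S and its predecessor, so the result matches an upward scan at a
   fraction of the training cost. A degenerate second eigenvalue falls back
   to a one-row map.
3. **Train the ensemble.** M maps (default 100) are trained with online
   Kohonen updates: Gaussian neighbourhood, radius decaying linearly from
   half the larger grid dimension to 1, learning rate from 0.05 to 0.01,
   100 iterations per gene, codebooks initialized from sampled data rows.
   Training and resampling run in compiled code but draw from R's RNG, so a
   single `seed` makes the whole fit reproducible.
4. **Resample.** Each gene is redrawn B times per map (default 500):
   Gaussian noise per timepoint on the raw trace, spread taken from the
   uncertainty column, then renormalized and assigned to the nearest
   codebook vector. The uncertainty column is interpreted as a standard
   deviation; `noise_scale = "variance"` reproduces the literal
   variance reading instead (the two differ only in taking a square root).
5. **Score pairs.** Per map, the co-mapping probability is
   `sum_c n1_c n2_c / B^2`; across maps its mean and SD enter the erf soft
   threshold `0.5 * (1 + erf((mu - theta) / (sigma * sqrt(2))))`. At
   `sigma = 0` the limit is a step function (1 above theta, 0 below, 0.5 at
   equality).
6. **Threshold.** Theta is derived per map as the kernel-density argmax of
   the self-consistency probabilities restricted to [0, 0.5] (Silverman
   bandwidth), averaged over maps. The low mode is the signature of
   noise-dominated genes, whose self-consistency is about 1/S. Two
   degeneracy rules guard the derivation: a map only contributes when at
   least 5% of genes fall in the window (otherwise there is no low mode,
   only stragglers) and when the density argmax is interior (an edge
   maximum is the tail of the high-consistency mode). When no map
   contributes, the configured floor (0.05) is used with a warning —
   which is also the expected regime for well-measured data.
7. **Modules and patterns.** Coefficients above 0.5 become edges; genes
   whose self-coefficient does not exceed 0.5 are removed as non-robust.
   Regulatory modules are the maximal cliques of the remaining graph
   (deterministic Bron–Kerbosch; modules sorted by size then members). A
   family with at least two robust genes is classified: one module holding
   everything = redundant; all-singleton modules = unique; disjoint modules
   with a shared one = distinct; every module overlapping another =
   gradated; overlap plus an isolated module = mixed. These five cases are
   exhaustive, so every classifiable family receives exactly one label.

## Tunable parameters

| parameter | default | unit | notes |
|---|---|---|---|
| expression threshold | 2.0 | FPKM | inclusive (max over the series ≥ threshold) |
| precluster target ratio | 0.98 | – | between/total SS for the hierarchical cut |
| soft-threshold beta | 30 | – | unsigned adjacency power |
| min module size | 30 | nodes | before eigengene merging |
| merge height | 0.25 | 1 − cor | merge modules at eigengene correlation ≥ 0.75 |
| static cut height | 0.99 | TOM dissimilarity | tree cut before the size filter |
| SOM target ratio | 0.85 | – | node-count selection |
| M | 100 | maps | ensemble size (tests and the acceptance script use 10–20) |
| B | 500 | draws | resampling depth (scaled runs use 50–200) |
| theta floor | 0.05 | probability | fallback threshold ≈ 1/S |
| RBH e-value | 1e-50 | – | significance for best-hit assignment |
| bias fold | 2 | – | inclusive two-fold expression bias |
| window / region threshold | 100 bp / 70% | – | conservation scan; step 1, gaps count as mismatch |

The network shape choices the published WGCNA configuration leaves open
(signed vs unsigned, tree-cut flavour, merge threshold) default to
unsigned, a static cut and merging at eigengene correlation 0.75, all
exposed as arguments. The tissue-specificity chi-square compares the
subset against the full gene set by default (`compare = "all"`), because
that construction reproduces the canonical worked example exactly; the
subset-vs-complement construction is available via a switch and agrees to
the order of magnitude.

## What the synthetic data emulates — and what it does not

`generate_family()` plants template traces (piecewise-linear over the
seven sampling days 22–72, standardized to unit variance) and realizes the
five patterns at the template level: one shared template (redundant),
mutually dissimilar templates with pairwise correlation at most 0.2
(unique; the same bound separates distinct groups and the isolated part of
a mixed family), and interpolation chains (gradated, mixed). Observed
traces add independent Gaussian noise per timepoint and carry that SD in
the uncertainty column. Template amplitude defaults to 1 FPKM over a
baseline of 10, so `noise_sd` reads directly as noise relative to the
signal's standard deviation: 0 is noiseless, 0.1 is a well-measured gene,
1 is noise on the order of the signal itself.

Two generator conventions deserve emphasis because the patterns they
realize are only detectable under them:

* **Chains are locally tight.** Neighbouring templates along a gradated
  chain have correlation 0.95 per step, with divergence accumulating
  toward the ends (endpoint correlation `cos((n-1) * acos(0.95))`). This
  mirrors the biological reading of a gradated family — copies share an
  overall profile and diverge stepwise, typically at a few late
  timepoints — and it is what makes neighbouring copies co-map while the
  chain ends do not. Chains between uncorrelated endpoints are simply
  families of dissimilar copies; no co-mapping method would (or should)
  call them gradated.
* **Mixed = one isolated copy plus a 4-point chain.** The taxonomy's
  verbal description (some modules overlapping, others not) is realized
  with the longest chain the default copy number allows, because a
  3-point chain collapses into a single clique too easily when both of
  its end links and the skip link all form.

The generator does not emulate read-level sequencing noise,
between-sample normalization artefacts, correlated noise across
timepoints, vernalization biology, or indels in the sequence fixtures.
Passing the recovery tests therefore demonstrates that the method
identifies the planted covariance structure under honest per-observation
noise — not that it is robust to misestimated uncertainties or alignment
artefacts in real data.

Recovery behaviour at the study conditions used by the acceptance script
(250 families, 50 per pattern, noise_sd 0.1, M = 20, B = 200, one CPU,
about a minute): redundant and unique recall are at or near 1.0 and
overall five-way accuracy is about 0.8 across seeds. Gradated and mixed
carry most of the residual error: their link structure depends on which
map quantizations the ensemble happens to draw, so single missing chain
links demote gradated families to distinct/mixed and over-complete chains
promote them toward redundant. Accuracy degrades monotonically with
noise_sd (a property test covers this), and at zero noise the
deterministic patterns (redundant, unique, distinct) are recovered
exactly.

## Numerical choices and degenerate inputs

* Population (1/n) variance for z-normalization; the "sample" convention
  is a switch. Uncertainty columns are rescaled by the same factor.
* Best-hit ties break by lower e-value then lexicographic subject id;
  clique enumeration and module ordering are deterministic, so repeated
  runs are byte-identical given a seed.
* Resampling draws that come out constant (unnormalizable) are redrawn,
  with a hard stop after 100 attempts; constant observed traces are
  excluded upstream with a warning.
* `co_mapping_probability` accumulates in double precision
  (`B^2 = 250000` fits exactly).
* Empty subsets yield flagged degenerate distributions rather than NaN
  surprises; empty hit tables yield empty maps; a profile shorter than the
  window yields one truncated window with a warning.
* Alignments delegate to Biostrings' global Needleman–Wunsch with affine
  gaps (match +1, mismatch −1, a gap of length L costs 5 + L); N scores as
  a mismatch against everything. Alignment coordinates are 0-based
  half-open, with projections onto each ungapped sequence available.

## Known limitations

* The same grid size is shared by all ensemble maps; re-sizing per map
  would confound the co-mapping statistics across maps.
* Clique-based modules are quadratic in family size; the implementation
  scores only within-family pairs, so genome-wide all-vs-all coefficient
  matrices are out of scope.
* The gradated/mixed boundary is sensitive to single links by
  construction (the taxonomy is combinatorial); cohort-level percentages
  are correspondingly more stable than per-family calls for those two
  patterns.
* The conservation scanner reports alignment-dependent quantities;
  different aligners will shift window identities by a few percent, so
  per-region percentages are comparable only within one aligner's output.
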