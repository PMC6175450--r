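# homeodiv

Retention and spatio-temporal expression divergence of duplicated genes in
allopolyploids.

## The problem

Allopolyploid crops such as oilseed rape (*Brassica napus*) carry several
copies of most genes: an ancient whole-genome triplication in the
*Brassica* lineage followed by interspecific hybridization of the A and C
genomes leaves up to six (and sometimes more) orthologues of each
Arabidopsis gene. Whether those copies kept the ancestral regulation
(redundancy), split it between them (subfunctionalization) or acquired new
regulation (neofunctionalization) decides how knowledge from diploid model
species transfers to the crop. This package implements an analysis suite
for that question on developmental transcriptome time series from two
tissues (first true leaf and shoot apex):

* **Retention statistics** — per-reference-gene copy-number distributions
  with two-sample proportion tests (`prop.test` convention, Yates
  corrected) between gene subsets (flowering-time set, transcription
  factors, syntenic/non-syntenic, expressed-only).
* **Expression filtering and tissue specificity** — a gene is expressed
  when its maximum FPKM over the series reaches 2.0; the 2×3 contingency
  of (apex-only / leaf-only / both) for a subset against the genome is
  tested with Pearson's chi-square (df = 2).
* **Reciprocal-best-hit homologue pairs** — directional best hits at
  e-value ≤ 1e-50 filtered for reciprocity.
* **A self-contained co-expression module detector** — hierarchical
  pre-clustering to a between/total sum-of-squares target of 0.98, an
  unsigned soft-thresholded adjacency `a_ij = |cor(x_i, x_j)|^30`,
  topological overlap, average-linkage tree cut and eigengene merging
  (minimum module size 30).
* **The ensemble-SOM divergence classifier** (the core method, below).
* **Sliding-window conservation scanning** — global pairwise alignment,
  100-bp sliding-window percent identity and ≥70 % conserved-region
  calling for cis-regulatory comparison.
* **A synthetic-data generator** that emulates every input — homologue
  families with known divergence patterns, copy-number tables with an
  enriched subset, hit tables with decoys, and sequence pairs with
  planted conserved blocks — so the full pipeline runs and is tested
  without any external download.

## The core method

For each tissue, expression traces `x_g` (FPKM at the sampled days) are
z-normalized to mean 0 and unit variance. A self-organizing map with `S`
nodes is trained on all expressed genes; `S` is the smallest node count
whose variance-explained ratio

    sum_c N_c (xbar_c - xbar)^2 / sum_g (x_g - xbar)^2  >=  0.85

is reached, with grid aspect matching the ratio of the first two
principal-component eigenvalues. Each gene's trace is then resampled
`B = 500` times under its per-timepoint uncertainty (Gaussian, centred on
the observed FPKM), renormalized and mapped to its nearest codebook
vector, giving node counts `n_{g,c}`. The probability that genes g1 and
g2 co-map is

    p(g1, g2) = sum_c n_{g1,c} n_{g2,c} / B^2

and `p(g, g)` measures how consistently a gene maps at all. Over an
ensemble of `M = 100` independently trained maps, the mean `mu_p` and
standard deviation `sigma_p` of `p` yield a **clustering coefficient**

    C(g1, g2) = 1/2 * (1 + erf((mu_p - theta) / (sigma_p * sqrt(2))))

where the threshold `theta` is the low mode of the self-consistency
density (its kernel-density argmax on [0, 0.5], averaged over maps, with
a floor of 0.05 when no low mode exists). Coefficients are binarized at
0.5; **regulatory modules** are the maximal cliques of the binary graph
after removing genes that do not robustly self-map. Each homologue
family's module structure is classified as one of five divergence
patterns: **redundant** (one module holds all copies), **distinct**
(disjoint modules, at least one shared), **gradated** (every module
overlaps another), **unique** (all singletons) or **mixed** (overlapping
and disjoint modules together).

## Worked example

```r
library(homeodiv)
cohort <- generate_cohort(n_per_pattern = 6, noise_sd = 0.1, seed = 42)
fit <- som_divergence(cohort$expression, cohort$families,
                      tissue = "apex", M = 10, B = 100, seed = 1)
print(fit)
summary(fit)
```

```
Ensemble-SOM regulatory divergence fit
  tissue: apex; 126 expressed genes; grid 7 x 2; M = 10 maps; B = 100 draws
  threshold theta = 0.0500
  30 families classified:
pattern
 distinct  gradated     mixed redundant    unique
       11         3         2         8         6
Divergence patterns over 30 families (theta = 0.0500):
   pattern  n percent
  distinct 11      37
  gradated  3      10
    unique  6      20
 redundant  8      27
     mixed  2       7
```

The cohort planted 6 families of each pattern; at this scale the
classifier recovers the redundant, unique and distinct families exactly
(8/6/11 include a few gradated and mixed families whose chain links fall
below the co-mapping threshold — see the methods vignette for why those
two patterns are intrinsically harder). `coef(fit)` returns the pairwise
`mu_p`/`sigma_p`/coefficient table, `coef(fit, family = ...)` one
family's coefficient matrix, and `plot(fit, family = ...)` the
corresponding heatmap. `run_pipeline(run_config(...))` chains every stage
(simulate/ingest → filter → normalize → retention → modules → SOM →
conservation) into a seeded, logged artefact bundle.

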