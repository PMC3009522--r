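---
title: "Gene selection with a multi-filter enhanced genetic ensemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene selection with a multi-filter enhanced genetic ensemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfge)
```

## The problem

Microarray (and more generally bulk or single-cell transcriptomic)
classification problems have an extreme feature-to-sample ratio: thousands
of genes, a few dozen labelled samples. Univariate *filters* (statistics
that score each gene's association with the class) are fast and generalize
well but ignore gene interactions; *wrappers* (search procedures scored by
a classifier) capture interactions but overfit when a single inductive
algorithm is the sole guide. `mfge` implements a hybrid: several filters
score every candidate gene, the scores are fused into a sampling
distribution, and a niched genetic algorithm (GA) — whose fitness is a
classifier-*ensemble* score — searches for small gene subsets, biased
toward filter-favoured genes. Repeating the GA many times and ranking genes
by how often they appear in the winning subsets gives a stable gene
ranking, evaluated on held-out data.

## The pipeline, stage by stage

### Preprocessing and the double cross-validation frame

1. Each gene is standardized to mean 0, variance 1 (population convention,
   i.e. dividing by $n$; the subsequent min–max step makes the choice
   invisible downstream), then rescaled per gene to $[0, 1]$. The $[0,1]$
   range matters later: it is what bounds ReliefF weights in $[-1, 1]$.
2. Samples are split by a *stratified external 3-fold* cross-validation.
   Everything that follows — gene ranking, filter scoring, the GA — sees
   only external training samples; external test folds are touched exactly
   once, to classify.
3. Within each external training set, genes are ranked by the
   between-group to within-group sum-of-squares ratio (BSS/WSS, the
   Dudoit–Fridlyand–Speed statistic) and the top 200 are retained. A
   perfect separator (WSS $= 0$, BSS $> 0$) ranks first ($+\infty$); a
   constant gene (0/0) ranks last (0); remaining ties keep original gene
   order, so the prefilter is deterministic.
4. The external training set is further split by a stratified internal
   3-fold cross-validation. Filter scores are computed on the internal
   training sets (averaged across the three of them), and GA fitness is
   the mean over the three internal train→test splits.

Standardization and normalization are applied to all samples before the
external split, following the protocol's "of the dataset" phrasing. This
leaks a small amount of scale information across folds; it is recorded
here as a known property, not resolved, because the per-gene rescaling is
label-free.

### The filter bank

Five filters are implemented. Four of them work on a discretized gene:

* **χ²-statistic** of the bin-by-class contingency table,
  $\sum_{v}\sum_{c}(N_{vc}-E_{vc})^2/E_{vc}$, with structural zeros
  ($E_{vc}=0$) contributing nothing.
* **Information gain** $IG = H(\text{class}) - H(\text{class}\mid g)$ in
  bits.
* **Gain ratio** $IG / H(g)$, where $H(g)$ is the split information; a
  single-bin gene is defined to score 0.
* **Symmetrical uncertainty**
  $SU = 2\,IG / (H(\text{class}) + H(g)) \in [0,1]$, with the
  doubly-constant case defined as 0.

Discretization is Fayyad–Irani MDLP: recursive entropy-minimizing binary
splitting, stopped by the minimum-description-length criterion;
parameter-free, and the de-facto standard in front of entropy-based
filters. A gene for which no cut passes MDLP gets a single bin and the
minimum score (0) under all four filters — uninformative genes cannot
accumulate score by chance binning. All four filters share one
discretization per gene.

* **ReliefF** works on the continuous $[0,1]$ matrix. For each probe
  sample the nearest same-class neighbour (hit) and nearest
  different-class neighbour (miss) are found by Euclidean distance over
  all genes (self excluded; distance ties go to the lowest sample index);
  the weight is the mean of (miss difference − hit difference) for the
  scored gene. With all samples probed (the default) the score is
  deterministic and the $1/n$ normalization provably keeps it in
  $[-1,1]$ on $[0,1]$ data. For $m>2$ classes the miss term is the
  prior-weighted average over opposing classes, which collapses to the
  plain two-term form for binary labels.

### Score fusion and the gene frequency map

Raw scores are not commensurable across filters, so each filter's score
vector is squashed by *softmax scaling*: standardize the vector
(population s.d.) and apply the logistic,
$\tilde s = 1/(1+e^{-(s-\bar s)/\sigma_s})$. This is order-preserving and
strictly inside $(0,1)$. The scaled scores are summed over filters,
multiplied by 10 and rounded (half-up — the convention is fixed and
documented because it affects nothing but determinism), with a floor of 1
so every candidate gene keeps a nonzero multiplicity.

The resulting integer score becomes the gene's multiplicity in the **gene
frequency map** — a multiset over candidate genes. All random gene choices
of the GA (initialization and mutation) draw uniformly from this pool, so
a gene's chance of entering a chromosome is proportional to its fused
filter score, yet no gene is excluded outright. The map is built once per
external fold, before any genetic iteration, never inside the loop. A
*uniform* map (all multiplicities 1) is available as the paired baseline:
with it the engine reduces to the plain genetic-ensemble search.

### The genetic engine

A chromosome is a string of 15 slots, each a candidate-gene index or the
empty marker 0, with non-zero entries pairwise distinct; it decodes to a
subset of 0–15 genes. Defaults (all overridable through `ga_config()`):
population 100 in 2 niches of 50 evolved separately; exchange of the
single favourite chromosome per niche every 10 generations; single-point
crossover at probability 0.7 with duplicate repair (a gene duplicated by
the tail swap keeps its earlier slot, the later one is zeroed); chained
multi-point mutation — a first point mutation with probability 0.1, each
further one with probability 0.25, so the expected count is
$0.1/0.75 \approx 0.133$; tournament selection of size 3; termination at
generation 100 or when a niche's mean pairwise Jaccard similarity of
decoded subsets reaches 0.9; fitness weights $w_1 = w_2 = 0.5$.

Choices the protocol leaves open, fixed here:

* **Replacement**: generational with elitism 1 per niche. Elitism makes
  best-fitness monotonicity a testable invariant and is standard practice.
* **Initialization fill rate**: each slot is filled with probability 0.4
  (else left empty), giving an expected initial subset size of 6 — the
  midpoint of the 2–10 band evolved subsets settle into.
* **Mutation target**: a mutated slot is emptied with probability 0.6
  (the slot-empty rate at initialization) or refilled from the map, so
  subset size is evolvable in both directions.
* **Similarity**: mean pairwise Jaccard over decoded subsets
  (empty-vs-empty counts as 1); the convergence criterion is "any niche
  at or above the threshold".
* **Migration count**: 1 favourite per niche per exchange.
* **Tie-breaks**: tournament and elite ties go to the smaller subset,
  then the earlier index — small subsets are preferred at equal fitness.

Each *genetic-ensemble iteration* runs this engine from a fresh seeded
population and contributes its best-ever chromosome; the engine runs (by
default) 100 such iterations per external fold.

### Ensemble fitness

A subset's fitness on one internal split combines two terms computed from
a bank of five classifiers — decision tree (rpart, with C4.5-like
splitting thresholds since the defaults would leave a root stump on
few-dozen-sample folds), random forest of 7 trees, 3- and
7-nearest-neighbour, Gaussian naive Bayes:

$$\mathrm{fitness}(s) = w_1 \cdot \underbrace{\tfrac1L\sum_{i=1}^{L}
BC(h_i(s), y)}_{\text{blocking}} + w_2 \cdot \underbrace{BC(V_k(h_1,
\dots, h_k), y)}_{\text{majority voting}}$$

where $BC$ is *balanced classification accuracy* — the mean per-class
sensitivity $\frac1m\sum_j Se_j$ — and $V_k$ the per-sample modal class
over the first $k$ voters (default $k = L = 5$; vote ties go to the
earliest classifier in bank order). Blocking forces the subset to satisfy
five inductive biases at once rather than overfitting one; voting rewards
subsets that make the ensemble's consensus accurate. A class absent from a
degenerate fold contributes sensitivity 0, penalizing rather than
inflating the score. Every classifier is re-fit from scratch for every
evaluated subset, under a bank-derived seed, so fitness evaluation is
deterministic. A chromosome's fitness is the mean over the fold's internal
splits, cached by subset, since the GA revisits subsets constantly.

### Ranking and evaluation

Each iteration's best subset is recorded with its termination generation
and size. A gene's **selection frequency** is the number of iterations
whose winning subset contains it (membership, not slot multiplicity);
genes are ranked by frequency, ties broken by integer score and then gene
order. Per external fold, the top 5/10/15/20 genes are used to fit the
bank on the external training set and classify the external test fold,
reporting per-classifier balanced accuracy, their mean, and the
majority-voting accuracy; the selection stage is repeated (default 5
times) and results are averaged over folds within repeat, then across
repeats. `overall_ranking()` additionally sums selection counts across
folds and repeats into one dataset-level gene list, the list a study would
report. `convergence_summary()` compares two engines (e.g. multi-filter
map vs uniform map) on mean termination generation and mean subset size
with a one-tailed paired t-test; an all-zero-difference pairing reports
p = 0.5 by convention.

## The synthetic-data model

`generate_synthetic()` emulates the regime the method targets: `n_genes`
(default 200, the post-prefilter size) independent unit-variance Gaussian
genes over two classes of 25 samples each, of which `n_informative`
(default 10) receive a class-mean shift of `effect_size` (default 1.5)
noise-sd units — a moderate, realistic separation for microarray
biomarkers. Options add a three-class layout (default sizes 24/20/28,
mimicking a leukemia-subtype task, each informative gene separating one
class pair round-robin), an equicorrelated informative block (redundant
genes), and heavy-tailed t(4) noise. What it deliberately does *not*
simulate: batch effects, probe saturation, heteroscedastic noise,
pathway-structured correlation. Passing tests on this generator therefore
demonstrate correctness of the machinery and sane behaviour of the
protocol (no leakage, recovery of planted signal, chance-level accuracy
under a null), not performance claims about any real dataset.

## Problem sizes used by the test and acceptance studies

The validation studies in `tests/testthat/` and `scripts/acceptance.R`
run the protocol end to end at smoke scale, the package's chosen study
conditions for a desk-sized machine: the generator defaults for the data,
the full 3×3 double cross-validation, and a genetic engine reduced to
population 16 (2 niches of 8), 12 generations cap, and 3–12 iterations
per fold depending on the study; the null-model study uses 40-gene
datasets with 12 + 12 samples. Selection-frequency rankings at this scale
are aggregated across the three external folds. Accuracy, leakage,
conservation and determinism properties are scale-free; the engine
*dynamics* are not. In the generator's equal-effect planted regime the
frequency map reliably raises best fitness and planted-gene recovery,
but the paired comparison against the uniform map shows it can also
*slow* similarity-based convergence slightly and leave subsets
marginally larger: with ten interchangeable informative genes the map
sustains several equally fit subsets, so a niche takes longer to
homogenize, whereas the uniform engine settles on whatever it finds
first. Convergence and compactness gains from score fusion therefore
depend on how concentrated the fused scores are — a property of the
data, not of the engine — and the suite reports the paired comparison's
direction and t-test rather than asserting an effect size.

## Numerical conventions and degenerate inputs

* Constant genes: standardized to all-zero (warning), normalized to 0.5,
  BSS/WSS 0, single MDLP bin, filter scores 0, ReliefF 0.
* Zero-variance score vectors softmax-scale to all 0.5 (warning);
  infinite raw scores squash to the logistic bound.
* Entropies use $0\log 0 = 0$; probabilities are validated to sum to 1
  within $10^{-9}$.
* Empty chromosomes are never created (all-empty initializations are
  redrawn) and an empty subset, should a caller construct one, scores
  fitness 0 with a warning.
* All stochastic stages draw seeds derived from one master seed through
  an integer-hash fan-out (`derive_seed()`), so any fold, repeat or
  iteration is replayable in isolation and full runs are byte-identical
  under the same master seed.

## Known limitations

* The wrapper stage's computational cost is dominated by classifier
  re-fits; at reference scale (100 iterations × population 100 × 3
  internal folds × 5 classifiers) a run is an overnight job on one CPU.
  The fitness cache mitigates but does not remove this.
* Filter scores are fused unweighted; no rank-aggregation alternatives.
* No probe-level preprocessing (CEL files, probe-to-gene mapping) and no
  biological annotation of selected genes.
* Majority voting is the only combiner; no stacking or
  probability-weighted votes.
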