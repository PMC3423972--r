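---
title: "Consensus clustering of chemogenomic profiles: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus clustering of chemogenomic profiles: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemoconsensus)
```

## The problem

A chemogenomic screen measures, for each compound, the fitness defect of
every strain in a genome-wide deletion collection, summarized as one p-value
per (compound, gene) pair. Compounds with similar interaction profiles tend
to share a mechanism of action, so the neighborhood of a reference
("signature") compound in profile space is a natural hunting ground for
repositioning candidates. The catch is that "neighborhood" depends on
arbitrary analysis choices: which dissimilarity measure, and which
agglomerative linkage. This package removes that arbitrariness by brute
force: it clusters the compounds under every combination of seven measures
and four linkages and ranks each compound by its *consensus frequency* — the
fraction of trials in which it lands in the signature compound's subcluster.
A compound that tracks the signature under centered and uncentered
correlation, Spearman rank correlation, their absolute variants, Euclidean
and city-block distance, across single, complete, average and centroid
linkage, is a robust candidate rather than an artifact of one metric.

## Dissimilarity measures

For profiles $x, y$ restricted to their co-present genes:

* centered correlation: $d = 1 - r$ with $r$ the Pearson coefficient;
* uncentered correlation: $d = 1 - \sum x y / \sqrt{\sum x^2 \sum y^2}$ (a
  cosine similarity, no mean subtraction);
* absolute variants: $d = 1 - |r|$, treating anti-correlated profiles as
  similar;
* Spearman: $d = 1 - r_s$, the Pearson coefficient of mid-ranks (ties get
  average ranks);
* Euclidean $\sqrt{\sum (x - y)^2}$ and city-block $\sum |x - y|$.

Missing cells are handled by pairwise-complete deletion: each pair of
compounds is compared over the genes present in both. The Euclidean and
city-block sums are deliberately *not* rescaled by the number of shared
genes — this matches the behavior family of the classic desktop clustering
tools this pipeline is compatible with — but `scale_by_shared = TRUE`
divides the sums by the shared-gene count for users who want
length-invariance under unequal missingness. An undefined correlation (a
constant profile, fewer than two shared genes, a zero norm) is replaced by
the measure's maximum distance (2, or 1 for the absolute variants) with a
warning: no evidence of similarity, scored conservatively. A Euclidean or
city-block pair with *no* shared genes has no defensible value at all; it is
left `NA` and the affected trial is skipped and excluded from the consensus
denominator.

## Agglomeration

`cluster_profiles()` performs greedy agglomeration: at each step the pair of
active clusters at minimum inter-cluster dissimilarity merges, and that
dissimilarity is the merge height. Single, complete and average linkage use
the min, max, and unweighted mean (UPGMA, not the weighted WPGMA — "average
linkage" unqualified conventionally means UPGMA) over cross pairs. Centroid
linkage computes each cluster's centroid in *profile space* (per-gene mean
over present entries) and evaluates the trial's measure between centroids.
This is the semantics the desktop clustering tools use, and it is the only
one that makes centroid linkage meaningful under correlation measures; the
Lance–Williams centroid update would be valid for squared Euclidean
distances only.

Numerical conventions worth stating:

* **Tie-breaking.** When several cluster pairs tie at the minimum distance,
  the pair whose (smaller, larger) tuple of minimal original row indices is
  lexicographically least merges first. Ties are measure-zero for continuous
  data but routine in toy examples; a fixed rule makes every run
  reproducible across platforms.
* **Monotonicity.** Single, complete and average linkage produce
  non-decreasing heights by construction. Centroid linkage can invert
  (a merged centroid can sit closer to a bystander than its parents were to
  each other); inversions are counted and reported via a `message()`, never
  rejected.
* **Determinism.** No stage draws randomness; permuting input rows yields an
  isomorphic tree with an identical height multiset.

The test suite pins the implementation to a naive $O(n^3)$ re-scan oracle
that recomputes every inter-cluster distance from scratch at every step, for
all 28 measure–linkage combinations, to $10^{-9}$, and cross-checks
complete-data cases against `stats::hclust`, `stats::dist` and `stats::cor`.

## Subcluster and consensus

The notion of "the compounds clustered with the signature" needs an
operational definition; two are provided. `min_size(m)` walks up the tree
from the signature leaf and returns the smallest ancestor cluster with at
least `m` leaves — the intuitive "nearest neighbors in the tree" reading,
robust to tree depth. `cut_k(k)` cuts the tree into `k` groups and takes the
signature's block. The package default is `min_size(max(2, ceil(0.05 n)))`;
the validation experiments use `min_size(8)` on 20 compounds. Both the
policy and the full trial list are recorded in the run metadata, because the
original screen analysis from which this design descends reported 19 of the
28 combinations without listing them; any subset is reproducible via
`enumerate_trials(exclude = ...)`.

Consensus frequency is co-clustering count divided by *completed* trials;
skipped (degenerate) trials carry no evidence and are excluded from the
denominator. Frequencies are sorted descending with ties broken by compound
identifier.

## The synthetic screen

`simulate_chemgen()` generates the study matrix: background entries are
Uniform(0, 1) — null p-values — and a planted block of module compounds by
module genes is drawn Beta($\alpha$, 1), a one-parameter family spanning the
null ($\alpha = 1$ is exactly Uniform) to strong signal ($\alpha \to 0$;
the block mean is $\alpha/(\alpha+1)$). Missingness is completely at random,
applied after value generation — the simplest model consistent with sporadic
assay dropout. Defaults are the validation conditions used throughout: 20
compounds $\times$ 100 genes, a 4-compound/20-gene module at
$\alpha = 0.05$, 5% missingness (the screen literature does not characterize
its dropout rate; 5% is a realistic sporadic-failure choice, made once).
The signature compound is by convention the first planted compound.

What the generator does *not* emulate: strain-specific growth kinetics,
batch effects, dose–response structure, or the dependence structure of a
real screen's p-values (real profiles are correlated through shared pathway
biology even off-module). Passing recovery tests on this generator
demonstrates that the pipeline's machinery ranks a planted signal correctly;
it does not certify performance on any real screen.

## What the planted-module experiment shows — and a known limitation

With a strong planted module (e.g. half the genome at $\alpha = 0.005$) the
three planted non-signature compounds occupy the top three consensus ranks
in every seed tested; the mechanism works. Under the much weaker default
conditions ($\alpha = 0.05$, 20 of 100 genes) recovery is partial: across
seed batches roughly half the screens place all three planted compounds in
the top three ranks. The reason is quantitative and follows from the model.
On raw p-values the expected centered correlation between two planted
profiles is

$$ r \approx \frac{f\,(\mu_B - \bar p)^2}{\mathrm{Var}(p)} \approx 0.25 $$

with module fraction $f = 0.2$, Beta mean $\mu_B \approx 0.048$, profile
mean $\bar p \approx 0.41$ and variance $\approx 0.10$ — a modest
separation, and only 12 of the 28 trials (centered, absolute-centered,
Spearman) discriminate well on raw p-values; the uncentered family barely
sees a low-p block (near-zero values contribute nothing to $\sum xy$), and
Euclidean/city-block gain only a small expected-distance margin. The
consensus is correspondingly noisy: planted compounds average a much higher
consensus frequency than background (about 0.91 vs 0.68 at these
conditions) without reliably monopolizing the top three ranks. The
$-\log_{10}$ transform (`transform_profiles(..., "neglog10")`), which
upweights significant interactions, roughly doubles full-recovery rates but
is an explicit, flagged alternative — the default pipeline clusters raw
p-values, faithful to the original analysis. Under the null
($\alpha = 1$) planted and background compounds are exchangeable: a pooled
permutation test across 100 simulated screens finds no enrichment of
planted compounds in the signature's neighborhood, which is the guarantee
that the ranking does not manufacture signal.

Problem sizes used in the validation suite — 10-compound screens for the
oracle-equivalence sweep (50 random matrices, all 28 combinations),
20-compound screens for recovery (20 seeds) and the null control (100
seeds) — were chosen so the whole suite exercises every code path at
desk scale.

## Downstream quantification statistics

The phenotyping end-points that are pure computation are implemented
exactly:

* `fisher_exact_2x2()`: exact conditional test, two-sided by the
  sum-of-as-or-less-probable-tables rule (relative tolerance $10^{-7}$ in
  the comparison, no mid-p). On the ectopic-vessel phenotype table (6/8
  affected controls vs 0/9 treated) it gives $p = 0.00226$. The test suite
  checks exhaustive-enumeration agreement for every table with total
  $\le 40$ and transposition/row–column-swap invariance.
* `tumor_volume()`: caliper formula $w^2 \ell / 2$; width/length swapped
  with a note if recorded in the wrong order.
* `wound_closure_ratio()`: $(A_0 - A_t)/A_0$; negative closure reported,
  not clamped.
* `dose_convert()`: mg/kg and µmol/kg from administered mass and body mass;
  under the stated 1 kg $\approx$ 1 L density assumption µmol/kg is read as
  µM-equivalent. 1 mg into a 20 g mouse is 50 mg/kg $\approx$ 250 µM for
  thiabendazole (201.25 g/mol, from C10H7N3S); 3 g for a 60 kg patient is
  50 mg/kg.
* `vessel_area_fraction()`: strict ">" pixel count above an intensity
  threshold, monotone non-increasing in the threshold.

## File formats

The matrix TSV dialect is a header row (corner label, then gene ids) and one
row per compound; empty cells and `NA` are missing; round-trip is identity
to 12 significant digits. `write_cdt_gtr()` emits the `.cdt`/`.gtr` pair
read by Java TreeView: rows in dendrogram leaf order, leaf ids `GENE{i}X`
(0-based original row index), merge nodes `NODE{k}X`, and similarity scores
$1 - h/h_{\max}$ so scores lie in $[0, 1]$ and decrease down the file for
monotone trees (the tree format does not itself prescribe a height
normalization; this choice matches TreeView's similarity-ordered
expectations). Only the compound (row) tree is emitted: the prioritization
depends solely on compound clustering, so no column tree or `.atr` file is
produced.

## Limitations

* The pipeline ranks candidates; it attaches no significance to consensus
  frequencies (and deliberately so — no bootstrap or resampling stability
  layer is included).
* Centroid linkage under non-Euclidean measures is heuristic by nature;
  inversions are possible and reported.
* Raw-p clustering weights non-significant noise heavily; see the recovery
  discussion above before trusting fine rank distinctions between
  mid-frequency compounds.
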