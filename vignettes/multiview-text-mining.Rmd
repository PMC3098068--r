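---
title: "Multi-view text mining for disease-gene prioritization and clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-view text mining for disease-gene prioritization and clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvtm)
```

## The problem and the model

Literature about genes can be turned into numeric profiles by indexing the
documents linked to each gene with a controlled vocabulary (CV): a fixed
term list derived from a bio-ontology. Each CV yields one *view* of the
same gene set — a gene-by-term matrix — and different CVs emphasize
different aspects of the biology (phenotypes, molecular function,
chemistry, anatomy). No single CV is reliably the best one for relating
genes to diseases, and the choice can change the quality of downstream
analysis by a factor of two or more. The multi-view strategy sidesteps the
choice: build all the views, then integrate them, so the result does not
hinge on guessing the right vocabulary in advance.

`mvtm` implements that strategy end to end for the two standard
disease-gene tasks:

* **Prioritization** — given a training set of genes known to cause a
  disease, rank candidate genes by similarity to the training set.
* **Clustering** — partition disease-relevant genes so that the groups
  recover the disease structure.

Profiles are built in three steps. `index_corpus()` counts CV terms per
document; `aggregate_gene_profiles()` averages the document vectors of
each gene's linked documents (the synthetic analogue of curated
gene-to-publication maps); `idf_transform()` rescales each term column by
`idf(t) = log(D / df_t)`. The inverse-document-frequency scheme is the
only weighting offered: TF-IDF and binary weighting are deliberately out
of scope, because IDF profiles are the configuration this pipeline is
built around. Two details are open in principle and therefore exposed as
arguments rather than hard-wired: the exact IDF formula (we use the plain
logarithm without smoothing) and whether document frequencies come from
the view's own doc-by-term matrix (the default) or from a corpus-wide
matrix (pass a merged matrix to `idf_transform()`).

Two merged baselines complete the view-construction module:
`merge_views()` indexes with the de-duplicated union of several CVs, and
`map_concepts()` collapses synonym term columns into concept columns
(applied to raw counts, before IDF, so each gene's total count is
conserved). `no_voc_vocabulary()` builds the vocabulary-free baseline that
indexes on every distinct corpus token.

## Latent semantic indexing

`lsi_decompose()` computes the top singular triplets of a view and
`select_rank()` applies a spectrum-fraction rule: keep the smallest `k`
such that the `(k+1)`-th value falls below a fraction (default 0.05%) of
the spectrum sum; if nothing falls below, keep everything and warn. The
rule is stated for "eigenvalues" in some sources and implemented on
singular values in others; we default to singular values of the
gene-by-term matrix and expose `use = "squared"` for the Gram-eigenvalue
reading. The decomposition is fitted on the full gene universe of a view
(labeled and unlabeled genes alike), mirroring whole-collection fitting.
At the matrix sizes this package targets (hundreds of genes, a few
thousand terms), an exact LAPACK decomposition truncated to `max_rank`
(default `min(genes, terms, 500) - 1`) is both simpler and more accurate
than iterative sparse solvers, so that is what `lsi_decompose()` uses.
`lsi_project()` returns gene rows in the latent basis (gene factors scaled
by singular values); at full computed rank it preserves pairwise gene
inner products and distances, so kernels and Hilbert-space clustering are
unchanged by a lossless projection.

## Prioritization

The base ranker is deliberately plain: `build_model()` averages the
training profiles, `score_correlation()` computes Pearson correlation of
each candidate with that model (zero-variance rows score 0 by convention),
and `rank_candidates()` sorts by score with ties broken by ascending
candidate id, attaching rank ratios `position / n`.

Per-view rankings are integrated in two families.

**Ensemble ranking.** `fuse_scores()` implements the average and maximum
operators. The order-statistics route works on rank ratios instead:
`q_statistic()` computes the joint cumulative probability that `N` uniform
order statistics all fall below the observed sorted ratios, using the fast
`V_k` recursion (`V_0 = 1`,
`V_k = sum_{i=1..k} (-1)^(i-1) V_{k-i} r_{N-k+1}^i / i!`, `Q = N! V_N`)
rather than the `N`-dimensional integral; the recursion is tested against
a Monte-Carlo oracle. Because Q values for random ratios are approximately
beta distributed for `N <= 5` and gamma distributed for larger `N`,
`calibrate_q()` fits that null by maximum likelihood on simulated Q
samples, and `q_pvalue()` converts a gene's Q into a left-tail p-value;
genes are ranked by ascending p-value.

**Kernel fusion.** `kernel_matrix()` builds a linear Gram matrix from
unit-norm gene rows and mean-centers the features (linear kernels only —
the profiles are high-dimensional, so nonlinear kernels add cost without
information). `fit_one_svm_fusion()` learns a convex combination
`Omega = sum_j mu_j K_j / r_j` of trace-scaled kernels by the one-class
support-vector program: minimize `t` subject to
`alpha' G_j alpha / r_j <= t` over every kernel's training submatrix
`G_j`, with `0 <= alpha_i <= 1/(nu M)` and `sum(alpha) = 1`. The kernel
weights are the duals of the quadratic constraints and sum to one. A lower
bound `mu_min` on each weight interpolates between the sparse optimum
(`mu_min = 0`, weight often concentrates on one or two kernels), a
guaranteed minimum contribution (`mu_min = 0.5/N`), and the exact uniform
average (`mu_min = 1/N`). We solve the program through its saddle-point
form: the concave value function
`h(mu) = min_alpha alpha' K(mu) alpha` is maximized over the bounded
simplex by projected supergradient ascent, and the inner one-class QP by
accelerated projected gradient with an exact breakpoint-scan projection
onto the box-constrained simplex (`solve_box_simplex_qp()`, cross-checked
against an interior-point oracle in the tests). Note the direction this
implies: enlarging the weight simplex (lowering `mu_min`) can only
increase the attained margin objective `t`, since `t` is a maximum over
that simplex — the uniform combination is the most constrained case.

Because the attained margin is a maximum over the weight simplex, the
`nu` parameter (default 0.5) controls how many training genes may act as
outliers; the exact value used in the original studies is not documented,
so the standard midpoint is the default and the argument is exposed.
`score_one_svm()` scores a candidate as
`sum_i alpha_i Omega(x, x_i)`, normalized by the model norm
`sqrt(alpha' Omega alpha)` and the candidate's self-similarity
`sqrt(Omega(x, x))` — the only bounded normalization consistent with
scores lying in `[-1, +1]` — with residual numerical overshoot clipped.

**Benchmarking.** `loo_benchmark()` implements the leave-one-out
protocol: each disease gene in turn becomes the "defector", removed from
training and hidden among randomly drawn unlabeled candidates (99 by
default, re-drawn per defector per repetition); the error is `1 - AUC`
with the defector as sole positive and midrank tie handling. Kernels are
built and centered once over the full gene universe (training plus the
entire candidate pool) and submatrices are taken per defector; pairwise
feature-space geometry is invariant to where the double-centering
happened, and one centering keeps the protocol fast enough to repeat
across many seeds.

## Clustering

`kmeans_partition()` is the base algorithm: Euclidean K-means on gene
rows, best of `n_restarts` seeded starts. Six consensus functions combine
per-view partitions (`consensus_combine()`): CSPA partitions the
co-association similarity graph; HGPA cuts the cluster hypergraph via a
bipartite spectral embedding of the gene-by-hyperedge incidence; MCLA
merges hyperedges greedily by Jaccard similarity into meta-clusters and
assigns genes by participation; QMI runs K-means in the centered
cluster-indicator space (the category-utility criterion); EACAL applies
average linkage to one minus the co-association matrix (evidence
accumulation — average linkage, the variant that outperforms single
linkage); AdacVote accumulates aligned votes in decreasing order of
partition entropy. The original graph-based methods rely on the
METIS/hMETIS partitioners; we substitute spectral embeddings with seeded
K-means, which removes a compiled external dependency at the cost of
exact fidelity to those heuristics. All inputs are relabeled canonically
(clusters numbered by first appearance) so every method is exactly
invariant to how input partitions number their clusters.

Kernel fusion clustering works on the same centered linear kernels.
`hilbert_distance()` converts a (weighted) average kernel into
feature-space distances `d(x, z) = sqrt(K(x,x) - 2K(x,z) + K(z,z))` —
with unit-norm rows and linear kernels this is the Euclidean distance on
the concatenated features — and `linkage_partition()` cuts a
single/complete/average/Ward dendrogram (`ward.D2`, appropriate for
Euclidean distances).

`okkc()` is the optimized kernel K-means: alternate (i) Girolami-style
kernel K-means on the current combination of trace-normalized kernels and
(ii) a fusion step that re-weights kernels to maximize the between-cluster
separation `s_i = sum_j u_j' (K_i / r_i) u_j` of the current labels.
Formulations of this fusion step vary (it can be posed as a
quadratically constrained program over per-class discriminant duals);
ours is designed so the alternation is provably monotone: both steps
descend the single objective `J(labels, mu) = tr(Khat(mu)) - s(labels)' mu + lambda ||mu||^2`,
whose `mu`-update is the closed-form projection of `s / (2 lambda)` onto
the `mu_min`-bounded simplex. `lambda` (default 0.01) smooths the weights:
small values give near-vertex (sparse) weights, large values near-uniform
ones. With `mu_min = 1/N` the fusion step is skipped and the algorithm is
exactly kernel K-means on the averaged trace-normalized kernel with the
same seed. Emptied clusters are re-seeded at the point farthest from its
centroid; the per-class discriminant duals
`beta_j = (Khat(mu) + lambda I)^{-1} l_j` are reported with the state.

**Validation.** `agreement()` counts the four pair types between a
partition and the disease labels via the contingency table — `a` pairs
together in both, `b` apart in both, `c` together only in the partition,
`d` together only in the labels — giving
`RI = (a + b) / (a + b + c + d)` and NMI with geometric-mean entropy
normalization, `NMI = M / sqrt(E_C E_P)` (the normalization is another
under-specified detail; the geometric mean is the common convention for
these consensus methods). When both partitions are the trivial single
cluster NMI is 1; when exactly one is trivial it is 0.
`pairwise_disease_eval()` runs the all-pairs protocol: for every
unordered disease pair, take the genes of either disease, drop genes
labeled with both, cluster into two groups, and score against the labels;
29 diseases yield 406 tasks, and pairs left with fewer than four genes
are skipped with a warning.

## The synthetic benchmark generator

Real inputs for this pipeline are bulky (hundreds of thousands of
abstracts, full ontology releases, a curated disease benchmark), so
`generate_benchmark()` produces a self-contained analogue with the same
moving parts:

* each disease, and each "distractor" topic carried by unlabeled
  candidate genes, is a latent term-topic — a random subset (default 25%)
  of a per-view signature term pool;
* a document about a gene mixes topic tokens and background tokens; the
  mixing weight is the view's `relevance`, the single knob that makes a
  view informative (`relevance = 1`), partially informative, or pure
  noise (`relevance = 0`). The share of signature terms in a view's
  vocabulary also scales with relevance, so a noise vocabulary contains
  no disease-informative terms and cannot pick up signal leaking from
  other views' tokens;
* labeled genes additionally mix in one private "interest" topic (70%
  disease / 30% interest within the topic tokens), so a held-out disease
  gene is not trivially closest to its disease model and candidate genes
  with their own literature can outrank it — without this the
  leave-one-out task is saturated at zero error;
* a small fraction of labeled genes (default 5%) carries two disease
  labels, exercising the overlap-removal step of the pairwise protocol;
* vocabularies are drawn from shared pools sized so that two views share
  roughly `overlap_frac` of their terms;
* document counts per gene are `1 + Poisson(docs_per_gene - 1)` and
  block lengths `Poisson(doc_length)` (default 50) per view.

Everything is a pure function of the configuration and the seed. The
generator emulates the *structure* of literature profiles — overlapping
vocabularies of different relevance, disease-topic signal diluted by
per-gene idiosyncrasy, a labeled multi-disease benchmark with candidates
drawn from unlabeled genes. It does not emulate real abstracts' Zipfian
token statistics, citation-driven document counts, term correlation
within ontology branches, or annotation noise in gene-document links.
Passing tests therefore demonstrate that the algorithms behave as
specified under controlled conditions, not that any particular error rate
will transfer to real corpora.

## Study conditions used by the test suite

The multi-view gain checks run on a fixed synthetic condition chosen once:
10 diseases of 20 genes, nine views of which five are relevant
(`relevance = 0.8`, a realistic mix of on-topic and background text) and
four are pure noise, vocabularies of 100 terms, 300 unlabeled candidate
genes, 99-candidate leave-one-out test sets with 10 repetitions, and 20
generator seeds. Under those conditions the uniform one-class-SVM fusion
is compared against the best single view by a paired t-test across seeds,
and ward-linkage fusion, EACAL, and OKKC (`mu_min = 0`) are required to
stay within 0.02 Rand-index points of the best single view. Smaller
instances (two to four diseases, 40-60 term vocabularies) back the
per-module properties, keeping the default suite a few minutes long.

## Numerical choices

* Ties in rankings break by ascending candidate id; AUC uses midranks —
  both deterministic and unbiased.
* Kernels are PSD by construction (Gram of centered features, then
  symmetrized); the fusion optimizer still validates training submatrices
  (minimum eigenvalue above `-1e-8`) unless `check = FALSE` in tight
  loops.
* The inner QP stops when the iterate moves less than `1e-9`; squared
  distances in `hilbert_distance()` may dip to `-1e-8` from rounding and
  are clipped at zero, anything lower is an error.
* Zero-document genes keep all-zero profiles, are flagged, and are
  excluded from training sets (they may still appear as candidates);
  all-zero training sets raise an error.
* `calibrate_q()` requires at least 10^4 samples and clips Q values away
  from the beta boundary by `1e-10` before fitting.
* Candidate draws, K-means restarts, and kernel K-means initializations
  derive per-task seeds from the user seed, so every report is exactly
  reproducible.

## Known limitations

* The supergradient search for `mu` (when `0 <= mu_min < 1/N`) is a
  first-order method: weights are feasible to machine precision but the
  optimum is located to modest accuracy; the uniform case is exact.
* MCLA's greedy Jaccard merging and the spectral stand-ins for
  METIS/hMETIS are faithful in spirit, not in implementation, to the
  original graph heuristics.
* Soft or overlapping clustering, internal validity indices, and the
  semi-infinite reformulation of the fusion program are out of scope.
* The generator's documents are bags of independent tokens; conclusions
  about absolute error rates on real literature require real corpora.
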