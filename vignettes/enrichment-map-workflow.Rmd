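---
title: "From two-class RNA-Seq counts to a clustered enrichment map"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From two-class RNA-Seq counts to a clustered enrichment map}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

Pathway enrichment analysis asks whether the genes that separate two
biological conditions concentrate in known functional gene sets. An
*enrichment map* summarizes the answer as a network: nodes are gene sets
that pass a significance filter, edges connect sets that share many member
genes, and clusters of connected nodes expose redundant pathway themes that
would otherwise be read as hundreds of overlapping rows in a result table.

`enrichmapr` implements the full desk-scale path from a two-class RNA-Seq
count matrix (or a pre-ranked gene list) plus a GMT gene-set database to
such a clustered network, with every stage exposed as an ordinary R
function and a thin command-line wrapper on top. This vignette records the
models, the parameters that matter, the numerical choices, and the known
limitations.

# The processing model, stage by stage

## Low-count filtering

Genes with too few reads carry no usable signal and inflate the multiple
testing burden. A gene is kept when (a) at least `n` samples reach a
counts-per-million (CPM) cutoff equivalent to `min_count` (default 10)
reads at the *median* library size, where `n` is the size of the smaller
class (damped toward `large_n + (n - large_n) * min_prop` when the smaller
class exceeds `large_n = 10` samples), and (b) its total count reaches
`min_total_count` (default 15). These are the published defaults of the
widely used `filterByExpr` rule; our implementation reproduces edgeR's
survivor sets exactly on random fixtures (see the test suite).

## TMM normalization

Sequencing depth alone does not make samples comparable: if a few highly
expressed transcripts dominate one library, every other gene's share
shrinks (composition bias). The trimmed mean of M-values (TMM) estimates a
per-sample scaling factor from pairwise log2 count ratios against a
reference sample (the one whose upper-quartile count fraction is closest to
the sample average). Per gene, with counts $y_{gj}$ and library sizes
$N_j$:

$$M_g = \log_2 \frac{y_{gO}/N_O}{y_{gR}/N_R}, \qquad
  A_g = \tfrac12\left(\log_2 \frac{y_{gO}}{N_O} + \log_2 \frac{y_{gR}}{N_R}\right)$$

After removing infinite values, the most extreme 30% of $M$ and 5% of $A$
(both two-sided) are trimmed, and the factor is
$2^{\sum w_g M_g / \sum w_g}$ with inverse asymptotic binomial variance
weights $w_g^{-1} = (N_O - y_{gO})/(N_O y_{gO}) + (N_R - y_{gR})/(N_R y_{gR})$.
Factors are rescaled to geometric mean 1. Our factors agree with
`edgeR::calcNormFactors` to machine precision on test fixtures. One
subtlety worth recording: rescaling a single column by a constant changes
that column's precision weights relative to the reference half of each
weight, so the factors are only *approximately* invariant to per-column
rescaling (within a couple of percent on small fixtures) — a property of
the TMM definition itself, not of this implementation.

## Dispersion and the exact test

Counts are modeled as negative binomial with $\mathrm{Var}(Y) = \mu +
\phi\mu^2$. With three samples per class there is no information to
estimate per-gene dispersions, so a single common $\phi$ is estimated by
maximizing the conditional ("quantile-adjusted") likelihood pooled across
genes: library sizes are first equalized by mapping each count to the
common (geometric-mean) library size through a quantile-to-quantile NB
transformation (averaging a normal and a gamma approximation), and the
likelihood of each class's counts conditional on their sum,

$$\ell_g(\phi) = \sum_j \log\Gamma(y_{gj} + \phi^{-1})
  - n\log\Gamma(\phi^{-1}) + \log\Gamma(n\phi^{-1})
  - \log\Gamma\!\left(\textstyle\sum_j y_{gj} + n\phi^{-1}\right),$$

is summed over genes and maximized by bounded one-dimensional search on
$[10^{-6}, 4]$ (tolerance $10^{-6}$), alternated twice with pseudo-count
recomputation. The bounds cover realistic bulk RNA-Seq; the procedure is
deterministic. On simulated data the estimate recovers the generating
dispersion (e.g. 0.200 at truth 0.2 with 2000 genes) and returns the lower
bound when replicates are identical.

Differential expression then uses the classic conditional exact test.
Conditional on a gene's total pseudo-count $z = z_1 + z_2$, the class-1 sum
follows a beta-binomial with shapes $n_1/\phi$ and $n_2/\phi$; the
two-sided p-value doubles the smaller tail (observed point included) and is
capped at 1. Totals above 900 use the limiting beta approximation with a
0.5 continuity correction; $\phi < 10^{-8}$ reduces to the binomial split.
Group sums are rounded to integers after equalization. Two implementation
details guarantee exact symmetry under swapping the class labels: the two
tails are summed as bitwise mirror images, and the normalizing constant is
assembled in a commutative order. Empirical type-I error at nominal 0.05 is
0.049-0.057 across dispersions 0.05-0.5 in the test suite.

## Rank scores

Genes are ranked by a signed significance score
$s_g = \mathrm{sign}(\widehat{\mathrm{logFC}}_g)\,(-\log_{10} p_g)$, with
the p-value floored at $10^{-300}$ (so scores stay finite) and a zero fold
change mapping to score 0. Fold changes come from class-mean CPMs with a
prior count of 0.5 per sample (scaled to effective library size) to avoid
logs of zero. Exact score ties order lexicographically by gene identifier,
making every downstream result deterministic. A pre-ranked RNK file can
replace this whole stage — the entry point for designs the internal test
does not support (covariates, batch effects, single replicates).

## Preranked GSEA

For a ranked list of $N$ genes and a set with $n$ members in the list, a
running sum is walked down the list: an in-set gene ("hit") at rank $i$
adds $|s_i|^p / \sum_{\text{hits}} |s|^p$ (uniform increments if that sum
is zero), an out-of-set gene subtracts $1/(N - n)$. The enrichment score
(ES) is the running-sum value of maximal absolute deviation from zero; the
positive branch wins magnitude ties (compared with a $10^{-12}$ relative
tolerance so exact rational ties cannot be flipped by summation-order
rounding). The leading edge is the hits at or before the positive extremum
(at or after it for negative ES). Default weight exponent $p = 1$.

The null distribution samples `n_permutations` same-size gene sets
uniformly without replacement from the ranked universe (a compiled kernel;
reproducible from the seed, and shared across all sets of equal size —
statistically free under gene sampling and a large speedup). Then

$$\mathrm{NES} = \frac{\mathrm{ES}}{\mathrm{mean}\,|\mathrm{ES}^\ast_{\text{same sign}}|},
\qquad
p = \frac{1 + \#\{|\mathrm{ES}^\ast_{\text{same sign}}| \ge |\mathrm{ES}|\}}
         {1 + \#\{\mathrm{ES}^\ast_{\text{same sign}}\}},$$

with $\mathrm{ES} = 0 \Rightarrow \mathrm{NES} = 0,\ p = 1$, and a
flagged $p = 1$ when no null value shares the observed sign. q-values are
Benjamini-Hochberg across all tested sets. Sets are first restricted to
the universe and kept when the restricted size lies in
`[min_set_size, max_set_size]` (defaults 15 and 500, common practice for
genome-scale databases).

**Resolution caveat.** The add-one estimator cannot produce
$p < 1/(n_{\text{same sign}} + 1)$, and BH multiplies the smallest
p-values by roughly $m/k$ (sets tested over sets at the floor). With
$10^5$ permutations and ~200 sets, the smallest reachable q-value is
about $5 \times 10^{-4}$. A q-filter at $10^{-4}$ — the convention for
large curated databases analyzed with analytic/adaptive GSEA
implementations whose p-values go far below the sampling floor — therefore
needs several million permutations here. `run_pipeline()` warns when the
configured filter is finer than the estimator's resolution; for
permutation-based runs at moderate depth we use and recommend a q cutoff
of 0.01 together with the rank ordering of the results.

## Network, clustering, labels

Sets with $q \le$ `q_max` become nodes (inclusive boundary). For every
unordered pair, similarity is the Jaccard coefficient
$|A \cap B| / |A \cup B|$ computed on members restricted to the ranked
universe (so node sizes and edge overlaps refer to the same gene space;
configurable), and an edge is drawn when similarity $\ge$ `similarity_min`
(default 0.5, inclusive). Node and edge order is lexicographic, so
construction is deterministic.

Clusters default to connected components of the thresholded graph — the
minimal faithful reading of "groups of highly overlapping sets", and
parameter-free. Greedy modularity communities (on similarity weights) are
available for dense graphs where components merge through chains. Cluster
ids are assigned by decreasing size with lexicographic tie-breaks, and each
cluster is labeled by the three most frequent words of its member set names
after tokenization, lowercasing, and removal of a fixed shipped stopword
list (function words plus generic nomenclature filler such as "pathway";
informative words like "regulation" or gene symbols are kept). A singleton
keeps its own name truncated to 60 characters. The labeler is a
deterministic, shipped-list analogue of the word-cloud annotation idea;
bubble/hull rendering is out of scope — cluster membership is exported so
any drawing tool can add geometry.

# The synthetic-data generator

`simulate_counts()` draws log-normal relative abundances (sdlog 1.2, a
realistic spread of bulk expression), library sizes uniform in
`c(8e5, 1.2e6)` (desk-scale libraries keep per-gene totals in the exact
test's fast range while preserving count granularity), and NB counts with
the same mean/dispersion parameterization the test assumes. A fraction
`de_fraction = 0.1` of genes receives a $\pm$`lfc` (default 2) fold change
in class B with balanced signs and *no renormalization* — so the matrix
carries genuine composition bias for TMM to correct. `simulate_genesets()`
plants (a) enriched sets drawing at least 60% of members from same-sign DE
genes, (b) decoys drawn uniformly from non-DE genes, and (c) overlapping
groups built by perturbing only the background members of a seed set, so
within-group Jaccard stays above `intra_overlap` while every variant keeps
the full DE complement; constraints are checked post hoc with bounded
retries. Everything is byte-reproducible from the seed.

What the generator deliberately does **not** emulate: gene length and GC
effects, correlated genes, outlier samples, batch structure, single-cell
zero inflation, and annotation bias in real GMT databases. Passing tests
therefore demonstrate correctness of the computations and recoverability
under the stated model — not performance on any particular real data set.

# Numerical and design choices

- **Exact test over quasi-likelihood GLMs:** the supported design is
  exactly two classes with no covariates, where the conditional exact test
  with a common qCML dispersion is self-contained and deterministic;
  tagwise/trended dispersion and GLM designs are out of scope.
- **p-value floor** $10^{-300}$ before $-\log_{10}$; **prior count** 0.5
  per sample for fold changes; **pseudo-count rounding** before the
  conditional test; **beta approximation** above totals of 900.
- **Tie-breaking:** rank-score ties lexicographic; ES magnitude ties
  positive (with a $10^{-12}$ relative guard); cluster-id ties by smallest
  member name. No stage consults global random state — seeds are explicit
  parameters.
- **Boundary conventions:** `q_value <= q_max` keeps a node,
  `similarity >= similarity_min` draws an edge (both inclusive).
- **Problem sizes in the shipped tests:** ES oracle checks at $N \le 50$;
  calibration at 2000 genes; end-to-end recovery at 10,000 genes,
  $3{+}3$ samples, $10^5$ permutations, ten seeds. These sizes make the
  whole suite run in about a minute on one core while keeping Monte-Carlo
  error well inside the asserted tolerances.

# Limitations

Two classes, one organism's symbol conventions (uppercase HGNC; Ensembl IDs
pass through with version suffixes stripped), no batch correction or
outlier handling (prepare a custom RNK upstream if needed), gene-sampling
permutations only (no phenotype permutation), and BH on nominal p-values
rather than the classic NES-histogram FDR. The permutation-resolution
caveat above is the practical constraint to keep in mind when filtering at
very small q.
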