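---
title: "Methods: multi-omics integration with interomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omics integration with interomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(interomics)
```

# Scope

`interomics` implements the statistical core of a time-course multi-omics
integration study of cytokine-stimulated human beta cells: chromatin
accessibility (ATAC-seq peak calls), transcription (RNA-seq) and translation
(proteomics) are compared and integrated through five analyses:

1. **Rank-rank hypergeometric overlap (RRHO)** between two log2FC-ranked
   gene lists;
2. **open-chromatin-to-gene linkage** through TSS-centred windows, with
   frequency, intensity and enrichment statistics;
3. **weighted co-expression module detection** per omics layer with a
   resampling-based module quality Z score;
4. **cross-layer module matching** between mRNA and protein modules;
5. **background-network analysis**: connector-node enrichment on
   protein-protein interaction (PPI) or gene-regulatory (GRN) networks and
   clique-based overlapping community detection.

Upstream processing (alignment, peak calling, quantification, differential
model fitting) is out of scope; differential tables, peak BED files,
expression matrices and edge lists are the package's inputs. A synthetic
data module generates all of these with known planted structure so that
every stage has a ground-truth recovery test.

# The statistics

## Hypergeometric enrichment tail

Every enrichment question in the pipeline (overlap of two ranked prefixes,
shared members of two modules, edges from a node into a module) reduces to
the upper hypergeometric tail
$$P(X \ge k), \qquad X \sim \mathrm{Hypergeom}(N, K, n),$$
the probability of at least $k$ successes when drawing $n$ items without
replacement from a universe of $N$ containing $K$ successes.
`hypergeom_tail()` evaluates it through `stats::phyper()` in log space, so
tails far below the double-precision underflow threshold remain usable; the
$-\log_{10}$ companion is capped at 320 purely as numeric hygiene. The unit
and acceptance suites check the tail against exhaustive subset enumeration
for every parameter combination with $N \le 12$.

## RRHO

Both differential tables are reduced to their common gene universe (size
$N$) and ranked by signed log2FC, ties broken lexicographically by feature
id so the order is reproducible. For every pair of rank thresholds
$(i, j)$ on a regular grid of step $s$ the overlap
$k_{ij} = |\mathrm{top}_i(A) \cap \mathrm{top}_j(B)|$ is scored by the
hypergeometric tail with parameters $(k_{ij}, N, i, j)$. The default step
$s = \max(1, \lfloor N/100 \rfloor)$ bounds the grid at roughly
$100 \times 100$ cells. Because each gene contributes to all cells beyond
its rank pair, the $k$ matrix is a 2-d cumulative sum of a binned rank
histogram — cost $O(N + \text{cells})$, not $O(N \cdot \text{cells})$.

Multiple testing across all cells jointly uses the Benjamini–Yekutieli
step-up procedure, which is valid under the strong positive dependence of
neighbouring cells. Only enrichment (the upper tail) is scored; the
signed four-quadrant RRHO variant is out of scope.

The shared signature of two lists (`shared_top_signature()`) grows both
prefixes in lock-step and collects genes the moment they have appeared in
both, stopping at `n_top` genes; output order is by mean rank. This is
the operation behind top-$n$ shared-signature extraction for downstream
queries (e.g. perturbagen databases).

## Peak-to-gene linkage

A peak (BED convention, 0-based half-open) is linked to a gene when it
overlaps the window $[\mathrm{TSS} - w/2,\ \mathrm{TSS} + w/2)$ by at least
one base pair; $w$ defaults to 40 kb ("within 20 kb of the TSS"). Overlap
uses an interval index (`IRanges::findOverlaps`); a brute-force all-pairs
oracle verifies it, including the half-open boundary cases, in the test
suite. A peak may link to several genes and counts once per gene; the
one-bp-overlap rule is the most permissive reading consistent with a
distance threshold, and the `by` argument of `status_frequency_by_links()`
exposes both "any gained peak" and "count of gained peaks" stratifications
since either could underlie a per-gene frequency figure.

Downstream statistics:

* **status frequencies** per linkage stratum (0, 1, 2, ≥3 gained peaks);
* **effect by gained-peak count** with a Jonckheere–Terpstra-style
  monotone-trend statistic whose null is obtained by seeded label
  permutation (default 10,000 permutations) — permutation rather than the
  asymptotic normal approximation because strata are small and tied;
* **gained-peak enrichment in a module** by a one-sided chi-squared test on
  the 2x2 table (in/out module) x (has/has-no gained peak), no continuity
  correction; the one-sided p is half the two-sided p in the enrichment
  direction and its complement otherwise, so direction flips p around 0.5.
  Degenerate margins raise an error suggesting Fisher's exact test.

The mRNA-protein concordance uses the default category thresholds
(|log2FC| > 0.58 strictly, FDR < 0.05 for mRNA and < 0.15 for protein) and
reports Pearson $r^2$ within the mRNA-up and mRNA-down categories.

## Co-expression modules

The network is unsigned and weighted: $a_{ij} = |\mathrm{cor}(x_i, x_j)|^
\beta$ with Pearson correlation and soft power $\beta$ (10 for RNA, 14 for
the within-group standardised protein layer by default; signedness and
powers are configuration inputs). The topological overlap matrix is
$$\mathrm{TOM}_{ij} = \frac{\sum_{u \ne i,j} a_{iu} a_{uj} + a_{ij}}
  {\min(k_i, k_j) + 1 - a_{ij}}, \qquad k_i = \sum_{u \ne i} a_{iu},$$
with $\mathrm{TOM}_{ii} = 1$, computed by matrix products and verified
against the literal triple sum to $10^{-12}$.

Modules come from average-linkage hierarchical clustering on
$1 - \mathrm{TOM}$ with a **static cut** — deliberately simpler than the
dynamic tree cut algorithm, deterministic and directly testable; a hook for
alternative cutters is the `cut_height` argument itself. Clusters below
`min_module_size` (20) stay unassigned (label 0). The default cut height is
0.99 for the power-10 RNA network. Because raising the soft power
compresses TOM toward zero, dissimilarities at $\beta = 14$ concentrate
just below 1 and the informative merges happen above 0.99; the pipeline
therefore cuts the protein network at 0.999 (`cut_height_prot`). Both are
exposed in the configuration.

Module eigengenes are the first principal component of the
feature-standardised submatrix, unit variance, sign-oriented to correlate
non-negatively with the mean member profile (the WGCNA convention).
Negating the whole data set therefore negates the eigengene; every
downstream quantity is correlation-based and unaffected. Modules whose
eigengene dissimilarity $1 - \mathrm{cor}$ is below 0.25 are merged
iteratively (closest pair first, eigengenes recomputed after every merge),
so on return no surviving pair sits below the threshold.

**Module quality.** For each module, density (mean intra-module adjacency)
and separability (density minus mean adjacency from members to
non-members) are compared with a resampling null: in each of
`n_resamples` rounds the samples are bootstrapped, the adjacency rebuilt,
and a size-matched random feature set scored.
$Z = (\mathrm{obs} - \mu_0)/\sigma_0$ per statistic and
$Z_\mathrm{summary} = \mathrm{median}(Z_\mathrm{density},
Z_\mathrm{separability})$; values above 2 indicate moderate and above 10
high module quality. The composite uses exactly these two statistics — the
full published preservation battery is intentionally not reproduced. The
default is 100 resamples (desk scale); 1000 suits full-scale
analyses.

## Cross-layer integration

Differentially expressed genes are selected at fold-change > 1.5 (i.e.
$|\mathrm{log2FC}| > \log_2 1.5$, strict) and FDR < 0.05; differentially
abundant proteins at raw t-test p < 0.05 — the asymmetry reflects the
lower replication and higher measurement noise typical of proteomics
layers.
Each (mRNA module, protein module) pair is scored by the hypergeometric
tail of its shared member count on a common universe;
Benjamini–Hochberg FDR is applied across pairs (BH is the conventional
default and the procedure is exposed in config), and
a pair is retained when FDR < 0.05 **and** at least 10 members are shared.
The universe is the union of all module members after id mapping — a
deliberate, conservative choice
(smaller universes make overlap p-values larger, not smaller).
Gene-protein mapping is 1:1 by shared identifier; unmapped features are
dropped with a logged count.

The retained-intron analysis stratifies proteins by the splicing change of
their gene: *removal* ($\Delta\mathrm{PSI} < -0.2$, FDR < 0.05),
*retention* ($\Delta\mathrm{PSI} > 0.2$, FDR < 0.05), *unchanged*
(everything else), and tests group differences of protein log2FC with a
seeded permutation one-way ANOVA on the F statistic.

## Background networks

Networks are first restricted to expressed nodes (mean abundance > 0.5,
e.g. RPKM, in at least one condition, strict). **Connector enrichment**
asks, for each candidate node $v$ with degree $d_v$ (out-degree on
directed regulatory networks) and $k$ neighbours in the module: is $k$
surprisingly large under the hypergeometric null
$(k;\ N-1,\ |M \setminus \{v\}|,\ d_v)$? The hypergeometric
neighbourhood test is the standard formulation of this question and is
exactly verifiable. BH-FDR runs across all tested nodes and admission
requires FDR < 0.01 plus at least 5 (PPI) or 4 (GRN) in-module
connections. Reported thresholds for this step vary between 0.01 and
0.05 in the field; the default is the stricter 0.01 and the
configuration can relax it. Module members themselves are not tested
unless `include_module = TRUE` (default off).

**Communities** follow an EAGLE-style agglomeration: maximal cliques of
size ≥ 6 seed communities; the pair with largest similarity
$|C_1 \cap C_2| / \min(|C_1|, |C_2|)$ merges repeatedly; the dendrogram is
cut where the extended modularity
$$EQ = \frac{1}{2m} \sum_C \sum_{i,j \in C}
  \frac{1}{O_i O_j}\left(A_{ij} - \frac{k_i k_j}{2m}\right)$$
($O_i$ = number of communities containing $i$) is maximal; nodes outside
all large cliques attach to the community they share most edges with
(ties: all tied communities), and communities below size 2 are dropped.
Communities may overlap. Maximal-clique enumeration is exponential in the
worst case, so graphs above 2,000 nodes are rejected — the intended inputs
are module neighbourhoods, not whole interactomes. The min-normalised
overlap similarity is the common choice among clique-agglomeration
variants.

# The synthetic data model

`simulate_multiomics()` draws log-scale Gaussian data rather than counts:
every analysis in scope operates on log2 fold-changes and correlations, so
a count layer would add nuisance parameters without exercising more of the
mathematics. Module members load on a shared per-sample latent factor,
$x = \sqrt{\rho} f + \sqrt{1-\rho}\,\varepsilon$, giving expected pairwise
correlation $\rho$ (`intra_cor`, default 0.8). The design is 2 conditions
(control/treated) x 2 time points (8 h, 24 h) x 10 replicates — 40
samples, the scale at which correlation-based module recovery is reliable.
Treated samples add a per-module, per-time mean shift drawn from
$N(0, \mathrm{effect\_sd}^2)$ with `effect_sd` = 2 log2 units, emulating
strong cytokine induction in which typical responsive modules comfortably
cross the 1.5-fold DEG threshold. The protein layer shares the latent
factors (so protein co-expression modules coincide with the mRNA modules),
scales effects by `protein_attenuation` (0.8) and doubles the decoupling
noise on downregulated modules, reproducing the weaker mRNA-protein
concordance of repressed genes. Differential tables are produced by Welch
t-tests with BH correction — generator-internal scaffolding, not one of
the methods under study.

`simulate_peaks()` places half the peaks uniformly inside TSS windows of
uniformly chosen genes and half on a background contig; window peaks of
upregulated genes are labelled gained with probability `p_gain_near_up`
(0.9) versus `p_gain_background` (0.1) elsewhere. `simulate_ranked_pair()`
plants exactly `n_shared_top` ids in both `top_size` prefixes with
disjoint fillers. `simulate_background_network()` adds planted connector
nodes, each wired to `k_connector` distinct module members, onto an
Erdős–Rényi background.

What the generator does **not** emulate: count noise and library-size
effects, batch structure, missing proteomics values, correlated
peak-width/GC biases, and any real gene identity. Passing recovery tests
therefore demonstrates correctness of the statistics under their own
assumptions, not robustness to the full messiness of real data.

# Numerical and design choices

* Coordinates are BED 0-based half-open everywhere; GTF input is converted
  on read. The TSS of a minus-strand gene is the last base of its
  interval.
* Strict inequalities at every printed threshold (">" means ">").
* Ties in rankings break lexicographically by feature id; all permutation
  tests take explicit seeds; generators restore the caller's RNG state.
* $-\log_{10}$ surfaces are capped at 320.
* The degenerate cases are defined, not accidental: empty peak files warn
  and return empty sets; empty strata yield NaN proportion rows with a
  warning; a zero null standard deviation reports an infinite Z with a
  warning; merging with no qualifying pair is a no-op.

# Problem sizes in the test suite

The suite verifies the hypergeometric tail on the complete $N \le 12$
enumeration grid, TOM on fifty random 10-node networks, linkage on one
hundred random instances against brute force, RRHO null calibration on 200
random list pairs of 1,000 genes, module recovery on twenty seeds of 2-4
planted blocks (40 features each, 40 samples), module quality on ten seeds
at 100 resamples, cross-layer overlap on fifty seeds, and connector
recovery on one hundred 500-node networks. These sizes were chosen so the
whole suite completes in well under a minute per property while keeping
Monte-Carlo acceptance margins meaningful.

# Known limitations

* The static tree cut requires a cut height matched to the soft power; it
  will fragment (or under unusual settings swallow) modules if the two are
  mismatched. Dynamic tree cutting is deliberately out of scope.
* Community detection is exact-clique based and rejects graphs above
  2,000 nodes.
* The module-overlap universe choice (union of module members) is one of
  several defensible definitions; a larger universe (all expressed
  features) would make the p-values smaller.
* An edge-list representation cannot carry isolated nodes; after
  expression restriction the kept node set is reported in an attribute.
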