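# interomics

Integration of time-course multi-omics experiments — chromatin
accessibility (ATAC-seq peak calls), transcription (RNA-seq) and
translation (proteomics) — for studies of stimulus-response in a single
cell system, such as cytokine-treated pancreatic beta cells. The package
is aimed at computational biologists who already have differential tables,
peak calls, expression matrices and background networks, and want the
integration statistics as tested, reusable functions rather than one-off
scripts.

## What it computes

Every enrichment in the pipeline is an upper hypergeometric tail
*P(X ≥ k)*, *X* ~ Hypergeom(*N*, *K*, *n*), evaluated in log space:

* **RRHO** — for two log2FC-ranked gene lists over a common universe of
  size *N*, the overlap *k(i, j)* of every pair of top-*i* / top-*j*
  prefixes on a step grid is scored by the hypergeometric tail and
  corrected across all cells with Benjamini–Yekutieli FDR; a shared
  top-of-list signature (e.g. top 150) is extracted by growing both
  prefixes in lock-step.
* **Peak-to-gene linkage** — a peak links to a gene when it overlaps the
  40 kb window centred on the TSS (BED 0-based half-open, ≥ 1 bp overlap).
  Downstream: status frequencies per gained-peak stratum, a permutation
  trend test of effect size versus gained-peak count, one-sided χ²
  enrichment of gained peaks in a module, and mRNA–protein concordance
  (r² within the up/down categories at |log2FC| > 0.58).
* **Co-expression modules** — unsigned weighted adjacency |cor|^β
  (β = 10 RNA, 14 protein), topological overlap matrix, average-linkage
  clustering with a static cut, eigengene merging at dissimilarity 0.25,
  and a module quality Z_summary (median of density and separability Z
  scores against a column-bootstrap null; > 10 = high quality).
* **Cross-layer module overlap** — DEG (FC > 1.5, FDR < 0.05) and DAP
  (p < 0.05) restricted module pairs scored by the hypergeometric tail
  with BH FDR; retained at FDR < 0.05 and ≥ 10 shared members.
* **Network connectors and communities** — nodes with significantly many
  edges into a module (hypergeometric, FDR < 0.01, ≥ 5 PPI / ≥ 4 GRN
  connections), module networks assembled from members plus admitted
  connectors, and overlapping communities from maximal-clique
  agglomeration cut at maximal extended modularity.

A synthetic-data module (`simulate_multiomics`, `simulate_peaks`,
`simulate_ranked_pair`, `simulate_background_network`) generates all
inputs with planted structure, so each stage has a ground-truth recovery
test. See the methods vignette (`vignettes/interomics-methods.Rmd`) for
the statistical details and design choices.

## Worked example

```r
library(interomics)

sim <- simulate_multiomics(seed = 1)          # 300 genes, 3 planted modules,
                                              # 2 conditions x 2 times x 10 reps
ra  <- rank_by_fold_change(sim$tables$mrna_24h)
rb  <- rank_by_fold_change(sim$tables$protein_24h)
rrho_map(ra, rb)
#> rrho_map: universe 300, step 3, grid 100 x 100
#> max -log10 adjusted p: 40.60

ann   <- synthetic_annotation(rownames(sim$mrna$values))
up    <- sim$tables$mrna_24h$feature_id[sim$tables$mrna_24h$status == "up"]
pk    <- simulate_peaks(ann, up, seed = 2)
links <- link_peaks_to_genes(pk$peaks, ann)
gained_enrichment_chi2(links, up, ann$gene_id)
#> chi2 = 65.6, one-sided p = 2.79e-16

net  <- build_network(sim$mrna, soft_power = 10)
mods <- merge_modules(detect_modules(net, 20, 0.99), sim$mrna)
module_quality(sim$mrna, mods, n_resamples = 100, seed = 1,
               soft_power = 10)[, c("module", "size", "z_summary")]
#>   module size z_summary
#> 1      1   40     81.23
#> 2      2   40     10.98
#> 3      3   40     35.89

mrna_protein_concordance(sim$tables$mrna_24h, sim$tables$protein_24h)$r2["up"]
#>   up
#> 0.74
```

The RRHO map shows a massively significant top-of-list overlap between the
mRNA and protein responses (−log10 adjusted p ≈ 41 at the best threshold
pair), gained open chromatin is strongly enriched near upregulated genes,
all three planted co-expression modules are recovered with high quality
(Z_summary > 10), and induced proteins track their mRNAs (r² = 0.74 in
the upregulated category) — the qualitative signatures the pipeline is
designed to detect.

The whole pipeline also runs end-to-end, writing TSV outputs plus a JSON
manifest (byte-identical across reruns with the same seed):

```r
cfg <- run_config(seed = 1, synthetic = TRUE)
run_pipeline(cfg, "out/")
```

A thin command-line wrapper with subcommands (`simulate`, `rrho`,
`link-ocr`, `modules`, `preserve`, `overlap`, `network`, `run-all`) is
installed at `inst/scripts/interomics-cli.R`.

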