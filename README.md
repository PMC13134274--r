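# follireg3d

Integrative analysis of stage-resolved multi-omics from avian granulosa
cells (GCs). During follicle development — through the ordered stages SWF,
LWF, SYF (prehierarchical), F5, F3, F1 (hierarchical) and POF
(postovulatory) — gene expression is steered by enhancers and
super-enhancers acting inside a largely stable 3D genome whose TAD
boundaries shift at a handful of stage-specific positions. `follireg3d`
implements the statistics needed to map that regulatory landscape from
processed data and to infer a TAD-constrained TF–Enhancer–Target gene
regulatory network, together with a synthetic multi-omics generator that
plants every structure the pipeline is supposed to find, so the whole
analysis is testable end-to-end without any external download.

It is aimed at computational biologists working on stage- or
condition-resolved epigenomes (expression + histone CUT&Tag/ChIP + Hi-C)
who need the individual statistics as reusable functions and the full
pipeline as one reproducible run.

## What it computes

* **Differential expression & specificity.** Per-gene Welch tests on
  log2(x+1) between adjacent stages with BH adjustment (called at
  FDR < 0.05, |log2FC| > 1); Fisher's exact test on DEG proportions;
  k-means (k = 8, k-means++ seeding) on z-scored stage profiles; the tau
  specificity index `tau = sum_i (1 - x_i/x_max) / (n-1)` and Cliff's
  delta `(#{a>b} - #{a<b}) / |A||B|`.
* **Super-enhancers / super-silencers (ROSE).** Peaks stitched across
  gaps ≤ 12.5 kb; regions ranked by summed signal load; the hockey-stick
  cutoff at the point where a slope-1 tangent touches the scaled
  rank–signal curve; stage-specific elements by whole-element
  subtraction; enhancer-count vs expression grouping (Bottom = 1,
  Middle = 10–20, Top ≥ 50).
* **3D genome.** Coverage QC; A/B compartments from the leading
  eigenvector of the O/E Pearson correlation matrix, oriented by gene
  density; insulation-score TAD boundaries (±10-bin window, prominence
  ≥ 0.1 z); a permutation-based stage-specific boundary classifier
  (Spearman correlation of ±200 kb boundary windows against a 1,000-draw
  null); intra-TAD contact strength; multi-resolution loop merging into
  25 kb bins and loop-anchored distal enhancer–gene linking.
* **Regulatory network.** Enhancer–gene Pearson correlation restricted to
  pairs sharing a TAD (BH, FDR < 0.05); log-odds PWM scanning on both
  strands with hypergeometric motif enrichment (raw P < 1e-5); tripartite
  network assembly; stability under random edge removal; a
  degree-preserving permutation test on the TF→gene path count; core-TF
  extraction (motif enriched in dynamic enhancers AND DEG co-clustered
  with ≥ 30% of targets); GWAS-locus → enhancer → gene mapping.
* **Synthetic data.** `simulate_dataset()` plants all of the above —
  archetype expression clusters, SE clusters, TAD blocks with
  stage-specific joints, a compartment checkerboard, loops at three
  resolutions, motif occurrences — and writes a ground-truth manifest
  keyed to every recovery test.

## Worked example

```r
library(follireg3d)

sim <- simulate_dataset(seed = 42)
sim
#> synthetic folliculogenesis dataset | seed 42
#>   600 genes, 500 enhancers, 7 stages, 3 Hi-C stages

d <- call_degs(sim$expression, "SYF", "F5")
sum(d$direction != "ns")
#> [1] 200      # 100 up / 100 down at FDR < 0.05, |log2FC| > 1

se <- call_super_elements(sim$peaks_k27ac$F1)
c(regions = nrow(se), supers = sum(se$is_super))
#> regions  supers
#>     624      13  # cutoff signal 3791.4

b <- call_boundaries(insulation_track(sim$hic$SYF$chr1))
nrow(b)
#> [1] 23          # TAD boundaries on chr1 in SYF

res <- run_pipeline(sim, default_run_params(seed = 7))
res$grn
#> reg_network: 5 TFs, 72 enhancers, 90 genes | 57 TF->E edges,
#>   98 E->G edges, 64 TF->gene paths
res$core_tfs$tf[res$core_tfs$core]
#> [1] "gene_154" "gene_203" "gene_228" "gene_418" "gene_439"

evaluate_recovery(sim, res)[c("boundary_sensitivity",
                              "compartment_accuracy", "grn_path_f1")]
#> $boundary_sensitivity [1] 1
#> $compartment_accuracy [1] 0.991
#> $grn_path_f1          [1] 0.92
```

The 200 DEGs are the planted archetype switches between SYF and F5; the
13 F1 supers are the 10 shared + 2 F1-specific planted SE clusters (plus
one borderline region above the tangent cutoff); the recovery block at
the end scores the pipeline's calls against the generator's manifest —
all 12 planted stage-specific boundaries flagged, 99.1% of bins assigned
to their planted compartment, and the planted TF→Enhancer→Gene paths
recovered at F1 = 0.92.

A thin command-line wrapper over the same functions ships in
`inst/cli/follireg3d.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","follireg3d.R",
                            package="follireg3d"))')" \
  simulate --seed 42 --out data/
```

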