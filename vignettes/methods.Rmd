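---
title: "Methods: regulatory-landscape and 3D-genome statistics in follireg3d"
author: "follireg3d authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regulatory-landscape and 3D-genome statistics in follireg3d}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model of the data

`follireg3d` analyses stage-resolved multi-omics of avian granulosa cells
(GCs) across the seven ordered follicle stages SWF, LWF, SYF, F5, F3, F1,
POF: replicate expression matrices, per-stage H3K27ac/H3K27me3 elements
with signal, binned cis Hi-C contact matrices at three stages (SYF, F5,
F1), multi-resolution chromatin-loop calls, enhancer sequences and TF
position weight matrices, and GWAS loci. All coordinates are 0-based
half-open throughout; strand is carried but ignored for regulatory
elements. Contact matrices are per-chromosome and cis-only — every
statistic computed here is a cis statistic.

The package is organised as a toolbox of stage functions plus one
orchestrator, `run_pipeline()`, and a synthetic-data generator,
`simulate_dataset()`, that emits a complete dataset with a planted-truth
manifest. The generator is first-class, tested code: every recovery claim
the test suite makes is a claim about these planted conditions, not about
any real dataset.

## Differential expression and specificity statistics

Differential expression between adjacent stages uses a per-gene Welch
two-sample t-test on log2(x + 1) replicate values with Benjamini–Hochberg
adjustment across all genes; a gene is called when FDR < 0.05 and
|log2FC| > 1, with the fold change computed on stage means after a
pseudocount of 1 (so fully-off stages are admissible). A
negative-binomial GLM would be the tool of choice on raw counts; the
package consumes pre-normalised abundances, for which the Welch test on
the log scale is a standard, calibrated choice — the suite verifies that
the null FDR stays at its nominal level. The threshold is strict (`>`) by
default with an `lfc_strict` switch, since both conventions circulate.

Expression clustering z-scores per-gene stage means (a zero-variance
guard sets sigma to 1) and runs k-means with k-means++ seeding, best of
`restarts` runs by within-cluster sum of squares, k = 8 by default,
deterministic under the mandatory seed.

Stage specificity uses the tau index on log2(x + 1) stage means,
tau = sum_i (1 − x_i / x_max) / (n − 1): 0 for flat profiles, 1 for
single-stage expression, with all-zero profiles mapped to 0 by
convention. Tau is the standard specificity index; nothing in the
analysis depends on the choice among the common variants. Effect sizes
between groups use Cliff's delta, the normalised count of concordant
minus discordant cross pairs.

## Super-enhancer and super-silencer calling

Element calling re-implements the ROSE procedure without alignments.
Peaks with region-mean signal are stitched transitively whenever gaps are
at most 12.5 kb (the ROSE default); optional TSS exclusion removes peaks
fully inside a ±`tss_exclusion` window before stitching (off by default —
the upstream convention varies and the inputs here are already distal
elements). Region signal is the summed constituent load, width × mean
signal, which stands in for ROSE's read counts. Regions are sorted by
ascending signal, both axes rescaled to [0, 1], and the cutoff placed at
the point lying furthest below the diagonal — equivalently, where a
slope-1 tangent touches the ranked-signal curve. Regions strictly above
the cutoff signal are super; ties break toward fewer supers, and
all-equal signals yield zero supers with a warning. The same machinery on
H3K27me3 yields super-silencers. The tangent construction is invariant
under affine rescaling of the signals (and the suite asserts this);
it is *not* invariant under arbitrary nonlinear monotone transforms,
which change the curve's shape — a known property of the rule, not a
defect of the implementation.

Stage-specific elements are whole elements unique to a stage: an element
survives when it has no ≥1 bp overlap with any other stage's set.
Elements are never clipped.

## Hi-C statistics

**Balancing.** `balance_matrix()` applies simple iterative proportional
scaling (20 iterations, tolerance 1e-5 on the coefficient of variation of
non-empty row sums). Compartment eigenvectors and intra-TAD strengths are
computed on balanced matrices.

**Insulation and boundaries.** The insulation score of a bin is the mean
of the `window_bins` × `window_bins` square of contacts spanning it
(10 bins = ±200 kb at 20 kb), as log2 ratio to the chromosome mean,
z-scored; edge bins are NA. Boundaries are local minima with prominence
≥ 0.1 z units (plateaus report their leftmost bin). The pipeline computes
insulation on **raw** counts: the score is already a within/around
coverage ratio, and iterative balancing of strongly block-enriched
matrices — by forcing equal row sums — imprints a shallow artifactual dip
(~0.1 z) at the centre of large TADs which the prominence threshold would
then call. On data without technical coverage bias (the synthetic
matrices here), raw-count insulation is the faithful choice;
`insulation_track()` accepts either and the choice is a single argument
in the pipeline.

**Stage-specific boundaries.** To compare boundaries between stages the
classifier extracts the insulation values of the 10 bins upstream and
downstream of each boundary and computes the Spearman correlation of the
two stages' windows; a null distribution is built from 1,000 windows at
uniformly sampled bins. A boundary is stage-specific iff (1) no boundary
of any adjacent stage lies within ±1 bin, and (2) its correlation with
every adjacent stage's track does not exceed that pair's null 95th
percentile. Two conventions had to be fixed: the window "signal" is the
insulation value (the natural per-bin summary of local structure), and
criterion 2 must hold against *all* adjacent stages. In practice the null
of window correlations between two stages of the same genome is
concentrated near 1 (windows share the global TAD landscape), so the 95th
percentile is high and criterion 2 acts as a guard against gross
mismatches while criterion 1 carries most of the discrimination — the
classifier's operating characteristics are therefore measured end-to-end
(sensitivity and false-flag rate against planted truth) rather than
criterion by criterion.

**Compartments.** Observed/expected normalisation by diagonal means over
informative (non-empty) bins, Pearson correlation matrix, leading
eigenvector; the sign is oriented so bins positively correlated with a
gene-density (or mean-expression) track are "A". Empty bins are NA. The
statistic is invariant to global matrix scaling.

**Intra-TAD strength** is the mean balanced contact among a TAD's bins
excluding the diagonal (NA below 2 bins); cross-stage comparisons are
two-sample tests on per-TAD values.

**Loops.** Loop calls from several resolutions are merged by re-binning
each anchor midpoint to 25 kb and collapsing identical re-binned loops,
keeping the maximum score — a deterministic rule that is idempotent by
construction. Distal enhancer–gene links require one anchor to overlap an
enhancer and the other a promoter (TSS ± 2 kb) by ≥1 bp; features on a
single anchor never link. Because merged anchors are 25 kb wide, a true
loop can legitimately link additional features that share its anchors;
the generator therefore validates the linker with decoy loops whose
anchors are kept clear of enhancers and promoters (they must produce
nothing) rather than by forbidding shared anchors.

## Regulatory-network inference

Enhancer–gene pairs are tested only within TADs: every pair whose
enhancer midpoint and gene TSS share a TAD is scored by the Pearson
correlation of per-stage activity (all 7 stages by default — the three
Hi-C stages give only 3 points, far too few for a correlation test),
p-values from the exact t transform with n − 2 df, BH-adjusted across all
tested pairs genome-wide, retained at FDR < 0.05. Constant profiles are
skipped and counted. With n = 7 stages the test is deliberately
low-powered per pair; the planted-truth recovery targets account for
that.

Motif analysis scans log-odds PWM scores against the background at every
position on both strands, calling hits at ≥ 0.8 of the maximum achievable
score (N windows skipped). Enrichment binarises sequences (≥1 hit) and
applies a one-sided hypergeometric test of hit-bearing target sequences
against the pooled target + background universe at raw P < 1e-5 —
uncorrected because the upstream convention quotes a raw threshold.
Enriched TFs contribute TF–enhancer pairs for each hit-bearing target
sequence; the pipeline's targets are the enhancers that entered
significant enhancer–gene pairs, with all remaining enhancers as
background.

The tripartite network joins TF→enhancer and enhancer→gene layers;
TF→gene paths exist iff some enhancer connects both. Two statistics
summarise robustness:

* **Stability** — per trial, remove ⌊0.1 E⌋ of the pooled edges uniformly
  at random (100 trials); the score is the mean fraction of original
  TF→gene paths still connected through some surviving route. The score
  is 1 in the zero-removal limit and non-increasing in the removal
  fraction.
* **Permutation test** — null networks by degree-preserving double-edge
  swaps within each bipartite layer (10 × E attempted swaps per layer),
  statistic = number of distinct TF→gene paths,
  p = (1 + #{null ≥ observed}) / (n_perm + 1). Degree preservation is
  asserted in every replicate. On networks where each enhancer carries
  one TF and one gene the null preserves the path count exactly and the
  p-value is uninformative (≈1) — this is the case for the generator's
  deliberately clean planted circuit, and the run reports it as such.
  The test's calibration (approximately uniform p on random bipartite
  graphs) and power (small p when TF edges concentrate on gene-rich
  enhancers while the layer also contains gene-poor enhancers) are
  demonstrated on dedicated fixtures in the suite.

Core TFs satisfy two criteria: (1) motif enrichment (raw P < 1e-5) in
dynamic enhancers — enhancers gained or lost between some adjacent stage
pair — against the remaining enhancers; and (2) the TF is a DEG in at
least one adjacent contrast *and* at least `co_min = 0.3` of its targets
share its expression cluster. The 0.3 floor is a package default (no
upstream value exists); it is configurable. GWAS loci map to genes by
locus→enhancer overlap followed by the enhancer's link table.

## The synthetic generator and what it does (not) emulate

`simulate_dataset()` draws everything from one master seed through named
substreams (genome, expression, elements, hic, loops, sequences, gwas),
so regeneration is byte-identical and layers can be re-drawn
independently. Default conditions: 2 chromosomes × 10 Mb at 20 kb bins;
7 stages × 4 expression replicates; Hi-C at SYF/F5/F1; 600 genes with 8
stage-profile archetypes (50 genes each, log-normal noise sigma 0.3 on
the log2 scale) plus flat background genes; 500 enhancers (60 proximal
targets of 5 core TFs, 30 distal loop-linked, 410 decoys) with per-stage
activity profiles (noise sigma 0.15); per-stage peak sets with 10 shared
and 2-per-stage specific super-enhancer clusters of ≥4 high-signal
constituents inside 25 kb; Poisson contact matrices built as distance
decay (exponent 1) × 3-fold within-TAD enrichment × 1.5-fold
same-compartment checkerboard, with 2 stage-specific boundaries per
Hi-C stage per chromosome planted off-centre inside large interior TADs;
loops at 10/20/25 kb duplicating 30 true links plus 60 decoys; 500 bp
enhancer sequences with planted 10-bp consensus occurrences for core TFs
(decoy TF motifs appear at background rates); 40 GWAS loci, 12 inside
linked enhancers. Three placement rules keep the planted truth
well-defined rather than tuning any statistic: specific boundaries avoid
TAD centres and terminal TADs (centre positions collide with the
balancing artifact described above; terminal TADs sit in the insulation
NA edge), TF targets prefer archetype genes without a same-archetype
neighbour in their TAD cell (otherwise the enhancer genuinely correlates
with two genes and "the" true path set is ambiguous), and decoy-loop
anchors stay clear of enhancers/promoters at the merge resolution.

The generator emulates processed-level data only. It does not emulate:
read-level artifacts (mapping, duplication, peak-calling noise),
inter-stage normalisation problems (inputs are comparably scaled by
construction), realistic genome sequence composition, trans contacts, or
biological coupling beyond what is planted. Passing recovery tests
therefore demonstrates that the statistical machinery recovers known
structure under the stated noise — not that it would perform identically
on real sequencing data.

## Numerical choices and degenerate inputs

Ties in the ROSE cutoff break toward fewer supers; plateau insulation
minima report their leftmost bin; boundary windows require ≥11 valid
pairs (NA otherwise, with a warning); zero-variance genes are z-score
guarded; constant correlation profiles are skipped and counted; all-zero
tau profiles return 0; `rank_and_cut` warns and calls nothing on
all-equal signals; degenerate (all-empty) contact matrices error.
Balancing runs 20 iterations at tolerance 1e-5. Problem sizes in the
suite — 500-bin chromosomes, ≤500-record oracle instances, 1,000-draw
boundary nulls, 60–300-replicate network permutations — were chosen so
the full suite exercises every claim at comfortable desk scale.

## Known limitations

The Welch-on-log substitute is not a count model; tau is one of several
specificity indices; the stability score and permutation statistic are
reasonable formalisations of informally described procedures, not
reconstructions; criterion 2 of the boundary classifier has little
discriminating power when stages share most structure; and the
permutation test is blind to circuits whose path count is
degree-determined. Each of these is surfaced in the API or the reports
rather than hidden.
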