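---
title: "Methods: nutrient-stress differential expression and stress-memory analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nutrient-stress differential expression and stress-memory analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The experiment this pipeline analyses

Hydroponically grown plants of two tissues (leaf, root) are exposed to iron
(-Fe) or phosphate (-Pi) deficiency in a four-timepoint design: an early
stress (T1, 24 h), recovery (T1Rec, 48 h back in full nutrients), a repeated
stress (T1T2, a second 24 h exposure of previously stressed plants), and a
late single stress (T2, a first 24 h exposure of previously unstressed
plants of the same age as T1T2). Controls are harvested alongside at T1,
T1Rec and at the final harvest, giving 11 groups per tissue; with three
biological replicates this is 66 RNA-seq libraries. Every stress group is
contrasted against the control of the same harvest age, so T1T2 and T2 both
reference the late control (the reference timepoint is configurable through
`contrast_spec(control_timepoint = )`, since designs differ in whether a
separate repeated-stress control is grown).

The scientific payoff of the design is the T1T2 vs T2 comparison: both
groups are the same age and currently stressed; they differ only in whether
they were stressed before. Genes that respond differently are
*stress-memory genes*, in two classes:

* **opposite**: significant at both T1T2 and T2 with opposite direction of
  expression;
* **T1T2-unique**: significant at T1T2 and at no other timepoint of that
  stress and tissue — differential expression that requires a prior
  exposure. A looser variant (`mode = "t1_only"`, requiring only
  non-significance at T1) is available because "not differentially expressed
  in response to an initial stress exposure" admits both readings; the
  default excludes all three other timepoints, the stricter reading of
  "unique". The two classes are disjoint by construction and this is
  asserted on every run.

## Differential expression model

Counts for gene $g$ in sample $j$ are modelled as negative binomial with
mean $s_j \mu_g$ and dispersion $\alpha_g$, variance
$\mu + \alpha \mu^2$. The stages are:

**Size factors** (`size_factors`) use the median-of-ratios estimator:
$s_j = \mathrm{median}_g \; k_{gj} / (\prod_{j'} k_{gj'})^{1/m}$ over genes
with a positive geometric mean. No post-hoc rescaling is applied; only
factor ratios are meaningful.

**Replicate QC** (`replicate_qc`) embeds samples in two dimensions by
classical MDS of Euclidean distances between $\log_2$(normalized count + 1)
profiles and flags a sample whose distance to its condition's replicate
centroid exceeds 3 times the median such distance across samples. The
multiplier is a reimplementation choice — the original analysis reports
removing "statistically different" replicates without giving a criterion.
Two guards temper the rule: conditions with fewer than two replicates are
skipped (with a warning), and removal never drops a condition below two
replicates — when several replicates of one condition flag at once, the
least outlying are kept, because a coherent group-level displacement in MDS
space is treatment biology, not a replicate artifact. Removal and
renormalization are the caller's responsibility (`run_pipeline` does both).

**Dispersion** (`estimate_dispersion`) is a method-of-moments estimate on
normalized counts: per condition with $\ge 2$ replicates,
$\hat\alpha_g = \max(0, (v - m)/m^2)$, averaged across conditions; the
common dispersion is the 10%-trimmed mean over genes, and per-gene values
are shrunk halfway toward it (weight configurable). With $n = 3$ replicates
the per-gene moment estimate is far too noisy to use raw; equal-weight
shrinkage is a deliberately simple stabilizer. Its calibration is checked
empirically: on null simulations at $\alpha = 0.1$ the realized type-I
error at $p < 0.05$ is 0.03-0.05 across expression strata.

**Exact test** (`exact_nb_test`). Group counts are scaled to a common
effective library size (the geometric mean of the size factors) and summed.
Writing the group sums as independent NB variables — a sum of $n$ i.i.d.
NB($\mu, \alpha$) variables is NB($n\mu$, $\alpha/n$) — the test conditions
on the total $t$ and sums the probabilities of all splits $(a, t-a)$ no more
probable than the observed one:
$$ p = \sum_{a : \Pr(a \mid t) \le \Pr(a_{obs} \mid t)} \Pr(a \mid t),
\qquad \Pr(a \mid t) \propto f_{NB}(a; n_1/\alpha, \mu_1)\,
f_{NB}(t - a; n_2/\alpha, \mu_2), $$
with $\mu_i \propto n_i$. At $\alpha = 0$ this reduces exactly to the
conditional binomial test of two Poisson samples, and the implementation is
verified against brute-force binomial enumeration for all totals $t \le 50$.
A zero total returns $p = 1$ by convention. This test is an original
implementation validated by its own error-control properties (null type-I
error, BH FDR behaviour), not by numeric identity to any published tool.

**Calling rule** (`call_degs`). Genes with normalized mean below 1 in both
groups are not tested (p-value validity at very low counts; configurable).
Log2 fold change uses normalized group means with pseudo-count 0.5 so zero
groups stay finite. FDR is Benjamini-Hochberg over tested genes. A gene is
significant when fold change $> 2$, $p < 0.05$ and FDR $< 0.05$ — all three
at once. These thresholds are the calling rule of the study design and are
parameters of `call_degs`.

## Enrichment and GO-percentage profiles

Term overrepresentation (`enrich_terms`) is the one-sided Fisher's exact
(upper-tail hypergeometric) test of the DEG set against the annotation
universe, Bonferroni-corrected. The test is one-sided because the question
is overrepresentation only. Two conventions matter and are configurable:

* the universe $N$ is the set of *annotated* genes of the namespace
  (unannotated genes carry no information about term membership); a
  whole-genome $N$ can be supplied via `universe_size`;
* the Bonferroni divisor $m$ counts testable terms (those with at least one
  DEG member); `m_all_terms = TRUE` divides by the whole namespace instead.

Significant GO terms with *identical* DEG gene lists are collapsed
(`collapse_go`) into the term with the largest genome annotation set — the
most general term available when no ontology graph is supplied — with
absorbed term ids recorded and the union of covered genes preserved.

GO-percentage profiles (`go_profile_matrix`) put each significant term on a
common scale: the cell for term $T$ and column (stress, timepoint,
direction) is $100 \cdot |D \cap G_T| / |G_T|$ where $D$ is the significant
DEG set of that direction and $G_T$ the term's genome-wide gene set.
Percentages give a 12-gene term and a 500-gene term equal visual weight.
Columns are direction-split (up/down) even though enrichment runs on
combined sets, because profile patterns are direction-specific. Profiles
are row-standardized and clustered (Euclidean, average linkage, tree cut at
$k$; defaults $k = 7$ for leaves, $3$ for roots, and top-5 / top-10 terms
for cluster annotation, following the full-scale analysis this emulates).
"Prevalence" for cluster annotation is the genome term size, ties broken by
term id; the linkage and the prevalence definition are declared choices, not
inferences — the original work states only "hierarchical clustering".
`tf_by_cluster` counts a DE transcription factor into every GO cluster it is
annotated to, once per cluster, by family.

## QTL overlay

`marker_interval` spans each QTL's SNP markers from minimum to maximum
position (two markers minimum — a single flanking marker defines no
interval and is rejected). `genes_in_interval` returns genes overlapping
the interval by at least 1 bp in 1-based inclusive coordinates (strict
containment behind a flag; BED input is converted from 0-based half-open on
read). `overlay_deg` emits one row per contained gene with its significant
log2 fold change per contrast (0 when not a DEG there) and ranks by maximum
|log2FC|, so the most differentially expressed candidate leads the table.

## The synthetic study and what it does (not) emulate

`sim_config()` / `generate_study()` produce the full design with planted
ground truth. Defaults define the desk-scale study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 5000 | genes |
| `replicates` | 3 | biological replicates per group |
| `baseline_log2_mean`, `_sd` | 5, 2 | log2-normal baseline means |
| `dispersion` | 0.1 | NB $\alpha$ (constant by default; gamma via `dispersion_shape`) |
| `effect_size` | 2 | planted \|log2FC\| (i.e. 4-fold) |
| `min_de_baseline` | 50 | baseline floor for planted DEGs |
| `min_memory_baseline` | 100 | baseline floor for planted memory genes |
| `sf_range` | [0.5, 2] | true size factors, log-uniform |
| `n_terms` | 200 | GO terms, sizes log-uniform 10-500 |
| `n_enriched`, `enrich_or` | 10, 8 | planted enriched terms and their odds ratio |
| `tff_sizes`, `tff_scale` | 9 families, 0.3 | genome family-size profile, scaled |
| `n_qtl`, `qtl_genes` | 3, 20 | QTL intervals and genes bracketed |

Planted classes per tissue and stress: 150 genes DE at T1 only, 100 at
T1Rec only, 40 responding in the same direction at T1T2 and T2, 100
opposite-memory genes, 350 T1T2-unique genes (30 of them shared between Fe
and Pi), and 60 at T2 only. Two sizing decisions deserve explanation.
First, planted enriched terms draw their sizes from [50, 500] rather than
the general [10, 500]: at odds ratio 8 against a ~150-gene DEG set, a term
below roughly 50 genes has an expected overlap too small to clear the
Bonferroni threshold, so planting smaller terms would plant undetectable
truth. Second, the memory classes are deliberately *larger* in proportion
than in real data, where T1T2-unique genes are roughly a quarter of T1T2
DEGs: the FDR-0.05 calling rule guarantees a floor of false positives
proportional to each contrast's called set, and a truth class sized near
that floor would make recovery precision measure the calling rule rather
than the classifier. Class sizes are therefore set to roughly an order of
magnitude above the expected false-positive floor of their defining
contrast.

What the generator does **not** emulate: GC/length bias, batch effects,
library-preparation artifacts, correlated genes (counts are independent
across genes given the design), annotation noise, or read-level data.
Passing recovery tests therefore demonstrates the statistical machinery is
correct and calibrated under the model it assumes — not that real data meet
those assumptions.

## Numerical conventions and degenerate inputs

* Z-scoring maps constant rows to all-zero rather than NaN.
* Cluster labels are renumbered by the cluster mean of the first column,
  ties by decreasing size, so partitions are stable under row permutation.
* Hypergeometric margins are validated; inconsistent margins are an error,
  as are terms with zero genome genes in profile construction.
* A gene's exact-test total of zero gives $p = 1$; empty DEG sets produce
  empty enrichment results with a warning.
* All randomness flows from one master seed through fixed per-stage child
  seeds, making every artefact byte-reproducible.

## Problem sizes used by the tests

The test suite and the acceptance script run the full pipeline on the
default 5000-gene, two-tissue configuration (about half a minute per
seed), a 10,000-gene single-tissue null for error calibration, exhaustive
hypergeometric enumeration for all backgrounds $N \le 30$, and small
dedicated simulations for clustering recovery. These sizes were chosen so a
complete run finishes in minutes on a laptop while keeping every recovery
metric estimated from several hundred planted genes.

## Known limitations

* The dispersion estimator is intentionally simple (moments + fixed-weight
  shrinkage); it is calibrated at the simulated conditions but has no
  empirical-Bayes adaptivity for strongly gene-dependent dispersion.
* The exact test rounds size-factor-adjusted pseudo-counts to integers;
  at very small totals this discretization makes the test conservative.
* GO collapsing without an ontology graph approximates "highest-order term"
  by largest annotation set; supplying a true ancestor relation would be
  more faithful.
* MDS outlier QC is a screening heuristic; its threshold trades false
  removals against retained artifacts, and on clean simulated data it
  occasionally sacrifices one replicate of a strongly responding condition.
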