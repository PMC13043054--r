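---
title: "Methods: OSN single-cell analysis, crispant scoring and targeting statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: OSN single-cell analysis, crispant scoring and targeting statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(osntools)
```

This vignette is the package's account of its methods: the models and
rules each stage implements, the parameters that matter and why their
defaults are what they are, what the synthetic-data generator emulates
(and deliberately does not), and the numerical choices and limitations a
user should know about before trusting a result.

## The biological setting

Zebrafish olfactory sensory neurons (OSNs) each converge on expressing a
single odorant receptor (OR) from a repertoire organised into subfamilies
of closely related genes lying at consecutive chromosomal positions. The
homology clade of the chosen OR (A, B or C) predicts the axon's first
target neuropil in the olfactory bulb: clade A/B neurons project to the
central-zone protoglomerulus, clade C neurons to the dorsal-zone
protoglomerulus. During development an OSN may transiently express more
than one OR, and that co-expression is concentrated among genomically
adjacent genes of the same subfamily — consistent with a shared enhancer
hub activating a small neighbourhood of OR loci before feedback restricts
expression to one. The analysis pipeline exists to (i) clean and stage a
droplet scRNA-seq matrix of maturing OSNs, (ii) decide each cell's
predominant OR and clade despite transient co-expression, (iii) find genes
differentially expressed between clade groups as candidate axon-guidance
molecules, and (iv) quantify the CRISPR F0 knockdown and axon-targeting
experiments that test those candidates.

## Quality control

`compute_cell_metrics()` computes, per cell: genes detected (count ≥ 1),
total counts, and the mitochondrial count fraction (0 for an empty cell,
which additionally fails with reason `empty`). `filter_cells()` applies
three rules; the defaults in `qc_thresholds()` are the study's values:

| parameter | default | rule |
| --- | --- | --- |
| `min_genes` / `max_genes` | 800 / 7000 | inclusive on both ends |
| `max_reads` | 50,000 | strict (`<`) |
| `max_mito_fraction` | 0.10 | strict (`<`) |

Two conventions are explicit choices rather than given facts. First, a
"800–7000" range carries no inclusivity; this package treats both ends as
inclusive and keeps the "less than" thresholds strict, and all four values
are configurable. Second, "reads per cell" is interpreted as total matrix
counts per cell — the only read-like quantity a count matrix retains.
Mitochondrial genes are identified by an annotation flag, not a symbol
prefix, so the rule is species- and nomenclature-agnostic.

## Maturity staging and immune flagging

The pipeline stages cells by marker programs rather than by graph
clustering: cluster boundaries are a property of one dataset, while the
marker panel is the reproducible content. Counts are normalised to
counts-per-10k, log1p-transformed, and z-scored per gene across cells; a
class score is the mean z-score over that class's markers; the stage is
the argmax over the immature, early-mature and mature scores. Markers of
the transitional program (axonal outgrowth, e.g. *gap43*) are counted
toward the early-mature score, since they mark cells leaving the immature
pool. Ties break toward the less mature stage, the direction of
developmental ordering, which makes the argmax deterministic. A cell is
flagged immune when its immune-marker score (T-cell markers such as
*tnfb*, *cxcr3.3*, *CD83*) exceeds every stage score **and** at least one
immune marker is actually detected — the second condition prevents
z-score noise from flagging cells that express no immune transcript at
all. Immune-flagged cells are excluded from every downstream stage.

This staging is a declared substitute for the clustering/UMAP view of the
same structure, not a reconstruction of it; on synthetic data it recovers
the generating stage for ≳ 99% of cells at the default marker effect
size, which shows the scoring is consistent, not that real maturity is
this clean.

## OR identity

`tabulate_or_calls()` uses detection (count ≥ 1) to categorise cells as
expressing none, a single, or multiple ORs. `assign_predominant_or()`
implements the dominance rule: a cell is assigned an OR identity if it
expresses exactly one OR, or if its top OR count is at least 5× the
second-highest (boundary inclusive); all other multi-OR cells stay
unassigned and drop out of clade-level analysis. The comparison uses raw
counts: within one cell, library size cancels, so a normalisation would
only re-weight the two counts by the same factor. The ratio is
configurable.

## Co-expression structure

`spearman_coexpression_matrix()` computes tie-corrected Spearman
correlations (midranks, then the product-moment formula on ranks) for
every OR pair across the multi-OR cells only, retaining zeros for
undetected ORs in those cells. Two guards keep entries honest: a pair
needs at least `min_cells_nonzero = 3` multi-OR cells detecting one of
its members, and constant rank vectors give a missing entry rather than a
0/0. ORs are ordered genomically (chromosome lexicographic, then start
coordinate), so adjacency in the matrix is adjacency in the genome.

`detect_coexpression_blocks()` declares a pair co-expressed when ρ ≥
`rho_min` (default 0.1) and its one-sided t-approximation p-value,
`t = ρ√((n−2)/(1−ρ²))`, survives BH at `alpha` (default 0.05) across all
defined pairs. A block is a maximal run of genomically consecutive
same-subfamily ORs in which **every adjacent pair** is co-expressed;
significant pairs spanning subfamilies are reported separately and never
join blocks. The thresholds are declared substitutes for what is, in the
underlying literature, a visual call on a heatmap; both are configurable,
and the block definition (adjacent-pair chaining rather than all-pairs
cliques) favours the genomic-contiguity interpretation of enhancer-hub
co-activation. Cells from all maturity stages are included: transient
co-expression is a property of maturing cells, and excluding immature
cells mostly removes signal, not artefact.

## Differential expression between clades

The package implements its own negative-binomial Wald test rather than
delegating to an external DE framework, so that the statistic, its
assumptions and its calibration are all in-repo and testable. The model:

- **Size factors** — per-cell total counts divided by the median total
  (median size factor exactly 1). This is deliberately simple, and has a
  known failure mode: when a large fraction of counts is differentially
  expressed in one group, totals absorb the shift and all null genes
  acquire a small opposite-direction bias (composition bias). With the
  handful of planted effects the generator defaults to, the bias is
  negligible; with ~5% of the transcriptome shifted it becomes visible as
  an inflated false-discovery proportion even while raw type-I error at
  the gene level stays nominal. Users with strongly asymmetric designs
  should interpret borderline hits accordingly.
- **Dispersion** — per-gene method of moments on normalised counts,
  `α = max((s² − m)/m², 1e-8)`, then shrunk halfway toward a fitted
  mean–dispersion trend `α_trend(m) = a₁/m + a₀` (least squares over
  genes). The half-weight is a fixed compromise: full shrinkage erases
  real gene-to-gene dispersion differences, none leaves small-count
  estimates too noisy.
- **Test** — effect `b = log((μ₁+ε)/(μ₂+ε))` with `ε = 1e-8`; delta-method
  `SE² = Σ_g (μ_g + αμ_g²)/(n_g μ_g²)` with group means floored at ε;
  `z = b/SE`; two-sided normal p. Genes with both group means zero are
  untestable and report `p = 1`, `log2fc = 0`. Genes expressed in only
  one group get an enormous SE from the floored term and therefore never
  reach significance — a conservative convention, stated rather than
  hidden.
- **Multiplicity** — Benjamini–Hochberg step-up within each comparison
  (`bh_adjust()` is its own implementation, cross-checked in tests
  against an independent one).

At the calibration conditions exercised in the acceptance suite (2,000
genes, 200 cells/group, α = 0.3, global null, 20 seeds) the empirical
type-I error at p ≤ 0.05 averages ≈ 0.050; with planted log2 fold-changes
of 1.5 at 300 cells/group, sensitivity at BH 0.05 exceeds 0.98 and the
fold-change bias is within ±0.15. Numerical agreement with any external
DE tool is explicitly not a contract of this package — calibration and
recovery on simulation are.

`clade_de()` wraps the model for the four comparisons of interest (A vs
B, A vs C, B vs C, and pooled A+B vs C), and `build_candidate_table()`
applies the curation rule: keep genes with `q ≤ 0.05` that carry a signal
peptide or a transmembrane domain (the membrane/secreted enrichment that
selects plausible guidance cues and receptors), ranked by −log10 q and
labeled with the clade in which they are higher. Passing a different flag
set (e.g. a DNA-binding flag) reuses the same machinery for transcription
factors.

## Crispant efficacy

`combine_knockout_scores()` combines per-guide knockout scores (fraction
of target loci carrying a frameshift or premature stop) under
independence: `1 − ∏(1 − k_i)`, reported both as a fraction and as a
percent rounded half-up to an integer — the rounding convention that
reproduces printed efficacy-table totals, stated here because such tables
rarely state it. `summarize_guide_table()` combines **both** the
knockout-score column and the %-frameshift column per gene, because
published totals are sometimes quoted from one column and sometimes from
the other; genes whose two rounded totals disagree are flagged
(`totals_disagree`) rather than silently reconciled. Upstream estimation
of the per-guide percentages (Sanger-trace deconvolution) is out of
scope; the percentages are inputs.

## Targeting statistics

Axon-termination scoring is blinded and duplicated; `consensus_scores()`
passes agreements through, applies supplied resolutions to disagreements,
and excludes (with a count) whatever remains unresolved.
`fisher_exact_one_tailed()` computes the exact hypergeometric tail by
log-factorial accumulation over all tables with the observed margins at
least as extreme in the stated direction; degenerate margins give `p = 1`.
`compare_conditions()` builds the 2×2 tables of a loss-of-function
comparison — correct-vs-not per condition, tested one-tailed for *fewer*
correct terminations in the knockdown, and each error direction vs rest,
tested one-tailed for *more* errors in the knockdown — and attaches
inclusive significance stars (`*` at p ≤ 0.05 through `****` at
p ≤ 1e-4). No multiplicity correction is applied across directions by
default, matching the per-direction reporting convention of the
experiments this models; `adjust = TRUE` enables BH. The unit of analysis
is the scored axon; within-embryo correlation is not modelled, a
limitation shared with the source convention. Note that for two identical
non-degenerate tables the one-tailed p is large but below 1, since the
observed table contributes its own probability to the tail; only
degenerate margins give exactly 1.

## The synthetic-data generator

`simulate_repertoire()` and `simulate_osn_counts()` generate the
structure the analysis assumes, with complete ground truth:

- **Repertoire** — `n_subfamilies = 20` subfamilies of
  `genes_per_subfamily = 4` ORs at consecutive coordinates on five
  chromosomes, clades cycling A/B/C over subfamilies (clade composition
  is therefore a consequence of repertoire composition, not a separate
  knob); ~1,500 background genes; a marker panel covering the four
  maturity/immune classes; five mitochondrial genes.
- **Cells** — 1,000 cells split 26/47/27% across immature, early-mature
  and mature stages (the composition of the assigned-cell population in
  the motivating dataset), plus 5% immune contaminants drawn per cell.
  Each non-immune cell draws one dominant OR uniformly.
- **Co-expression** — each subfamily is partitioned into consecutive
  enhancer hubs of `hub_span = 3` genes; with probability
  `multi_or_cell_fraction = 0.4` a cell expresses its dominant's whole
  hub, secondaries at `secondary_or_expression_ratio = 0.3` of the
  dominant mean. The ratio is a free parameter — no published estimate
  exists — chosen so that co-expressing cells typically *fail* the 5×
  dominance rule, which is the realistic hard case for assignment. One
  configurable cross-subfamily leak pair (by default the first genes of
  the first two subfamilies) mimics a known between-subfamily
  co-expression anomaly and serves as the negative control for block
  detection.
- **Expression** — planted clade-linked effects
  (`default_clade_de_genes()`: four protocadherin-like membrane genes and
  two guidance receptors at log2FC 1.5); stage markers elevated 8-fold in
  their stage; counts negative binomial with `nb_dispersion = 0.3`
  (variance μ + αμ², the same law the DE model fits); per-cell depth
  lognormal around `mean_depth = 8000` with sdlog 0.3; mitochondrial
  fraction Beta-distributed (mean 0.05, concentration 30) so that a
  realistic minority of cells deliberately fails the mitochondrial QC
  rule.
- **Determinism** — one master seed; each generation phase derives its
  stream by a fixed offset, so outputs are byte-identical across runs and
  adding a phase does not perturb earlier draws.

What the generator does **not** emulate: ambient RNA, doublets, batch
effects between timepoints, read-level OR misassignment between similar
paralogs, and OR expression below the detection floor. Passing tests on
synthetic data therefore demonstrates internal consistency — the pipeline
recovers the structure it assumes — not robustness to those artefacts in
real data.

`simulate_de_matrix()` is a direct two-group NB simulator used for the
calibration and power studies (its `depth_sdlog = 0` mode gives exactly
constant within-group means, which is what the mean–variance law test
needs). `simulate_guide_outcomes()` and
`simulate_targeting_experiment()` provide ground-truth tables for the
crispant and targeting modules.

## Problem sizes and reproducibility

The test suite runs the recovery checks at the generator defaults over 20
seeds (~1,000 cells × ~1,600 genes each), the DE calibration at 2,000
genes × 400 cells × 20 seeds, and the exact-test oracle comparisons on
hundreds of random instances; the full suite completes in about a minute
on one core. All file outputs (Matrix Market trio, annotation TSV,
results CSV/JSON with 6-significant-digit floats) are byte-deterministic
given a seed, which the acceptance suite verifies by hashing two
independent runs.

## Known limitations

- Total-count size factors carry composition bias under strongly
  asymmetric differential expression (discussed above).
- The dominance rule on raw counts and the ρ/α thresholds for block
  calls are conventions standing in for judgements that were originally
  made by eye; both are exposed as parameters.
- Genes expressed in exactly one group are never called significant by
  the Wald test as implemented; a likelihood-ratio or exact test would be
  needed at that boundary.
- Marker-score staging assigns every non-immune cell a stage even when
  all stage scores are weak; there is no "unstageable" category.
- The targeting tests treat axons as independent observations.
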