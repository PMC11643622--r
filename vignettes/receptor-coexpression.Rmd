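---
title: "Calling combinatorial receptor co-expression in vomeronasal neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling combinatorial receptor co-expression in vomeronasal neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vrcall)
```

## The analysis problem

Sensory neurons of the mouse vomeronasal organ sort into an apical
zone (Gnai2⁺ cells expressing type-1 vomeronasal receptors, V1Rs) and
a basal zone (Gnao1⁺ cells expressing type-2 receptors, V2Rs, and
non-classical MHC Ib H2-Mv genes). Unlike the main olfactory
epithelium, basal cells express *several* receptor genes at once in
structured combinations: one family-A/B/D V2R, plus either the
family-C1 receptor Vmn2r1 or a multi-member subset of the family-C2
receptors Vmn2r2–Vmn2r7, plus 0–4 H2-Mv genes. Deciding, per cell,
which receptors are genuinely expressed — against a background of
ambient RNA, sampling noise and droplet doublets — is the core
computational task this package addresses.

The decision rule is deliberately simple and auditable: a receptor is
called expressed in a cell iff its log-normalized expression strictly
exceeds a per-family threshold, and a co-expression *combination* is
reported only when the identical called set recurs in at least two
cells. All downstream statistics (dosage scaling, subtype fractions,
differential expression) are built on these calls.

## Normalization and quality control

Cells are retained when they detect between `qc.min_genes = 200` and
`qc.max_genes = 7000` genes (closed interval — the bounds themselves
pass), have no count in a hemoglobin-class gene, and have at most
`qc.max_pct_mito = 20` percent of counts on mitochondrial genes.

Two of these rules are deliberate simplifications of practice that
uses clustering: dying-cell removal is often done by dropping a
mitochondria-enriched *cluster*, and red-blood-cell contamination by
dropping an Hbb-bs-positive cluster. Clustering is out of scope here,
so both are expressed as deterministic per-cell rules; the
hemoglobin rule uses any nonzero count (the strictest reading — no
published count threshold exists), and the mitochondrial cutoff is
configurable. QC is computed on raw counts, before any ambient-RNA
consideration, so that the filter does not depend on model choices
made later in the pipeline.

Normalization is the standard log transform
\(x_{gc} = \ln(1 + s\,c_{gc}/T_c)\) with `norm.scale` \(s = 10^4\) and
per-cell total \(T_c\). Zero counts map to exactly zero, so sparsity
is preserved; within a cell the transform is monotone in the raw
count.

Cell types are assigned from markers on normalized expression with
cutoff `markers.cut = 1.0`: cells above the cutoff for both Gnao1 and
Gnai2 are `ambiguous` (typically doublets); otherwise Gap43
distinguishes immature from mature neurons of the dominant G-protein
type, Ascl1/Neurod1 mark progenitors, and everything else is `other`.
An externally supplied label table (e.g. from a clustering the user
trusts) bypasses this entirely.

## The bimodal expression threshold

Pooled nonzero normalized values of a receptor family across cells
form a bimodal distribution: a low ambient peak and a true-expression
peak. "The start of the second peak" is a visual notion; the
reproducible analogue used here is the *density valley*: fit a
Gaussian-kernel KDE on a 512-point grid, find the two highest modes
separated by at least `thresholds.min_separation = 0.2` normalized
units, and take the argmin of the density between them.

Two numerical choices matter:

* **Zeros are excluded** from the pooled values. The exact-zero point
  mass would dominate any density estimate, while the valley position
  — the only quantity used downstream — is unaffected by it; the
  ambient peak is carried by low *positive* values.
* **Bandwidth is Sheather–Jones**, not Silverman's rule of thumb.
  Silverman's bandwidth scales with the overall standard deviation,
  which for a well-separated mixture is dominated by the
  between-component distance; it oversmooths the sharp ambient
  component and drags the detected valley far toward the wide
  expression component. On a two-component reference mixture
  \(0.7\,N(0.1, 0.05^2) + 0.3\,N(3.0, 0.5^2)\) with \(n = 10^4\),
  Silverman places the valley near 0.99 where the analytic density
  argmin is 0.409; Sheather–Jones lands at 0.398 with a 20-seed
  spread below 0.06. When the SJ bandwidth equation has no solution
  (tiny or degenerate samples) the code falls back to Silverman.

If no two qualifying modes exist the configured default is returned
with `fallback_used = TRUE` and a warning. The defaults — and the
values used when thresholds are pinned with `thresholds.mode =
"fixed"` — are `2.5` for V1R and `1.25` for V2R and H2-Mv, the values
used in the analysis this pipeline reproduces. Pooling is done over a
configurable cell subset; the pipeline default is the mature neurons
of the relevant type (V1R on mature Gnai2 cells, V2R/H2-Mv on mature
Gnao1 cells), since those are the populations in which the families
are genuinely expressed — pooling over all cells only adds ambient
mass and does not move the valley.

## Calling, patterns, and the doublet filter

Calling is strict (`value > threshold`, never ≥): ties sit on the
ambient side. Cells calling nothing are kept — they populate the
k = 0 bin of the per-cell count histograms.

A combination is the sorted set of called `family:gene` tags within a
scope (`C` pools C1 and C2; cross-family scopes such as
`ABD × C × H2Mv` concatenate per-family sets). Each cell contributes
its exact called set once; an optional subset-counting mode credits
every nonempty subset instead, for comparison with studies that count
partial patterns. Combinations observed in fewer than
`patterns.min_cells = 2` cells are dropped: a doublet is a one-off
event, so a spurious chimeric combination is overwhelmingly unlikely
to recur, while genuine programs do. This frequency filter is the
package's entire doublet treatment — no model-based doublet scoring
is attempted, matching the analysis being reproduced.

Dosage analysis sums the normalized expression of called family
members per cell and groups cells by k. Because normalized values of
genuinely expressed receptors concentrate around a common level, the
median summed expression is close to proportional to k, while the
Gnao1 control stays flat; a doublet explanation would move the
control too. Summaries are medians and quartiles; means are available
from the per-cell table.

Mature Gnao1 cells are classified as `C1` (C1 called, no C2),
`C2_H2Mv_pos` / `C2_H2Mv_neg`, `C_none`, or `mixed` for the rare
cells calling both C1 and C2 — these exist in real data (Vmn2r1 with
Vmn2r7) and are reported separately rather than forced into either
class. The headline fraction of H2-Mv-negative cells among family-C
callers is reported alongside.

## Differential expression and over-representation

The per-gene test is a two-sided Wilcoxon rank-sum on normalized
expression. For group sizes ≤ 10 the exact permutation distribution
is enumerated (ties permitted); otherwise the normal approximation
with tie correction and continuity correction is used. The two
branches agree within ~10% relative p in the bulk of the
distribution. Fold change is computed on de-logged means:
\(\log_2\!\big(\frac{\overline{e^{x_A}-1} + 1}{\overline{e^{x_B}-1} + 1}\big)\),
the convention of the workflow ecosystem this pipeline mirrors. The
test family is all genes detected in at least `de.min_pct = 1%` of
either group; Bonferroni correction is applied over that family.
Significance uses the adjusted p (`p_adj < 1e-6`) together with
`|log2FC| > 1`; published figure axes sometimes read as raw-p cutoffs,
but the stated criterion is the adjusted one and that is what the
code applies.

Over-representation is an upper-tail hypergeometric test of a gene
set's overlap with a query list against a universe (here: all tested
genes), with sets intersected with the universe first. Gene sets are
supplied as GMT; no ontology database is bundled — term databases
version badly and would make counts irreproducible.

## Axis profiles

Immunofluorescence quantification operates on exported ROI tables
(position, channel, intensity), not images. Each ROI is min-max
normalized independently — per-ROI rather than per-section, so that a
bright section cannot dominate pooled fits — with position 0 = apical.
The trendline is a locally weighted degree-1 regression (tricube
weights, `profile.span = 0.5`) evaluated on a 101-point grid; a
generalized additive model would serve equally, but the local
regression has exactly one tunable and no basis/penalty choices to
document. Channel co-trends are summarized by the Spearman
correlation of fitted curves, which is invariant to monotone
intensity distortions between antibodies.

## The simulator

`generate_dataset()` draws negative-binomial counts
(`dispersion = 0.1`, i.e. NB size 10) with lognormal per-cell library
scaling (`lib_logsd = 0.3`) over a panel at loosely mouse scale: 150
V1R, 70 ABD-V2R, Vmn2r1 + Vmn2r2–Vmn2r7, 6 H2-Mv, 1000 background
genes (gamma-distributed means, shape 0.8 × scale 15, giving ~13k
median counts/cell), 50 ER genes, canonical markers, 5 mitochondrial
genes and Hbb-bs. The default population is 5,000 cells: 1,500 each
mature Gnao1/Gnai2, 600 each immature, 400 progenitors, 400
non-neuronal.

Planted structure mirrors the biology the pipeline must detect:

* mature Gnai2 cells carry one V1R, or with probability
  `p_V1R_pair = 0.05` one of five recurring planted pairs;
* mature Gnao1 cells carry one ABD member plus either C1
  (`p_C1_vs_C2 = 0.4`) or a uniform 2–6-member C2 subset; H2-Mv sets
  of 1–4 members attach with probability 0.65 given C2 and 0.1 given
  C1. These rates put the planted H2-Mv-negative fraction among
  family-C callers at ≈ 0.57, the regime reported for real basal
  neurons; 2% of C1 cells also carry Vmn2r7, emulating the observed
  rare C1+C2 co-expressors;
* every gene has a small ambient mean (`ambient_mean = 0.02`) in
  every cell, so pooled receptor values are genuinely bimodal and
  thresholding is exercised against contamination — this stands in
  for the upstream ambient-correction step, which is out of scope;
* expressed receptors use `on_mean = 100`, a 5000-fold separation
  from ambient on the count scale (the qualitative requirement is
  only ≥ 8-fold);
* ER genes are upregulated `er_log2fc = 2` in Gnao1 cells; 1% of
  barcodes are doublets (summed count profiles of two cells, the
  constituents removed); 1% carry Hbb-bs and 2% are low-quality
  (library scaled ×0.005), so the QC stage has real work to do.

Everything is a pure function of (config, seed).

What the simulator does **not** emulate: UMI chemistry and saturation,
batch and sample effects, gene–gene correlation beyond the planted
blocks, empirical library-size distributions, cluster substructure
within types, and biologically realistic ABD–C family biases.
Passing tests therefore demonstrate that the *algorithms* recover
planted truth under the stated noise model — not that the thresholds
or rates transfer to any particular real dataset, where the
auto-detected threshold should always be inspected against the pooled
distribution (or pinned to published values).

## Verification sizes and numerical conventions

The checks shipped with the package use: the two-component reference
mixture at \(n = 10^4\) values × 20 seeds for threshold recovery
(tolerance 0.15 against the analytic valley, spread ≤ 0.1); the
default 5,000-cell simulation for call accuracy (precision/recall
≥ 0.98), pattern recovery under the 2-cell filter (≥ 0.95 both ways),
and dosage ratios (k = 2 / k = 1 within [1.6, 2.4], control within
[0.9, 1.1]); and 20 seeds of a 1,050-gene, 200-cells-per-group layout
for DE calibration (zero null genes passing the criteria in ≥ 95% of
seeds, ≥ 90% planted recall). Brute-force oracles (full permutation
enumeration, exhaustive pattern tallies, combinatorial hypergeometric
sums) back the statistical kernels at small n. These sizes were
chosen as the smallest at which the binomial noise of the measured
rates is comfortably inside the asserted bands.

Tie-breaking and degenerate-input conventions, in one place: calling
is strictly `>`; QC bounds are inclusive; a constant channel min-max
normalizes to zeros with a warning; a unimodal pooled distribution
falls back to the configured threshold with a warning; zero-total
cells are an error naming the barcode; empty pattern tables and empty
DE inputs propagate as empty tables, not errors; all counts must be
non-negative integers at load time.

## Known limitations

* Thresholds are per family, not per gene; a family whose members
  have very different expression scales would need the per-gene
  extension this package deliberately omits.
* The doublet filter is frequency-based; for extremely abundant
  combinations (e.g. the full C2 set) a recurring doublet-induced
  pattern cannot be distinguished from a genuine rare program — the
  dosage control is the guard there.
* The marker classifier is rule-based and assumes well-separated
  marker levels; noisy real data should use external cluster labels.
* `run_pipeline` holds the dense per-gene matrices used by the DE
  stage in memory; very large datasets (> ~10⁵ cells) would need a
  blocked implementation.
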