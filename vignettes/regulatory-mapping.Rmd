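---
title: "Mapping regulatory regions with regmap: models, rules, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping regulatory regions with regmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regmap)
```

## Scope and scientific background

`regmap` implements an integrative analysis of the regulatory landscape
of a tissue — the motivating system is human myometrium at term
pregnancy — starting from per-specimen histone-mark ChIP-seq peak sets
and ending at enhancer–gene associations, transcription-factor (TF)
colocalization statistics, signature-based TF activity scores, and
CRISPR-activation (CRISPRa) Perturb-seq activation calls. Upstream steps
(read alignment, peak calling, loop calling, motif enrichment) are out
of scope: the package consumes their standard outputs (BED/narrowPeak,
BEDPE, count/FPKM tables, MTX matrices).

The biological reasoning the package encodes:

* Genomic regions carrying both **H3K27ac** and **H3K4me1** marks behave
  like active enhancers, so double-positive regions are called
  *putative enhancers*.
* Clusters of H3K27ac peaks that stitch together across small gaps into
  unusually long regions behave like **super enhancers**; here the rule
  is purely geometric (see below), not the ROSE signal-ranking
  algorithm.
* Enhancers regulate genes mostly within a bounded genomic
  neighbourhood; associations are drawn by a **TSS window** (default
  100 kb) and, where chromatin-conformation data exist, by **Hi-C loop
  anchors** (enhancer in one anchor, TSS in the other).
* A TF's activity in a specimen can be inferred from an **up/down gene
  signature** (e.g. a progesterone-receptor signature derived from a
  knockout model) and correlated with a candidate target gene's
  expression.
* CRISPRa Perturb-seq assigns a guide RNA identity to each cell;
  activation of a known target is a fold change above a threshold in
  that guide's single-guide ("singlet") cells versus non-targeting
  controls.

## Coordinate and interval conventions

All coordinates are **0-based, half-open** (BED convention),
everywhere. This is stated prominently because peak-processing
literature rarely does: an interval `[start, end)` has length
`end - start`, and the package rejects zero-length intervals at every
entry point.

Merging follows **bedtools `-d` semantics**: two intervals join when the
gap between them is *at most* `max_gap`; book-ended intervals
(`[0,100)`, `[100,200)`) join at `max_gap = 0`. "Common" intervals
across specimens are counted on the merged union of all samples
(`consensus_intervals()`), never against a reference sample, which makes
the count symmetric in the samples. Overlap of at least **1 bp** defines
"common" and "colocalized" throughout; the threshold is configurable
(`min_overlap_bp`) because the convention is an assumption, not a
published rule.

Chromosome names match by exact string equality — no `chr` aliasing.
Strand is ignored for all peak arithmetic (histone marks are
unstranded); strand is used only to derive a TSS from a stranded gene
span (plus strand → span start, minus strand → span end − 1).

## Putative enhancers: two definitions

`call_putative_enhancers()` exposes two modes because the narrative
descriptions in the field are ambiguous between them:

* `double_positive_union` (default): merge the two mark tracks and keep
  each union interval that contains at least one peak of *each* mark.
  This mirrors the "union peaks" construction used when the tracks are
  combined with a bedtools merge.
* `intersection`: the exact base-pair AND of the two tracks.

The mode is recorded in the output's metadata so downstream accounting
is self-describing.

## Super enhancers: the geometric rule

`call_super_enhancers()` stitches **H3K27ac peaks** (not double-positive
enhancers) with a gap tolerance of **12,500 bp** and calls a stitched
region a super enhancer when its span is **strictly greater than
15,000 bp**. "Within 12.5 kb" is interpreted as gap ≤ 12,500 (bedtools
`-d`), and "larger than 15 kb" as a strict inequality, so a 15,000 bp
region is *not* a super enhancer and a gap of exactly 12,500 *does*
merge. Stitching runs per sample first; commonality across samples is a
consensus over the stitched spans. There is deliberately no
signal-based ranking.

## Expression bins and association fractions

Genes are binned by mean FPKM across specimens: inactive `< 1`, low
`[1, 5)`, mid `[5, 15)`, high `≥ 15`; boundary values land in the upper
bin, matching the usual "≥" phrasing of the thresholds. Window
association uses the **enhancer midpoint** to the TSS point by default
(HOMER-like); an `edge` mode (distance to the nearest enhancer edge,
zero when the TSS lies inside) is provided because the reference point
is not standardized. Per-bin association fractions are computed **over
enhancers** (the fraction of enhancers with ≥ 1 link to a gene of the
bin), so an enhancer may count toward several bins and fractions need
not sum to one. Both of these conventions are open design points; the
package uses the ≥1-link convention and documents it in the output.

## TF activity T-scores

The published analyses this package generalizes report per-specimen
"T-scores" from a signature-scoring application whose internal formula
is not printed. `compute_tscores()` therefore uses a documented
stand-in with the right invariances: genes are z-scored across
specimens, and a specimen's T-score is the **Welch two-sample
t-statistic** comparing its z-scores of the up-signature genes against
the down-signature genes (or against all non-signature genes when the
signature has no down side). Consequences that the tests assert:
swapping up and down negates every score exactly; per-gene affine
rescaling of the expression matrix leaves scores unchanged; planted
per-specimen activity is recovered with Spearman > 0.9 at n = 43.
Signature genes are matched case-insensitively so a mouse-symbol
signature can score a human matrix; an explicit orthology table can be
applied upstream instead. Correlation of activity with a target gene
uses plain Pearson on FPKM, untransformed — whether the source analyses
log-transformed first is unstated, so the package does the simplest
thing and leaves transformation to the caller.

Count preprocessing helpers implement the stated normalizations
exactly: `scale_counts()` multiplies each specimen by
`56.5e6 / total mapped pairs`, and `filter_expressed()` keeps genes with
mean normalized count **strictly** greater than 1.

## Perturb-seq calling

A gRNA is *detected* in a cell when its count is at least `min_count`
(default 1 — the detection threshold is not standardized, so it is
configurable and reported). Cells partition into `none` / `singlet` /
`multiplet`; only singlets are analysed, and zero-gRNA cells are
excluded from all comparisons. Normalization is a deterministic
stand-in for variance-stabilizing transforms: per-cell depth scaling to
the median library size followed by `log1p`. The Wilcoxon rank-sum test
(normal approximation with tie and continuity corrections, matching
`wilcox.test(exact = FALSE)`) runs on the log scale, while **fold
changes are computed on the linear depth-normalized scale** (via
`expm1`), the convention of single-cell marker finders — computing mean
ratios on the log1p scale would systematically attenuate them.
Activation of a known target requires fold change **strictly** greater
than 1.5; differential-expression hits additionally require
Benjamini–Hochberg adjusted p < 0.05. Both arms must have at least
3 cells.

## The synthetic world

`simulate_*()` generators produce every input the pipeline consumes,
with planted ground truth in a manifest; regeneration from
`(seed, parameters)` is bit-identical, and generators restore the
caller's RNG state. Defaults encode the stated study design where one
exists: 3 specimens for the peak sets, 43 specimens and planted
ρ = 0.47 for the activity correlation, multiplicity proportions
16.3% / 56.7% / 27.0% (none/singlet/multiplet) and an 8-guide panel
around one target gene for the Perturb-seq screen, 76% / 20% planted
occupancy coverage for super enhancers versus enhancers. Where no value
is stated, defaults are chosen once at realistic scales (peak widths
0.6–1.6 kb, negative-binomial size 10 for single-cell counts,
log-uniform FPKM within bin bounds) and not revisited.

Two generator-design points worth knowing:

* `simulate_expression_and_links()` builds its *own* enhancer grid with
  a pitch wider than twice the association window. This is what makes
  planted per-bin fractions exactly recoverable — with arbitrary
  enhancer spacing, a gene planted for one enhancer could fall into a
  neighbour's window and inflate the fractions.
* `simulate_super_enhancer_landscape()` constructs clusters with exact
  planted spans (first peak starts the span, last peak ends it, all
  internal gaps ≤ 12.5 kb) separated from everything else by more than
  the stitch gap, so recovery is exact, not approximate.

What a green test does **not** establish: the generators draw
independent peaks and genes with idealized noise; they do not model
copy-number structure, mappability, batch effects, peak-caller
artefacts, guide-capture chemistry, or ambient RNA. Recovery of planted
truth validates the *rules*, not the biology of any particular dataset.

## Numerical choices and degenerate inputs

* Fold changes carry an ε pseudocount of 1e-9 on normalized means.
* All-tied genes in the rank-sum test get p = 1 and a `tied` flag.
* Zero-variance genes are dropped from z-scoring with a warning; a
  signature needs ≥ 2 usable genes per side or scoring errors with the
  missing-gene counts.
* The colocalization contrast reports the sample odds ratio (the 76/100
  vs 20/100 construction gives (76·80)/(24·20) ≈ 12.67) with a Fisher
  exact p-value; zero marginals flag the odds ratio as undefined rather
  than returning infinity. The contrast is an artifact addition — the
  motivating analyses report raw percentages only — and is labelled as
  such.
* Pipeline reports round every number to 10 significant digits before
  JSON serialization so reruns are byte-identical.

## Known limitations

* The T-score is a stand-in, not a reimplementation of any specific
  signature-scoring tool; absolute score magnitudes are not comparable
  across tools (orderings and signs are).
* Super-enhancer calling is geometry-only by design; datasets where
  signal ranking matters need a ROSE-style tool instead.
* `double_positive_union` and `intersection` enhancer counts can differ
  substantially on sparse tracks; comparisons across studies must fix
  the mode.
* The per-base oracle equivalence tests run on chromosomes ≤ 100 kb;
  the interval engine itself is integer-exact at genome scale (it
  delegates to IRanges), but the oracles do not scale beyond that.

## A minimal end-to-end run

```{r, eval = FALSE}
dir <- tempfile()
cfg <- write_fixture(dir, seed = 1)   # synthetic inputs + config
report <- run_pipeline(cfg)
report$enhancers$n_common             # planted consensus size
report$colocalization$super_enhancers$percent
report$activity$r                     # vs planted rho = 0.47 at n = 43
```
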