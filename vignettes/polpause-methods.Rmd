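---
title: "polpause: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{polpause: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polpause)
```

`polpause` quantifies RNA polymerase II (PolII) promoter-proximal
pausing from binned coverage tracks, relates pausing to the promoter
occupancy of a chromatin factor given as a ChIP-seq peak set, and
compares pausing and expression between a wild-type and a knockdown
condition. This vignette is the package's account of the underlying
models, the choices we made where the design was genuinely open, and
what the synthetic-data validation does and does not establish.

## Coordinate conventions

Every interval inside the package is 0-based and half-open
`[start, end)`, exactly as in BED and bedGraph. GTF input (1-based,
closed) is converted once, at the reader boundary. The TSS of a gene
is its annotated 5′ end: `start` for a `+` gene, `end − 1` for a `−`
gene. Chromosome names are never normalised; when two inputs disagree
on their chromosome sets, `check_chromosomes()` raises a hard error
listing the symmetric difference, because a silent empty join is the
classic failure mode of this kind of pipeline.

## The pausing index

For each gene the pausing index (PI, also called traveling ratio) is

$$\mathrm{PI} \;=\; \frac{d_\mathrm{TSS} + \varepsilon}
                         {d_\mathrm{body} + \varepsilon},$$

where $d_\mathrm{TSS}$ and $d_\mathrm{body}$ are mean signal
densities (signal per bp) over the TSS region and the gene body.
Densities — not sums — make the index independent of gene length and
of global scaling: with $\varepsilon = 0$, multiplying the whole
track by any $c > 0$ leaves every PI exactly unchanged, and a flat
track gives PI = 1 for every gene. Both properties are enforced by
tests.

Region geometry, oriented by strand:

* **TSS region**: `tss_window` around the TSS, default
  $(-250, +250)$, i.e. the 501-bp window `[TSS − 250, TSS + 251)` —
  the same ±250 nt extension that defines the promoter for binding
  calls, so the package has a single promoter geometry.
* **Body**: from `body_offset` (default 500 bp) downstream of the TSS
  to the annotated 3′ end.

The exact windows of published pausing-index variants differ between
laboratories and are rarely printed; all three numbers are plain
configuration (`pi_config()`). We default the TSS window to the
promoter definition rather than inventing a second window, trading a
possible mismatch with any particular published variant for internal
consistency and one fewer free parameter.

Numerical details:

* $\varepsilon$ defaults to 0.001 per bp — one read-equivalent per
  kb. It is added to *both* densities, so an empty (all-zero) track
  has PI exactly 1 rather than 0/0, and genes with a silent body do
  not blow up to infinity.
* Densities are computed from fixed-width bins (default 10 bp, which
  resolves the 501-nt TSS window into ~50 bins) with partial-bin
  length weighting; bins beyond the track's extent read as zero.
* A gene is **ineligible** when shorter than `min_gene_length`
  (default 1000 bp) or when its body would be shorter than one bin.
  Ineligible genes are reported with `pi = NA` and `eligible =
  FALSE`, never silently dropped and never given an infinite PI.
* A gene is **highly paused** when `PI ≥ 4`, the conventional
  threshold for promoter-proximal accumulation; it is configurable as
  `pi_threshold`.

## Positional correlation between peak sets

`positional_correlation()` summarises the co-localization of two peak
sets as a histogram of midpoint offsets: for every anchor midpoint
$a$ and target midpoint $t$ on the same chromosome with
$|t - a| \le w$ (default $w = 10$ kbp), the offset $t - a$ is
binned, and the counts are divided by $|A|\cdot|B|$ so that profiles
are comparable across datasets of different sizes.

Binning uses a **centre-bin layout**: $2w/b + 1$ bins (default
$b = 100$ bp) with centres at $-w, -w+b, \dots, w$, each offset
assigned to the nearest centre. We chose this over the more obvious
edge-aligned layout because edge binning breaks the exchange symmetry
for offsets that land exactly on a bin boundary, whereas
nearest-centre assignment (with ties resolved to the even multiple,
which is symmetric in sign) guarantees that the profile of $(B, A)$
is exactly the reverse of the profile of $(A, B)$ — an identity the
test suite asserts bin by bin, along with the integer conservation
identity $\sum_k \mathrm{count}_k = $ number of in-window pairs.

`overlap_fraction(A, B)` is the companion scalar: the fraction of
peaks of $A$ sharing at least 1 bp with any peak of $B$ (half-open
semantics). `subtract_overlapping()` splits a set by co-occurrence
with another — the building block for analyses that separate factor
peaks inside and outside repressive-mark territory.

## Feature annotation and promoter binding

`annotate_peaks()` assigns each peak, by its midpoint, to exactly one
category: the first in a precedence list (default `promoter >
tes_proximal > gene_body > intergenic`) whose intervals contain the
midpoint. Midpoint assignment guarantees single-category counts whose
fractions sum to 1 without fractional bookkeeping; permuting the
precedence can only reassign peaks whose midpoint lies in several
features at once.

The gene model is deliberately single-transcript (one record per
gene, no exon structure), so the built-in categories are gene-level.
Where an exon/intron split is wanted, exon intervals can be supplied
through the `features` argument under any category name and slotted
into the precedence list; the assignment machinery is agnostic to
where the intervals came from.

`promoter_binding()` calls a gene *bound* when at least one peak
overlaps its promoter window — TSS ± 250 nt, the `flank` parameter —
by at least 1 bp. Any-overlap (rather than midpoint) is used here
because the question is whether the factor touches the promoter at
all, not where the peak is centred.

## Stratified comparisons

All group comparisons use the Mann–Whitney–Wilcoxon rank test
(`mann_whitney_u()`), reporting the U statistic, a two-sided p-value,
group medians and the direction of the median difference. Two-sided
tests are the default throughout; direction is reported separately
rather than folded into one-sided p-values.

* **Exact mode** computes the exact null distribution of U —
  equivalent to enumerating all $\binom{n_1+n_2}{n_1}$ labelings —
  and is used automatically when $n_1 + n_2 \le 20$ and there are no
  ties; otherwise the test falls back, with a warning, to the normal
  approximation with tie and continuity corrections. The test suite
  checks exact p-values against a literal full-enumeration oracle for
  all $n_1, n_2 \le 7$, and checks the approximation's type-I error
  calibration (rejection rate 0.05 ± 0.02 at $\alpha = 0.05$ over
  1000 null simulations at $n = 50$ per group).
* **Degenerate strata** (every value identical in both groups) carry
  no rank information; the tie-corrected variance is zero there, so
  the test reports $p = 1$ directly instead of a 0/0.
* **Paired variant.** The wild-type-vs-knockdown comparison of the
  same genes could arguably be paired; the headline analysis uses the
  unpaired Mann–Whitney test, matching how such comparisons are
  conventionally annotated on boxplots, and the paired signed-rank
  variant is available under `paired = TRUE`.

`fold_change_labels()` is a deliberately transparent stand-in for a
full differential-expression model: with $r = (\mathrm{KD} +
\varepsilon)/(\mathrm{WT} + \varepsilon)$, a gene is `up` when
$r \ge$ `fc_threshold` (default 2), `down` when $r \le 1/$
`fc_threshold`, else `unchanged`. The rule is exactly antisymmetric
under swapping the conditions. The expression pseudocount defaults to
0.01 — two orders of magnitude below the typical expression scale of
the synthetic data — so labels are driven by the ratio except at
near-zero expression. Negative-binomial DE modelling is out of scope;
`build_stratified_dataset()` accepts an external `de_status` vector
so any DE caller's labels can be substituted without touching the
rest of the pipeline.

`high_pi_comparison()` packages the analysis of the highly paused
set: genes selected on **wild-type** PI only (so the selection is not
influenced by the knockdown outcome), the WT-vs-KD comparison within
that set, the set split by binding status with Pearson and Spearman
correlations of WT and KD PIs per subset, and — the decisive check —
a comparison of the per-gene pausing change $\log_2(\mathrm{PI}_{KD}
/ \mathrm{PI}_{WT})$ between bound and unbound genes. If the factor's
promoter occupancy caused the pausing change, that last test should
reject; if the change is occupancy-independent, it should not.

## The synthetic-data generator

`simulate_dataset()` generates the full input bundle with known
ground truth. What it emulates, stage by stage:

* **Genome** (`simulate_genome()`): one 10-Mb chromosome with 1000
  non-overlapping genes by default; log-normal gene lengths (median
  4 kb, clamped to 1.5–50 kb), strands 50/50. Placement allocates the
  free space left after genes and a 1-kb minimum spacing as random
  inter-gene gaps drawn from the uniform simplex, which is uniform
  over feasible arrangements, always succeeds when the genes fit, and
  errors informatively when they cannot. The spacing guarantees that
  promoter and TES windows never reach a neighbouring gene, which is
  what makes planted labels exactly recoverable.
* **Expression**: log-normal (meanlog 2, sdlog 1.2 — a TPM-like
  scale with median ≈ 7.4 and a long right tail).
* **Pausing** (`simulate_polii_coverage()`): each gene draws a
  planted TSS/body ratio ρ from a mixture (default 50% ρ=1, 30% ρ=4,
  20% ρ=8, giving a realistic ~25–30% highly paused fraction);
  coverage is per-bin Poisson around a piecewise-constant rate —
  background 0.2/bp outside genes, `depth` = 5/bp (50 per 10-bp bin)
  over the gene, ρ·depth over the TSS window. Expected bin masses use
  exact partial-bin weighting so the planted ratio is recovered
  without binning bias; gene segments replace (not add to) the
  background so the ratio is not diluted. Poisson bin noise, not
  read-level simulation: sufficient for density-ratio statistics and
  orders of magnitude cheaper.
* **Binding** (part of `simulate_genome()`): the probability that a
  gene's promoter receives a factor peak is
  `base + expr_slope · (expression quantile) + rho_bonus · 1[ρ ≥ 4]`
  (defaults 0.1, 0.5, 0.2) — binding increases with expression and
  pausing, reproducing the empirical association between promoter
  occupancy, transcription and pausing. A `constant` mode is
  available for null experiments.
* **Peaks** (`simulate_peaks()`): bound promoters get a 300-bp factor
  peak centred on the TSS; background factor peaks are planted *by
  category* (150 TES-proximal, 350 gene-body, 700 intergenic by
  default, placed so each peak's category under the annotation rules
  is unambiguous), which sets the promoter share of factor peaks near
  25% and makes annotation recovery exact. Mark peak sets (PolII,
  H3K27ac, H3K4me1, H3K9me3) are co-placed at factor peaks with
  configured conditional probabilities and Gaussian positional
  jitter, plus independent uniform peaks; a conditional probability
  of zero makes the mark avoid factor peaks entirely, emulating a
  mutually exclusive repressive mark.
* **Knockdown** (`simulate_expression_and_kd()` and the KD coverage
  track): 1.34% of genes get a 4× expression increase and 1.45% a 4×
  decrease (multiplicative log-normal noise, sdlog 0.1) — the scale
  of a perturbation that deregulates a small fraction of an
  expressed transcriptome; independently, the pausing ratio of every
  gene with ρ ≥ 4 is multiplied by `pi_effect` = 0.8 *regardless of
  binding*, so the ground truth of the decisive binding-split test is
  "no difference".

Everything is driven by one integer seed (stage-specific fixed
offsets keep stages independently reproducible), and identically
configured runs are byte-identical on disk — a property the suite
checks file by file.

**What passing tests do and do not show.** The generator plants the
statistical *structure* of promoter-occupancy data — density ratios,
co-localization offsets, binding-expression coupling, a sparse
knockdown — under Poisson noise. It does not model read-level
artefacts (fragment-length shifts, PCR duplicates, mappability
holes), input-control normalisation, transcript isoforms or
alternative TSSs, or biological covariance beyond the planted
couplings. Recovery results on synthetic data therefore validate the
*computational* contracts (the estimators recover what was planted;
the tests are calibrated), not the biological fidelity of any real
dataset.

## Problem sizes used in validation

The validation suite runs the planted-recovery checks at the default
study scale (1000 genes, 10 Mb, 50 reads per bin), where the median
PI recovers planted ratios 1, 4 and 6 within 5%; exact-label recovery
and determinism checks use 150–400-gene genomes, which exercise every
code path identically at a fraction of the cost. The acceptance
script (`scripts/acceptance.R`) recomputes all headline quantities at
the default scale from a caller-supplied seed.

## Known limitations

* The PI uses raw PolII signal; if an input-control track should be
  subtracted or divided out, that must happen upstream (the bedGraph
  reader accepts negative values under a flag for input-subtracted
  tracks).
* One record per gene: transcript collapsing and alternative-TSS
  selection are out of scope, and `read_gene_annotation()` refuses
  duplicate gene ids rather than guessing.
* `fold_change_labels()` is a thresholded ratio, not a statistical DE
  caller; treat its labels as descriptive unless substituted with a
  proper caller's output.
* Peak calling itself, BAM/FASTQ handling and bigWig input are out of
  scope: the package consumes called peaks and text coverage tracks.

## Session info

```{r}
sessionInfo()
```
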