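# polpause

Integrative analysis of RNA polymerase II (PolII) promoter-proximal
pausing and transcription-factor promoter occupancy, from ChIP-seq
peak calls and coverage tracks.

Many chromatin regulators — the KRAB-associated scaffold protein
KAP1/TRIM28 being a prominent example — accumulate at the promoters of
actively transcribed genes, where PolII often sits in a
promoter-proximal paused state. `polpause` provides the quantitative
machinery to ask what such promoter occupancy has to do with pausing
and with the transcriptional response to depleting the factor:

* **Pausing index.** For each gene, the pausing index (PI, also called
  traveling ratio) is the ratio of PolII signal density over the TSS
  region to density over the gene body:

  `PI = (d_TSS + ε) / (d_body + ε)`

  with the TSS region `TSS ± 250` bp, the body from `TSS + 500` bp to
  the annotated 3′ end (both oriented by strand), densities in signal
  per bp, and a small pseudocount `ε` (default 0.001/bp). `PI ≥ 4`
  flags a gene as highly paused.
* **Positional correlation.** The histogram of midpoint offsets
  between two peak sets within a symmetric ±10 kbp window, normalised
  by the product of the set sizes — a scale-free picture of
  co-localization between, say, factor peaks and PolII or histone-mark
  peaks.
* **Feature annotation.** Single-category assignment of peaks to
  promoter / TES-proximal / gene-body / intergenic space by midpoint
  and a configurable precedence order.
* **Promoter-binding stratification.** A gene is *bound* when a peak
  overlaps its promoter (TSS ± 250 nt) by ≥ 1 bp; all downstream
  comparisons (expression, PI, wild-type vs knockdown) are stratified
  by this call and tested with the Mann–Whitney–Wilcoxon test.
* **Synthetic data with ground truth.** A deterministic generator
  plants pausing ratios, binding labels, co-localization structure and
  knockdown effects, so every stage of the pipeline can be validated
  end-to-end at desk scale — no sequencing data required.

Inputs are plain standard formats: BED (peaks), bedGraph (coverage),
minimal GTF or BED6 (one record per gene), TSV (expression). All
internal coordinates are 0-based half-open.

## Worked example

A complete run on the default synthetic study conditions (one 10-Mb
chromosome, 1000 genes, planted pausing mixture, graded
promoter-binding probability, knockdown perturbing expression of ~3%
of genes and damping the pausing ratio of highly paused genes):

```r
library(polpause)
res <- run_pipeline(run_config("demo_run", seed = 42))

res$annotation$table
#>                  category count   fraction
#> promoter         promoter   433 0.26515615
#> tes_proximal tes_proximal   150 0.09185548
#> gene_body       gene_body   350 0.21432945
#> intergenic     intergenic   700 0.42865891

res$comparisons$expr_bound_vs_unbound_WT
#> <comparison_result> expression (WT): bound vs unbound promoters
#>   n = 433 vs 567; medians 11.04 vs 5.723 (group1 up)
#>   statistic = 163742, p = 1.344e-19

res$high_pi
#> <high_pi_comparison> 262 gene(s) with WT PI >= 4
#> <comparison_result> PI WT vs KD, WT PI >= 4
#>   n = 262 vs 262; medians 7.91 vs 6.315 (group1 up)
#>   statistic = 53247, p = 9.22e-28
#>   WT-vs-KD PI correlation by promoter binding:
#>  bound   n   pearson  spearman
#>   TRUE 137 0.9985921 0.6528273
#>  FALSE 125 0.9981131 0.6900338
#> <comparison_result> PI change (log2 KD/WT): bound vs unbound
#>   n = 137 vs 125; medians -0.3279 vs -0.3248 (group1 down)
#>   statistic = 8045, p = 0.3987
```

Reading the output: about 26% of factor peaks sit at promoters; bound
genes are markedly more expressed (median 11.0 vs 5.7, Mann–Whitney
p ≈ 1e-19) and more paused than unbound genes; the highly paused set
(PI ≥ 4 in the wild type) loses pausing under knockdown (median PI
7.9 → 6.3, p ≈ 1e-27), but the per-gene shift is indistinguishable
between promoter-bound and unbound genes (p ≈ 0.4) — the planted
knockdown effect was indeed independent of binding, and the pipeline
says so.

The run directory contains every artifact as TSV/JSON (`pi_WT.tsv`,
`pi_KD.tsv`, `xcorr_<mark>.tsv`, `annotation.tsv`, `binding.tsv`,
`report.tsv`, `comparisons.json`), the generated inputs under `sim/`,
and the effective configuration (`config.yaml`). Identically seeded
runs are byte-identical.

Individual stages are available as functions (`pi_table()`,
`positional_correlation()`, `annotate_peaks()`, `promoter_binding()`,
`compare_strata()`, `high_pi_comparison()`, ...) and through a thin
command-line wrapper, `inst/scripts/polpause.R`, with `run`,
`simulate`, `pi`, `xcorr` and `annotate` subcommands.

## Documentation

`vignettes/polpause-methods.Rmd` describes the model and its
assumptions, every tunable parameter with its default and rationale,
what the synthetic generator does and does not emulate, and the
package's numerical conventions and limitations.
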