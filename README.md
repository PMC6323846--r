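# gselexmine

Integrated mining of genomic SELEX-Seq (gSELEX-Seq) binding-site catalogues
and differential-expression data, built around the regulon of the
*Aspergillus oryzae* transcription factor XlnR — a fungal Zn(II)2Cys6
factor controlling xylanolytic and cellulolytic genes — plus 1:1
binding-kinetics analysis of biolayer-interferometry (BLI) sensorgrams.

The package is for computational biologists who want a fully testable,
desk-scale implementation of the analysis: every input (genome, promoters,
fragment library, selected pools, reads, expression table, sensorgrams) can
be simulated from a seeded generator with planted ground truth, so each
stage's recovery behaviour is measurable.

## What it computes

- **Selection model.** Fragment binding weight `b + sum(w_m * n_m)` over the
  XlnR motifs (GGCTAA, GGCTGA, GGCTAG, CGGNTAAW, TTAGSCTAA); three rounds of
  multinomial enrichment proportional to abundance x weight; the
  round-0-normalized relative-binding curve; paired-end read emission.
- **Tag processing.** Linker trimming, exact seed-and-verify mapping,
  Poisson local-lambda peak calling with fold-enrichment (FE) ranking,
  summit detection and 50-bp summit windows.
- **Promoter annotation.** The upstream-1000 promoter set (position 1000 =
  base adjacent to the start codon) and an ungapped seeded matcher assigning
  windows to candidate regulated promoters.
- **Motif mining.** Both-strand IUPAC motif counting, coexistence flags,
  k-mer over-representation ranking of summit windows, Fisher's exact test
  of canonical-motif presence (intersecting vs non-intersecting DEGs), and
  Spearman/Pearson correlation of motif counts, coexistence flags, FE and
  summit position against expression ratios.
- **Kinetics.** The 1:1 Langmuir model
  `R(t) = Req (1 - exp(-(ka C + kd) t))`, `Req = Rmax C/(C + KD)`,
  dissociation `R(t) = R(ta) exp(-kd t)`; global Levenberg-Marquardt fitting
  of shared (ka, kd, Rmax) across analyte concentrations; `KD = kd/ka` in
  nM.

## Worked example

```r
library(gselexmine)

report <- run_pipeline(seed = 1)
report
#> <gselex_report> seed 1
#>   genes: 20 (5 regulated); peaks: 31; candidate promoters: 13
#>   DEGs (> 5-fold): 4; intersection: 4
#>   planted-promoter recall: 100%
#>   top k-mer: GGCTAA
```

The default run simulates a 20-gene genome in which 5 promoters carry
planted high-affinity GGCTAA sites, selects a 50,000-fragment library for
three rounds, sequences 20,000 read pairs of round 3, and mines the result.
Here all 5 planted promoters are recovered among the 13 candidates, and the
k-mer ranking of the top summit windows recovers GGCTAA — the factor's
strongest binding site — at rank 1:

```r
head(report$kmer, 3)
#> # A tibble: 3 x 6
#>   kmer   fg_count bg_count bg_expected log2_odds  rank
#> 1 GGCTAA       31     3146       0.923      3.79     1
#> 2 TAGCCA       10     2087       0.612      2.80     2
#> 3 GGGCTA       14     3139       0.921      2.67     3
```

`report$enrichment_curve` shows the relative binding of the selected pools
rising monotonically from 1 (round 0) — 6.9, 10.0, 11.6 here — and
`report$correlations` holds the Spearman/Pearson table of every binding
parameter against the expression ratio.

Kinetics:

```r
data <- sim_sensorgrams(ka = 1e5, kd = 1e-2, Rmax = 1,
                        concentrations = c(0, 25e-9, 50e-9, 100e-9),
                        noise_sd = 0.02, seed = 1)
fit <- bli_global_fit(data)
fit
#> <bli_fit> 1:1 global fit
#>   ka = 9.72e+04 1/(M s); kd = 0.0101 1/s; KD = 103 nM; Rmax = 1.02
#>   RSS = 3.539 over 4503 points; converged: TRUE
kd_from_rates(7.14e4, 2.22e-2)   # 311 (nM)
```

## Package layout

- `R/` — generator (`sim_genome`, `plant_motifs`, `sim_expression`,
  `build_library`), selection (`run_selection`, `relative_binding`,
  `emit_reads`), tag processing (`trim_adapters`, `map_reads`,
  `call_peaks`, `extract_windows`), annotation (`build_upstream1000`,
  `assign_windows`), mining (`count_motifs`, `kmer_enrichment`,
  `select_degs`, `intersect_sets`, `fisher_motif_presence`,
  `correlate_parameters`, `run_pipeline`), kinetics (`sim_sensorgrams`,
  `bli_global_fit`, `kd_from_rates`).
- `vignettes/gselex-mining.Rmd` — the methods vignette: models,
  assumptions, parameter choices, limitations.
- `inst/scripts/pipeline.R` — thin command-line wrapper over
  `run_pipeline()`.
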