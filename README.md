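# reprogR

Fold-change distribution thresholding and immune-gene-panel reprogramming for
bulk RNA-seq.

## What it does

In models of sepsis, cecal-microbiome injury massively rewires the expression
of immune genes, and candidate therapeutics are judged by how far they push
that response back toward baseline. reprogR quantifies this for a
three-condition design — uninjured reference (`sham`), injury (`cm`), and
injury plus treatment (`cm_ntci`) — over a curated panel of human inborn
errors of immunity (IEI) genes mapped to mouse symbols:

1. **Differential expression.** Median-of-ratios size factors and a two-group
   negative-binomial Wald test per contrast against `sham`. With few
   replicates the raw method-of-moments dispersion is too noisy for a normal
   reference, so each gene's dispersion is moderated toward the median of the
   expressed genes with a fixed prior weight (`prior_df = 10`) and the
   statistic referred to a t distribution on `residual df + prior_df`; the
   prior was calibrated on null simulations to hold the nominal 0.05 size at
   3 replicates per group.
2. **Distribution thresholding.** Every log2 fold change is rounded *down* to
   the nearest 0.1 and equal values summed; a Gaussian or Lorentzian peak is
   fit to the resulting histogram by Levenberg–Marquardt least squares.
   Significant genes (Benjamini–Hochberg `padj < 0.05`) beyond
   `center ± width` are `increased`/`decreased`; the rest of the fitted bulk
   is `unchanged`.
3. **Panel mapping.** Human panel symbols resolve to mouse symbols by curated
   exception, the panel's own mapping, or the Title-case convention, in that
   precedence.
4. **Reprogramming.** The two contrasts are paired per panel gene. The
   treatment's effect is `enhanced` or `suppressed` either when the category
   changes between contrasts (`rule = "category_change"`) or when the shift
   `delta_log2fc` exceeds the fitted width of the treatment contrast's
   distribution (`rule = "delta"`), with the fold ratio
   `2^(-delta_log2fc)` rendered as prose ("reduced 6.5-fold").

A negative-binomial simulator with known truth (`simulate_dataset()`,
`sepsis_panel_spikes()`, `recovery_experiment()`) measures sensitivity,
specificity, and false-positive reprogramming calls of the whole chain.
Model details, parameter defaults, and limitations are documented in
`vignettes/reprogramming-methods.Rmd`.

## Worked example

Simulate a dataset with the bundled 485-gene panel and known spikes
(Il10 170-fold up under injury, suppressed 6.5-fold by treatment; Nlrp12
40-fold down, reversed 4-fold), then run the full analysis:

```r
library(reprogR)
panel <- read_panel(system.file("extdata", "iei_panel_485_synthetic.tsv",
                                package = "reprogR"))
cfg <- sim_config(n_genes = 4000, seed = 42,
                  spike_table = sepsis_panel_spikes(panel, n_sensitivity = 20))
sim <- simulate_dataset(cfg, panel)
dim(sim$counts)
#> [1] 4000    9

an <- analyze_dataset(sim$counts, sim$sheet, panel, reprogram_rule = "delta")
#> stage classify [spleen/cm_vs_sham]: alpha=0.05 bin_width=0.1 model=gaussian center=-0.0031 width=0.3178
#> stage classify [spleen/cm_ntci_vs_sham]: alpha=0.05 bin_width=0.1 model=gaussian center=-0.0033 width=0.3220
#> stage reprogram [spleen]: rule=delta delta=0.3220

an$summary
#> Panel response summary (spleen)
#>   significantly expressed panel genes: 24 (of 485 present)
#>   increased 11 (45.8%), decreased 13 (54.2%), unchanged 0 (0.0%)
#>   reprogrammed by treatment: 7 (enhanced 6, suppressed 1)

an$fits[["cm_vs_sham"]]
#> gaussian peak fit: center = -0.0031, width = 0.3178, amplitude = 489.3, sse = 6.53e+03 (converged)

rec <- an$records
fold_statement(rec[rec$gene_id == "Il10", ])
#> [1] "reduced 6.5-fold"
fold_statement(rec[rec$gene_id == "Nlrp12", ])
#> [1] "reversed 4.0-fold"
```

The same run from the shell:

```sh
Rscript inst/scripts/reprog-cli.R simulate --panel <panel.tsv> --n-genes 4000 --seed 42 --out simdir
Rscript inst/scripts/reprog-cli.R run-all --counts simdir/counts.tsv \
    --samples simdir/samples.csv --panel <panel.tsv> --rule delta --out outdir
```

which writes per-organ DE tables, fit reports, gene classes, the panel
intersection, the reprogramming table, and `summary.json`. Externally produced
DE tables (e.g. from DESeq2) can replace the internal engine via
`read_de_table()` or the `de_cm`/`de_cm_ntci` paths in the run configuration.

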