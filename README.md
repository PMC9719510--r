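# chromexpr

Region-stratified integration of chromatin signal with gene expression.

## What problem this solves

Perturbation studies in epigenomics — for example, deleting a histone
methyltransferase in a T-cell subset — routinely produce two genome-wide
readouts: peak-level chromatin signal (H3K36me3 or H3K27ac ChIP-seq /
CUT&Tag, RNA polymerase II occupancy) per condition, and a gene-level
differential-expression table. The analytical question is whether changes
in chromatin signal *track* changes in transcription, and whether that
coupling is specific to the region classes where the mark is deposited
(promoters and gene bodies) rather than distal intergenic space.

`chromexpr` is an R package for that integration. For gene *g* and region
class *c* it computes the average per-peak fold change

    s_gc = mean over peaks p assigned to (g, c) of log2FC(p)

and the summed-counts locus statistic

    S_g = log2( (sum of normalized ko counts over locus peaks + pc) /
                (sum of normalized ctrl counts over locus peaks + pc) )

then reports, per region class, the Pearson correlation (with
t-distribution p-value) between `s_gc` and the mRNA log2 fold change, the
proportions of genes in each sign quadrant, and the hypergeometric
enrichment of the overlap between differential-peak genes and
differential-expression genes. Supporting modules provide GTF/BED12 gene
models, promoter/gene-body/intergenic partitioning, consensus-peak
merging, median-of-ratios normalization with a Welch-test differential
stand-in, RPKM coverage tracks, scaled metagene profiles, the
three-criteria DE significance filter, signature/top-N gene sets,
per-sample Z-scores and a colitis histology score. A synthetic-data
generator with planted region-specific correlations makes the whole chain
testable without any external data.

## Worked example

```r
library(chromexpr)

# a synthetic study: 200 genes, planted correlation of 0.8 between
# promoter-class peak effects and mRNA log2FC, nothing planted elsewhere
study <- simulate_study(synthetic_config(seed = 1, n_genes = 200))
res <- integrate_study(study)

res$integration$promoter_5utr
#> integration_result [promoter_5utr]: n = 169, R = 0.806 (p = 6.57e-40)
#>   quadrants: Q1 37.3%  Q2 8.9%  Q3 44.4%  Q4 9.5%  (0 on-axis excluded, 31 without peaks)

res$integration$distal_intergenic
#> integration_result [distal_intergenic]: n = 119, R = 0.029 (p = 0.752, NS)
#>   quadrants: Q1 23.5%  Q2 26.1%  Q3 26.1%  Q4 24.4%  (0 on-axis excluded, 81 without peaks)
```

Reading the output: of the 200 genes, 169 had at least one promoter/5'UTR
peak; their average peak log2FC correlates with mRNA log2FC at R = 0.806
(the planted 0.8), with most genes in the concordant Q1/Q3 quadrants
(up/up and down/down). The intergenic class, where no effect was planted,
is flat (`NS`) and its quadrants are near 25% each — the region
specificity the method is designed to expose.

File-based runs use a YAML config
(`validate_config()` + `run_integration()`), or the thin CLI:

```sh
Rscript inst/scripts/chromexpr.R simulate --seed 1 --n-genes 200 --out study/
Rscript inst/scripts/chromexpr.R run-all --config config.yaml
```

which writes the partition BED, consensus-peak BED, per-peak differential
TSV, per-gene fold-change TSVs, the integration table, metagene profiles
and a run log.

## Package layout

- `R/intervals.R`, `R/annotation.R`, `R/partition.R` — gene models,
  interval algebra, region partitioning and peak-to-gene assignment
- `R/signal.R` — coverage tracks, RPKM, interval quantification, metagene
  profiles, fragment counting
- `R/peaks.R` — consensus peaks, size factors, per-peak differential
  statistics, per-gene fold-change aggregations
- `R/de.R` — DE filters, signatures, top-N sets, Z-scores, histology score
- `R/integration.R` — correlation, quadrants, overlap enrichment
- `R/simulate.R` — the synthetic study generator
- `R/pipeline.R`, `inst/scripts/chromexpr.R` — config, orchestration, CLI
- `vignettes/integrating-chromatin-and-expression.Rmd` — methods notes:
  model, conventions, parameter choices, limitations
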