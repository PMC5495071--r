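# gnotoreg

Integrative statistical analysis for gnotobiotic 2x2 regulatory genomics:
how does microbiota colonization reshape a host transcription factor's
regulatory program?

## The problem

Studies of host-microbiota interaction commonly cross host genotype
(wild-type vs a transcription-factor mutant, WT/Mut) with colonization state
(germ-free vs conventionalized, GF/CV), then integrate RNA-seq with
condition-specific binding sites or enhancer marks, and finally ask whether
the same regulatory signature appears in human disease cohorts through
ortholog maps. `gnotoreg` implements that whole analysis chain as a tested,
reusable R package, together with a synthetic-data generator that plants
known structure in every input — so each stage, and the pipeline end to end,
can be validated without any sequencing data.

The statistical core:

* **Differential testing** — a fully specified negative-binomial two-group
  likelihood-ratio test with median-of-ratios normalization, per-gene
  method-of-moments dispersion pooled across design cells, and an
  `F(1, df)` reference that keeps null p-values calibrated at 2–3
  replicates; BH FDR control. One test serves both gene counts and
  regulatory-region counts.
* **Set logic** — four-way differential membership (union + all 15 Venn
  regions) and fold-change quadrant classification: with x = log2FC(GF/CV)
  and y = log2FC(WT/Mut), genes in the `(+,+)` quadrant are *suppressed by
  the microbiota and activated by the factor* — the class whose share among
  microbiota-suppressed genes is the headline quantity.
* **Region association** — single-nearest-TSS assignment within 10 kb
  (summit else midpoint; lexicographic tie-break), GF/CV peak-set sharing,
  and RPKM-normalized flanking-signal profile matrices.
* **Concordance** — a two-sample Kolmogorov–Smirnov test comparing CV/GF
  expression fold changes of genes near CV-enriched vs GF-enriched regions:
  `D = max |ECDF_A - ECDF_B|`, asymptotic p at effective size
  `n1*n2/(n1+n2)`, exact mode for small samples.
* **Ortholog enrichment** — one-to-one filtering, three-way chaining, and
  upper-tail hypergeometric enrichment `P(X >= k)`,
  `X ~ Hypergeom(N, K, n)`, BH-adjusted across the disease x condition
  grid.
* **Deming regression** — errors-in-variables slopes for paired orthologous
  fold changes,
  `m = (s_yy - d*s_xx + sqrt((s_yy - d*s_xx)^2 + 4*d*s_xy^2)) / (2*s_xy)`
  with jackknife standard errors, one-sided slope-comparison z tests, and a
  labeled concordance grid against reference comparisons.

## Worked example

```r
library(gnotoreg)

report <- run_pipeline(pipeline_config(sim_config(seed = 1)))
print(report)
#> Integrative pipeline report (seed 1 )
#>   differential genes per contrast: WTCV/WTGF=310, MutCV/MutGF=181, WTCV/MutCV=219, WTGF/MutGF=183
#>   union of differential genes: 479
#>   coregulated (both axes): 88; suppressed & activated fraction: 0.839
#>   KS concordance: D = 0.994, p = 8.85e-66, shift +1
#>   peaks: 535 GF (183 GF-specific), 510 CV (158 CV-specific)
#>   Deming slopes: WTCV/WTGF=0.378, MutCV/MutGF=0.342, MutCV/WTCV=0.727, MutGF/WTGF=0.736, MutCV/WTCV (assoc)=0.785
```

Reading the numbers: 479 of 2000 simulated genes are differential somewhere
in the 2x2 design; 88 are significant on both the microbiota and genotype
axes, and 83.9% of the microbiota-suppressed ones are factor-activated
(planted mixture: 90%, within the binomial band at n = 56). The KS test
confirms that genes near CV-enriched regions shift toward CV expression
(shift +1) with overwhelming significance. The GF binding-site set is larger
than the CV set, with 158 CV-specific sites. The Deming slope of the
synthetic disease fold changes on the MutCV/WTCV comparison (0.727,
planted slope 0.8 attenuated slightly by fold-change estimation error)
clearly exceeds the WTCV/WTGF null comparison (0.378), and restricting to
genes with a GF binding association raises it further (0.785) — the
signature sharpens among directly bound genes.

Individual stages are plain functions (`differential_table()`,
`assign_peaks_to_genes()`, `ks_region_expression()`,
`hypergeometric_enrichment()`, `deming_fit()`, ...) and all file formats are
standard (BED, bedGraph, TSV, JSON); see the methods vignette
(`vignettes/methods.Rmd`) for models, defaults and design decisions. A thin
CLI (`inst/scripts/gnotoreg`) exposes `simulate` and `run-all` over a YAML
config.

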