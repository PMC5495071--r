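---
title: "Methods: models, planted structure and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, planted structure and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gnotoreg)
```

# Scope

`gnotoreg` implements the statistical backbone of a class of host-microbiota
regulatory genomics studies: a 2x2 design crossing host genotype (wild-type
vs a transcription-factor mutant) with colonization state (germ-free, GF, vs
conventionalized, CV), integrated with condition-specific binding/enhancer
regions, cross-species ortholog maps, and human disease differential-gene
lists. Every stage runs on synthetic data with planted ground truth, so the
whole analysis is testable on a desktop with no sequencing data. This
vignette records the models, the generator's assumptions, and the design
choices that were genuinely open.

# The differential test

Counts are modeled per gene as negative binomial with mean `mu` and
dispersion `alpha` (variance `mu + alpha*mu^2`). Normalization uses
median-of-ratios size factors rescaled to geometric mean 1. For one
contrast, group means are maximum-likelihood under per-sample means
`m * s_j` (size factor `s_j`), and the common-mean null is compared to the
per-group alternative by a likelihood ratio.

Two numerical choices matter:

* **Dispersion.** `alpha` is a per-gene method-of-moments estimate: each
  design cell with at least two replicates contributes `(s2 - m)/m^2`
  (computed on normalized counts, with the shot-noise term scaled by `1/s`
  so the estimate is invariant to a global rescaling of library sizes), and
  cells are pooled by a df-weighted mean on the *dispersion* scale. Pooling
  on the dispersion scale rather than the variance scale keeps the estimate
  unbiased for genes whose means differ across cells, which is exactly the
  genes the test must rank well. Estimates are floored at 1e-8. All four
  design cells inform each gene's estimate — within-gene pooling only; there
  is deliberately no shrinkage across genes, so each gene's result is
  self-contained.
* **Reference distribution.** With 2-3 replicates per cell the dispersion
  estimate carries only `N - k` residual df (6 in the default 3/3/2/2
  design). Treating it as known and using chi-square(1) is strongly
  anti-conservative at these sizes (measured type-I error ~0.11 at nominal
  0.05). The LRT is therefore referred to `F(1, df_dispersion)`, the
  quasi-likelihood-style correction; the chi-square reference is its
  large-`N` limit. Measured at 3 vs 3 replicates this gives type-I error
  ~0.045 and a null p-value distribution indistinguishable from uniform
  (KS D ~ 0.014 over 2000 genes). The cost is tail power: extreme p-values
  are bounded by the F tail, so recovery of planted effects at the default
  dispersion 0.1 is ~60-70% per contrast rather than the near-complete
  recovery an anti-conservative reference would claim. We consider that
  trade honest and correct.

Fold changes are `log2((m1 + 0.5)/(m2 + 0.5))` on the normalized scale with
the numerator group first; swapping numerator and denominator negates the
fold change and leaves p-values unchanged. Genes with zero counts across a
contrast are reported untested. BH adjustment is the standard step-up rule;
the default significance cuts are q < 0.05 for genes (a conventional choice,
exposed in the config) and q < 0.01 for regions.

# Four-way logic and quadrant classes

The four contrasts (WTCV/WTGF, MutCV/MutGF, WTCV/MutCV, WTGF/MutGF) share
one gene universe. Membership flags at the q cut define the union and all 15
disjoint Venn regions; their sum equals the union size by construction and
is asserted on every run. Quadrant classification places each gene
significant on both axes by its fold-change sign pair, with the microbiota
axis oriented GF-over-CV (positive = suppressed by the microbiota) and the
genotype axis WT-over-Mut (positive = activated by the factor). The
headline summary is the fraction of microbiota-suppressed coregulated genes
that are factor-activated. A zero fold change with a significant q is
treated as contradictory input, not silently classified.

# Regions, assignment and concordance

Intervals are 0-based half-open everywhere, with no 1-based auto-detection —
the classic silent off-by-one is the failure mode we refuse to risk. Peaks
are assigned to the single nearest gene TSS within 10 kb, measured from the
summit when one is recorded and from the floored midpoint otherwise (one
rule covering both summit-bearing binding peaks and edge-defined
histone-mark regions); exact ties break to the lexicographically smaller
gene id so results are reproducible. Distance is to the TSS only, not the
gene body.

The enhancer-state/expression concordance test takes the CV/GF expression
fold changes of genes assigned to CV-enriched regions (sample A) and
GF-enriched regions (sample B) and compares them with a two-sample
Kolmogorov-Smirnov test. A positive shift sign means enhancer state and
expression agree in direction. Genes near both kinds of region contribute to
both samples (count reported) rather than being dropped. The p-value uses
the asymptotic Kolmogorov distribution at effective size `n1*n2/(n1+n2)`;
an exact mode (via the Smirnov distribution) is used automatically for
`n1*n2 <= 1e4` without ties. At group sizes around 50 the statistic is
discrete, so null p-values are valid but conservative between atoms —
calibration should be judged by rejection rates, not strict uniformity. A
background mode comparing each group against all genes is available; the
pairwise mode is the default because it is the minimal construction that
tests the direction claim.

Signal profiles around summits are RPKM-style: per-bin coverage sums divided
by `(bin_width/1000) * (library_size/1e6)`, with bedGraph values read as
per-base depth and any read-length factor absorbed into the recorded
normalization constant, so GF and CV profiles computed with the same
parameters are directly comparable. Bins truncated at a chromosome start are
zero-filled, flagged, and excluded from profile means.

# Orthologs, enrichment, Deming

One-to-one filtering removes every pair whose partner on either side is
ambiguous; it is idempotent, and chaining two filtered maps through the
middle species yields one-to-one-to-one triples. The enrichment test is the
upper-tail hypergeometric `P(X >= k)`. The background universe is defined as
the genes that survive ortholog chaining *and* appear in the annotation —
the natural population from which both the query and annotated sets are
drawn; this definition is a package decision (recorded in output metadata),
since enrichment backgrounds are frequently left unstated in the literature.
BH adjustment is applied across the disease-list-by-condition grid, and raw
`-log10 p` is emitted alongside.

Cross-species fold-change concordance uses Deming (errors-in-variables)
regression, appropriate because both axes are estimated log2 fold changes
with comparable noise. With error-variance ratio `delta` (default 1, the
standard choice when per-point error variances are unknown), the slope has
the closed form
`(s_yy - delta*s_xx + sqrt((s_yy - delta*s_xx)^2 + 4*delta*s_xy^2)) / (2*s_xy)`,
which minimizes `sum (y - a - b*x)^2 / (delta + b^2)`. The slope standard
error is a leave-one-out jackknife — assumption-light and directly
checkable by CI coverage on simulations (measured coverage 0.90-0.98 at the
planted-slope conditions). Slope comparisons are normal-theory z tests on
jackknife SEs, one-sided "greater" by default to match the directional
question the grid answers; raw and BH-adjusted p-values are both emitted
because multiplicity handling for such grids is often unstated. Ordinary
least squares on the same noisy data is attenuated below the Deming slope;
that contrast is asserted in the tests as the reason the errors-in-variables
choice matters.

# The synthetic-data generator

The generator defines the study conditions; it is not a tuning dial.
Defaults: 2000 genes over three chromosomes (60/40/25 Mb); replicate layout
3/3/2/2 (WTGF/WTCV/MutGF/MutCV), mirroring the common situation where mutant
animals are scarcer; NB dispersion 0.1 and log2 baseline means uniform on
[3, 10], typical of bulk RNA-seq in this tissue; per-sample depth factors
log-normal with sd 0.15; effect size 2 on the log2 scale for every planted
axis; class mixture 4.5% suppressed+activated, 0.5% suppressed+repressed,
1% induced+activated, 4% induced+repressed, 10% colonization-only, 10%
genotype-only, 70% null. The suppressed classes dominate their induced
counterparts in the activated column (9:1), emulating a factor that mostly
activates microbiota-suppressed genes; single-axis classes draw a random
effect sign. Effects are additive on the log2 mean with no
genotype-by-colonization interaction by default (an `interaction` knob
exists, default 0); consequently the two genotype contrasts are
exchangeable in truth, and the colonization contrasts likewise, which is why
the pipeline's Deming grid designates WTCV/WTGF as its null comparison.

Peaks: every planted-effect gene receives exactly one peak (width 200-400
bp) with its summit within ±900 bp of the TSS — inside the assignment
radius and always nearer its own gene than any neighbor at the 2 kb TSS
spacing floor, keeping assignment ground truth unambiguous. A planted
gene's peak is *specific to its expression-concordant condition* with
probability `peak_gf_bias` (default 0.8): GF-specific when the gene is
higher in GF, CV-specific when higher in CV, shared otherwise;
genotype-only genes get shared peaks. We chose this direction-aligned rule
(rather than making every condition-specific peak GF-only) because the
enhancer-state/expression concordance stage is only testable when both
enriched region sets carry genes with a real expression shift; under the
suppression-dominated default mixture the GF cistrome is still the larger
one, emulating colonization-dependent binding loss. Null genes contribute
background peaks at random positions (rate 0.05, both conditions),
exercising the unassigned path. Coverage tracks are flat background 1 with
a triangular bump (height 15) at each present peak's summit; region count
matrices are NB draws around each condition track's integral over the
region.

Orthologs: mouse/human partners are name-derived (`m_`/`h_` prefixes) with
independent dropout (default 0.1) per pairwise table and paralog injection
(default 0.05) that the one-to-one filter must remove. The disease list
shares its latent axis with the expression simulator: for each orthologized
gene, `y = 0.8 * x_star + noise` where `x_star` is the planted MutCV/WTCV
log2 fold change and both noise SDs default to 0.3; genes with a nonzero
genotype effect form the list's significant subset, labeled by the sign of
`y`. Deming pairs are built over *all* orthologized genes, not only the
disease-significant subset: restricting to significant genes concentrates
genotype-only genes (x near 0, |y| near the planted effect), whose
unexplained vertical variance the errors-in-variables model must attribute
to the line, inflating the null-comparison slope and defeating the
planted-versus-null ordering the design intends. The direction labels of
the significant subset feed the enrichment and proportion stages instead.

What the generator does *not* emulate: read-level noise and mappability,
GC/length biases, correlated dispersion across genes, multi-peak genes,
motif content, and annotation errors. Passing tests therefore demonstrate
that the statistical machinery is correct and well calibrated under the
stated model — not that real libraries meet that model.

# Pipeline and determinism

`run_pipeline()` executes simulate (or load) → four differential tables →
region differential → assignment → four-way/quadrant/KS concordance → peak
comparison → profiles → ortholog enrichment → Deming grid, writing
intermediate TSV/JSON files when an output directory is set. One seed
controls the run; each generator stage derives a fixed substream from it, so
stage re-runs reproduce run-all results and identical config+seed gives
byte-identical reports. The report records the seed, an MD5 of the config,
and the package version.

Problem sizes used by the test suite: oracle equivalences run on
hundreds-to-thousands of small random instances; calibration uses 2000 null
genes; recovery and end-to-end checks use the default 2000-gene
configuration across 50 seeded runs. These sizes give the Monte Carlo
assertions comfortable margins while keeping the suite quick on one core.

# Known limitations

* Power at 2 replicates per group is intrinsically poor under honest
  calibration with per-gene dispersion; cross-gene shrinkage would help but
  is out of scope by design.
* The KS p-value is discrete at small group sizes (see above).
* The jackknife slope SE can be optimistic for n < ~20 pairs; the package
  refuses fits below 3 points but does not warn between 3 and 20.
* `delta` is a global constant; per-point error variances (weighted Deming)
  are not supported.
* The region differential stage consumes replicated region counts; when
  only coverage tracks exist, the synthetic route draws replicates around
  track integrals, which understates biological replicate variability.
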