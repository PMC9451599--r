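# evotriage

Somatic mutations in a tumor cohort record the outcome of selection:
mutations that raised cancer-cell fitness are enriched (drivers), while
genes whose intact function the tumor needs show a systematic *deficit* of
protein-altering mutations. That deficit — negative selection — cannot be
seen in one tumor; it emerges only as a cohort-level shortfall relative to
what a gene's size predicts. `evotriage` scores both directions of
selection for every gene in a cohort, with particular attention to
immune-interaction genes, where negative selection marks functions a tumor
keeps in order to evade the host response.

## The statistic

For gene *g* in a cohort of *n* patients:

- raw fraction `f_g = k_g / n` of patients with ≥1 protein-altering
  mutation (nonsynonymous, truncating, canonical splice-site; a patient
  counts once per gene);
- coverage-corrected fraction `c_g = f_g / m_g`, where `m_g` is the cohort
  median fraction of the gene's coding bases sequenced to sufficient depth
  (≥14 tumor / ≥8 normal reads);
- size adjustment by linear regression of `sqrt(c_g)` on
  `sqrt(coding length)` over all kept genes (OLS by default, Huber robust
  optional);
- selection score `SR_g = residual_g / residual standard error`.

`SR ≤ -1` flags conserved (under-mutated) genes, `SR ≥ 1` over-mutated
genes; reporting tiers at |SR| ≥ 1.65 (p ≈ 0.1) and |SR| ≥ 2.0 (p ≈ 0.05).
Genes with median coverage < 50%, log2 expression < 2.0, or annotation
errors are excluded before the fit. Patients are first stratified into
driver cohorts (mKRAS / mBRAF / mEGFR / WT, multi-driver patients
excluded) from hotspot and indel rules, because selection differs by
initiating oncogene.

## Worked example

Everything below runs from a seeded synthetic cohort — 400 patients,
2 000 genes, 20 genes planted fully conserved and 5 planted five-fold
over-mutated, plus KRAS/BRAF/EGFR hotspot drivers:

```r
library(evotriage)

cfg <- synthetic_cohort_config(n_patients = 400, n_conserved = 20,
                               n_drivers = 5,
                               hotspot_drivers = hotspot_driver_spec(),
                               seed = 7)
bundle <- generate_cohort(cfg, dir = "synthetic")
run <- run_pipeline(list(maf = "synthetic/maf.tsv",
                         coverage = "synthetic/coverage.tsv",
                         expression = "synthetic/expression.tsv",
                         annotation = "synthetic/annotation.tsv",
                         out_dir = "triage_out"))
#> assign_cohorts: excluded=15, mBRAF=8, mEGFR=21, mKRAS=89, WT=267

head(run$scores$WT[c("gene_symbol", "n_mutated", "f", "m", "c",
                     "sr", "label", "tier")])
#>   gene_symbol n_mutated     f     m     c    sr label     tier
#> 1 G01551              0     0 0.974     0 -7.97 conserved significant
#> 2 G00481              0     0 0.971     0 -7.22 conserved significant
#> 3 G00254              0     0 0.974     0 -7.18 conserved significant
#> 4 G00002              0     0 0.972     0 -6.34 conserved significant
#> 5 G01855              0     0 0.970     0 -5.79 conserved significant
#> 6 G00407              0     0 0.974     0 -5.38 conserved significant
```

The six most negative scores in the WT cohort are all long genes with zero
observed mutations — far below their size expectation — and all six are
planted conserved genes; across the whole run, all 20 planted conserved
genes score SR ≤ -1.65. The other end of the ranking is dominated by the
planted over-mutated genes:

```r
tail(run$scores$WT[c("gene_symbol", "n_mutated", "f", "sr", "label")], 3)
#>   gene_symbol n_mutated     f    sr label
#> 1 G01077             76 0.285  6.69 over_mutated
#> 2 G00111             94 0.352  7.35 over_mutated
#> 3 G00483            131 0.491  7.49 over_mutated

length(frequently_mutated(run$scores$WT))   # genes mutated in > 10% of patients
#> [1] 49
```

`triage_out/` contains per-cohort score TSVs, filter reports with
per-gene exclusion reasons, cohort assignments, and a JSON manifest of
input checksums and counts; reruns on identical inputs are
byte-identical. With a panel YAML (template in
`inst/extdata/immune_panels_template.yaml`), `run_pipeline()` also writes
Table-style conserved / over-mutated panel reports per cohort and the
cross-cohort overlap; see `panel_report()` and `cross_cohort_overlap()`.

For real data, point `maf` at a TCGA MC3-dialect MAF (gzip fine), supply
per-sample per-gene coverage fractions and a gene annotation/expression
table, and keep the defaults; `vignettes/evolutionary-triage.Rmd` explains
every modelling choice, parameter and limitation.

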