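---
title: "Scoring somatic selection with coverage-corrected size-adjusted residuals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring somatic selection with coverage-corrected size-adjusted residuals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evotriage)
```

## The model

Tumor evolution removes mutations that cost the cancer cell fitness and
enriches those that raise it. Positively selected ("driver") genes are
therefore mutated more often than chance predicts, while genes whose intact
function the tumor cell needs — including many genes that mediate immune
evasion — accumulate *fewer* protein-altering mutations than a passenger
gene of the same size. The negatively selected class is invisible in any
single tumor; it only appears as a systematic deficit across a cohort.

`evotriage` quantifies both directions with a single per-gene statistic.
For a cohort of $n$ patients and a gene $g$:

1. **Raw mutated fraction.** $f_g = k_g / n$, where $k_g$ is the number of
   patients carrying at least one protein-altering mutation
   (nonsynonymous, truncating, or canonical splice-site) in $g$. A patient
   counts once per gene no matter how many mutations they carry.
2. **Coverage correction.** $c_g = f_g / m_g$, where $m_g$ is the cohort
   median of the per-sample fraction of the gene's coding bases (longest
   transcript, 25 bp flanks) with sufficient depth — at least 14 reads in
   the tumor and 8 in the matched normal. Without this step, poorly
   sequenced genes masquerade as conserved. $c_g$ is deliberately not
   capped at 1.
3. **Size adjustment.** Longer genes present a larger mutational target, so
   $\sqrt{c_g}$ is regressed on $\sqrt{L_g}$ ($L_g$ = coding length in
   bases) across all kept genes. The square-root transform both linearizes
   the relationship (for small per-base rates $r$, $c_g \approx r L_g$, so
   $\sqrt{c_g} \approx \sqrt{r}\,\sqrt{L_g}$) and approximately stabilizes
   the binomial sampling variance of the patient fractions.
4. **Standardized residual.** Each gene's selection score is
   $\mathrm{SR}_g = (y_g - \hat y_g)/\hat\sigma$ with $y_g = \sqrt{c_g}$
   and $\hat\sigma$ the residual standard error
   $\sqrt{\mathrm{RSS}/(n_\text{genes}-2)}$. Genes with
   $\mathrm{SR} \le -1$ are called conserved, $\mathrm{SR} \ge 1$
   over-mutated, and the rest background; reporting concentrates on
   $|\mathrm{SR}| \ge 1.65$ (normal two-sided $p \approx 0.1$) and
   $|\mathrm{SR}| \ge 2.0$ ($p \approx 0.05$). No multiple-testing
   correction is applied, and the normal $p$-values are reference
   quantities, not calibrated error rates — the score is a ranking and
   flagging device.

Genes with cohort median coverage below 50%, log2 expression below 2.0, or
annotation errors are excluded before the fit: the first class has
artificially depressed observed rates even after correction, and the
second is unlikely to be under meaningful selection if the tumor does not
express it. Values exactly at a boundary (0.50, 2.0) are kept, matching
the strict-inequality convention of the exclusion rules.

## Cohort stratification

Because selection pressures differ by initiating oncogene, patients are
stratified before scoring. A patient is assigned `mKRAS`, `mBRAF` or
`mEGFR` when exactly one of the rule genes carries a qualifying mutation:
a non-synonymous substitution at a hotspot residue (KRAS G12/G13/Q61/A146;
BRAF V600/N581/G464/G466/G469/G596/D594; EGFR L858/S768/L861/G719/T790) or,
for EGFR, an indel in exons 18–21. Patients matching two or more rule genes
are excluded; patients matching none form the `WT` (no known driver)
cohort. Matching uses the *reference* residue parsed from the HGVSp string
(`p.G12D` matches the G12 site whatever the alternate allele; `p.G12G`
does not, since a synonymous change cannot be an activating driver
lesion), with three-letter residue codes normalized to one-letter form.
When an indel's exon number is absent from the MAF, a configurable
protein-residue window (default 688–875 for EGFR) stands in — the exon
boundaries of the relevant kinase-domain exons.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `tumor_min`, `normal_min` | 14, 8 reads | per-base depth sufficiency |
| `flank` | 25 bp | region flank around coding bases |
| `min_median_cov` | 0.50 | gene filter on cohort median coverage |
| `min_expression_log2` | 2.0 log2 counts | gene filter on expression |
| `flag` / `suggestive` / `significant` | 1.0 / 1.65 / 2.0 | SR tiers |
| `estimator` | `"ols"` | size-regression estimator |
| frequent-mutation cutoff | 0.10 (strict) | `frequently_mutated()` |

**OLS vs robust.** The size regression can be fitted by ordinary least
squares or by a Huber M-estimator (`estimator = "huber"`, tuning 1.345 via
`MASS::rlm`). Strong drivers are extreme positive outliers and inflate
both the OLS slope and the residual scale, slightly compressing everyone
else's SR; the Huber fit resists this. OLS is the default because its
standardized residuals have an exact closed form (used as an independent
oracle in the test suite), its residuals sum to zero so the SR
distribution is automatically centred, and on realistic cohorts the two
fits differ little. When the two estimators disagree materially, the data
contain influential outliers and the robust fit is the safer ranking.

**Standardized-residual flavour.** The default divides every residual by
one global residual scale. `sr_method = "studentized"` additionally
divides by $\sqrt{1-h_g}$ (leverage $h_g$), which matters only for genes
at the extremes of the length distribution; with thousands of genes the
leverages are tiny and the two flavours agree to a few percent.

**Zero-mutation genes** are retained in the fit: $\sqrt{0}=0$ is
well-defined, and removing them would bias the background line upward
exactly where negative selection is informative.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure of a real cohort
so every stage is testable without any sequencing data:

* coding lengths are log-normal (median 1 500 bp, $\sigma = 0.6$ on the
  log scale), spanning roughly 300 bp–8 kb like real transcripts;
* each patient mutates each gene independently with probability
  $1-(1-r\mu_g)^{L_g}$, where $r = 2\times10^{-5}$ per base per patient —
  chosen so a median-length neutral gene is hit in about 3% of patients,
  a typical exome-cohort magnitude — and $\mu_g$ is the gene's selection
  multiplier (1 neutral, 0 fully conserved, >1 positively selected);
* per-sample coverage fractions are Beta(60, 2) (median ≈ 0.97), with
  planted low-coverage genes drawn from Beta(20, 30) so their cohort
  median is safely below 0.5 at any realistic cohort size;
* log2 expression is Normal(7, 2) floored at 2.0, with planted
  low-expression genes uniform on (0.5, 1.5); the floor guarantees that
  exactly the planted genes fail the expression filter, which is what the
  filter-exactness checks require of the generator;
* optional hotspot plantings write HGVSp strings and exon numbers that
  match the stratification rules, with per-rule planting fractions
  echoing the relative LUAD prevalences (KRAS > EGFR > BRAF); background
  events always use a serine reference residue and exons 1–5, so under
  the default rules only planted rows can match and the per-patient truth
  labels are exact;
* all randomness derives from one root seed through fixed per-stream
  offsets, so a fixed seed reproduces the bundle byte-for-byte and the
  streams (lengths, expression, coverage, mutations, hotspots) can be
  varied independently.

What the generator does *not* emulate: trinucleotide mutational
signatures, regional mutation-rate covariates (replication timing,
chromatin), hypermutator patients, subclonality, and correlated
coverage dropout. Passing the synthetic recovery checks therefore shows
the statistic does what it claims **given its own model of the data** —
per-patient Bernoulli events with a size-linear rate — not that real
cohorts satisfy that model. On real data the residual spread includes
rate heterogeneity that the binomial model ignores, which is precisely
why the method treats SR as a flag-and-rank score with conservative
reporting tiers rather than as a calibrated test.

## Numerical choices and degenerate inputs

* The regression refuses to fit fewer than 3 genes or an all-equal length
  vector, and refuses to standardize residuals when the fit is perfect
  (residual scale below $10^{-12}$ of the data scale) — both indicate a
  degenerate instance rather than a recoverable condition.
* Median coverage with an even sample count is the mean of the two
  central values (the standard convention).
* Genes present in the annotation but absent from the coverage table are
  treated as median 0 (excluded, reason "coverage") and counted in a
  message, never dropped silently.
* Ties in hotspot matching cannot arise (site sets are disjoint per
  rule); a patient matching several *rules* is excluded by construction.
* Multi-sample patients keep the primary-tumor (`-01`) sample, breaking
  remaining ties by lexicographically smallest barcode — a deterministic
  rule chosen because reproducibility matters more than matching any
  particular upstream convention.

## Problem sizes used in validation

The shipped validation suite exercises: 20 random ≤50-gene instances
against the closed-form OLS oracle (agreement to $10^{-10}$); 20 neutral
cohorts of 200 patients × 2 000 genes (fraction of $|\mathrm{SR}|\ge2$
flags stays below 10%, mean SR centred at 0); 20 replicates of 400
patients with 20 fully conserved and 5 five-fold over-mutated genes
planted in the longest length quartile (all conserved plants recovered at
$\mathrm{SR}\le-1.65$; the top-ranked gene is always a planted driver);
filter and stratification exactness on smaller planted cohorts; and
byte-identical reproduction of every artifact under a fixed seed. These
sizes keep each property statistically decisive while the whole suite
runs in about a minute.

## A worked run

```{r example, eval = FALSE}
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
head(run$scores$WT)          # most conserved genes first
plot_sr_expression(run$scores$WT)
```

`triage_out/` then holds per-cohort score tables, filter reports, the
cohort assignments and a JSON manifest with input checksums and counts,
all byte-stable across reruns.

## Known limitations

* The SR thresholds assume the standardized residuals are roughly
  normal; for genes with expected mutation counts near zero the residual
  distribution is discrete and left-skewed, so very small cohorts
  over-flag short genes. The coverage and expression filters remove part
  of, but not all of, this class.
* Coverage correction divides by a *median*; a gene covered well in half
  the cohort and not at all in the other half is corrected as if
  uniformly covered.
* Stratification sees only point mutations and indels in the MAF —
  fusion- or amplification-driven tumors land in `WT`.
* The curated panel template shipped in `inst/extdata` is intentionally
  partial (symbols recoverable from published summary tables only);
  serious use requires a user-supplied panel YAML.
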