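test_that("multiplier zero silences a gene completely", {
  cfg <- synthetic_cohort_config(n_patients = 80, n_genes = 50,
                                 selection_multiplier = c(G00007 = 0),
                                 seed = 21)
  bundle <- generate_cohort(cfg)
  pa <- bundle$records[is_protein_altering(bundle$records), ]
  expect_false("G00007" %in% pa$gene_symbol)
  expect_equal(bundle$truth_genes$multiplier[
    bundle$truth_genes$gene_symbol == "G00007"], 0)
})

test_that("a fixed seed reproduces the bundle byte-for-byte", {
  cfg <- synthetic_cohort_config(n_patients = 40, n_genes = 60,
                                 n_conserved = 2, n_low_coverage = 2,
                                 hotspot_drivers = hotspot_driver_spec(),
                                 seed = 5)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  b1 <- generate_cohort(cfg, dir = d1)
  b2 <- generate_cohort(cfg, dir = d2)
  expect_equal(b1$records, b2$records)
  expect_equal(b1$coverage, b2$coverage)
  expect_equal(b1$truth_genes, b2$truth_genes)
  for (f in c("maf.tsv", "coverage.tsv", "expression.tsv", "annotation.tsv",
              "truth_genes.tsv", "truth_patients.tsv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
})

test_that("neutral mutated fractions track the closed-form Bernoulli rate", {
  # all genes 1500 bp (sigma 0) so each neutral gene has per-patient
  # probability 1 - (1 - 2e-5)^1500 ~ 0.0296; pool 20 replicates and compare
  # with the exact binomial expectation within 3 standard errors
  p_expect <- 1 - (1 - 2e-5)^1500
  hits <- 0L
  trials <- 0L
  for (i in 1:20) {
    cfg <- synthetic_cohort_config(n_patients = 300, n_genes = 50,
                                   length_sigma = 0, seed = 1000 + i)
    bundle <- generate_cohort(cfg)
    pa <- bundle$records[is_protein_altering(bundle$records), ]
    mf <- mutation_fraction(pa, bundle$truth_patients$patient_id,
                            genes = bundle$truth_genes$gene_symbol)
    hits <- hits + sum(mf$n_mutated)
    trials <- trials + 300L * 50L
  }
  se <- sqrt(p_expect * (1 - p_expect) / trials)
  expect_lt(abs(hits / trials - p_expect), 3 * se)
})

test_that("raising one multiplier never lowers that gene's mutated fraction", {
  # identical seeds share the uniform draws, so a higher per-gene
  # probability yields a superset of mutation events
  for (i in 1:20) {
    lo <- generate_cohort(synthetic_cohort_config(
      n_patients = 60, n_genes = 40, seed = 500 + i))
    hi <- generate_cohort(synthetic_cohort_config(
      n_patients = 60, n_genes = 40,
      selection_multiplier = c(G00010 = 3), seed = 500 + i))
    pa_lo <- lo$records[is_protein_altering(lo$records), ]
    pa_hi <- hi$records[is_protein_altering(hi$records), ]
    f_lo <- length(unique(pa_lo$patient_id[pa_lo$gene_symbol == "G00010"]))
    f_hi <- length(unique(pa_hi$patient_id[pa_hi$gene_symbol == "G00010"]))
    expect_gte(f_hi, f_lo)
  }
})

test_that("planted low-coverage genes are excluded for coverage, every time", {
  for (i in 1:5) {
    cfg <- synthetic_cohort_config(n_patients = 50, n_genes = 120,
                                   n_low_coverage = 4, n_low_expression = 4,
                                   n_annotation_error = 2, seed = 300 + i)
    bundle <- generate_cohort(cfg)
    cov_med <- median_coverage(bundle$coverage)
    flt <- filter_genes(bundle$annotation, cov_med)
    truth <- bundle$truth_genes
    rep <- flt$report
    lowcov <- truth$gene_symbol[truth$planted_low_coverage]
    lowexp <- truth$gene_symbol[truth$planted_low_expression]
    annerr <- truth$gene_symbol[truth$planted_annotation_error]
    expect_true(all(grepl("coverage",
                          rep$reasons[rep$gene_symbol %in% lowcov])))
    expect_true(all(grepl("expression",
                          rep$reasons[rep$gene_symbol %in% lowexp])))
    expect_true(all(grepl("annotation",
                          rep$reasons[rep$gene_symbol %in% annerr])))
    expect_setequal(setdiff(truth$gene_symbol, flt$kept),
                    c(lowcov, lowexp, annerr))
  }
})

test_that("the emitted MAF re-parses losslessly", {
  cfg <- synthetic_cohort_config(n_patients = 25, n_genes = 40,
                                 hotspot_drivers = hotspot_driver_spec(),
                                 seed = 8)
  dir <- withr::local_tempdir()
  bundle <- generate_cohort(cfg, dir = dir)
  back <- read_maf(bundle$paths$maf)
  expect_equal(as.data.frame(back), as.data.frame(bundle$records))
})

test_that("degenerate truth gives NA recovery metrics, not errors", {
  cfg <- synthetic_cohort_config(n_patients = 60, n_genes = 200, seed = 17)
  r <- recovery_experiment(cfg)
  expect_true(is.na(r$sensitivity))             # nothing planted
  expect_true(is.na(r$rank_agreement))          # all multipliers equal
  expect_true(is.na(r$top_sr_is_planted_driver))
  expect_true(r$false_flag_rate <= 0.10)
})

test_that("config validation rejects impossible rates and unknown genes", {
  expect_error(synthetic_cohort_config(per_base_rate = 2))
  expect_error(synthetic_cohort_config(selection_multiplier = c(X = -1)))
  cfg <- synthetic_cohort_config(n_genes = 10,
                                 selection_multiplier = c(NOPE = 2))
  expect_error(generate_cohort(cfg), "NOPE")
})
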