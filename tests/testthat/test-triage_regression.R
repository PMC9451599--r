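test_that("mutation fraction counts each patient at most once per gene", {
  # one patient with three missense mutations in one gene, cohort of 10
  rec <- make_records(patient_id = rep("TCGA-AA-0001", 3),
                      gene_symbol = "TP53",
                      protein_change = c("p.R175H", "p.R248Q", "p.G245S"))
  cohort <- sprintf("TCGA-AA-%04d", 1:10)
  mf <- mutation_fraction(rec, cohort, genes = c("TP53", "KRAS"))
  expect_equal(mf$n_mutated[mf$gene_symbol == "TP53"], 1L)
  expect_equal(mf$f[mf$gene_symbol == "TP53"], 0.1)
  # absent gene -> zero
  expect_equal(mf$f[mf$gene_symbol == "KRAS"], 0)
  expect_error(mutation_fraction(rec, character()), "empty")
})

test_that("mutation fraction reproduces a 37-of-313 cohort count", {
  carriers <- sprintf("TCGA-WT-%04d", 1:37)
  rec <- make_records(patient_id = carriers, gene_symbol = "TLR4",
                      protein_change = "p.D299G")
  cohort <- sprintf("TCGA-WT-%04d", 1:313)
  mf <- mutation_fraction(rec, cohort)
  expect_equal(mf$n_mutated, 37L)
  expect_equal(mf$f, 37 / 313, tolerance = 1e-12)
  expect_equal(round(mf$f, 2), 0.12)
})

test_that("coverage correction divides by the median covered fraction", {
  expect_equal(corrected_fraction(0.10, 0.5), 0.20)
  expect_equal(corrected_fraction(0.10, 1.0), 0.10)
  expect_equal(corrected_fraction(0, 0.7), 0)
  expect_error(corrected_fraction(0.1, 0), "positive")
})

test_that("collinear points are fitted exactly", {
  x <- c(10, 30, 50)
  y <- 0.1 + 0.002 * x
  model <- fit_triage(x, y)
  expect_equal(model$slope, 0.002, tolerance = 1e-12)
  expect_equal(model$intercept, 0.1, tolerance = 1e-12)
  expect_error(standardized_residuals(model, x, y), "degenerate")
})

test_that("OLS fit matches the normal-equation oracle and is replication-invariant", {
  set.seed(31)
  x <- sqrt(round(runif(10, 300, 8000)))
  y <- 0.02 + 0.004 * x + rnorm(10, sd = 0.01)
  model <- fit_triage(x, y)
  oracle <- ols_oracle(x, y)
  expect_equal(model$intercept, oracle$intercept, tolerance = 1e-10)
  expect_equal(model$slope, oracle$slope, tolerance = 1e-10)
  sr <- standardized_residuals(model, x, y)
  expect_equal(sr, oracle$sr, tolerance = 1e-10)

  # duplicating every gene leaves the coefficients unchanged
  model2 <- fit_triage(rep(x, 2), rep(y, 2))
  expect_equal(model2$slope, model$slope, tolerance = 1e-10)
  expect_equal(model2$intercept, model$intercept, tolerance = 1e-10)
})

test_that("fit rejects degenerate inputs", {
  expect_error(fit_triage(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_triage(rep(5, 4), 1:4), "all equal")
})

test_that("standardized residuals behave as residual/scale with OLS identities", {
  set.seed(77)
  x <- sqrt(round(runif(40, 200, 9000)))
  y <- 0.01 + 0.005 * x + rnorm(40, sd = 0.02)
  model <- fit_triage(x, y)
  sr <- standardized_residuals(model, x, y)
  # a gene exactly on the line scores zero
  on_line <- model$intercept + model$slope * x[1]
  expect_equal(standardized_residuals(model, x[1], on_line), 0,
               tolerance = 1e-12)
  # residuals (and so SRs) sum to ~0 under OLS with intercept
  expect_lt(abs(sum(sr * model$residual_scale)), 1e-9 * length(x))
  # adding a constant to y shifts only the intercept, all SR unchanged
  model_b <- fit_triage(x, y + 0.37)
  expect_equal(model_b$intercept, model$intercept + 0.37, tolerance = 1e-10)
  expect_equal(model_b$slope, model$slope, tolerance = 1e-10)
  expect_equal(standardized_residuals(model_b, x, y + 0.37), sr,
               tolerance = 1e-8)
  # with the model held fixed, SR strictly increases in corrected fraction
  cs <- seq(0.001, 0.2, length.out = 25)
  srs <- standardized_residuals(model, rep(x[5], 25), sqrt(cs))
  expect_true(all(diff(srs) > 0))
  # studentized option divides by sqrt(1 - leverage)
  h <- 1 / length(x) + (x - mean(x))^2 / sum((x - mean(x))^2)
  expect_equal(standardized_residuals(model, x, y, method = "studentized"),
               sr / sqrt(1 - h), tolerance = 1e-10)
})

test_that("huber estimator resists a planted outlier better than OLS", {
  set.seed(13)
  x <- sqrt(round(runif(60, 300, 9000)))
  y <- 0.01 + 0.004 * x + rnorm(60, sd = 0.005)
  y[1] <- y[1] + 0.5  # one strongly over-mutated gene
  ols <- fit_triage(x, y, estimator = "ols")
  hub <- fit_triage(x, y, estimator = "huber")
  truth <- fit_triage(x[-1], y[-1], estimator = "ols")
  expect_lt(abs(hub$slope - truth$slope), abs(ols$slope - truth$slope))
  expect_equal(hub$estimator, "huber")
})

test_that("classification thresholds define label, tier and p-value", {
  cls <- classify_sr(c(-2.5, -1.7, -0.3, 0, 1.2, 1.7, 2.4))
  expect_equal(cls$label,
               c("conserved", "conserved", "background", "background",
                 "over_mutated", "over_mutated", "over_mutated"))
  expect_equal(cls$tier,
               c("significant", "suggestive", "none", "none", "none",
                 "suggestive", "significant"))
  expect_equal(cls$p_two_sided, 2 * pnorm(-abs(cls$sr)), tolerance = 1e-12)
  expect_error(triage_thresholds(flag = 2, suggestive = 1.65))
})

test_that("frequently mutated genes use a strict 10% cutoff", {
  tab <- tibble::tibble(gene_symbol = c("A", "B", "C"),
                        f = c(0.11, 0.10, 0.02))
  expect_equal(frequently_mutated(tab), "A")
  expect_length(frequently_mutated(tab[0, ]), 0)
})

test_that("triage_scores assembles the full statistic end to end", {
  cfg <- synthetic_cohort_config(n_patients = 150, n_genes = 400,
                                 n_conserved = 4, n_drivers = 2, seed = 3)
  bundle <- generate_cohort(cfg)
  cov_med <- median_coverage(bundle$coverage)
  sc <- triage_scores(bundle$records, bundle$truth_patients$patient_id,
                      bundle$annotation, cov_med)
  expect_equal(nrow(sc), 400)
  expect_true(all(sc$f >= 0 & sc$f <= 1))
  expect_equal(sc$f, sc$n_mutated / sc$cohort_size)
  expect_equal(sc$c, sc$f / sc$m)
  expect_equal(sc$y, sqrt(sc$c))
  expect_equal(sc$residual, sc$y - sc$fitted)
  model <- attr(sc, "model")
  expect_equal(sc$sr, sc$residual / model$residual_scale, tolerance = 1e-12)
  # label consistency with thresholds
  expect_true(all(sc$label[sc$sr <= -1] == "conserved"))
  expect_true(all(sc$label[abs(sc$sr) < 1] == "background"))
  # the most inflated planted gene tops the ranking
  planted_pos <- bundle$truth_genes$gene_symbol[bundle$truth_genes$planted_driver]
  expect_true(sc$gene_symbol[which.max(sc$sr)] %in% planted_pos)
})
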