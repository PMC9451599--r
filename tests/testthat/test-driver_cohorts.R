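rules <- default_driver_rules()

test_that("hotspot substitutions match on reference residue and position", {
  g12c <- make_records(gene_symbol = "KRAS", protein_change = "p.G12C")
  g12d <- make_records(gene_symbol = "KRAS", protein_change = "p.G12D")
  expect_true(match_rule(g12c, rules$KRAS))
  expect_true(match_rule(g12d, rules$KRAS))          # alternate-insensitive
  expect_false(match_rule(g12c, rules$EGFR))         # gene mismatch
  expect_true(match_rule(make_records(gene_symbol = "kras",
                                      protein_change = "p.A146T"),
                         rules$KRAS))                # case-insensitive gene
  expect_true(match_rule(make_records(gene_symbol = "KRAS",
                                      protein_change = "p.Gln61His"),
                         rules$KRAS))                # three-letter HGVSp
  # synonymous change at a rule position is not an activating match
  expect_false(match_rule(make_records(gene_symbol = "KRAS",
                                       protein_change = "p.G12G"),
                          rules$KRAS))
  # non-hotspot position
  expect_false(match_rule(make_records(gene_symbol = "KRAS",
                                       protein_change = "p.G60D"),
                          rules$KRAS))
})

test_that("EGFR indels match by exon range with residue-window fallback", {
  in19 <- make_records(gene_symbol = "EGFR", protein_change = "p.E746_A750del",
                       variant_classification = "In_Frame_Del",
                       is_indel = TRUE, exon_number = 19L)
  expect_true(match_rule(in19, rules$EGFR))
  in22 <- make_records(gene_symbol = "EGFR", protein_change = "p.S900del",
                       variant_classification = "In_Frame_Del",
                       is_indel = TRUE, exon_number = 22L)
  expect_false(match_rule(in22, rules$EGFR))
  # exon unknown: fall back to the protein-residue window 688-875
  no_exon <- make_records(gene_symbol = "EGFR", protein_change = "p.E746_A750del",
                          variant_classification = "In_Frame_Del",
                          is_indel = TRUE, exon_number = NA_integer_)
  expect_true(match_rule(no_exon, rules$EGFR))
  outside <- make_records(gene_symbol = "EGFR", protein_change = "p.S1000del",
                          variant_classification = "In_Frame_Del",
                          is_indel = TRUE, exon_number = NA_integer_)
  expect_false(match_rule(outside, rules$EGFR))
})

test_that("unparseable protein changes on a rule gene warn and do not match", {
  odd <- make_records(gene_symbol = "KRAS", protein_change = "weird?")
  expect_warning(hit <- match_rule(odd, rules$KRAS), "unparseable")
  expect_false(hit)
})

test_that("patients are labelled mGENE, WT, or excluded", {
  rec <- rbind(
    make_records("TCGA-AA-0001", "KRAS", protein_change = "p.G13D"),
    make_records("TCGA-AA-0002", "KRAS", protein_change = "p.G12V"),
    make_records("TCGA-AA-0002", "EGFR", protein_change = "p.L858R"),
    make_records("TCGA-AA-0003", "TP53", protein_change = "p.R175H"),
    make_records("TCGA-AA-0004", "BRAF", protein_change = "p.V600E")
  )
  suppressMessages(asg <- assign_cohorts(rec, rules))
  lbl <- setNames(asg$label, asg$patient_id)
  expect_equal(unname(lbl[c("TCGA-AA-0001", "TCGA-AA-0002",
                            "TCGA-AA-0003", "TCGA-AA-0004")]),
               c("mKRAS", "excluded", "WT", "mBRAF"))
  expect_equal(asg$matched_rules[asg$patient_id == "TCGA-AA-0002"],
               "EGFR,KRAS")
  # label/matched_rules invariants
  expect_true(all((asg$label == "excluded") == (asg$n_matched > 1)))
  expect_true(all((asg$label == "WT") == (asg$n_matched == 0)))
})

test_that("cohort labels partition the patients and ignore record order", {
  cfg <- synthetic_cohort_config(n_patients = 120, n_genes = 80,
                                 hotspot_drivers = hotspot_driver_spec(),
                                 seed = 11)
  bundle <- generate_cohort(cfg)
  suppressMessages(asg <- assign_cohorts(bundle$records, rules))
  expect_equal(nrow(asg), length(unique(bundle$records$patient_id)))
  expect_equal(sum(table(asg$label)), nrow(asg))

  set.seed(99)
  shuffled <- bundle$records[sample(nrow(bundle$records)), ]
  suppressMessages(asg2 <- assign_cohorts(shuffled, rules))
  expect_equal(asg2, asg)
})

test_that("empty rule sets are configuration errors", {
  expect_error(assign_cohorts(make_records(), list()), "no driver rules")
  expect_error(driver_rule("KRAS"), "hotspot sites")
  expect_error(driver_rule("KRAS", sites = "12G"), "malformed")
})

test_that("driver rules round-trip through YAML", {
  path <- file.path(withr::local_tempdir(), "rules.yaml")
  writeLines(c(
    "KRAS:",
    "  sites: [G12, G13, Q61, A146]",
    "EGFR:",
    "  sites: [L858]",
    "  indel_exons: [18, 21]",
    "  indel_residue_window: [688, 875]"), path)
  loaded <- read_driver_rules(path)
  expect_named(loaded, c("KRAS", "EGFR"))
  expect_equal(loaded$KRAS$sites, c("G12", "G13", "Q61", "A146"))
  expect_equal(loaded$EGFR$indel_exons, c(18L, 21L))
  expect_true(match_rule(make_records(gene_symbol = "KRAS",
                                      protein_change = "p.G12D"),
                         loaded$KRAS))
})
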