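# shared fixture builders and independent oracles

# minimal mutation-record tibble; defaults give a single missense record
make_records <- function(patient_id = "TCGA-AA-0001",
                         gene_symbol = "TP53",
                         variant_classification = "Missense_Mutation",
                         protein_change = "p.R175H",
                         is_indel = FALSE,
                         exon_number = NA_integer_,
                         sample_id = NULL) {
  n <- max(length(patient_id), length(gene_symbol),
           length(variant_classification), length(protein_change),
           length(is_indel), length(exon_number))
  patient_id <- rep_len(patient_id, n)
  if (is.null(sample_id)) sample_id <- paste0(patient_id, "-01A")
  pos <- evotriage::parse_hgvsp(rep_len(protein_change, n))$pos
  tibble::tibble(
    patient_id = patient_id,
    sample_id = rep_len(sample_id, n),
    gene_symbol = rep_len(gene_symbol, n),
    variant_classification = rep_len(variant_classification, n),
    protein_change = rep_len(protein_change, n),
    protein_position = pos,
    is_indel = rep_len(is_indel, n),
    exon_number = rep_len(as.integer(exon_number), n)
  )
}

# write a small MAF text file and return its path
write_maf_fixture <- function(rows, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "fixture.maf")
  header <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification",
              "HGVSp_Short", "Variant_Type", "Exon_Number")
  writeLines(c(paste(header, collapse = "\t"),
               vapply(rows, paste, character(1), collapse = "\t")), path)
  path
}

# long-format coverage tibble from a named list sample -> fraction, one gene
make_coverage <- function(gene, fractions) {
  tibble::tibble(gene_symbol = gene,
                 sample_id = names(fractions),
                 fraction = unname(fractions))
}

# closed-form OLS normal equations + residual standard error; the
# independent oracle for the size regression and its standardized residuals
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  scale <- sqrt(sum(res^2) / (length(x) - 2))
  list(intercept = beta[1], slope = beta[2], scale = scale,
       sr = as.numeric(res / scale))
}
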