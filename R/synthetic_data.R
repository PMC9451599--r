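#' Configuration for a synthetic somatic-mutation cohort
#'
#' Describes a seeded simulated cohort that exercises every pipeline stage:
#' a gene universe with log-normal coding lengths, patient-level Bernoulli
#' mutation events whose per-gene probability is
#' `1 - (1 - per_base_rate * multiplier)^length`, near-1 coverage fractions
#' with planted low-coverage genes, expression values with planted
#' low-expression genes, and optional planted hotspot driver mutations that
#' match the cohort-stratification rules.
#'
#' Selection multipliers of 1 are neutral; below 1 models negative selection
#' (conserved genes), above 1 positive selection. Planted conserved and
#' positively selected genes are drawn from the longest length quartile so
#' their expected mutation deficits/excesses are large relative to binomial
#' noise.
#'
#' @param n_patients Cohort size (default 200).
#' @param n_genes Number of background genes (default 2000).
#' @param length_median,length_sigma Log-normal coding-length parameters
#'   (median 1500 bp, sigma 0.6 on the log scale).
#' @param per_base_rate Per-base per-patient mutation probability
#'   (default 2e-5, giving a 1500 bp neutral gene a per-patient
#'   protein-altering mutation probability of about 0.03).
#' @param selection_multiplier Optional named numeric vector overriding
#'   multipliers for specific genes.
#' @param n_conserved,conserved_multiplier Number of planted conserved genes
#'   (longest quartile) and their multiplier (default 0 genes, multiplier 0).
#' @param n_drivers,driver_multiplier Number of planted positively selected
#'   genes (longest quartile) and their multiplier (default 0 genes,
#'   multiplier 5).
#' @param hotspot_drivers Optional tibble of hotspot plantings (see
#'   [hotspot_driver_spec()]): columns `gene`, `protein_change`,
#'   `classification`, `is_indel`, `exon`, `frac`.
#' @param n_low_coverage,n_low_expression,n_annotation_error Counts of genes
#'   planted to fail each exclusion filter.
#' @param coverage_shape,low_coverage_shape Beta(shape1, shape2) parameters
#'   for per-sample coverage fractions of normal (default Beta(60, 2), mean
#'   ~0.97) and planted low-coverage genes (default Beta(20, 30), mean 0.4).
#' @param expression_mean,expression_sd Normal parameters for log2
#'   expression, floored at 2.0 so only planted genes fail the expression
#'   filter; planted low-expression genes are uniform on (0.5, 1.5).
#' @param silent_rate_factor Relative per-base rate of synonymous (Silent)
#'   events, which are never under selection (default 0.5).
#' @param seed Root seed; all streams derive from it, so a fixed seed gives
#'   byte-identical output.
#' @return An object of class `synthetic_cohort_config`.
#' @export
synthetic_cohort_config <- function(n_patients = 200L, n_genes = 2000L,
                                    length_median = 1500, length_sigma = 0.6,
                                    per_base_rate = 2e-5,
                                    selection_multiplier = NULL,
                                    n_conserved = 0L, conserved_multiplier = 0,
                                    n_drivers = 0L, driver_multiplier = 5,
                                    hotspot_drivers = NULL,
                                    n_low_coverage = 0L, n_low_expression = 0L,
                                    n_annotation_error = 0L,
                                    coverage_shape = c(60, 2),
                                    low_coverage_shape = c(20, 30),
                                    expression_mean = 7, expression_sd = 2,
                                    silent_rate_factor = 0.5,
                                    seed = 1L) {
  stopifnot(n_patients >= 1, n_genes >= 3,
            per_base_rate >= 0, per_base_rate <= 1,
            conserved_multiplier >= 0, driver_multiplier >= 0,
            silent_rate_factor >= 0)
  if (!is.null(selection_multiplier)) {
    stopifnot(!is.null(names(selection_multiplier)),
              all(selection_multiplier >= 0))
  }
  structure(list(
    n_patients = as.integer(n_patients), n_genes = as.integer(n_genes),
    length_median = length_median, length_sigma = length_sigma,
    per_base_rate = per_base_rate,
    selection_multiplier = selection_multiplier,
    n_conserved = as.integer(n_conserved),
    conserved_multiplier = conserved_multiplier,
    n_drivers = as.integer(n_drivers), driver_multiplier = driver_multiplier,
    hotspot_drivers = hotspot_drivers,
    n_low_coverage = as.integer(n_low_coverage),
    n_low_expression = as.integer(n_low_expression),
    n_annotation_error = as.integer(n_annotation_error),
    coverage_shape = coverage_shape, low_coverage_shape = low_coverage_shape,
    expression_mean = expression_mean, expression_sd = expression_sd,
    silent_rate_factor = silent_rate_factor,
    seed = as.integer(seed)), class = "synthetic_cohort_config")
}

#' Standard hotspot-driver planting
#'
#' Plants hotspot mutations matching the default LUAD stratification rules:
#' KRAS G12/G13/Q61/A146 substitutions, a BRAF V600E class, EGFR L858R, and
#' an EGFR exon-19 in-frame deletion. Each row independently assigns its
#' mutation to a random `frac` of patients, so a realistic minority of
#' patients match two rule genes and end up excluded. Planting fractions
#' echo the LUAD cohort proportions (KRAS most common, then EGFR, then
#' BRAF).
#'
#' @return A tibble usable as the `hotspot_drivers` field of
#'   [synthetic_cohort_config()].
#' @export
hotspot_driver_spec <- function() {
  tibble::tribble(
    ~gene,  ~protein_change,   ~classification,     ~is_indel, ~exon, ~frac,
    "KRAS", "p.G12D",          "Missense_Mutation", FALSE,     2L,    0.14,
    "KRAS", "p.G12C",          "Missense_Mutation", FALSE,     2L,    0.10,
    "KRAS", "p.G13D",          "Missense_Mutation", FALSE,     2L,    0.03,
    "KRAS", "p.Q61H",          "Missense_Mutation", FALSE,     3L,    0.02,
    "KRAS", "p.A146T",         "Missense_Mutation", FALSE,     4L,    0.01,
    "BRAF", "p.V600E",         "Missense_Mutation", FALSE,     15L,   0.05,
    "EGFR", "p.L858R",         "Missense_Mutation", FALSE,     21L,   0.07,
    "EGFR", "p.E746_A750del",  "In_Frame_Del",      TRUE,      19L,   0.04
  )
}

# lengths of the hotspot rule genes' longest coding transcripts (bp)
.hotspot_gene_lengths <- c(KRAS = 570L, BRAF = 2301L, EGFR = 3633L)

.stream_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + k) %% 2147483629)
}

.pa_classes <- c("Missense_Mutation", "Nonsense_Mutation", "Splice_Site",
                 "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del")
.pa_weights <- c(0.70, 0.10, 0.05, 0.07, 0.04, 0.04)

#' Generate a synthetic cohort bundle
#'
#' Draws the gene universe, plants selection and filter failures, simulates
#' patient-level mutation events, coverage and expression, and returns
#' in-memory tibbles in exactly the shapes the pipeline consumes. With
#' `dir` set, also writes `maf.tsv`, `coverage.tsv`, `expression.tsv`,
#' `annotation.tsv`, `truth_genes.tsv` and `truth_patients.tsv` there.
#'
#' Background protein changes always use a serine reference residue and
#' (for indels) exon numbers 1-5, so under the default stratification rules
#' only planted hotspot rows can match a driver rule and the per-patient
#' truth labels are exact.
#'
#' @param config A [synthetic_cohort_config()].
#' @param dir Optional output directory (created if needed).
#' @return A list: `records` (mutation records), `coverage` (long tibble),
#'   `expression`, `annotation`, `truth_genes`, `truth_patients`, `config`,
#'   and `paths` when `dir` was given.
#' @export
generate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  n_p <- config$n_patients
  patients <- sprintf("TCGA-SY-%04d", seq_len(n_p))
  samples <- paste0(patients, "-01A")

  ## gene universe + planted selection -------------------------------------
  set.seed(.stream_seed(config$seed, 1L))
  genes <- sprintf("G%05d", seq_len(config$n_genes))
  lengths <- pmax(150L, as.integer(round(stats::rlnorm(
    config$n_genes, meanlog = log(config$length_median),
    sdlog = config$length_sigma))))
  hot <- config$hotspot_drivers
  if (!is.null(hot)) {
    extra <- setdiff(unique(hot$gene), genes)
    genes <- c(genes, extra)
    extra_len <- ifelse(extra %in% names(.hotspot_gene_lengths),
                        .hotspot_gene_lengths[extra], 1500L)
    lengths <- c(lengths, as.integer(extra_len))
  }
  n_g <- length(genes)
  names(lengths) <- genes

  mult <- stats::setNames(rep(1, n_g), genes)
  if (!is.null(config$selection_multiplier)) {
    ov <- config$selection_multiplier
    unknown <- setdiff(names(ov), genes)
    if (length(unknown) > 0) {
      stop("selection_multiplier names not in gene universe: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    mult[names(ov)] <- ov
  }
  base_genes <- genes[seq_len(config$n_genes)]
  q75 <- stats::quantile(lengths[base_genes], 0.75, names = FALSE)
  long_pool <- base_genes[lengths[base_genes] >= q75 & mult[base_genes] == 1]
  planted_cons <- planted_driv <- character()
  if (config$n_conserved > 0) {
    planted_cons <- sample(long_pool, config$n_conserved)
    mult[planted_cons] <- config$conserved_multiplier
    long_pool <- setdiff(long_pool, planted_cons)
  }
  if (config$n_drivers > 0) {
    planted_driv <- sample(long_pool, config$n_drivers)
    mult[planted_driv] <- config$driver_multiplier
  }
  # genes planted to trip the filters are neutral, non-hotspot genes
  filter_pool <- setdiff(base_genes[mult[base_genes] == 1],
                         c(planted_cons, planted_driv))
  planted_lowcov <- planted_lowexpr <- planted_annerr <- character()
  if (config$n_low_coverage > 0) {
    planted_lowcov <- sample(filter_pool, config$n_low_coverage)
    filter_pool <- setdiff(filter_pool, planted_lowcov)
  }
  if (config$n_low_expression > 0) {
    planted_lowexpr <- sample(filter_pool, config$n_low_expression)
    filter_pool <- setdiff(filter_pool, planted_lowexpr)
  }
  if (config$n_annotation_error > 0) {
    planted_annerr <- sample(filter_pool, config$n_annotation_error)
  }

  ## expression -------------------------------------------------------------
  set.seed(.stream_seed(config$seed, 2L))
  expr <- pmax(stats::rnorm(n_g, config$expression_mean, config$expression_sd),
               2.0)
  names(expr) <- genes
  if (length(planted_lowexpr) > 0) {
    expr[planted_lowexpr] <- stats::runif(length(planted_lowexpr), 0.5, 1.5)
  }

  ## coverage ---------------------------------------------------------------
  set.seed(.stream_seed(config$seed, 3L))
  is_low <- genes %in% planted_lowcov
  sh1 <- ifelse(is_low, config$low_coverage_shape[1], config$coverage_shape[1])
  sh2 <- ifelse(is_low, config$low_coverage_shape[2], config$coverage_shape[2])
  coverage <- tibble::tibble(
    gene_symbol = rep(genes, each = n_p),
    sample_id = rep(samples, times = n_g),
    fraction = stats::rbeta(n_g * n_p, rep(sh1, each = n_p),
                            rep(sh2, each = n_p))
  )

  ## background mutation events ----------------------------------------------
  set.seed(.stream_seed(config$seed, 4L))
  rate <- pmin(pmax(config$per_base_rate * mult, 0), 1)
  p_gene <- 1 - (1 - rate)^lengths
  hits <- stats::runif(n_g * n_p) < rep(p_gene, each = n_p)
  gi <- rep(seq_len(n_g), each = n_p)[hits]
  pi <- rep(seq_len(n_p), times = n_g)[hits]
  cls <- sample(.pa_classes, sum(hits), replace = TRUE, prob = .pa_weights)
  pos <- 1L + as.integer(floor(stats::runif(sum(hits)) *
                                 pmax(1, lengths[gi] %/% 3)))
  is_ind <- cls %in% c("Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del")
  suffix <- ifelse(cls == "Missense_Mutation", "L",
                   ifelse(cls == "Nonsense_Mutation", "*",
                          ifelse(is_ind, "fs", "L")))
  bg <- tibble::tibble(
    patient_id = patients[pi],
    sample_id = samples[pi],
    gene_symbol = genes[gi],
    variant_classification = cls,
    protein_change = ifelse(cls == "Splice_Site", "",
                            paste0("p.S", pos, suffix)),
    is_indel = is_ind,
    exon_number = ifelse(is_ind, 1L + (pos %% 5L), NA_integer_)
  )

  # synonymous events: neutral, never under selection
  p_silent <- 1 - (1 - pmin(config$per_base_rate * config$silent_rate_factor,
                            1))^lengths
  sh <- stats::runif(n_g * n_p) < rep(p_silent, each = n_p)
  gs <- rep(seq_len(n_g), each = n_p)[sh]
  ps <- rep(seq_len(n_p), times = n_g)[sh]
  spos <- 1L + as.integer(floor(stats::runif(sum(sh)) *
                                  pmax(1, lengths[gs] %/% 3)))
  silent <- tibble::tibble(
    patient_id = patients[ps],
    sample_id = samples[ps],
    gene_symbol = genes[gs],
    variant_classification = "Silent",
    protein_change = paste0("p.S", spos, "S"),
    is_indel = FALSE,
    exon_number = NA_integer_
  )

  ## hotspot drivers ---------------------------------------------------------
  driver_rows <- NULL
  patient_driver_genes <- stats::setNames(vector("list", n_p), patients)
  if (!is.null(hot)) {
    set.seed(.stream_seed(config$seed, 5L))
    rows <- list()
    for (i in seq_len(nrow(hot))) {
      chosen <- which(stats::runif(n_p) < hot$frac[i])
      if (length(chosen) == 0) next
      rows[[i]] <- tibble::tibble(
        patient_id = patients[chosen],
        sample_id = samples[chosen],
        gene_symbol = hot$gene[i],
        variant_classification = hot$classification[i],
        protein_change = hot$protein_change[i],
        is_indel = hot$is_indel[i],
        exon_number = as.integer(hot$exon[i])
      )
      for (p in chosen) {
        patient_driver_genes[[p]] <- union(patient_driver_genes[[p]],
                                           hot$gene[i])
      }
    }
    driver_rows <- dplyr::bind_rows(rows)
  }

  records <- dplyr::bind_rows(bg, silent, driver_rows)
  hg <- parse_hgvsp(records$protein_change)
  records$protein_position <- hg$pos
  records <- records[order(records$patient_id, records$gene_symbol,
                           records$variant_classification,
                           records$protein_change), ]
  records <- records[, c("patient_id", "sample_id", "gene_symbol",
                         "variant_classification", "protein_change",
                         "protein_position", "is_indel", "exon_number")]

  ## bundle ------------------------------------------------------------------
  annotation <- tibble::tibble(
    gene_symbol = genes,
    coding_length = as.integer(lengths),
    expression_log2 = unname(expr),
    annotation_error = genes %in% planted_annerr
  )
  expression <- annotation[c("gene_symbol", "expression_log2")]
  truth_genes <- tibble::tibble(
    gene_symbol = genes,
    coding_length = as.integer(lengths),
    multiplier = unname(mult),
    planted_conserved = genes %in% planted_cons,
    planted_driver = genes %in% planted_driv,
    planted_low_coverage = genes %in% planted_lowcov,
    planted_low_expression = genes %in% planted_lowexpr,
    planted_annotation_error = genes %in% planted_annerr
  )
  n_driver_genes <- vapply(patient_driver_genes, length, integer(1))
  truth_patients <- tibble::tibble(
    patient_id = patients,
    driver_genes = vapply(patient_driver_genes, function(g)
      paste(sort(g), collapse = ","), character(1)),
    expected_label = ifelse(n_driver_genes == 0, "WT",
                            ifelse(n_driver_genes > 1, "excluded",
                                   paste0("m", vapply(patient_driver_genes,
                                                      function(g)
                                                        if (length(g) == 1) g
                                                        else "",
                                                      character(1)))))
  )

  out <- list(records = records, coverage = coverage,
              expression = expression, annotation = annotation,
              truth_genes = truth_genes, truth_patients = truth_patients,
              config = config)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(
      maf = file.path(dir, "maf.tsv"),
      coverage = file.path(dir, "coverage.tsv"),
      expression = file.path(dir, "expression.tsv"),
      annotation = file.path(dir, "annotation.tsv"),
      truth_genes = file.path(dir, "truth_genes.tsv"),
      truth_patients = file.path(dir, "truth_patients.tsv")
    )
    write_maf(records, paths$maf)
    readr::write_tsv(coverage, paths$coverage, progress = FALSE)
    readr::write_tsv(expression, paths$expression, progress = FALSE)
    readr::write_tsv(annotation, paths$annotation, progress = FALSE)
    readr::write_tsv(truth_genes, paths$truth_genes, progress = FALSE)
    readr::write_tsv(truth_patients, paths$truth_patients, progress = FALSE)
    out$paths <- paths
  }
  out
}

#' Run the pipeline on a synthetic cohort and score recovery
#'
#' Generates a cohort from `config`, runs coverage summarization, gene
#' filtering and the triage regression over all patients, and compares the
#' resulting standardized residuals with the planted truth:
#' * `sensitivity` — fraction of planted conserved genes (multiplier <= 0.1
#'   and coding length at or above the cohort 75th length percentile) with
#'   SR <= -1.65 (`NA` when none were planted);
#' * `false_flag_rate` — fraction of neutral genes (multiplier 1, nothing
#'   planted) with |SR| >= 2;
#' * `rank_agreement` — Spearman correlation between multiplier and SR among
#'   genes with non-neutral multipliers (`NA` when degenerate);
#' * `top_sr_is_planted_driver` — whether the highest-SR gene is a planted
#'   positively selected gene (`NA` when none were planted).
#'
#' @param config A [synthetic_cohort_config()].
#' @param estimator Passed to [triage_scores()].
#' @param thresholds Passed to [triage_scores()].
#' @return A list with the four metrics plus `scores` and `truth_genes`.
#' @export
recovery_experiment <- function(config, estimator = "ols",
                                thresholds = triage_thresholds()) {
  bundle <- generate_cohort(config)
  cov_med <- median_coverage(bundle$coverage)
  patients <- bundle$truth_patients$patient_id
  scores <- triage_scores(bundle$records, patients, bundle$annotation,
                          cov_med, estimator = estimator,
                          thresholds = thresholds)
  truth <- bundle$truth_genes
  tab <- dplyr::inner_join(scores[c("gene_symbol", "sr")], truth,
                           by = "gene_symbol")
  q75 <- stats::quantile(truth$coding_length[seq_len(config$n_genes)], 0.75,
                         names = FALSE)
  cons <- tab$multiplier <= 0.1 & tab$coding_length >= q75
  neutral <- tab$multiplier == 1 & !tab$planted_low_coverage &
    !tab$planted_low_expression & !tab$planted_annotation_error
  planted_pos <- tab$multiplier > 1

  sensitivity <- if (any(cons)) mean(tab$sr[cons] <= -1.65) else NA_real_
  false_flag_rate <- if (any(neutral)) mean(abs(tab$sr[neutral]) >= 2)
    else NA_real_
  nonneutral <- tab$multiplier != 1
  rank_agreement <- if (sum(nonneutral) >= 2 &&
                          length(unique(tab$multiplier[nonneutral])) >= 2 &&
                          length(unique(tab$sr[nonneutral])) >= 2) {
    stats::cor(tab$multiplier[nonneutral], tab$sr[nonneutral],
               method = "spearman")
  } else NA_real_
  top_sr_is_planted_driver <- if (any(planted_pos)) {
    tab$gene_symbol[which.max(tab$sr)] %in% tab$gene_symbol[planted_pos]
  } else NA

  list(sensitivity = sensitivity, false_flag_rate = false_flag_rate,
       rank_agreement = rank_agreement,
       top_sr_is_planted_driver = top_sr_is_planted_driver,
       scores = scores, truth_genes = truth)
}
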