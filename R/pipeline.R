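#' Run the full evolutionary-triage pipeline
#'
#' Orchestrates every stage end-to-end: read the MAF, reduce to one sample
#' per patient, assign driver cohorts, summarize coverage, filter genes,
#' fit the per-cohort size regression, classify genes, and (when panels are
#' supplied) emit conserved / over-mutated panel reports plus the
#' cross-cohort overlap. All intermediate tables are written to `out_dir`
#' so any stage can be audited, together with a JSON run manifest holding
#' input checksums, the effective configuration and per-stage counts.
#' Outputs are deterministic: running twice on identical inputs produces
#' byte-identical files.
#'
#' @param config A named list (or path to a YAML file with the same layout)
#'   with elements:
#'   * `maf`, `coverage`, `annotation` — input paths (required);
#'   * `expression` — per-gene expression TSV (optional when the annotation
#'     table already carries `expression_log2`);
#'   * `panels` — panel YAML path (optional);
#'   * `driver_rules` — driver-rule YAML path (optional; defaults to the
#'     LUAD KRAS/BRAF/EGFR rules);
#'   * `out_dir` — output directory (required);
#'   * `estimator` (`"ols"`/`"huber"`), `sr_method`, `min_median_cov`,
#'     `min_expression_log2`, `min_cohort_size` (default 30), `cohorts`
#'     (labels to analyze; default every non-excluded label meeting the
#'     size minimum), `panel_sr_cutoff` (default 1.65 magnitude).
#' @return Invisibly, a list with `assignments`, `scores` (named list of
#'   per-cohort score tibbles), `conserved_reports`, `over_mutated_reports`,
#'   `overlap`, and `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  for (key in c("maf", "coverage", "annotation", "out_dir")) {
    if (is.null(config[[key]])) {
      stop("pipeline config is missing required entry: ", key, call. = FALSE)
    }
  }
  for (key in c("maf", "coverage", "annotation", "expression", "panels",
                "driver_rules")) {
    p <- config[[key]]
    if (!is.null(p) && !file.exists(p)) {
      stop("pipeline input not found (", key, "): ", p, call. = FALSE)
    }
  }
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  estimator <- config$estimator %||% "ols"
  sr_method <- config$sr_method %||% "scale"
  min_cov <- config$min_median_cov %||% 0.5
  min_expr <- config$min_expression_log2 %||% 2.0
  min_cohort <- config$min_cohort_size %||% 30L
  panel_cut <- config$panel_sr_cutoff %||% 1.65
  rules <- if (!is.null(config$driver_rules)) {
    read_driver_rules(config$driver_rules)
  } else default_driver_rules()

  ## ingest ------------------------------------------------------------------
  records <- read_maf(config$maf)
  records <- one_sample_per_patient(records)
  coverage <- read_coverage(config$coverage)
  annotation <- read_annotation(config$annotation)
  if (!is.null(config$expression)) {
    expr <- read_expression(config$expression)
    annotation$expression_log2 <- NULL
    annotation <- dplyr::left_join(annotation, expr, by = "gene_symbol")
  }
  if (!"expression_log2" %in% names(annotation)) {
    stop("no expression values: supply config$expression or an ",
         "expression_log2 column in the annotation table", call. = FALSE)
  }

  ## cohorts -----------------------------------------------------------------
  assignments <- assign_cohorts(records, rules)
  readr::write_tsv(assignments, file.path(out_dir, "cohort_assignments.tsv"),
                   progress = FALSE)
  sizes <- table(assignments$label)
  cohorts <- config$cohorts %||%
    setdiff(names(sizes)[as.integer(sizes) >= min_cohort], "excluded")
  if (length(cohorts) == 0) {
    stop("no cohort reaches the minimum size of ", min_cohort, call. = FALSE)
  }
  cov_patient <- substr(coverage$sample_id, 1, 12)

  panels <- if (!is.null(config$panels)) read_panels(config$panels)
  scores <- cons_reports <- over_reports <- list()
  for (coh in sort(cohorts)) {
    patients <- assignments$patient_id[assignments$label == coh]
    if (length(patients) == 0) {
      stop("requested cohort has no patients: ", coh, call. = FALSE)
    }
    coh_cov <- coverage[cov_patient %in% patients, , drop = FALSE]
    cov_med <- median_coverage(coh_cov)
    sc <- triage_scores(records, patients, annotation, cov_med,
                        estimator = estimator, sr_method = sr_method,
                        min_median_cov = min_cov,
                        min_expression_log2 = min_expr)
    scores[[coh]] <- sc
    readr::write_tsv(
      sc[c("gene_symbol", "n_mutated", "cohort_size", "f", "m", "c", "sr",
           "label", "tier", "p_two_sided")],
      file.path(out_dir, paste0("scores_", coh, ".tsv")), progress = FALSE)
    readr::write_tsv(attr(sc, "filter_report"),
                     file.path(out_dir, paste0("filter_report_", coh, ".tsv")),
                     progress = FALSE)
    if (!is.null(panels)) {
      cons_reports[[coh]] <- panel_report(sc, panels, "conserved",
                                          sr_cutoff = -abs(panel_cut))
      over_reports[[coh]] <- panel_report(sc, panels, "over_mutated",
                                          sr_cutoff = abs(panel_cut))
      readr::write_tsv(cons_reports[[coh]],
                       file.path(out_dir, paste0("panel_conserved_", coh, ".tsv")),
                       progress = FALSE)
      readr::write_tsv(over_reports[[coh]],
                       file.path(out_dir, paste0("panel_over_mutated_", coh, ".tsv")),
                       progress = FALSE)
    }
  }

  ## cross-cohort overlap ----------------------------------------------------
  overlap <- NULL
  if (!is.null(panels) && length(cons_reports) >= 2) {
    combos <- utils::combn(names(cons_reports), 2, simplify = FALSE)
    overlap <- dplyr::bind_rows(lapply(combos, function(pr) {
      shared <- cross_cohort_overlap(cons_reports[[pr[1]]],
                                     cons_reports[[pr[2]]])
      if (length(shared) == 0) return(NULL)
      tibble::tibble(cohort_a = pr[1], cohort_b = pr[2], gene_symbol = shared)
    }))
    if (is.null(overlap) || nrow(overlap) == 0) {
      overlap <- tibble::tibble(cohort_a = character(),
                                cohort_b = character(),
                                gene_symbol = character())
    }
    readr::write_tsv(overlap, file.path(out_dir, "conserved_overlap.tsv"),
                     progress = FALSE)
  }

  ## manifest ----------------------------------------------------------------
  input_paths <- Filter(Negate(is.null),
                        config[c("maf", "coverage", "expression",
                                 "annotation", "panels", "driver_rules")])
  manifest <- list(
    package = "evotriage",
    version = as.character(utils::packageVersion("evotriage")),
    inputs = lapply(input_paths, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    settings = list(estimator = estimator, sr_method = sr_method,
                    min_median_cov = min_cov,
                    min_expression_log2 = min_expr,
                    min_cohort_size = min_cohort,
                    panel_sr_cutoff = panel_cut),
    counts = list(
      n_records = nrow(records),
      n_patients = length(unique(records$patient_id)),
      cohort_sizes = as.list(stats::setNames(as.integer(sizes), names(sizes))),
      genes_scored = lapply(scores, nrow)
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(assignments = assignments, scores = scores,
                 conserved_reports = cons_reports,
                 over_mutated_reports = over_reports,
                 overlap = overlap, manifest = manifest))
}
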