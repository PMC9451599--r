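#' Sequencing-depth sufficiency thresholds
#'
#' A coding base counts as sufficiently covered when tumor depth is at least
#' `tumor_min` and matched-normal depth at least `normal_min`; regions are
#' the longest-transcript coding bases extended by `flank` bp on each side.
#'
#' @param tumor_min Minimum tumor depth (default 14).
#' @param normal_min Minimum normal depth (default 8).
#' @param flank Flanking bases included around coding regions (default 25).
#' @return An object of class `depth_thresholds`.
#' @export
depth_thresholds <- function(tumor_min = 14L, normal_min = 8L, flank = 25L) {
  stopifnot(tumor_min > 0, normal_min > 0, flank > 0)
  structure(list(tumor_min = as.integer(tumor_min),
                 normal_min = as.integer(normal_min),
                 flank = as.integer(flank)),
            class = "depth_thresholds")
}

#' Fraction of sufficiently covered bases in one gene region
#'
#' @param tumor_depths Integer vector of per-base tumor depths over the gene
#'   region (coding bases plus flanks).
#' @param normal_depths Integer vector of per-base normal depths, same bases.
#' @param thresholds A [depth_thresholds()].
#' @return Fraction in \[0, 1\]: bases with tumor depth >= `tumor_min` AND
#'   normal depth >= `normal_min`, divided by region length.
#' @export
#' @examples
#' coverage_fraction(c(20, 20, 5, 20), c(10, 10, 10, 7), depth_thresholds())
coverage_fraction <- function(tumor_depths, normal_depths,
                              thresholds = depth_thresholds()) {
  if (length(tumor_depths) != length(normal_depths)) {
    stop("tumor and normal depth arrays must cover the same bases",
         call. = FALSE)
  }
  if (length(tumor_depths) == 0) {
    stop("empty gene region: no bases to assess", call. = FALSE)
  }
  mean(tumor_depths >= thresholds$tumor_min &
         normal_depths >= thresholds$normal_min)
}

#' Read a per-sample per-gene coverage-fraction table
#'
#' @param path TSV with columns `gene_symbol`, `sample_id`, `fraction`.
#' @return Tibble with those columns; fractions validated to \[0, 1\].
#' @export
read_coverage <- function(path) {
  cov <- readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
  required <- c("gene_symbol", "sample_id", "fraction")
  missing <- setdiff(required, names(cov))
  if (length(missing) > 0) {
    stop("coverage table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(cov$fraction < 0 | cov$fraction > 1, na.rm = TRUE)) {
    stop("coverage fractions must lie in [0, 1]", call. = FALSE)
  }
  cov[required]
}

#' Per-gene median coverage over a cohort
#'
#' Summarizes a long per-sample coverage table to the per-gene median
#' fraction over the given cohort samples. Cohort samples absent from the
#' coverage table are skipped with a message; an even sample count uses the
#' mean of the two central values (the usual median convention).
#'
#' @param coverage Tibble with `gene_symbol`, `sample_id`, `fraction`.
#' @param cohort_samples Character vector of sample (or patient) ids defining
#'   the cohort; `NULL` uses every sample present.
#' @return Tibble with `gene_symbol`, `median_fraction`, `n_samples`.
#' @export
median_coverage <- function(coverage, cohort_samples = NULL) {
  if (!is.null(cohort_samples)) {
    present <- unique(coverage$sample_id)
    absent <- setdiff(cohort_samples, present)
    if (length(absent) == length(cohort_samples)) {
      stop("no cohort samples present in the coverage table", call. = FALSE)
    }
    if (length(absent) > 0) {
      message("median_coverage: ", length(absent),
              " cohort sample(s) missing from coverage table, skipped")
    }
    coverage <- coverage[coverage$sample_id %in% cohort_samples, , drop = FALSE]
  }
  coverage |>
    dplyr::group_by(.data$gene_symbol) |>
    dplyr::summarise(median_fraction = stats::median(.data$fraction),
                     n_samples = dplyr::n(), .groups = "drop")
}

#' Read a gene annotation table
#'
#' @param path TSV with columns `gene_symbol`, `coding_length` (longest
#'   transcript, bases), optional `expression_log2` and `annotation_error`.
#' @return Tibble with `gene_symbol`, `coding_length`, `annotation_error`
#'   (and `expression_log2` when present).
#' @export
read_annotation <- function(path) {
  ann <- readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
  required <- c("gene_symbol", "coding_length")
  missing <- setdiff(required, names(ann))
  if (length(missing) > 0) {
    stop("annotation table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(ann$coding_length <= 0, na.rm = TRUE)) {
    stop("coding_length must be strictly positive", call. = FALSE)
  }
  if (!"annotation_error" %in% names(ann)) ann$annotation_error <- FALSE
  ann$annotation_error <- as.logical(ann$annotation_error)
  ann
}

#' Read a per-gene expression table
#'
#' @param path TSV with columns `gene_symbol`, `expression_log2`.
#' @return Tibble with those columns.
#' @export
read_expression <- function(path) {
  expr <- readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
  missing <- setdiff(c("gene_symbol", "expression_log2"), names(expr))
  if (length(missing) > 0) {
    stop("expression table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  expr[c("gene_symbol", "expression_log2")]
}

#' Apply the gene exclusion filters
#'
#' Excludes genes with cohort median coverage below 50%, log2 expression
#' below 2.0, or an annotation error, since these genes either have
#' artificially low observed mutation rates or are unlikely to matter when
#' unexpressed. Boundary values (median exactly 0.5, expression exactly 2.0)
#' are kept. Genes missing from the coverage summary are treated as median 0
#' (and reported); genes missing expression are treated as unexpressed.
#'
#' @param annotation Tibble with `gene_symbol`, `coding_length`,
#'   `expression_log2`, `annotation_error`.
#' @param coverage_medians Tibble from [median_coverage()].
#' @param min_median_cov Minimum median coverage fraction kept (default 0.5).
#' @param min_expression_log2 Minimum expression kept (default 2.0).
#' @return A list with `kept` (character vector of gene symbols) and
#'   `report` (tibble: gene_symbol, median_fraction, expression_log2,
#'   annotation_error, kept, reasons — comma-separated among
#'   "coverage", "expression", "annotation").
#' @export
filter_genes <- function(annotation, coverage_medians,
                         min_median_cov = 0.5, min_expression_log2 = 2.0) {
  if (!"expression_log2" %in% names(annotation)) {
    stop("annotation must carry an expression_log2 column ",
         "(join read_expression() output first)", call. = FALSE)
  }
  rep_tbl <- dplyr::left_join(
    annotation[c("gene_symbol", "expression_log2", "annotation_error")],
    coverage_medians[c("gene_symbol", "median_fraction")],
    by = "gene_symbol")
  n_nocov <- sum(is.na(rep_tbl$median_fraction))
  if (n_nocov > 0) {
    message("filter_genes: ", n_nocov,
            " gene(s) absent from coverage summary treated as median 0")
    rep_tbl$median_fraction[is.na(rep_tbl$median_fraction)] <- 0
  }
  rep_tbl$expression_log2[is.na(rep_tbl$expression_log2)] <- -Inf

  low_cov <- rep_tbl$median_fraction < min_median_cov
  low_expr <- rep_tbl$expression_log2 < min_expression_log2
  ann_err <- rep_tbl$annotation_error %in% TRUE
  reasons <- mapply(function(a, b, c) {
    paste(c(if (a) "coverage", if (b) "expression", if (c) "annotation"),
          collapse = ",")
  }, low_cov, low_expr, ann_err)
  rep_tbl$kept <- !(low_cov | low_expr | ann_err)
  rep_tbl$reasons <- unname(reasons)
  rep_tbl <- rep_tbl[c("gene_symbol", "median_fraction", "expression_log2",
                       "annotation_error", "kept", "reasons")]
  list(kept = rep_tbl$gene_symbol[rep_tbl$kept], report = rep_tbl)
}
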