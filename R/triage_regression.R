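#' Standardized-residual classification thresholds
#'
#' `flag` separates background from conserved/over-mutated (|SR| >= 1);
#' `suggestive` (|SR| >= 1.65, two-sided normal p ~ 0.1) and `significant`
#' (|SR| >= 2.0, p ~ 0.05) mark the confidence tiers used for reporting.
#'
#' @param flag,suggestive,significant Positive thresholds,
#'   `flag <= suggestive <= significant`.
#' @return An object of class `triage_thresholds`.
#' @export
triage_thresholds <- function(flag = 1.0, suggestive = 1.65, significant = 2.0) {
  stopifnot(flag > 0, flag <= suggestive, suggestive <= significant)
  structure(list(flag = flag, suggestive = suggestive,
                 significant = significant),
            class = "triage_thresholds")
}

#' Fraction of cohort patients with a protein-altering mutation per gene
#'
#' A patient counts at most once per gene regardless of how many qualifying
#' mutations they carry; the denominator is the cohort size, so genes never
#' mutated in the cohort get fraction 0.
#'
#' @param records Mutation-record tibble already restricted to
#'   protein-altering variants (see [is_protein_altering()]).
#' @param cohort_patients Character vector of patient ids in the cohort.
#' @param genes Optional character vector of genes to report; defaults to
#'   every gene seen in `records`. Genes without mutations get `n_mutated`
#'   0 and fraction 0.
#' @return Tibble with `gene_symbol`, `n_mutated`, `f`.
#' @export
mutation_fraction <- function(records, cohort_patients, genes = NULL) {
  if (length(cohort_patients) == 0) {
    stop("cohort is empty: cannot compute mutation fractions", call. = FALSE)
  }
  cohort_patients <- unique(cohort_patients)
  rec <- records[records$patient_id %in% cohort_patients,
                 c("gene_symbol", "patient_id"), drop = FALSE]
  rec <- dplyr::distinct(rec)
  counts <- rec |>
    dplyr::count(.data$gene_symbol, name = "n_mutated")
  if (is.null(genes)) genes <- sort(unique(records$gene_symbol))
  out <- tibble::tibble(gene_symbol = genes) |>
    dplyr::left_join(counts, by = "gene_symbol") |>
    dplyr::mutate(n_mutated = ifelse(is.na(.data$n_mutated), 0L,
                                     as.integer(.data$n_mutated)),
                  f = .data$n_mutated / length(cohort_patients))
  out
}

#' Coverage-corrected mutation fraction
#'
#' Divides the mutated-patient fraction by the gene's cohort median coverage
#' fraction, so genes with incomplete sequencing are not mistaken for
#' conserved ones. The result is not capped at 1.
#'
#' @param f Raw mutated-patient fraction(s).
#' @param m Median coverage fraction(s), > 0 (genes with median 0 should
#'   have been removed by [filter_genes()]).
#' @return Corrected fraction(s) `f / m`.
#' @export
corrected_fraction <- function(f, m) {
  if (any(m <= 0)) {
    stop("median coverage must be positive; genes with zero coverage ",
         "should have been excluded by filter_genes()", call. = FALSE)
  }
  f / m
}

#' Fit the mutation-fraction vs gene-size regression
#'
#' Fits `y ~ x` where `x = sqrt(coding length)` and
#' `y = sqrt(corrected mutation fraction)`; the square-root transforms
#' stabilize the binomial sampling variance of the patient fractions and
#' make the size relationship close to linear through small fractions.
#' The default estimator is ordinary least squares; `"huber"` uses an
#' M-estimator (Huber psi, tuning constant 1.345) so that strongly selected
#' outlier genes pull less on the background line.
#'
#' @param x Numeric vector, `sqrt(coding_length)` per gene.
#' @param y Numeric vector, `sqrt(corrected_fraction)` per gene.
#' @param estimator `"ols"` or `"huber"`.
#' @return A `triage_model` list: `intercept`, `slope`, `residual_scale`
#'   (residual standard error for OLS, robust scale for Huber), `n_genes`,
#'   `estimator`.
#' @export
fit_triage <- function(x, y, estimator = c("ols", "huber")) {
  estimator <- match.arg(estimator)
  stopifnot(length(x) == length(y))
  if (length(x) < 3) {
    stop("need at least 3 genes to fit the size regression", call. = FALSE)
  }
  if (isTRUE(all.equal(stats::var(x), 0)) || length(unique(x)) == 1) {
    stop("degenerate gene sizes: x values are all equal", call. = FALSE)
  }
  if (estimator == "ols") {
    fit <- stats::lm(y ~ x)
    coefs <- stats::coef(fit)
    rss <- sum(stats::residuals(fit)^2)
    scale <- sqrt(rss / (length(x) - 2))
  } else {
    fit <- MASS::rlm(y ~ x, psi = MASS::psi.huber, k = 1.345, maxit = 100)
    coefs <- stats::coef(fit)
    scale <- fit$s
  }
  structure(list(intercept = unname(coefs[1]), slope = unname(coefs[2]),
                 residual_scale = scale, n_genes = length(x),
                 estimator = estimator),
            class = "triage_model")
}

#' @export
print.triage_model <- function(x, ...) {
  cat("Triage size regression (", x$estimator, "), ", x$n_genes, " genes\n",
      "  sqrt(corrected fraction) = ", format(x$intercept, digits = 4), " + ",
      format(x$slope, digits = 4), " * sqrt(coding length)\n",
      "  residual scale: ", format(x$residual_scale, digits = 4), "\n",
      sep = "")
  invisible(x)
}

#' Standardized residuals from a triage model
#'
#' The standardized residual of a gene is its vertical distance from the
#' regression line divided by the model's residual scale; the
#' `"studentized"` option additionally divides by `sqrt(1 - leverage)`
#' (internal studentization, OLS leverage from the fitted x values).
#'
#' @param model A `triage_model` from [fit_triage()].
#' @param x,y The gene coordinates the model was fitted on.
#' @param method `"scale"` (default) or `"studentized"`.
#' @return Numeric vector of standardized residuals.
#' @export
standardized_residuals <- function(model, x, y,
                                   method = c("scale", "studentized")) {
  method <- match.arg(method)
  if (model$residual_scale <= max(abs(y), 1) * 1e-12) {
    stop("residual scale is zero (perfect fit); standardized residuals are ",
         "undefined — the input is degenerate", call. = FALSE)
  }
  res <- y - (model$intercept + model$slope * x)
  sr <- res / model$residual_scale
  if (method == "studentized") {
    h <- 1 / length(x) + (x - mean(x))^2 / sum((x - mean(x))^2)
    sr <- sr / sqrt(pmax(1 - h, .Machine$double.eps))
  }
  sr
}

#' Classify genes by standardized residual
#'
#' Genes with SR <= -flag are conserved (under-mutated), SR >= flag are
#' over-mutated, the rest background. Tiers mark |SR| >= suggestive (normal
#' two-sided p ~ 0.1) and |SR| >= significant (p ~ 0.05). A reference
#' two-sided normal p-value `2 * pnorm(-|SR|)` is attached; no
#' multiple-testing correction is applied.
#'
#' @param sr Numeric vector of standardized residuals.
#' @param thresholds A [triage_thresholds()].
#' @return Tibble with `sr`, `label`, `tier`, `p_two_sided`.
#' @export
classify_sr <- function(sr, thresholds = triage_thresholds()) {
  label <- ifelse(sr <= -thresholds$flag, "conserved",
                  ifelse(sr >= thresholds$flag, "over_mutated", "background"))
  tier <- ifelse(abs(sr) >= thresholds$significant, "significant",
                 ifelse(abs(sr) >= thresholds$suggestive, "suggestive", "none"))
  tibble::tibble(sr = sr, label = label, tier = tier,
                 p_two_sided = 2 * stats::pnorm(-abs(sr)))
}

#' Frequently mutated genes
#'
#' Genes mutated in strictly more than `cutoff` of cohort patients (raw,
#' uncorrected fraction).
#'
#' @param scores A tibble with `gene_symbol` and raw fraction `f`
#'   (e.g. from [mutation_fraction()] or [triage_scores()]).
#' @param cutoff Fraction cutoff, default 0.10.
#' @return Character vector of gene symbols with `f > cutoff`.
#' @export
frequently_mutated <- function(scores, cutoff = 0.10) {
  scores$gene_symbol[scores$f > cutoff]
}

#' Score every kept gene in a cohort
#'
#' The full per-cohort statistic: restrict records to protein-altering
#' variants and cohort patients, compute per-gene mutated-patient fractions,
#' correct by median coverage, square-root transform fraction and coding
#' length, fit the size regression, and classify each gene by its
#' standardized residual.
#'
#' @param records Mutation-record tibble (one sample per patient).
#' @param cohort_patients Character vector of patient ids in the cohort.
#' @param annotation Gene annotation tibble (`gene_symbol`, `coding_length`,
#'   `expression_log2`, `annotation_error`).
#' @param coverage_medians Per-gene median coverage from [median_coverage()]
#'   for this cohort.
#' @param policy [variant_class_policy()] selecting protein-altering classes.
#' @param estimator `"ols"` or `"huber"` (see [fit_triage()]).
#' @param thresholds [triage_thresholds()].
#' @param sr_method `"scale"` or `"studentized"`.
#' @param min_median_cov,min_expression_log2 Gene filters, see
#'   [filter_genes()].
#' @return A tibble (one row per kept gene) with columns `gene_symbol`,
#'   `n_mutated`, `cohort_size`, `f`, `m`, `c`, `coding_length`,
#'   `expression_log2`, `x`, `y`, `fitted`, `residual`, `sr`, `label`,
#'   `tier`, `p_two_sided`, sorted by `sr`. The fitted `triage_model` is
#'   attached as attribute `"model"` and the filter report as
#'   attribute `"filter_report"`.
#' @export
triage_scores <- function(records, cohort_patients, annotation,
                          coverage_medians,
                          policy = variant_class_policy(),
                          estimator = c("ols", "huber"),
                          thresholds = triage_thresholds(),
                          sr_method = c("scale", "studentized"),
                          min_median_cov = 0.5, min_expression_log2 = 2.0) {
  estimator <- match.arg(estimator)
  sr_method <- match.arg(sr_method)
  flt <- filter_genes(annotation, coverage_medians,
                      min_median_cov = min_median_cov,
                      min_expression_log2 = min_expression_log2)
  kept <- flt$kept
  if (length(kept) < 3) {
    stop("fewer than 3 genes pass the coverage/expression filters",
         call. = FALSE)
  }
  pa <- records[is_protein_altering(records, policy), , drop = FALSE]
  frac <- mutation_fraction(pa, cohort_patients, genes = kept)

  tab <- frac |>
    dplyr::left_join(annotation[c("gene_symbol", "coding_length",
                                  "expression_log2")],
                     by = "gene_symbol") |>
    dplyr::left_join(coverage_medians[c("gene_symbol", "median_fraction")],
                     by = "gene_symbol") |>
    dplyr::rename(m = "median_fraction") |>
    dplyr::mutate(cohort_size = length(unique(cohort_patients)),
                  c = corrected_fraction(.data$f, .data$m),
                  x = sqrt(.data$coding_length),
                  y = sqrt(.data$c))

  model <- fit_triage(tab$x, tab$y, estimator = estimator)
  tab$fitted <- model$intercept + model$slope * tab$x
  tab$residual <- tab$y - tab$fitted
  cls <- classify_sr(
    standardized_residuals(model, tab$x, tab$y, method = sr_method),
    thresholds)
  tab$sr <- cls$sr
  tab$label <- cls$label
  tab$tier <- cls$tier
  tab$p_two_sided <- cls$p_two_sided

  out <- tab[order(tab$sr), c("gene_symbol", "n_mutated", "cohort_size",
                              "f", "m", "c", "coding_length",
                              "expression_log2", "x", "y", "fitted",
                              "residual", "sr", "label", "tier",
                              "p_two_sided")]
  attr(out, "model") <- model
  attr(out, "filter_report") <- flt$report
  out
}

#' Plot standardized residual against expression
#'
#' Scatter of per-gene SR versus log2 expression, coloring and labelling
#' genes beyond the flag threshold (conserved below, over-mutated above) —
#' the standard way to read a cohort's selection landscape for a gene set.
#'
#' @param scores Output of [triage_scores()] (optionally subset to a panel).
#' @param thresholds [triage_thresholds()]; the flag level is drawn.
#' @param label_genes Label genes with |SR| >= flag (default TRUE).
#' @return A ggplot object.
#' @export
plot_sr_expression <- function(scores, thresholds = triage_thresholds(),
                               label_genes = TRUE) {
  scores$status <- factor(scores$label,
                          levels = c("conserved", "background", "over_mutated"))
  p <- ggplot2::ggplot(scores,
                       ggplot2::aes(x = .data$expression_log2, y = .data$sr,
                                    colour = .data$status)) +
    ggplot2::geom_hline(yintercept = c(-thresholds$flag, thresholds$flag),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(conserved = "#b2182b",
                                            background = "grey60",
                                            over_mutated = "#2166ac"),
                                 drop = FALSE) +
    ggplot2::labs(x = "expression (log2 counts)",
                  y = "standardized residual (SR)", colour = NULL)
  if (label_genes) {
    lab <- scores[abs(scores$sr) >= thresholds$flag, , drop = FALSE]
    if (nrow(lab) > 0) {
      p <- p + ggplot2::geom_text(
        data = lab, ggplot2::aes(label = .data$gene_symbol),
        size = 2.7, vjust = -0.6, show.legend = FALSE)
    }
  }
  p
}
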