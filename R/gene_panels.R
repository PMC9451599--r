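#' Read curated gene panels from YAML
#'
#' Panels map a functional category (e.g. "Antigen Processing",
#' "Complement") to a set of gene symbols; a gene may belong to several
#' categories.
#'
#' @param path YAML file: `category: [GENE1, GENE2, ...]`.
#' @return Named list of character vectors.
#' @export
read_panels <- function(path) {
  panels <- yaml::read_yaml(path)
  if (length(panels) == 0) stop("panel file is empty: ", path, call. = FALSE)
  panels <- lapply(panels, as.character)
  empty <- lengths(panels) == 0
  if (any(empty)) {
    stop("panel categor(ies) with no genes: ",
         paste(names(panels)[empty], collapse = ", "), call. = FALSE)
  }
  panels
}

#' Panel report of conserved or over-mutated genes
#'
#' Maps triage scores onto curated categories and reports, per category, the
#' panel genes whose SR meets the cutoff in the requested direction
#' (`conserved`: SR <= cutoff, cutoff negative; `over_mutated`: SR >=
#' cutoff). Within a category rows are sorted by |SR| descending; a gene in
#' several categories appears once per category. Symbol matching is exact
#' and case-insensitive, with an optional alias map for synonyms
#' (e.g. `c(NECTIN2 = "PVRL2")` maps panel symbol NECTIN2 to score symbol
#' PVRL2). Panel symbols absent from the scores produce a warning and are
#' skipped.
#'
#' @param scores Output of [triage_scores()].
#' @param panels Named list of character vectors (see [read_panels()]).
#' @param direction `"conserved"` or `"over_mutated"`.
#' @param sr_cutoff SR cutoff; defaults to -1.65 for conserved and +1.65 for
#'   over-mutated when `NULL`.
#' @param aliases Optional named character vector: names are panel symbols,
#'   values the symbols used in `scores`.
#' @return Tibble with `category`, `gene_symbol`, `sr`.
#' @export
panel_report <- function(scores, panels,
                         direction = c("conserved", "over_mutated"),
                         sr_cutoff = NULL, aliases = NULL) {
  direction <- match.arg(direction)
  if (is.null(sr_cutoff)) sr_cutoff <- if (direction == "conserved") -1.65 else 1.65
  if (direction == "conserved" && sr_cutoff > 0) {
    stop("conserved reports need a non-positive sr_cutoff", call. = FALSE)
  }
  if (direction == "over_mutated" && sr_cutoff < 0) {
    stop("over-mutated reports need a non-negative sr_cutoff", call. = FALSE)
  }
  lookup <- scores$sr
  names(lookup) <- toupper(scores$gene_symbol)

  rows <- list()
  unknown <- character()
  for (cat in names(panels)) {
    syms <- panels[[cat]]
    if (!is.null(aliases)) {
      hit <- toupper(syms) %in% toupper(names(aliases))
      syms[hit] <- unname(aliases[match(toupper(syms[hit]),
                                        toupper(names(aliases)))])
    }
    known <- toupper(syms) %in% names(lookup)
    unknown <- c(unknown, syms[!known])
    syms <- syms[known]
    if (length(syms) == 0) next
    sr <- unname(lookup[toupper(syms)])
    keep <- if (direction == "conserved") sr <= sr_cutoff else sr >= sr_cutoff
    if (!any(keep)) next
    block <- tibble::tibble(category = cat, gene_symbol = syms[keep],
                            sr = sr[keep])
    rows[[cat]] <- block[order(-abs(block$sr)), ]
  }
  if (length(unknown) > 0) {
    warning("panel_report: ", length(unknown), " panel symbol(s) not in ",
            "scores, skipped: ",
            paste(unique(unknown), collapse = ", "), call. = FALSE)
  }
  if (length(rows) == 0) {
    return(tibble::tibble(category = character(), gene_symbol = character(),
                          sr = numeric()))
  }
  dplyr::bind_rows(rows)
}

#' Genes meeting the cutoff in two cohorts
#'
#' Intersection of the gene symbols appearing in two panel reports built
#' with the same direction and cutoff convention — e.g. the genes conserved
#' in both the wild-type and the mutant-KRAS cohort.
#'
#' @param report_a,report_b Tibbles from [panel_report()].
#' @return Character vector of shared gene symbols (sorted).
#' @export
cross_cohort_overlap <- function(report_a, report_b) {
  sort(intersect(unique(report_a$gene_symbol), unique(report_b$gene_symbol)))
}
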