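#' Define a driver-mutation rule
#'
#' A rule names a gene and the hotspot residues (reference amino acid +
#' position, e.g. `"G12"`) and/or an inclusive exon interval in which indels
#' qualify. When a qualifying record is an indel but its exon number is
#' missing, an optional protein-residue window is used as a fallback.
#'
#' @param gene_symbol Gene symbol (matched case-insensitively).
#' @param sites Character vector of hotspot residues like `"G12"`, `"Q61"`.
#' @param indel_exons Optional integer vector `c(low, high)`: inclusive exon
#'   interval in which any indel matches.
#' @param indel_residue_window Optional fallback `c(low, high)` protein-residue
#'   window used for indels whose exon number is unavailable.
#' @return An object of class `driver_rule`.
#' @export
driver_rule <- function(gene_symbol, sites = character(),
                        indel_exons = NULL, indel_residue_window = NULL) {
  if (length(sites) == 0 && is.null(indel_exons)) {
    stop("a driver rule needs hotspot sites and/or an indel exon range",
         call. = FALSE)
  }
  if (length(sites) > 0) {
    ok <- grepl("^[A-Z*]\\d+$", sites)
    if (!all(ok)) {
      stop("malformed hotspot site(s): ", paste(sites[!ok], collapse = ", "),
           call. = FALSE)
    }
  }
  if (!is.null(indel_exons)) {
    stopifnot(length(indel_exons) == 2, all(indel_exons > 0),
              indel_exons[1] <= indel_exons[2])
  }
  structure(list(gene_symbol = gene_symbol, sites = sites,
                 indel_exons = indel_exons,
                 indel_residue_window = indel_residue_window),
            class = "driver_rule")
}

#' Default LUAD driver rules
#'
#' The standard lung-adenocarcinoma stratification rules: recurrent hotspot
#' substitutions in KRAS (G12, G13, Q61, A146), BRAF (V600, N581, G464, G466,
#' G469, G596, D594) and EGFR (L858, S768, L861, G719, T790 plus indels in
#' exons 18-21, with a residue window 688-875 fallback when the exon number
#' is not recorded).
#'
#' @return Named list of [driver_rule()] objects.
#' @export
default_driver_rules <- function() {
  list(
    KRAS = driver_rule("KRAS", c("G12", "G13", "Q61", "A146")),
    BRAF = driver_rule("BRAF", c("V600", "N581", "G464", "G466", "G469",
                                 "G596", "D594")),
    EGFR = driver_rule("EGFR", c("L858", "S768", "L861", "G719", "T790"),
                       indel_exons = c(18L, 21L),
                       indel_residue_window = c(688L, 875L))
  )
}

#' Read driver rules from a YAML file
#'
#' Expected layout: `GENE: {sites: [G12, ...], indel_exons: [18, 21],
#' indel_residue_window: [688, 875]}`.
#'
#' @param path YAML file path.
#' @return Named list of [driver_rule()] objects.
#' @export
read_driver_rules <- function(path) {
  spec <- yaml::read_yaml(path)
  if (length(spec) == 0) stop("driver-rule file is empty: ", path, call. = FALSE)
  rules <- lapply(names(spec), function(g) {
    s <- spec[[g]]
    driver_rule(g, sites = as.character(s$sites %||% character()),
                indel_exons = if (!is.null(s$indel_exons)) as.integer(s$indel_exons),
                indel_residue_window = if (!is.null(s$indel_residue_window))
                  as.integer(s$indel_residue_window))
  })
  names(rules) <- names(spec)
  rules
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Match mutation records against one driver rule
#'
#' A record matches when its gene equals the rule's gene (case-insensitive)
#' and either (a) the reference residue + position parsed from its protein
#' change is one of the rule's hotspot sites and the change is not
#' synonymous, or (b) the record is an indel whose exon number falls in the
#' rule's indel exon range (protein-residue window fallback when the exon is
#' missing). Records on the rule gene whose protein change cannot be parsed
#' trigger a warning and are treated as non-matches.
#'
#' @param records Mutation-record tibble.
#' @param rule A [driver_rule()].
#' @return Logical vector, one element per record.
#' @export
match_rule <- function(records, rule) {
  n <- nrow(records)
  if (n == 0) return(logical(0))
  on_gene <- toupper(records$gene_symbol) == toupper(rule$gene_symbol)
  out <- rep(FALSE, n)
  if (!any(on_gene)) return(out)

  hg <- parse_hgvsp(records$protein_change[on_gene])
  site_hit <- rep(FALSE, sum(on_gene))
  if (length(rule$sites) > 0) {
    key <- ifelse(is.na(hg$ref) | is.na(hg$pos), NA_character_,
                  paste0(hg$ref, hg$pos))
    synonymous <- !is.na(hg$alt) & hg$alt == "="
    site_hit <- !is.na(key) & key %in% rule$sites & !synonymous
  }

  indel_hit <- rep(FALSE, sum(on_gene))
  if (!is.null(rule$indel_exons)) {
    exon <- records$exon_number[on_gene]
    is_ind <- records$is_indel[on_gene]
    exon_known <- !is.na(exon)
    indel_hit <- is_ind & exon_known &
      exon >= rule$indel_exons[1] & exon <= rule$indel_exons[2]
    if (!is.null(rule$indel_residue_window)) {
      w <- rule$indel_residue_window
      fallback <- is_ind & !exon_known & !is.na(hg$pos) &
        hg$pos >= w[1] & hg$pos <= w[2]
      indel_hit <- indel_hit | fallback
    }
  }

  unparsed <- is.na(hg$pos) & nzchar(records$protein_change[on_gene]) &
    !records$is_indel[on_gene]
  if (any(unparsed)) {
    warning("match_rule: ", sum(unparsed), " unparseable protein change(s) on ",
            rule$gene_symbol, " treated as non-matching", call. = FALSE)
  }

  out[on_gene] <- site_hit | indel_hit
  out
}

#' Assign patients to driver-defined cohorts
#'
#' Each patient is labelled `m<GENE>` when exactly one rule gene matches any
#' of their records, `excluded` when two or more rule genes match, and `WT`
#' when none do. Records are expected to be one sample per patient
#' (see [one_sample_per_patient()]).
#'
#' @param records Mutation-record tibble (one sample per patient).
#' @param rules Named list of [driver_rule()] objects, e.g.
#'   [default_driver_rules()].
#' @return A tibble with columns `patient_id`, `label`, `matched_rules`
#'   (comma-separated gene symbols) and `n_matched`.
#' @export
assign_cohorts <- function(records, rules = default_driver_rules()) {
  if (length(rules) == 0) stop("no driver rules supplied", call. = FALSE)
  patients <- sort(unique(records$patient_id))
  hits <- lapply(rules, function(r) {
    m <- match_rule(records, r)
    unique(records$patient_id[m])
  })
  matched <- lapply(patients, function(p) {
    sort(names(rules)[vapply(hits, function(h) p %in% h, logical(1))])
  })
  n_matched <- lengths(matched)
  label <- ifelse(n_matched == 0, "WT",
                  ifelse(n_matched > 1, "excluded",
                         paste0("m", vapply(matched, function(x)
                           if (length(x) == 1) x else "", character(1)))))
  out <- tibble::tibble(
    patient_id = patients,
    label = label,
    matched_rules = vapply(matched, paste, character(1), collapse = ","),
    n_matched = as.integer(n_matched)
  )
  counts <- table(out$label)
  message("assign_cohorts: ",
          paste(names(counts), as.integer(counts), sep = "=", collapse = ", "))
  out
}
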