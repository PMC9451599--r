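#' Variant classification policy
#'
#' Defines which MAF `Variant_Classification` strings count as
#' protein-altering (nonsynonymous, truncating, or canonical splice-site).
#' The default set covers the MAF controlled vocabulary categories that
#' change the encoded protein; `Silent`, UTR, intronic and flank classes are
#' deliberately absent.
#'
#' @param protein_altering Character vector of MAF classification strings
#'   treated as protein-altering.
#' @return An object of class `variant_class_policy`.
#' @export
#' @examples
#' policy <- variant_class_policy()
#' is_protein_altering("Missense_Mutation", policy)
variant_class_policy <- function(protein_altering = c(
                                   "Missense_Mutation", "Nonsense_Mutation",
                                   "Nonstop_Mutation", "Frame_Shift_Del",
                                   "Frame_Shift_Ins", "In_Frame_Del",
                                   "In_Frame_Ins", "Splice_Site",
                                   "Translation_Start_Site")) {
  stopifnot(is.character(protein_altering), length(protein_altering) > 0)
  structure(list(protein_altering = unique(protein_altering)),
            class = "variant_class_policy")
}

# Three-letter -> one-letter amino-acid code, Ter/* included.
.aa3to1 <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
  Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
  Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
  Tyr = "Y", Val = "V", Ter = "*", Sec = "U"
)

#' Parse HGVSp-short protein changes
#'
#' Extracts the reference residue (one-letter), 1-based position and the
#' trailing alternate description from HGVSp strings such as `p.G12D`,
#' `p.Gly12Asp`, `p.E746_A750del`, or `p.G12fs`. Three-letter residue codes
#' are normalized to one-letter form. Unparseable or empty strings yield NA.
#'
#' @param x Character vector of protein-change strings.
#' @return A tibble with columns `ref` (one-letter reference residue),
#'   `pos` (integer residue position) and `alt` (normalized alternate;
#'   `"="` for synonymous).
#' @export
parse_hgvsp <- function(x) {
  x <- as.character(x)
  out <- tibble::tibble(ref = NA_character_, pos = NA_integer_,
                        alt = NA_character_, .rows = length(x))
  ok <- !is.na(x) & nzchar(x)
  if (!any(ok)) return(out)

  body <- sub("^p\\.\\(?", "", x[ok])
  body <- sub("\\)$", "", body)
  # three-letter form first (e.g. Gly12Asp), then one-letter (G12D)
  m3 <- regmatches(body, regexec("^([A-Z][a-z]{2})(\\d+)(.*)$", body))
  m1 <- regmatches(body, regexec("^([A-Z*])(\\d+)(.*)$", body))

  ref <- alt_raw <- rep(NA_character_, length(body))
  pos <- rep(NA_integer_, length(body))
  for (i in seq_along(body)) {
    g3 <- m3[[i]]
    if (length(g3) == 4 && g3[2] %in% names(.aa3to1)) {
      ref[i] <- unname(.aa3to1[g3[2]])
      pos[i] <- as.integer(g3[3])
      alt_raw[i] <- g3[4]
    } else {
      g1 <- m1[[i]]
      if (length(g1) == 4) {
        ref[i] <- g1[2]
        pos[i] <- as.integer(g1[3])
        alt_raw[i] <- g1[4]
      }
    }
  }
  # normalize alternate: leading three-letter residue -> one-letter;
  # a bare repeat of the reference or "=" means synonymous
  alt <- alt_raw
  has_alt <- !is.na(alt) & nzchar(alt)
  a3 <- substr(alt[has_alt], 1, 3)
  one <- .aa3to1[a3]
  conv <- !is.na(one) & substr(alt[has_alt], 1, 1) %in% LETTERS &
    grepl("^[A-Z][a-z]{2}", alt[has_alt])
  alt[has_alt][conv] <- paste0(unname(one[conv]),
                               substr(alt[has_alt][conv], 4,
                                      nchar(alt[has_alt][conv])))
  syn <- !is.na(alt) & !is.na(ref) & (alt == ref | alt == "=")
  alt[syn] <- "="

  out$ref[ok] <- ref
  out$pos[ok] <- pos
  out$alt[ok] <- alt
  out
}

.parse_exon <- function(x) {
  # MAF Exon_Number is often "19/28"; keep the leading integer
  x <- as.character(x)
  n <- suppressWarnings(as.integer(sub("^([0-9]+).*$", "\\1", x)))
  n[!grepl("^[0-9]", ifelse(is.na(x), "", x))] <- NA_integer_
  n
}

#' Read a MAF file into mutation records
#'
#' Reads a tab-separated somatic mutation table in the TCGA MC3 dialect
#' (plain or gzip) and normalizes each row to a mutation record: patient
#' barcode (first 12 characters of the tumor sample barcode), full sample
#' barcode, Hugo symbol, variant classification, HGVSp-short protein change,
#' parsed protein position, indel flag, and exon number. Rows with a missing
#' gene symbol are dropped with a message. Columns are addressed by name;
#' unknown extra columns are ignored.
#'
#' @param path Path to a MAF file (`.maf`, `.maf.gz`, or any TSV).
#' @param policy A [variant_class_policy()] (kept for symmetry of the I/O
#'   surface; classification strings are passed through unmodified).
#' @return A tibble of mutation records with columns `patient_id`,
#'   `sample_id`, `gene_symbol`, `variant_classification`, `protein_change`,
#'   `protein_position`, `is_indel`, `exon_number`.
#' @export
read_maf <- function(path, policy = variant_class_policy()) {
  if (!file.exists(path)) {
    stop("cannot read MAF file: ", path, call. = FALSE)
  }
  raw <- readr::read_tsv(path, comment = "#", progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()),
                         na = c("", "NA", "."))
  required <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("MAF is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  n0 <- nrow(raw)
  raw <- raw[!is.na(raw$Hugo_Symbol) & nzchar(raw$Hugo_Symbol), , drop = FALSE]
  if (nrow(raw) < n0) {
    message("read_maf: dropped ", n0 - nrow(raw), " row(s) with missing gene symbol")
  }
  protein_change <- if ("HGVSp_Short" %in% names(raw)) raw$HGVSp_Short else NA_character_
  protein_change <- ifelse(is.na(protein_change), "", protein_change)
  variant_type <- if ("Variant_Type" %in% names(raw)) raw$Variant_Type else NA_character_
  exon_col <- intersect(c("Exon_Number", "EXON"), names(raw))
  exon <- if (length(exon_col) > 0) .parse_exon(raw[[exon_col[1]]]) else
    rep(NA_integer_, nrow(raw))

  hg <- parse_hgvsp(protein_change)
  is_indel <- !is.na(variant_type) & variant_type %in% c("DEL", "INS")
  # fall back on classification when Variant_Type is absent
  cls_indel <- raw$Variant_Classification %in%
    c("Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins")
  is_indel <- is_indel | (is.na(variant_type) & cls_indel)

  tibble::tibble(
    patient_id = substr(raw$Tumor_Sample_Barcode, 1, 12),
    sample_id = raw$Tumor_Sample_Barcode,
    gene_symbol = raw$Hugo_Symbol,
    variant_classification = raw$Variant_Classification,
    protein_change = protein_change,
    protein_position = hg$pos,
    is_indel = is_indel,
    exon_number = exon
  )
}

#' Write mutation records back to a MAF file
#'
#' Inverse of [read_maf()]: emits `Hugo_Symbol`, `Tumor_Sample_Barcode`,
#' `Variant_Classification`, `HGVSp_Short`, `Variant_Type` and `Exon_Number`
#' so that re-reading reproduces the records field-by-field.
#'
#' @param records A mutation-record tibble as returned by [read_maf()].
#' @param path Output path; `.gz` suffix compresses.
#' @return `path`, invisibly.
#' @export
write_maf <- function(records, path) {
  ins <- records$variant_classification %in% c("Frame_Shift_Ins", "In_Frame_Ins")
  vt <- ifelse(records$is_indel, ifelse(ins, "INS", "DEL"), "SNP")
  out <- tibble::tibble(
    Hugo_Symbol = records$gene_symbol,
    Tumor_Sample_Barcode = records$sample_id,
    Variant_Classification = records$variant_classification,
    HGVSp_Short = ifelse(nzchar(records$protein_change),
                         records$protein_change, NA_character_),
    Variant_Type = vt,
    Exon_Number = records$exon_number
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Is a variant protein-altering?
#'
#' @param x A mutation-record tibble (uses its `variant_classification`
#'   column) or a character vector of classification strings.
#' @param policy A [variant_class_policy()].
#' @return Logical vector, `TRUE` where the classification is in the
#'   policy's protein-altering set.
#' @export
is_protein_altering <- function(x, policy = variant_class_policy()) {
  cls <- if (is.data.frame(x)) x$variant_classification else x
  cls %in% policy$protein_altering
}

#' Reduce a cohort to one tumor sample per patient
#'
#' When a patient contributed several tumor samples, keeps all records from
#' exactly one of them: the sample whose TCGA sample-type code (barcode
#' characters 14-15) is `"01"` (primary tumor) if present, breaking ties by
#' the lexicographically smallest barcode. Retained/dropped sample counts are
#' reported via `message()`.
#'
#' @param records A mutation-record tibble.
#' @return The subset of `records` from the selected samples.
#' @export
one_sample_per_patient <- function(records) {
  if (nrow(records) == 0) return(records)
  samples <- unique(records[, c("patient_id", "sample_id")])
  type <- substr(samples$sample_id, 14, 15)
  ord <- order(samples$patient_id, type != "01", samples$sample_id)
  samples <- samples[ord, ]
  keep <- samples[!duplicated(samples$patient_id), , drop = FALSE]
  dropped <- nrow(samples) - nrow(keep)
  if (dropped > 0) {
    message("one_sample_per_patient: kept ", nrow(keep), " sample(s), dropped ",
            dropped, " extra sample(s)")
  }
  records[records$sample_id %in% keep$sample_id, , drop = FALSE]
}
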