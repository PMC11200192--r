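# Allele-name normalization and pseudosequence tables.
#
# Canonical form is LOCUS*GG:PP at four-digit resolution, e.g. "DRB1*07:01".
# DQ/DP molecules are alpha/beta heterodimers and are written as a pair joined
# by "/", e.g. "DQA1*05:01/DQB1*02:01". Inputs without an explicit four-digit
# typing cannot be normalized and are flagged so the caller can drop them.

#' Normalize an HLA class II allele name
#'
#' Accepts the common spellings found in epitope tables (`HLA-DRB1_0701`,
#' `DRB1*07:01`, `HLA-DRB1*07:01`, `DRB10701`, and `-`/`/`-joined
#' alpha/beta pairs for DQ and DP) and maps them to a canonical
#' `LOCUS*GG:PP` form. Alleles typed at less than four-digit resolution
#' cannot be normalized: they come back as `NA` because downstream models
#' need an unambiguous protein-level identity.
#'
#' @param raw Character vector of raw allele names.
#' @return Character vector of normalized names; `NA` where the input has no
#'   explicit four-digit typing.
#' @examples
#' normalize_allele(c("HLA-DRB1_0701", "DQA1*05:01-DQB1*02:01", "DRB1*07"))
#' @export
normalize_allele <- function(raw) {
  vapply(raw, normalize_allele_one, character(1), USE.NAMES = FALSE)
}

normalize_allele_one <- function(raw) {
  if (is.na(raw) || !nzchar(trimws(raw))) stopf("allele name is empty")
  x <- trimws(raw)
  # Heterodimer pairs may be joined by "/" or by "-" between chain blocks.
  if (grepl("/", x, fixed = TRUE)) {
    parts <- strsplit(x, "/", fixed = TRUE)[[1]]
  } else {
    # Split on "-" only between two chain names (avoid splitting "HLA-").
    x2 <- sub("^HLA-", "", x, ignore.case = TRUE)
    parts <- strsplit(x2, "-(?=D[PQR])", perl = TRUE)[[1]]
  }
  norm <- vapply(parts, normalize_chain, character(1))
  if (anyNA(norm)) return(NA_character_)
  paste(norm, collapse = "/")
}

normalize_chain <- function(x) {
  x <- sub("^HLA[-_]?", "", trimws(x), ignore.case = TRUE)
  m <- regmatches(x, regexec("^(D[PQR][AB]?[0-9]?)[*_]?([0-9:]*)$", toupper(x)))[[1]]
  if (length(m) == 0L) return(NA_character_)
  locus <- m[2]
  digits <- gsub(":", "", m[3], fixed = TRUE)
  if (nchar(digits) < 4L) return(NA_character_)  # two-digit-only typing
  paste0(locus, "*", substr(digits, 1, 2), ":", substr(digits, 3, 4))
}

#' Locus of a normalized allele name
#'
#' @param allele Character vector of normalized allele names.
#' @return `"DR"`, `"DQ"` or `"DP"` per element.
#' @export
allele_locus <- function(allele) {
  loc <- substr(allele, 1, 2)
  ifelse(loc %in% c("DR", "DQ", "DP"), loc, NA_character_)
}

#' Read an allele pseudosequence table
#'
#' The table maps each allele to its binding-groove pseudosequence in two
#' resolutions: the 34 peptide-contacting residues (`short_seq`, used by
#' one-hot/BLOSUM62 encodings) and the 269-residue form (`full_seq`, used by
#' the distance-profile encoding). The table is data, not code: any source
#' following the NetMHCIIpan pseudo-position convention can be supplied.
#'
#' @param path TSV/CSV with columns `allele`, `short_seq`, `full_seq`
#'   (`full_seq` may be empty for alleles lacking a full-length model).
#' @return Tibble with normalized `allele`, `short_seq`, `full_seq`.
#' @export
read_pseudosequences <- function(path) {
  tbl <- read_delim_quiet(path)
  need <- c("allele", "short_seq")
  miss <- setdiff(need, names(tbl))
  if (length(miss) > 0L)
    stopf("pseudosequence table is missing column(s): %s", paste(miss, collapse = ", "))
  if (!"full_seq" %in% names(tbl)) tbl$full_seq <- NA_character_
  tbl <- tibble::as_tibble(tbl[, c("allele", "short_seq", "full_seq")])
  tbl$allele <- normalize_allele(tbl$allele)
  bad <- nchar(tbl$short_seq) != 34L
  if (any(bad))
    stopf("short_seq must be 34 residues; offending allele(s): %s",
          paste(tbl$allele[bad], collapse = ", "))
  badf <- !is.na(tbl$full_seq) & nzchar(tbl$full_seq) & nchar(tbl$full_seq) != 269L
  if (any(badf))
    stopf("full_seq must be 269 residues; offending allele(s): %s",
          paste(tbl$allele[badf], collapse = ", "))
  tbl
}
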