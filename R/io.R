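# Readers and writers for the pipeline's tabular and sequence formats.
# Peptide tables are TSV-native; CSV is accepted by delimiter sniffing.

PEPTIDE_COLS <- c("peptide", "allele", "label", "gene", "n_flank", "c_flank",
                  "domain", "source")

#' Read a peptide observation table
#'
#' Each row is one peptide x allele observation. Required columns are
#' `peptide`, `allele` and `label`; `gene`, `n_flank`, `c_flank`, `domain`,
#' `source` and `assay_supported` are optional and filled with defaults.
#' Rows whose peptide (or flank) contains characters outside the 20-letter
#' amino-acid alphabet are rejected, with row-indexed diagnostics attached to
#' the result as attribute `"rejected"`.
#'
#' @param path TSV or CSV file.
#' @param domain Domain tag applied to rows lacking one: `"antigenic"`
#'   (presentation / eluted-ligand data) or `"immunogenic"` (T-cell response
#'   data).
#' @return Tibble of validated records with normalized allele names. Labels
#'   are integer 0/1 or `NA` for unknown.
#' @export
read_peptide_table <- function(path, domain = c("antigenic", "immunogenic")) {
  domain <- rlang::arg_match(domain)
  if (!file.exists(path)) stopf("no such file: %s", path)
  tbl <- read_delim_quiet(path, col_types = readr::cols(.default = "c"))
  if (nrow(tbl) == 0L) stopf("empty peptide table: %s", path)
  need <- c("peptide", "allele", "label")
  miss <- setdiff(need, names(tbl))
  if (length(miss) > 0L)
    stopf("peptide table is missing required column(s): %s", paste(miss, collapse = ", "))

  tbl$peptide <- toupper(trimws(tbl$peptide))
  ok <- is_valid_peptide(tbl$peptide)
  rejected <- tibble::tibble(
    row = which(!ok),
    peptide = tbl$peptide[!ok],
    reason = "peptide contains characters outside the 20-AA alphabet"
  )
  out <- tbl[ok, , drop = FALSE]

  out$label <- suppressWarnings(as.integer(out$label))
  out$label[!out$label %in% c(0L, 1L)] <- NA_integer_
  out$allele <- normalize_allele(out$allele)
  for (col in c("gene", "n_flank", "c_flank", "source")) {
    if (!col %in% names(out)) out[[col]] <- ""
    out[[col]][is.na(out[[col]])] <- ""
  }
  out$n_flank <- toupper(out$n_flank)
  out$c_flank <- toupper(out$c_flank)
  if (!"domain" %in% names(out)) out$domain <- domain
  out$domain[is.na(out$domain) | !nzchar(out$domain)] <- domain
  if ("assay_supported" %in% names(out))
    out$assay_supported <- as.logical(out$assay_supported)
  keep <- c(PEPTIDE_COLS, intersect("assay_supported", names(out)))
  out <- tibble::as_tibble(out[, keep])
  attr(out, "rejected") <- rejected
  out
}

#' Write a peptide table
#'
#' Inverse of [read_peptide_table()]: writes the standard TSV layout so that
#' a read/write round trip is the identity on valid records.
#'
#' @param records Peptide record tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(records, path) {
  cols <- intersect(c(PEPTIDE_COLS, "assay_supported"), names(records))
  readr::write_tsv(records[, cols], path, progress = FALSE)
  invisible(path)
}

#' Read a reference proteome
#'
#' @param path FASTA file (wrapped or unwrapped).
#' @return Named character vector of uppercase protein sequences.
#' @export
read_proteome <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  stats::setNames(toupper(as.character(seqs)), names(seqs))
}

#' Write a proteome FASTA
#'
#' @param proteins Named character vector of protein sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_proteome <- function(proteins, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(proteins), path)
  invisible(path)
}

#' Read a gene expression table
#'
#' @param path TSV/CSV with columns `gene` and `tpm` (transcripts per
#'   million, non-negative).
#' @return Tibble `gene`, `tpm`.
#' @export
read_expression_table <- function(path) {
  tbl <- read_delim_quiet(path)
  miss <- setdiff(c("gene", "tpm"), names(tbl))
  if (length(miss) > 0L)
    stopf("expression table is missing column(s): %s", paste(miss, collapse = ", "))
  if (any(tbl$tpm < 0, na.rm = TRUE)) stopf("negative TPM values in %s", path)
  tibble::as_tibble(tbl[, c("gene", "tpm")])
}

#' Read a residue-pair distance table
#'
#' A square matrix of C-alpha/C-alpha distances (Angstrom) indexed by 0-based
#' position in the 269-residue full pseudosequence, as TSV with a header row
#' of positions.
#'
#' @param path TSV matrix file.
#' @return Numeric matrix.
#' @export
read_distance_table <- function(path) {
  tbl <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(tbl)
  if (nrow(m) != ncol(m)) stopf("distance table must be square; got %d x %d", nrow(m), ncol(m))
  dimnames(m) <- NULL
  m
}
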