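# Cleavage-site windows and the gene-expression feature.

#' Extract cleavage-site windows around a peptide within its source protein
#'
#' Antigen processing leaves a proteolytic signature in the residues flanking
#' a ligand's termini. Each terminus contributes a 6-residue window: three
#' residues upstream and three downstream of the cut site, in N-to-C order.
#' Windows are padded with `X` where they extend past the protein ends, so
#' both windows are always exactly 6 residues.
#'
#' @param protein Source protein sequence.
#' @param start 0-based start index of the peptide in `protein`.
#' @param end 0-based exclusive end index of the peptide.
#' @return List with `n_window` and `c_window`, both 6-character strings.
#' @examples
#' extract_windows("ABCDEFGHIJKLMNOPQRST", 6, 13)
#' @export
extract_windows <- function(protein, start, end) {
  L <- nchar(protein)
  if (start >= end) stopf("start (%d) must be < end (%d)", start, end)
  if (start < 0 || end > L)
    stopf("peptide span [%d, %d) outside protein of length %d", start, end, L)
  list(
    n_window = padded_substr(protein, start - 3L, start + 3L),
    c_window = padded_substr(protein, end - 3L, end + 3L)
  )
}

# substring over 0-based [from, to), X-padded outside [0, nchar).
padded_substr <- function(x, from, to) {
  L <- nchar(x)
  left <- max(0L, -from)
  right <- max(0L, to - L)
  core <- substr(x, max(from, 0L) + 1L, min(to, L))
  paste0(strrep(AA_PAD, left), core, strrep(AA_PAD, right))
}

#' Flank-derived cleavage windows for a peptide record
#'
#' Builds the two 6-residue windows from a record's stored flanks instead of
#' a proteome lookup: `n_window` = 3-residue N flank + first 3 peptide
#' residues, `c_window` = last 3 peptide residues + 3-residue C flank.
#' Missing flank residues are X-padded (left-padded for the N flank,
#' right-padded for the C flank).
#'
#' @param peptide Peptide string (length >= 3).
#' @param n_flank,c_flank Flanking residue strings, possibly empty.
#' @return List with `n_window` and `c_window`.
#' @export
record_windows <- function(peptide, n_flank = "", c_flank = "") {
  if (nchar(peptide) < 3L) stopf("peptide too short for cleavage windows: %s", peptide)
  nf <- pad_flank(n_flank, side = "left")
  cf <- pad_flank(c_flank, side = "right")
  list(
    n_window = paste0(nf, substr(peptide, 1L, 3L)),
    c_window = paste0(substr(peptide, nchar(peptide) - 2L, nchar(peptide)), cf)
  )
}

pad_flank <- function(flank, side) {
  flank <- if (is.na(flank)) "" else flank
  if (nchar(flank) > 3L) {
    flank <- if (side == "left") substr(flank, nchar(flank) - 2L, nchar(flank))
             else substr(flank, 1L, 3L)
  }
  pad <- strrep(AA_PAD, 3L - nchar(flank))
  if (side == "left") paste0(pad, flank) else paste0(flank, pad)
}

#' Per-position background amino-acid frequencies over decoy windows
#'
#' Builds the null distribution against which cleavage signatures are
#' measured: for each of the 12 window positions (6 N-terminal + 6
#' C-terminal), the frequency of each amino acid across the decoy set.
#' Decoy windows come from record flanks when present, else from a proteome
#' lookup of the peptide; decoys locatable nowhere are skipped with a
#' warning count.
#'
#' @param decoys Decoy record tibble.
#' @param proteome Optional named character vector of proteins for flank
#'   lookup.
#' @return `12 x 20` matrix of frequencies; rows sum to 1 (padding symbols
#'   are excluded from the tally).
#' @export
cleavage_background <- function(decoys, proteome = NULL) {
  if (nrow(decoys) == 0L) stopf("empty decoy set")
  win <- windows_for_records(decoys, proteome)
  skipped <- sum(!win$ok)
  if (skipped > 0L)
    rlang::warn(sprintf("cleavage_background: skipped %d unlocatable decoy(s)", skipped))
  if (!any(win$ok)) stopf("no locatable decoys")
  chars <- matrix(unlist(strsplit(paste0(win$n_window[win$ok], win$c_window[win$ok]), "")),
                  ncol = 12L, byrow = TRUE)
  freq <- t(apply(chars, 2, function(col) {
    col <- col[col != AA_PAD]
    if (length(col) == 0L) return(rep(1 / 20, 20L))
    tab <- table(factor(col, levels = AA_ALPHABET))
    as.numeric(tab) / sum(tab)
  }))
  dimnames(freq) <- list(c(paste0("N", 1:6), paste0("C", 1:6)), AA_ALPHABET)
  freq
}

windows_for_records <- function(records, proteome = NULL) {
  n <- nrow(records)
  nw <- cw <- character(n)
  ok <- logical(n)
  nf <- if ("n_flank" %in% names(records)) records$n_flank else rep("", n)
  cf <- if ("c_flank" %in% names(records)) records$c_flank else rep("", n)
  for (i in seq_len(n)) {
    if (nzchar(nf[i]) || nzchar(cf[i])) {
      w <- record_windows(records$peptide[i], nf[i], cf[i])
    } else if (!is.null(proteome)) {
      w <- lookup_windows(records$peptide[i], proteome)
      if (is.null(w)) { ok[i] <- FALSE; next }
    } else {
      w <- record_windows(records$peptide[i], "", "")
    }
    nw[i] <- w$n_window; cw[i] <- w$c_window; ok[i] <- TRUE
  }
  tibble::tibble(n_window = nw, c_window = cw, ok = ok)
}

lookup_windows <- function(peptide, proteome) {
  for (prot in proteome) {
    pos <- regexpr(peptide, prot, fixed = TRUE)
    if (pos > 0L) {
      return(extract_windows(prot, pos - 1L, pos - 1L + nchar(peptide)))
    }
  }
  NULL
}

#' Gene-expression feature
#'
#' Looks up a gene's TPM and maps it to logarithmic space as
#' `log10(X + 10^6)`. In vaccine-candidate mode a fixed TPM override
#' (conventionally 50) stands in for unavailable RNA-seq. Genes absent from
#' the table with no override yield `NA`, signalling that the record should
#' be excluded from analysis.
#'
#' @param gene Character vector of gene symbols.
#' @param table Expression tibble (`gene`, `tpm`), or `NULL` when only the
#'   override is used.
#' @param tpm_override Optional fixed TPM applied to every gene.
#' @return Numeric vector of transformed values (`NA` = excluded).
#' @examples
#' expression_feature("G1", tibble::tibble(gene = "G1", tpm = 0))  # 6
#' @export
expression_feature <- function(gene, table = NULL, tpm_override = NULL) {
  if (!is.null(tpm_override)) {
    if (tpm_override < 0) stopf("negative TPM: %g", tpm_override)
    return(rep(log10(tpm_override + 1e6), length(gene)))
  }
  if (is.null(table)) return(rep(NA_real_, length(gene)))
  tpm <- table$tpm[match(gene, table$gene)]
  if (any(tpm < 0, na.rm = TRUE)) stopf("negative TPM in expression table")
  log10(tpm + 1e6)
}

# Map the log-space expression value onto [0,1] for score fusion. TPM cannot
# exceed 1e6, so log10(X + 1e6) lives in [6, log10(2e6)]; rescale that range.
expression_score <- function(transformed) {
  pmin(1, pmax(0, (transformed - 6) / (log10(2e6) - 6)))
}
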