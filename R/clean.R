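# Data-cleaning rules for immunogenicity (T-cell response) records.

#' Clean an immunogenicity record table
#'
#' Applies the quality filters used to curate class II T-cell response data:
#'
#' 1. records without an explicit four-digit HLA typing are dropped;
#' 2. peptide length is restricted to `length_range` (default 11-19 mer,
#'    inclusive);
#' 3. records without experimental support for their label are dropped
#'    (boolean column `assay_supported`; if the column is absent all rows are
#'    treated as supported);
#' 4. duplicate peptide x allele groups with conflicting labels collapse to a
#'    single positive record, reflecting the fluctuating nature of
#'    immunogenicity assays;
#' 5. records restricted by an HLA-DPB-only allele are removed.
#'
#' The operation is idempotent. Per-rule removal counts are attached as
#' attribute `"removal_counts"` and emitted as a message.
#'
#' @param records Peptide record tibble (see [read_peptide_table()]).
#' @param length_range Inclusive length bounds, default `c(11, 19)`.
#' @param quiet Suppress the removal-count message.
#' @return Filtered tibble, one row per peptide x allele.
#' @export
clean_immunogenicity <- function(records, length_range = c(11L, 19L), quiet = FALSE) {
  n0 <- nrow(records)
  counts <- c(no_four_digit = 0L, length = 0L, unsupported = 0L,
              dpb_only = 0L, merged_duplicates = 0L)

  keep <- !is.na(records$allele)
  counts["no_four_digit"] <- sum(!keep)
  records <- records[keep, , drop = FALSE]

  len <- nchar(records$peptide)
  keep <- len >= length_range[1] & len <= length_range[2]
  counts["length"] <- sum(!keep)
  records <- records[keep, , drop = FALSE]

  if ("assay_supported" %in% names(records)) {
    keep <- !is.na(records$assay_supported) & records$assay_supported
    counts["unsupported"] <- sum(!keep)
    records <- records[keep, , drop = FALSE]
  }

  # DPB-only restriction (a beta chain without its alpha partner) is removed;
  # full DPA/DPB pairs are kept.
  dpb_only <- vapply(strsplit(records$allele, "/", fixed = TRUE), function(chains) {
    all(startsWith(chains, "DPB"))
  }, logical(1))
  counts["dpb_only"] <- sum(dpb_only)
  records <- records[!dpb_only, , drop = FALSE]

  merged <- records |>
    dplyr::group_by(.data$peptide, .data$allele) |>
    dplyr::summarise(
      label = if (all(is.na(.data$label))) NA_integer_ else max(.data$label, na.rm = TRUE),
      dplyr::across(dplyr::any_of(c("gene", "n_flank", "c_flank", "domain", "source")),
                    ~ .x[1]),
      dplyr::across(dplyr::any_of("assay_supported"), ~ any(.x)),
      .groups = "drop"
    )
  counts["merged_duplicates"] <- nrow(records) - nrow(merged)

  if (!quiet)
    message(sprintf(
      "clean_immunogenicity: %d -> %d records (removed: %s)",
      n0, nrow(merged),
      paste(sprintf("%s=%d", names(counts), counts), collapse = ", ")))
  attr(merged, "removal_counts") <- counts
  merged
}
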