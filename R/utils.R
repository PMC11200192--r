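# Shared constants and small helpers.

# The 20 proteinogenic amino acids in alphabetical one-letter order; 'X' is
# the padding/unknown symbol everywhere in the package.
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AA_PAD <- "X"

#' Amino-acid alphabet used throughout the package
#'
#' @return Character vector of the 20 one-letter amino-acid codes, in
#'   alphabetical order. The padding symbol `"X"` is not included.
#' @export
aa_alphabet <- function() AA_ALPHABET

aa_index <- stats::setNames(seq_along(AA_ALPHABET), AA_ALPHABET)

is_valid_peptide <- function(x) {
  !is.na(x) & nzchar(x) & !grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"), x)
}

split_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Delimiter sniffing: tabs win if present in the header, else comma.
sniff_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) return("\t")
  if (grepl("\t", header)) "\t" else ","
}

read_delim_quiet <- function(path, ...) {
  readr::read_delim(path, delim = sniff_delim(path), show_col_types = FALSE,
                    progress = FALSE, ...)
}

# Seed scoping: every stochastic function takes a seed and restores RNG state.
with_seed <- function(seed, code) withr::with_seed(as.integer(seed), code)

stopf <- function(fmt, ...) rlang::abort(sprintf(fmt, ...))
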