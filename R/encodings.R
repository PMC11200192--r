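# Amino-acid sequence encodings for peptides and allele pseudosequences.
#
# Three schemes: one-hot over 20 AAs + padding channel, BLOSUM62 similarity
# rows + padding indicator, and a distance-profile encoding of the 269-residue
# full pseudosequence. All are deterministic and length-covariant: the first
# L rows depend only on the first L residues.

blosum62_rows <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
    }
    cache
  }
})

#' One-hot encode a sequence
#'
#' Encodes a peptide (or 34-residue pseudosequence) as a `(pad_to, 21)`
#' matrix: 20 amino-acid channels plus a padding channel `X`. Positions
#' beyond the true length are one-hot on the padding channel, so every row
#' sums to 1.
#'
#' @param seq Amino-acid string (uppercase, 20-letter alphabet).
#' @param pad_to Total number of rows; must be >= `nchar(seq)`.
#' @return Numeric matrix `(pad_to, 21)` with attributes `true_length` and
#'   `scheme`.
#' @export
encode_onehot <- function(seq, pad_to = nchar(seq)) {
  chars <- check_encodable(seq, pad_to)
  L <- length(chars)
  m <- matrix(0, nrow = pad_to, ncol = 21L,
              dimnames = list(NULL, c(AA_ALPHABET, AA_PAD)))
  m[cbind(seq_len(L), aa_index[chars])] <- 1
  if (pad_to > L) m[(L + 1L):pad_to, 21L] <- 1
  structure(m, true_length = L, scheme = "onehot")
}

#' BLOSUM62 similarity encode a sequence
#'
#' Row i holds the BLOSUM62 substitution scores of residue i against the 20
#' amino acids, plus a 21st padding-indicator column. Padding rows are
#' all-zero with indicator 1, so one-hot and BLOSUM62 encodings agree on
#' which rows are padding.
#'
#' @inheritParams encode_onehot
#' @return Numeric matrix `(pad_to, 21)` with attributes `true_length` and
#'   `scheme`.
#' @export
encode_blosum <- function(seq, pad_to = nchar(seq)) {
  chars <- check_encodable(seq, pad_to)
  L <- length(chars)
  m <- matrix(0, nrow = pad_to, ncol = 21L,
              dimnames = list(NULL, c(AA_ALPHABET, "pad")))
  m[seq_len(L), 1:20] <- blosum62_rows()[chars, , drop = FALSE]
  if (pad_to > L) m[(L + 1L):pad_to, 21L] <- 1
  structure(m, true_length = L, scheme = "blosum62")
}

check_encodable <- function(seq, pad_to) {
  if (is.na(seq) || !nzchar(seq)) stopf("cannot encode an empty sequence")
  if (!is_valid_peptide(seq))
    stopf("sequence contains characters outside the 20-AA alphabet: %s", seq)
  if (nchar(seq) > pad_to)
    stopf("sequence length %d exceeds pad_to = %d", nchar(seq), pad_to)
  split_chars(seq)
}

#' Distance-profile encoding of a full-length allele pseudosequence
#'
#' Represents each of the 269 residues of the full pseudosequence by its
#' spatial relation to the peptide-binding groove: the vector for residue i
#' is `exp(-d(i, a) / sigma)` over a fixed panel of groove anchor positions
#' `a` (proximity weights; larger = closer), concatenated with the residue's
#' BLOSUM62 row. Distances come from a residue-pair C-alpha distance table
#' supplied as data, so any structural model can back the encoding.
#'
#' @param full_seq 269-residue pseudosequence string.
#' @param distance_table Square numeric matrix of C-alpha/C-alpha distances
#'   (Angstrom) over the 269 positions.
#' @param anchors 0-based indices of the groove anchor panel; defaults to 34
#'   positions evenly spaced over the sequence.
#' @param sigma Length scale of the proximity transform, in Angstrom.
#' @return Numeric matrix `(269, length(anchors) + 20)` with attribute
#'   `scheme = "ca_distance"`.
#' @export
encode_ca_distance <- function(full_seq, distance_table,
                               anchors = default_groove_anchors(),
                               sigma = 8) {
  if (is.na(full_seq) || !nzchar(full_seq))
    stopf("full 269-residue pseudosequence is missing; use the one-hot or BLOSUM62 encoding of the 34-residue pseudosequence instead")
  chars <- split_chars(full_seq)
  L <- length(chars)
  if (L != 269L)
    stopf("distance-profile encoding needs the 269-residue pseudosequence, got %d residues", L)
  if (nrow(distance_table) != L || ncol(distance_table) != L)
    stopf("distance table must be %d x %d, got %d x %d",
          L, L, nrow(distance_table), ncol(distance_table))
  stopifnot(all(anchors >= 0), all(anchors < L))
  prox <- exp(-distance_table[, anchors + 1L, drop = FALSE] / sigma)
  sim <- matrix(0, nrow = L, ncol = 20L)
  known <- chars %in% AA_ALPHABET
  sim[known, ] <- blosum62_rows()[chars[known], , drop = FALSE]
  structure(cbind(prox, sim), true_length = L, scheme = "ca_distance")
}

#' Default groove anchor panel for the distance-profile encoding
#'
#' 34 positions (0-based) evenly spaced over the 269-residue full
#' pseudosequence, mirroring the size of the peptide-contact panel.
#'
#' @return Integer vector of 34 0-based positions.
#' @export
default_groove_anchors <- function() {
  as.integer(round(seq(0, 268, length.out = 34)))
}

# Stacked encoding used by the sequence branches of the presentation model:
# one-hot and BLOSUM62 channels concatenated column-wise, (pad_to, 42).
# BLOSUM62 scores are divided by their maximum magnitude (11) to keep both
# channel blocks on comparable scale for the encoder input projection.
encode_stacked <- function(seq, pad_to) {
  cbind(encode_onehot(seq, pad_to), encode_blosum(seq, pad_to) / 11)
}
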