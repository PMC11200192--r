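# Cross-validation splits at peptide level.
#
# Splits are made over *unique peptide strings*, never over rows, so that an
# identical peptide occurring in several records (e.g. under different
# alleles) can never straddle a fold boundary and leak between training and
# held-out partitions.

#' Assign repeated k-fold cross-validation splits
#'
#' Produces `repeats` independent peptide-level partitions into `folds`
#' folds. Within each repeat, every unique peptide string is assigned to
#' exactly one fold; all records sharing a peptide string inherit that fold.
#' Assignments are deterministic given `seed`.
#'
#' @param records Peptide record tibble.
#' @param folds Number of folds (>= 2), default 5.
#' @param repeats Number of repeats (>= 1), default 10.
#' @param seed Integer seed.
#' @return Tibble with columns `repeat_id`, `peptide`, `fold`; one row per
#'   (repeat, unique peptide).
#' @export
make_cv_splits <- function(records, folds = 5L, repeats = 10L, seed = 1L) {
  if (folds < 2L) stopf("folds must be >= 2, got %d", folds)
  if (repeats < 1L) stopf("repeats must be >= 1, got %d", repeats)
  peptides <- sort(unique(records$peptide))   # canonical: record-order invariant
  n <- length(peptides)
  if (n < folds) stopf("dataset has %d unique peptides, fewer than %d folds", n, folds)
  with_seed(seed, {
    purrr::map_dfr(seq_len(repeats), function(r) {
      # Balanced fold sizes: shuffle, then deal fold labels round-robin.
      shuffled <- sample(peptides)
      fold <- rep_len(seq_len(folds), n)
      tibble::tibble(repeat_id = r, peptide = shuffled, fold = fold)
    })
  })
}

#' Split records into train and validation sets
#'
#' Peptide-level split at the given ratio (default 4:1 train:validation);
#' identical peptide strings never straddle the boundary.
#'
#' @param records Peptide record tibble.
#' @param val_fraction Fraction of unique peptides held out, default 0.2.
#' @param seed Integer seed.
#' @return List with tibbles `train` and `val`.
#' @export
split_train_val <- function(records, val_fraction = 0.2, seed = 1L) {
  peptides <- sort(unique(records$peptide))   # canonical: record-order invariant
  n_val <- max(1L, round(length(peptides) * val_fraction))
  val_peps <- with_seed(seed, sample(peptides, n_val))
  list(
    train = records[!records$peptide %in% val_peps, , drop = FALSE],
    val   = records[records$peptide %in% val_peps, , drop = FALSE]
  )
}
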