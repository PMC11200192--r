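# Evaluation protocol: ranking metrics, PPVn with proteome decoys, and the
# neoantigen binding-core scan.

#' Area under the ROC curve
#'
#' Mann-Whitney formulation with tie correction (tied scores contribute
#' 1/2 per positive/negative pair, via average ranks).
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1); both classes must be present.
#' @return AUC in [0, 1].
#' @export
auc <- function(scores, labels) {
  check_two_class(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Average precision: the sum over distinct score thresholds of the change
#' in recall times the precision at that threshold, scanning scores in
#' decreasing order with tied scores grouped.
#'
#' @inheritParams auc
#' @return AUPR in [0, 1].
#' @export
aupr <- function(scores, labels) {
  check_two_class(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # group ties: cumulative counts at the last index of each distinct score
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(y)[last]
  fp <- cumsum(1 - y)[last]
  n_pos <- sum(y)
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' F1 score at a probability threshold
#'
#' @inheritParams auc
#' @param threshold Decision threshold on the score (default 0.5).
#' @return F1 in [0, 1] (0 when no positive predictions and no true
#'   positives).
#' @export
f1_score <- function(scores, labels, threshold = 0.5) {
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Balanced accuracy at a probability threshold
#'
#' Mean of sensitivity and specificity.
#'
#' @inheritParams f1_score
#' @return Balanced accuracy in [0, 1].
#' @export
balanced_accuracy <- function(scores, labels, threshold = 0.5) {
  check_two_class(labels)
  pred <- as.numeric(scores >= threshold)
  sens <- sum(pred == 1 & labels == 1) / sum(labels == 1)
  spec <- sum(pred == 0 & labels == 0) / sum(labels == 0)
  (sens + spec) / 2
}

check_two_class <- function(labels) {
  if (length(unique(labels[!is.na(labels)])) < 2L)
    stopf("metric needs both classes present")
  invisible(TRUE)
}

#' Positive predictive value over the top-n fraction (PPVn)
#'
#' Ranks all records by score and takes the top `k = ceiling(fraction * n)`
#' (ties broken by stable record order). The `precision` variant reports
#' the fraction of those k that are true binders; the `recall` variant
#' reports the fraction of all binders captured in the top k. Precision is
#' the default: it is the reading under which performance necessarily
#' degrades as the fraction grows in a decoy-dominated design.
#'
#' @inheritParams auc
#' @param fraction Top fraction of the dataset, in (0, 1].
#' @param variant `"precision"` (default) or `"recall"`.
#' @return PPVn value in [0, 1].
#' @export
ppvn <- function(scores, labels, fraction = 0.02,
                 variant = c("precision", "recall")) {
  variant <- rlang::arg_match(variant)
  if (fraction <= 0 || fraction > 1) stopf("fraction must be in (0, 1], got %g", fraction)
  n <- length(scores)
  k <- ceiling(fraction * n)
  ord <- order(-scores, seq_len(n))   # stable: ties by record order
  top <- labels[ord[seq_len(k)]]
  if (variant == "precision") sum(top == 1) / k else sum(top == 1) / sum(labels == 1)
}

#' Generate length-matched proteome decoys
#'
#' For each hit, draws `per_hit` random substrings of identical length from
#' the proteome, excluding any sequence present in the hit set and any
#' window containing a non-standard residue. Deterministic given the seed.
#'
#' @param hits Tibble with a `peptide` column (alleles/genes are copied
#'   through when present).
#' @param proteome Named character vector of protein sequences.
#' @param per_hit Decoys per hit (the canonical benchmark design uses 98).
#' @param seed Integer seed.
#' @return Tibble of decoy records (`label = 0`, `source = "decoy"`).
#' @export
make_decoys <- function(hits, proteome, per_hit = 98L, seed = 1L) {
  if (length(proteome) == 0L) stopf("empty proteome")
  hit_set <- unique(hits$peptide)
  prot_names <- names(proteome) %||% paste0("prot", seq_along(proteome))
  prot_len <- nchar(proteome)
  with_seed(seed, {
    out <- vector("list", nrow(hits))
    for (i in seq_len(nrow(hits))) {
      L <- nchar(hits$peptide[i])
      eligible <- which(prot_len >= L)
      if (length(eligible) == 0L)
        stopf("no protein long enough for a %d-mer decoy", L)
      peps <- character(per_hit); genes <- character(per_hit)
      got <- 0L; tries <- 0L
      while (got < per_hit) {
        tries <- tries + 1L
        if (tries > per_hit * 1000L)
          stopf("cannot draw %d decoys of length %d without hit overlap", per_hit, L)
        pi_ <- eligible[sample.int(length(eligible), 1L)]
        start <- sample.int(prot_len[pi_] - L + 1L, 1L)
        cand <- substr(proteome[pi_], start, start + L - 1L)
        if (cand %in% hit_set || !is_valid_peptide(cand)) next
        got <- got + 1L
        peps[got] <- cand; genes[got] <- prot_names[pi_]
      }
      out[[i]] <- tibble::tibble(
        peptide = peps,
        allele = if ("allele" %in% names(hits)) hits$allele[i] else NA_character_,
        label = 0L, gene = genes, n_flank = "", c_flank = "",
        domain = if ("domain" %in% names(hits)) hits$domain[i] else "antigenic",
        source = "decoy")
    }
    dplyr::bind_rows(out)
  })
}

#' Scan an oligomer for its best 9-mer binding core
#'
#' Scores every 9-residue window of the oligomer with the supplied scorer
#' and returns the highest-scoring core; an 18-mer yields exactly 10
#' windows. Ties go to the smallest offset (stable tie-break).
#'
#' @param oligomer Amino-acid string of length >= 9 (canonically 18).
#' @param scorer Function mapping a character vector of 9-mers to numeric
#'   scores.
#' @return List with `core`, 0-based `offset`, `score`, and the full
#'   `scores` tibble.
#' @export
core_scan <- function(oligomer, scorer) {
  L <- nchar(oligomer)
  if (L < 9L) stopf("oligomer must be at least 9 residues, got %d", L)
  offs <- 0:(L - 9L)
  cores <- substring(oligomer, offs + 1L, offs + 9L)
  sc <- scorer(cores)
  stopifnot(length(sc) == length(cores))
  best <- which.max(sc)   # which.max returns the first maximum: stable
  list(core = cores[best], offset = offs[best], score = sc[best],
       scores = tibble::tibble(offset = offs, core = cores, score = sc))
}

#' Stratified evaluation report
#'
#' Computes AUC, AUPR, F1, balanced accuracy and PPVn overall and per
#' stratum: HLA locus (`pan` = all records, `DR`, `DQ&DP`) and peptide
#' length. Strata with a single class get `NA` metrics (undefined, not
#' zero); empty strata are omitted.
#'
#' @inheritParams auc
#' @param meta Tibble aligned with `scores` carrying `allele` and
#'   `peptide`.
#' @param ppvn_fraction Fraction for the PPVn column (default 0.02).
#' @return Tibble with one row per stratum (class `evaluation_report`).
#' @export
stratified_report <- function(scores, labels, meta, ppvn_fraction = 0.02) {
  stopifnot(nrow(meta) == length(scores))
  locus <- allele_locus(meta$allele)
  len <- nchar(meta$peptide)
  strata <- list(list(name = "pan", idx = seq_along(scores)))
  for (lc in list(c("DR", "DR"), c("DQ&DP", "DQ|DP"))) {
    idx <- which(grepl(lc[2], locus))
    if (length(idx) > 0L) strata <- c(strata, list(list(name = lc[1], idx = idx)))
  }
  for (l in sort(unique(len))) {
    strata <- c(strata, list(list(name = sprintf("length_%d", l), idx = which(len == l))))
  }
  rows <- purrr::map_dfr(strata, function(st) {
    s <- scores[st$idx]; y <- labels[st$idx]
    one_class <- length(unique(y)) < 2L
    tibble::tibble(
      stratum = st$name, n = length(st$idx), n_pos = sum(y == 1),
      auc = if (one_class) NA_real_ else auc(s, y),
      aupr = if (one_class) NA_real_ else aupr(s, y),
      f1 = if (one_class) NA_real_ else f1_score(s, y),
      balanced_acc = if (one_class) NA_real_ else balanced_accuracy(s, y),
      ppvn = if (one_class) NA_real_ else ppvn(s, y, ppvn_fraction))
  })
  structure(rows, class = c("evaluation_report", class(rows)))
}
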