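# Brute-force oracles for the ranking metrics, written independently of the
# implementations: explicit loops over pairs, thresholds and contingency
# tables.

auc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  total / (length(pos) * length(neg))
}

aupr_brute <- function(scores, labels) {
  ths <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0; ap <- 0
  for (t in ths) {
    tp <- sum(scores >= t & labels == 1)
    fp <- sum(scores >= t & labels == 0)
    prec <- tp / (tp + fp)
    rec <- tp / sum(labels == 1)
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

test_that("auc and aupr match brute-force enumeration on random instances", {
  withr::local_seed(100)
  for (i in 1:60) {
    n <- sample(4:50, 1)
    labels <- c(0, 1, sample(0:1, n - 2, TRUE))     # both classes guaranteed
    scores <- round(runif(n), sample(c(1, 2, 6), 1)) # rounding induces ties
    expect_equal(auc(scores, labels), auc_brute(scores, labels), tolerance = 1e-12)
    expect_equal(aupr(scores, labels), aupr_brute(scores, labels), tolerance = 1e-12)
  }
})

test_that("auc handles perfect, partial and fully tied rankings", {
  expect_equal(auc(c(0.9, 0.8, 0.7, 0.6), c(1, 1, 0, 0)), 1)
  expect_equal(auc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 0.75)
  expect_equal(auc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_error(auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("f1 and balanced accuracy match textbook formulas on a 2x2 grid", {
  for (tp in 0:3) for (fp in 0:3) for (fn in 0:3) for (tn in 0:3) {
    if (tp + fn == 0 || fp + tn == 0) next   # need both classes
    scores <- c(rep(1, tp), rep(1, fp), rep(0, fn), rep(0, tn))
    labels <- c(rep(1, tp), rep(0, fp), rep(1, fn), rep(0, tn))
    f1_ref <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    ba_ref <- (tp / (tp + fn) + tn / (fp + tn)) / 2
    expect_equal(f1_score(scores, labels), f1_ref)
    expect_equal(balanced_accuracy(scores, labels), ba_ref)
  }
})

test_that("ppvn follows the top-k design with ceiling and stable ties", {
  # 10 binders ranked first among 990 records, fraction 2%
  scores <- c(seq(1, 0.991, length.out = 10), runif(980, 0, 0.9))
  labels <- c(rep(1, 10), rep(0, 980))
  expect_equal(ppvn(scores, labels, 0.02, "precision"), 10 / 20)  # k = ceil(19.8)
  expect_equal(ppvn(scores, labels, 0.02, "recall"), 1)
  # binders ranked last: zero under both variants
  worst <- ppvn(-scores, labels, 0.02, "precision")
  expect_equal(worst, 0)
  expect_equal(ppvn(-scores, labels, 0.02, "recall"), 0)
  expect_error(ppvn(scores, labels, 0), "fraction")
  expect_error(ppvn(scores, labels, 1.5), "fraction")
})

test_that("ppvn(recall) is non-decreasing in the fraction", {
  withr::local_seed(8)
  scores <- runif(200); labels <- rbinom(200, 1, 0.3)
  fr <- seq(0.05, 1, by = 0.05)
  vals <- vapply(fr, function(f) ppvn(scores, labels, f, "recall"), numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("ppvn(precision) under random ranking has expectation = prevalence", {
  withr::local_seed(21)
  labels <- c(rep(1, 30), rep(0, 120))
  vals <- replicate(1000, ppvn(runif(150), labels, 0.2, "precision"))
  expect_equal(mean(vals), 0.2, tolerance = 0.02)   # prevalence = 30/150
})

test_that("decoys are length-matched, hit-excluded and deterministic", {
  proteome <- simulate_proteome(n_proteins = 8, mean_len = 120, seed = 3)
  hits <- make_records(random_peptides(10, seed = 4))
  d <- make_decoys(hits, proteome, per_hit = 98L, seed = 5L)
  expect_equal(nrow(d), 980L)
  expect_equal(nchar(d$peptide), rep(nchar(hits$peptide), each = 98L))
  expect_length(intersect(d$peptide, hits$peptide), 0L)
  expect_false(any(grepl("[^ACDEFGHIKLMNPQRSTVWY]", d$peptide)))
  expect_equal(make_decoys(hits, proteome, 98L, seed = 5L)$peptide, d$peptide)

  # proteome regions with non-standard residues are never emitted
  px <- c(p1 = paste0(strrep("A", 20), "XXXXX", strrep("C", 20)))
  dx <- make_decoys(make_records("DDDDDDDDDD"), px, per_hit = 20L, seed = 6L)
  expect_false(any(grepl("X", dx$peptide)))

  expect_error(make_decoys(make_records(strrep("A", 50)),
                           c(p = "ACDEFG"), 5L, 1L), "long enough")
})

test_that("core_scan enumerates all 9-mer windows and returns the argmax", {
  oligo <- paste(rep(c("A", "C"), 9), collapse = "")   # 18-mer
  calls <- 0
  scorer <- function(cores) { calls <<- calls + length(cores); seq_along(cores) * 0 }
  res <- core_scan(oligo, scorer)
  expect_equal(calls, 10L)                  # 18 - 9 + 1 windows
  expect_equal(res$offset, 0L)              # constant scorer: stable tie-break
  # peaked scorer: brute-force argmax at window 4
  peaked <- function(cores) as.numeric(seq_along(cores) == 5L)
  res2 <- core_scan(oligo, peaked)
  expect_equal(res2$offset, 4L)
  expect_equal(res2$core, substr(oligo, 5, 13))
  expect_error(core_scan("ACDEFGHI", scorer), "at least 9")
})

test_that("stratified report computes per-stratum metrics and flags
           undefined strata", {
  meta <- dplyr::bind_rows(
    make_records(random_peptides(20, c(12, 12), seed = 1), alleles = "DRB1*07:01"),
    make_records(random_peptides(20, c(15, 15), seed = 2),
                 alleles = "DQA1*05:01/DQB1*02:01"))
  labels <- rep(c(1, 0), 20)
  scores <- ifelse(labels == 1, runif(40, 0.6, 1), runif(40, 0, 0.4))
  rep_ <- stratified_report(scores, labels, meta)
  expect_equal(rep_$auc[rep_$stratum == "pan"], auc(scores, labels))
  expect_equal(rep_$auc[rep_$stratum == "DR"], 1)
  expect_equal(rep_$auc[rep_$stratum == "DQ&DP"], 1)
  expect_true(all(c("length_12", "length_15") %in% rep_$stratum))

  # single-class stratum: metrics undefined, not zero
  meta2 <- make_records(c(random_peptides(5, c(12, 12), seed = 3),
                          random_peptides(5, c(13, 13), seed = 4)))
  labs2 <- c(1, 1, 1, 1, 1, 1, 0, 1, 0, 1)
  rep2 <- stratified_report(runif(10), labs2, meta2)
  expect_true(is.na(rep2$auc[rep2$stratum == "length_12"]))
  expect_false(is.na(rep2$auc[rep2$stratum == "length_13"]))
})
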