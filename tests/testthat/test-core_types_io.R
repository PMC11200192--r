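test_that("read_peptide_table validates and round-trips records", {
  recs <- make_records(c("ACDEFGHIKLMNP", "WYVTSRQPNMLKI", "GGGGGGGGGGGG"),
                       labels = c(1L, 0L, 1L), genes = "G1",
                       n_flanks = "AAA", c_flanks = "CCC")
  path <- write_tsv_tmp(recs)
  got <- read_peptide_table(path)
  expect_equal(nrow(got), 3L)
  expect_equal(got$peptide, recs$peptide)

  # round trip is the identity on valid records
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_peptide_table(got, path2)
  again <- read_peptide_table(path2)
  expect_equal(as.data.frame(again), as.data.frame(got))
})

test_that("rows with invalid residues are rejected with row diagnostics", {
  recs <- make_records(c("ACDEFGHIKLMN", "ACDB1FGHIKLM", "MMMMMMMMMMMM"))
  got <- read_peptide_table(write_tsv_tmp(recs))
  expect_equal(nrow(got), 2L)
  rej <- attr(got, "rejected")
  expect_equal(rej$row, 2L)
  expect_match(rej$reason, "alphabet")
})

test_that("missing required columns and empty tables are format errors", {
  noallele <- tibble::tibble(peptide = "ACDEFGHIKLMN", label = 1L)
  expect_error(read_peptide_table(write_tsv_tmp(noallele)), "allele")
  empty <- tibble::tibble(peptide = character(), allele = character(),
                          label = integer())
  expect_error(read_peptide_table(write_tsv_tmp(empty)), "empty")
  expect_error(read_peptide_table("/nonexistent/file.tsv"), "no such file")
})

test_that("csv input is accepted by delimiter sniffing", {
  recs <- make_records("ACDEFGHIKLMN")
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(recs, path)
  expect_equal(read_peptide_table(path)$peptide, "ACDEFGHIKLMN")
})

test_that("allele names normalize to LOCUS*GG:PP with heterodimer pairs", {
  expect_equal(normalize_allele("HLA-DRB1_0701"), "DRB1*07:01")
  expect_equal(normalize_allele("DRB1*07:01"), "DRB1*07:01")
  expect_equal(normalize_allele("DQA1*05:01-DQB1*02:01"), "DQA1*05:01/DQB1*02:01")
  expect_equal(normalize_allele("DQA1*05:01/DQB1*02:01"), "DQA1*05:01/DQB1*02:01")
  expect_equal(normalize_allele("HLA-DPA1*01:03-DPB1*04:01"), "DPA1*01:03/DPB1*04:01")
  # two-digit-only typing is un-normalizable
  expect_true(is.na(normalize_allele("DRB1*07")))
  expect_true(is.na(normalize_allele("DRB1")))
  expect_error(normalize_allele(""), "empty")
})

test_that("allele_locus extracts the locus", {
  expect_equal(allele_locus(c("DRB1*07:01", "DQA1*05:01/DQB1*02:01", "DPA1*01:03/DPB1*04:01")),
               c("DR", "DQ", "DP"))
})

test_that("clean_immunogenicity applies the curation rules", {
  recs <- dplyr::bind_rows(
    make_records("ACDEFGHIKL"),                               # 10-mer: dropped
    make_records("ACDEFGHIKLMNPQW"),                          # 15-mer DRB1: kept
    make_records("ACDEFGHIKLMNPQW", labels = 0L),             # conflict -> positive
    make_records("WWWWWWWWWWWWWWW"),                          # kept
    tibble::tibble(peptide = "CCCCCCCCCCCCCCC", allele = NA_character_,
                   label = 1L, gene = "", n_flank = "", c_flank = "",
                   domain = "immunogenic", source = "test"),  # no 4-digit type
    make_records("DDDDDDDDDDDDDDD", alleles = "DPB1*04:01")   # DPB-only: dropped
  )
  out <- clean_immunogenicity(recs, quiet = TRUE)
  expect_setequal(out$peptide, c("ACDEFGHIKLMNPQW", "WWWWWWWWWWWWWWW"))
  expect_equal(out$label[out$peptide == "ACDEFGHIKLMNPQW"], 1L)
  counts <- attr(out, "removal_counts")
  expect_equal(unname(counts["length"]), 1L)
  expect_equal(unname(counts["no_four_digit"]), 1L)
  expect_equal(unname(counts["dpb_only"]), 1L)
  expect_equal(unname(counts["merged_duplicates"]), 1L)

  # idempotent
  out2 <- clean_immunogenicity(out, quiet = TRUE)
  expect_equal(as.data.frame(out2), as.data.frame(out), ignore_attr = TRUE)
})

test_that("assay support column gates records only when present", {
  recs <- make_records(c("ACDEFGHIKLMNPQW", "MMMMMMMMMMMMMMM"))
  recs$assay_supported <- c(TRUE, FALSE)
  out <- clean_immunogenicity(recs, quiet = TRUE)
  expect_equal(out$peptide, "ACDEFGHIKLMNPQW")
  # absent column: all rows treated as supported
  out2 <- clean_immunogenicity(recs[, setdiff(names(recs), "assay_supported")],
                               quiet = TRUE)
  expect_equal(nrow(out2), 2L)
})

test_that("heterodimer pairs with a DPB chain are retained", {
  recs <- make_records("ACDEFGHIKLMNPQW", alleles = "DPA1*01:03/DPB1*04:01")
  out <- clean_immunogenicity(recs, quiet = TRUE)
  expect_equal(nrow(out), 1L)
})

test_that("cv splits are balanced, peptide-level and deterministic", {
  peps <- random_peptides(100, seed = 5)
  recs <- make_records(peps)
  sp <- make_cv_splits(recs, folds = 5L, repeats = 3L, seed = 9L)
  expect_equal(nrow(sp), 300L)
  for (r in 1:3) {
    tab <- table(sp$fold[sp$repeat_id == r])
    expect_equal(unname(c(tab)), rep(20L, 5L))
    # every unique peptide covered exactly once per repeat
    expect_setequal(sp$peptide[sp$repeat_id == r], peps)
  }
  # duplicated peptide strings land in the same fold via the join
  dup <- make_records(rep(peps[1], 2), alleles = c("DRB1*07:01", "DRB1*15:01"))
  spd <- make_cv_splits(dplyr::bind_rows(recs, dup), folds = 5L, repeats = 1L, seed = 9L)
  folds_of_dup <- spd$fold[spd$peptide == peps[1]]
  expect_equal(length(folds_of_dup), 1L)   # one row per unique peptide

  expect_equal(make_cv_splits(recs, 5L, 2L, seed = 3L),
               make_cv_splits(recs, 5L, 2L, seed = 3L))
  expect_error(make_cv_splits(recs[1:3, ], folds = 5L), "fewer")
  expect_error(make_cv_splits(recs, folds = 1L), "folds")
})

test_that("train/val split is peptide-level at the requested ratio", {
  recs <- make_records(random_peptides(50, seed = 2))
  sp <- split_train_val(recs, val_fraction = 0.2, seed = 4L)
  expect_equal(nrow(sp$train) + nrow(sp$val), 50L)
  expect_equal(nrow(sp$val), 10L)
  expect_length(intersect(sp$train$peptide, sp$val$peptide), 0L)
})

test_that("pseudosequence tables are validated", {
  ps <- toy_pseudo(c("DRB1*07:01", "DRB1*15:01"))
  got <- read_pseudosequences(write_tsv_tmp(ps))
  expect_equal(got$allele, ps$allele)
  expect_equal(nchar(got$short_seq), c(34L, 34L))
  bad <- ps; bad$short_seq[1] <- "TOOSHORT"
  expect_error(read_pseudosequences(write_tsv_tmp(bad)), "34")
})
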