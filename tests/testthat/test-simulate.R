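test_that("generator cardinality, determinism and schema", {
  cfg <- sim_config(n_pos = 100, n_neg = 100, seed = 5)
  sim <- simulate_dataset(cfg)
  expect_equal(nrow(sim$antigenic) + nrow(sim$immunogenic), 400L)
  expect_true(all(c("peptide", "allele", "label", "gene", "n_flank",
                    "c_flank", "domain", "source") %in% names(sim$antigenic)))
  expect_equal(unique(sim$antigenic$domain), "antigenic")
  expect_equal(unique(sim$immunogenic$domain), "immunogenic")
  expect_equal(unname(nchar(sim$pseudo$short_seq)), rep(34L, nrow(sim$pseudo)))
  expect_equal(unname(nchar(sim$pseudo$full_seq)), rep(269L, nrow(sim$pseudo)))
  expect_true(all(sim$expression$tpm >= 0))

  # byte-identical reruns, including written files
  sim2 <- simulate_dataset(cfg)
  expect_identical(sim$antigenic, sim2$antigenic)
  expect_identical(sim$immunogenic, sim2$immunogenic)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_peptide_table(sim$antigenic, p1)
  write_peptide_table(sim2$antigenic, p2)
  expect_identical(readLines(p1), readLines(p2))

  expect_error(sim_config(domain_shift_strength = 2), "\\[0, 1\\]")
  expect_error(sim_config(length_range = c(2L, 2L)), "core")
})

test_that("antigenic lengths are uniform over the configured range", {
  sim <- simulate_dataset(sim_config(n_alleles = 1, n_pos = 1500, n_neg = 1500,
                                     seed = 7))
  lens <- nchar(sim$antigenic$peptide)
  expect_setequal(sort(unique(lens)), 12:19)
  tab <- table(factor(lens, levels = 12:19))
  pchi <- stats::chisq.test(tab)$p.value
  expect_gt(pchi, 0.01)
})

test_that("core offsets follow the configured prior", {
  # fixed length so all records share the same admissible offset range
  cfg <- sim_config(n_alleles = 1, n_pos = 5000, n_neg = 0,
                    length_range = c(15L, 15L), label_noise = 0, seed = 9)
  sim <- simulate_dataset(cfg)
  offs <- sim$truth$antigenic$core_offset[sim$truth$antigenic$true_label == 1]
  prior <- sim$truth$offset_prior
  tab <- table(factor(offs, levels = 0:(length(prior) - 1L)))
  pchi <- stats::chisq.test(tab, p = prior)$p.value
  expect_gt(pchi, 0.01)
})

test_that("positives outscore negatives under the planted PWM", {
  sim <- simulate_dataset(sim_config(n_alleles = 1, n_pos = 200, n_neg = 200,
                                     label_noise = 0, seed = 11))
  pwm <- sim$truth$pwms[[1]][[1]]
  bgf <- table(factor(strsplit(paste(sim$antigenic$peptide, collapse = ""), "")[[1]],
                      levels = aa_alphabet()))
  bgf <- as.numeric(bgf) / sum(bgf)
  score_pep <- function(p) {
    chars <- strsplit(p, "")[[1]]
    offs <- seq_len(length(chars) - 8L)
    max(vapply(offs, function(o)
      sum(log(pwm[cbind(1:9, match(chars[o:(o + 8)], aa_alphabet()))] /
                bgf[match(chars[o:(o + 8)], aa_alphabet())])), numeric(1)))
  }
  sc <- vapply(sim$antigenic$peptide, score_pep, numeric(1))
  expect_gt(mean(sc[sim$antigenic$label == 1]), mean(sc[sim$antigenic$label == 0]))
})

test_that("hit flanks carry the proline/alanine cleavage signature", {
  sim <- simulate_dataset(sim_config(n_alleles = 1, n_pos = 400, n_neg = 400,
                                     cleavage_enrichment = 0.5, label_noise = 0,
                                     seed = 13))
  near_terminus_pa <- function(records) {
    mean(c(substr(records$n_flank, 2, 3),
           substr(records$c_flank, 1, 2)) |>
           strsplit("") |> unlist() %in% c("P", "A"))
  }
  hits <- dplyr::filter(sim$antigenic, label == 1)
  negs <- dplyr::filter(sim$antigenic, label == 0)
  expect_gt(near_terminus_pa(hits), near_terminus_pa(negs) + 0.1)
})

test_that("zero domain shift makes the immunogenic rules match the
           antigenic ones", {
  cfg0 <- sim_config(n_alleles = 1, n_pos = 600, n_neg = 0, label_noise = 0,
                     domain_shift_strength = 0, seed = 15)
  sim0 <- simulate_dataset(cfg0)
  arom_at5 <- function(records, truth) {
    pos <- truth$true_label == 1
    ext <- extend_peptides(records[pos, ])
    core5 <- substr(ext, truth$core_offset[pos] + 5L, truth$core_offset[pos] + 5L)
    mean(core5 %in% c("F", "W", "Y"))
  }
  a0 <- arom_at5(sim0$antigenic, sim0$truth$antigenic)
  i0 <- arom_at5(sim0$immunogenic, sim0$truth$immunogenic)
  expect_lt(abs(a0 - i0), 0.08)
  # and the composition laws agree
  hyd <- function(records) {
    mean(strsplit(paste(records$peptide, collapse = ""), "")[[1]] %in%
           c("I", "L", "M", "V"))
  }
  expect_lt(abs(hyd(sim0$antigenic) - hyd(sim0$immunogenic)), 0.03)

  # at full shift the aromatic stretch dominates the immunogenic positives,
  # the background turns hydrophobic, and negatives carry planted cores
  cfg1 <- sim_config(n_alleles = 1, n_pos = 600, n_neg = 200, label_noise = 0,
                     domain_shift_strength = 1, seed = 15)
  sim1 <- simulate_dataset(cfg1)
  expect_gt(arom_at5(sim1$immunogenic, sim1$truth$immunogenic), 0.95)
  expect_gt(hyd(sim1$immunogenic), hyd(sim1$antigenic) + 0.1)
  neg_cores <- sim1$truth$immunogenic$core_offset[sim1$truth$immunogenic$true_label == 0]
  expect_gt(mean(!is.na(neg_cores)), 0.95)  # presented-but-non-immunogenic
})

test_that("the toy proteome is clean and reproducible", {
  p1 <- simulate_proteome(n_proteins = 5, seed = 3)
  p2 <- simulate_proteome(n_proteins = 5, seed = 3)
  expect_identical(p1, p2)
  expect_false(any(grepl("[^ACDEFGHIKLMNPQRSTVWY]", p1)))
  expect_true(all(nchar(p1) >= 60))
})
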