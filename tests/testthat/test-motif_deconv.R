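# The EM deconvolution is checked against closed forms (K = 0), exhaustive
# posterior enumeration (K = 1, few peptides) and planted-PWM recovery.

test_that("extend_peptides adds 3-residue flanks with X padding", {
  recs <- make_records("ACDEFGHIKLMNPQW", n_flanks = "WYV", c_flanks = "TSR")
  expect_equal(extend_peptides(recs), "WYVACDEFGHIKLMNPQWTSR")
  expect_equal(nchar(extend_peptides(recs)), 21L)
  # no context: X padding
  bare <- make_records("ACDEFGHIKLMNPQW")
  expect_equal(extend_peptides(bare), "XXXACDEFGHIKLMNPQWXXX")
  # short flank: left-padded (N side) to 3
  short <- make_records("ACDEFGHIKLMNPQW", n_flanks = "WY", c_flanks = "T")
  expect_equal(extend_peptides(short), "XWYACDEFGHIKLMNPQWTXX")
  # proteome lookup fills flanks when record fields are empty
  prot <- c(p1 = "MMMMACDEFGHIKLMNPQWSSSS")
  expect_equal(extend_peptides(bare, prot), "MMMACDEFGHIKLMNPQWSSS")
})

test_that("K = 0 gives the closed-form background log-likelihood", {
  seqs <- c("ACDEFGHIKLMN", "PQRSTVWYACDEF", "GGGGGGGGGGGG")
  m <- fit_motifs(seqs, K = 0)
  bg <- m$background
  manual <- sum(vapply(seqs, function(s)
    sum(log(bg[strsplit(s, "")[[1]]])), numeric(1)))
  expect_equal(m$loglik, manual, tolerance = 1e-12)
  expect_equal(m$K, 0L)
  expect_equal(m$mixture_weights, 1)
})

test_that("EM objective is monotone non-decreasing on fuzz inputs", {
  for (s in 1:6) {
    withr::local_seed(s)
    n <- sample(15:40, 1)
    lens <- sample(9:20, n, replace = TRUE)
    seqs <- vapply(lens, function(L)
      paste(sample(aa_alphabet(), L, TRUE), collapse = ""), character(1))
    m <- fit_motifs(seqs, K = sample(1:3, 1), restarts = 2, seed = s)
    expect_true(all(diff(m$trace) >= -1e-8))
  }
})

test_that("model components are normalized", {
  seqs <- random_peptides(30, seed = 17)
  m <- fit_motifs(seqs, K = 2, restarts = 2, seed = 17)
  for (k in 1:2) expect_equal(rowSums(m$pwms[[k]]), rep(1, 9),
                              ignore_attr = TRUE)
  expect_equal(rowSums(m$offset_priors), rep(1, 2))
  expect_equal(sum(m$mixture_weights), 1)
})

test_that("fit is deterministic given the seed", {
  seqs <- random_peptides(25, seed = 3)
  m1 <- fit_motifs(seqs, K = 1, restarts = 2, seed = 9)
  m2 <- fit_motifs(seqs, K = 1, restarts = 2, seed = 9)
  expect_equal(m1$pwms, m2$pwms)
  expect_equal(m1$loglik, m2$loglik)
})

test_that("empty input and short sequences are errors", {
  expect_error(fit_motifs(character(0), K = 1), "no sequences")
  expect_error(fit_motifs(c("ACDEFGHIK", "SHORT"), K = 1), ">= 9")
  expect_warning(fit_motifs(random_peptides(3, seed = 1), K = 5,
                            restarts = 1, seed = 1), "exceeds")
})

test_that("EM responsibilities match exhaustive posterior enumeration", {
  # <= 6 peptides, K = 1: the (motif, offset) posterior is enumerable
  seqs <- random_peptides(5, c(11, 14), seed = 23)
  m <- fit_motifs(seqs, K = 1, restarts = 1, seed = 23)
  asn <- assign_cores(m, seqs)
  resp <- attr(asn, "responsibilities")
  w <- m$mixture_weights; bg <- m$background; pwm <- m$pwms[[1]]
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[i], "")[[1]]
    n_off <- length(chars) - 9L + 1L
    # brute force: full joint likelihood of every offset and the background
    joint <- numeric(n_off + 1L)
    for (o in seq_len(n_off)) {
      p <- m$offset_priors[1, o] * w[1]
      for (j in seq_along(chars)) {
        aa <- chars[j]
        p <- p * if (j >= o && j < o + 9) pwm[j - o + 1, aa] else bg[aa]
      }
      joint[o] <- p
    }
    joint[n_off + 1L] <- w[2] * prod(bg[chars])
    post <- joint / sum(joint)
    expect_equal(as.numeric(resp[[i]]$motif), post[seq_len(n_off)],
                 tolerance = 1e-9)
    expect_equal(resp[[i]]$bg, post[n_off + 1L], tolerance = 1e-9)
    # responsibilities sum to 1 per peptide
    expect_equal(sum(resp[[i]]$motif) + resp[[i]]$bg, 1, tolerance = 1e-12)
  }
})

test_that("total responsibility mass is conserved", {
  seqs <- random_peptides(20, seed = 31)
  m <- fit_motifs(seqs, K = 2, restarts = 1, seed = 31)
  resp <- attr(assign_cores(m, seqs), "responsibilities")
  total <- sum(vapply(resp, function(r) sum(r$motif) + r$bg, numeric(1)))
  expect_equal(total, 20, tolerance = 1e-9)
})

test_that("a planted consensus embedded at a known offset is recovered", {
  sim <- simulate_dataset(sim_config(n_alleles = 1, n_pos = 400, n_neg = 0,
                                     label_noise = 0, seed = 41))
  ext <- extend_peptides(sim$antigenic)
  m <- fit_motifs(ext, K = 1, restarts = 10, seed = 41)
  planted <- sim$truth$pwms[[1]][[1]]
  cons_p <- strsplit(pwm_consensus(planted), "")[[1]]
  cons_r <- strsplit(pwm_consensus(m$pwms[[1]]), "")[[1]]
  expect_gte(sum(cons_p == cons_r), 8L)

  # a peptide that is exactly the consensus embedded at offset 2 is
  # assigned to that offset
  probe <- paste0("LV", pwm_consensus(m$pwms[[1]]), "KT")
  asn <- assign_cores(m, probe)
  expect_equal(asn$motif, 1L)
  expect_equal(asn$offset, 2L)

  # background-dominated random sequence goes to the background class
  withr::local_seed(5)
  noise <- paste(sample(aa_alphabet(), 13, TRUE), collapse = "")
  m_sharp <- m
  asn2 <- assign_cores(m_sharp, noise)
  expect_true(asn2$motif == 0L || asn2$responsibility < 0.99)
})

test_that("offset feature normalizes the prior by the motif's modal offset", {
  seqs <- random_peptides(15, seed = 51)
  m <- fit_motifs(seqs, K = 1, restarts = 1, seed = 51)
  asn <- assign_cores(m, seqs)
  feat <- offset_feature(asn, m)
  expect_true(all(feat >= 0 & feat <= 1))
  # force the modal offset: feature 1
  modal <- which.max(m$offset_priors[1, ]) - 1L
  asn_modal <- asn[1, ]
  asn_modal$motif <- 1L; asn_modal$offset <- modal
  expect_equal(offset_feature(asn_modal, m), 1)
  # uniform prior: 1 everywhere
  m_unif <- m
  m_unif$offset_priors[1, ] <- 1 / ncol(m$offset_priors)
  expect_equal(offset_feature(asn[asn$motif == 1L, ], m_unif),
               rep(1, sum(asn$motif == 1L)))
  # background assignments get the neutral value
  asn_bg <- asn[1, ]; asn_bg$motif <- 0L
  expect_equal(offset_feature(asn_bg, m), 0.5)
})

test_that("export_logos writes one logo and PWM table per motif", {
  seqs <- random_peptides(15, seed = 61)
  m <- fit_motifs(seqs, K = 2, restarts = 1, seed = 61)
  dir <- withr::local_tempdir()
  files <- export_logos(m, dir)
  expect_length(files, 4L)
  expect_true(all(file.exists(files)))
  pwm_back <- readr::read_tsv(files[1], show_col_types = FALSE)
  expect_equal(as.matrix(pwm_back[, -1]), unclass(m$pwms[[1]]),
               ignore_attr = TRUE, tolerance = 1e-9)
  # K = 0: background composition chart only
  m0 <- fit_motifs(seqs, K = 0)
  f0 <- export_logos(m0, dir)
  expect_true(file.exists(f0))
})

test_that("tidy and glance summarize the mixture", {
  seqs <- random_peptides(15, seed = 71)
  m <- fit_motifs(seqs, K = 1, restarts = 1, seed = 71)
  td <- tidy(m)
  expect_equal(nrow(td), 9L * 20L)
  expect_equal(sum(td$prob), 9, tolerance = 1e-9)
  gl <- glance(m)
  expect_equal(gl$K, 1L)
  expect_true(gl$converged)
})
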