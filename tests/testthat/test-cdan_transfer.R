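ns <- asNamespace("mhc2epi")

test_that("multilinear map computes the flattened outer product", {
  expect_equal(multilinear_map(c(1, 0), c(0.5, 0.5)), c(0.5, 0.5, 0, 0))
  expect_equal(multilinear_map(c(0, 0, 0), c(0.3, 0.7)), rep(0, 6))
  expect_error(multilinear_map(c(1, 2), c(0.9, 0.3)), "simplex")
  expect_error(multilinear_map(numeric(0), c(1, 0)), "non-empty")
})

test_that("oversized outer products use the seed-fixed randomized projection", {
  f <- rnorm(600); g <- c(0.25, 0.25, 0.5)
  h1 <- multilinear_map(f, g, max_dim = 1024L, seed = 7L)
  h2 <- multilinear_map(f, g, max_dim = 1024L, seed = 7L)
  expect_length(h1, 1024L)
  expect_equal(h1, h2)
  h3 <- multilinear_map(f, g, max_dim = 1024L, seed = 8L)
  expect_false(isTRUE(all.equal(h1, h3)))
})

test_that("randomized projection gradients match finite differences", {
  withr::local_seed(10)
  f <- rnorm(5); g <- c(0.4, 0.6)
  maps <- ns$mm_maps(5L, 2L, 4L, seed = 3L)   # forces the random branch
  wf <- rnorm(4)
  fwd <- ns$mm_fwd(f, g, maps)
  bwd <- ns$mm_bwd(wf, fwd$cache)
  gf <- num_grad(function(v) sum(ns$mm_fwd(v, g, maps)$h * wf), f)
  gg <- num_grad(function(v) sum(ns$mm_fwd(f, v, maps)$h * wf), g)
  expect_equal(bwd$df, gf, tolerance = 1e-6)
  expect_equal(bwd$dg, gg, tolerance = 1e-6)
  # exact branch too
  maps2 <- ns$mm_maps(5L, 2L, 1024L, seed = 3L)
  fwd2 <- ns$mm_fwd(f, g, maps2)
  wf2 <- rnorm(10)
  bwd2 <- ns$mm_bwd(wf2, fwd2$cache)
  gf2 <- num_grad(function(v) sum(ns$mm_fwd(v, g, maps2)$h * wf2), f)
  expect_equal(bwd2$df, gf2, tolerance = 1e-6)
})

im_fixture <- function(seed = 17, n = 40) {
  sim <- simulate_dataset(sim_config(n_alleles = 1, n_pos = n, n_neg = n,
                                     domain_shift_strength = 1, seed = seed))
  el <- build_el_model(tiny_el_config(seed = seed, epochs = 1))
  list(sim = sim, el = el)
}

test_that("cdan_losses has the right closed forms", {
  fx <- im_fixture()
  im <- init_im_model(fx$el, cdan_config(seed = 2))
  # discriminator forced to output 0.5: zero its weights
  for (nm in grep("^D_", names(im$params), value = TRUE))
    im$params[[nm]] <- im$params[[nm]] * 0
  ant <- fx$sim$antigenic[1:6, ]
  imm <- fx$sim$immunogenic[1:6, ]
  ls <- cdan_losses(im, ant, imm, fx$sim$pseudo)
  expect_equal(ls$L_adv, log(2), tolerance = 1e-12)
  expect_true(ls$L_a > 0 && ls$L_i > 0)
  expect_error(cdan_losses(im, ant[0, ], imm, fx$sim$pseudo), "both domains")
})

test_that("gradient reversal equals -omega times the adversarial gradient", {
  # finite-difference check on a batch of one record per domain
  fx <- im_fixture(seed = 23, n = 4)
  cdan <- cdan_config(omega = 0.7, seed = 5, warmup_frac = 0)
  im <- init_im_model(fx$el, cdan)
  # keep discriminator logits in the smooth range for the FD quotient
  for (nm in grep("^D_", names(im$params), value = TRUE))
    im$params[[nm]] <- im$params[[nm]] * 0.1
  cfg <- im$cfg
  ant <- fx$sim$antigenic[1, ]; ant$label <- NA_integer_   # no supervised term
  imm <- fx$sim$immunogenic[1, ]; imm$label <- NA_integer_
  psa <- ns$pseudo_lookup(ant, fx$sim$pseudo)
  psi <- ns$pseudo_lookup(imm, fx$sim$pseudo)
  ea <- ns$el_encode_pair(ant$peptide, psa, cfg)
  ei <- ns$el_encode_pair(imm$peptide, psi, cfg)
  # full-path check: let the adversarial gradient flow through g as well
  cd_off <- cdan_config(omega = 0.7, seed = 5, warmup_frac = 0,
                        target_supervised = FALSE, detach_conditioning = FALSE)
  im$cdan <- cd_off
  step <- ns$cdan_step(im$params, cfg, cd_off, im$maps, list(ea), NA_integer_,
                       list(ei), NA_integer_, omega_t = 0.7)

  # L_adv as a function of a feature-extractor parameter, by recomputation
  L_adv_of <- function(params) {
    fa <- ns$cdan_forward_one(params, cfg, ea$Xp, ea$Xa, im$maps)
    fi <- ns$cdan_forward_one(params, cfg, ei$Xp, ei$Xa, im$maps)
    (ns$bce_logits(matrix(fa$zD, 1), 0)$loss +
       ns$bce_logits(matrix(fi$zD, 1), 1)$loss) / 2
  }
  for (nm in c("ban_U", "G_W1")) {
    idx <- c(1L, 5L)
    for (i in idx) {
      eps <- 1e-5
      pp <- im$params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- im$params; pm[[nm]][i] <- pm[[nm]][i] - eps
      dnum <- (L_adv_of(pp) - L_adv_of(pm)) / (2 * eps)
      # cdan_step sums per-sample adversarial gradients (2 x the mean loss
      # derivative) and reverses them with weight omega
      expect_equal(step$g_fg[[nm]][i], -0.7 * 2 * dnum, tolerance = 1e-4)
    }
  }
  # the discriminator itself descends the (unreversed) domain loss
  D_of <- function(params) {
    pp <- im$params
    pp[grep("^D_", names(params), value = TRUE)] <-
      params[grep("^D_", names(params), value = TRUE)]
    L_adv_of(pp)
  }
  ppD <- im$params; ppD$D_W1[1] <- ppD$D_W1[1] + 1e-5
  pmD <- im$params; pmD$D_W1[1] <- pmD$D_W1[1] - 1e-5
  dnumD <- (D_of(ppD) - D_of(pmD)) / (2e-5)
  # g_d averages per-sample gradients over the whole batch: d L_adv / d theta
  expect_equal(step$g_d$D_W1[1], dnumD, tolerance = 1e-4)
})

test_that("omega = 0 with no target supervision gives a purely supervised
           source gradient", {
  fx <- im_fixture(seed = 29, n = 4)
  cd <- cdan_config(omega = 0, seed = 5, target_supervised = FALSE)
  im <- init_im_model(fx$el, cd)
  cfg <- im$cfg
  ant <- fx$sim$antigenic[1, ]; ant$label <- NA_integer_
  imm <- fx$sim$immunogenic[1, ]; imm$label <- NA_integer_
  ea <- ns$el_encode_pair(ant$peptide, ns$pseudo_lookup(ant, fx$sim$pseudo), cfg)
  ei <- ns$el_encode_pair(imm$peptide, ns$pseudo_lookup(imm, fx$sim$pseudo), cfg)
  step <- ns$cdan_step(im$params, cfg, cd, im$maps, list(ea), NA_integer_,
                       list(ei), NA_integer_, omega_t = 0)
  # with no labels and omega 0 every F/G gradient vanishes
  expect_true(all(vapply(step$g_fg, function(g) max(abs(g)), numeric(1)) < 1e-12))
})

test_that("immunogenicity predictions are probabilities and flag unknown
           alleles", {
  fx <- im_fixture(seed = 31, n = 10)
  cd <- cdan_config(epochs = 2, seed = 3)
  m <- train_im(fx$el, fx$sim$antigenic, fx$sim$immunogenic, fx$sim$pseudo, cd)
  recs <- fx$sim$immunogenic[1:5, ]
  pr <- predict_im(m, recs, fx$sim$pseudo)
  expect_true(all(pr$s_im >= 0 & pr$s_im <= 1))
  expect_true(all(pr$scored))
  pr2 <- predict_im(m, recs, fx$sim$pseudo)
  expect_equal(pr$s_im, pr2$s_im)

  unk <- make_records("ACDEFGHIKLMN", alleles = "DRB1*88:88")
  pu <- predict_im(m, unk, fx$sim$pseudo)
  expect_false(pu$scored)
  expect_true(is.na(pu$s_im))

  expect_error(train_im(fx$el, fx$sim$antigenic[0, ], fx$sim$immunogenic,
                        fx$sim$pseudo, cd), "both domains")
})
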