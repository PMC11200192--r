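# Conditional domain-adversarial transfer to the immunogenicity domain.
#
# The presentation model's feature extractor F (encoders + bilinear
# attention) is transferred and adapted: an immunogenic decoder G (two dense
# layers + softmax) classifies, while a domain discriminator D (three dense
# layers) tries to tell antigenic from immunogenic samples from the
# multilinear map h = f (x) g of features and classifier predictions. F and
# G minimize their classification losses while *confusing* D, implemented by
# gradient reversal with weight omega; D minimizes the domain loss. With
# omega = 0 the procedure reduces to plain supervised fine-tuning.

#' Configuration of the domain-adversarial transfer stage
#'
#' @param omega Adversarial weight (> 0 for adversarial training; 0 gives
#'   plain fine-tuning). Default 1, reached after a linear warm-up over the
#'   first `warmup_frac` of steps.
#' @param warmup_frac Fraction of steps over which omega ramps up
#'   (default 0.1).
#' @param lr AdamW learning rate for F and G (default 1e-3).
#' @param lr_d AdamW learning rate for the discriminator (default 1e-3).
#' @param batch_size Records drawn per domain per step (default 32).
#' @param epochs Training epochs (default 30).
#' @param max_h_dim Maximum width of the multilinear map before the
#'   randomized projection is used (default 1024).
#' @param target_supervised Add the supervised loss of G on the labelled
#'   immunogenic records (default `TRUE`).
#' @param detach_conditioning Treat the classifier predictions `g` as
#'   constant inside the conditioning map `h` (default `TRUE`, as in
#'   standard conditional adversarial practice): the reversed adversarial
#'   gradient then reaches the feature extractor only, which keeps the
#'   decoder from being corrupted by the alignment pressure.
#' @param balance_adversarial Rescale the reversed adversarial gradient,
#'   when necessary, so its per-batch norm never exceeds the supervised
#'   gradient norm (default `TRUE`). Prevents the alignment term from
#'   collapsing the classifier on small batches while leaving it free to
#'   act at full strength otherwise.
#' @param seed Integer seed.
#' @return List of class `cdan_config`.
#' @export
cdan_config <- function(omega = 1, warmup_frac = 0.1, lr = 1e-3, lr_d = 1e-3,
                        batch_size = 32L, epochs = 30L, max_h_dim = 1024L,
                        target_supervised = TRUE, detach_conditioning = TRUE,
                        balance_adversarial = TRUE, seed = 1L) {
  if (omega < 0) stopf("omega must be >= 0")
  structure(list(omega = omega, warmup_frac = warmup_frac, lr = lr, lr_d = lr_d,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 max_h_dim = as.integer(max_h_dim),
                 target_supervised = isTRUE(target_supervised),
                 detach_conditioning = isTRUE(detach_conditioning),
                 balance_adversarial = isTRUE(balance_adversarial),
                 seed = as.integer(seed)),
            class = "cdan_config")
}

#' Multilinear map of features and classifier predictions
#'
#' Captures the multiplicative interaction between a feature vector `f` and
#' a class-probability vector `g`: the flattened outer product `f (x) g`
#' when its dimension is at most `max_dim`, otherwise a seed-fixed
#' randomized multilinear projection of width `max_dim`,
#' `h = (R_f f) * (R_g g) / sqrt(max_dim)`.
#'
#' @param f Numeric feature vector.
#' @param g Class-probability vector (must lie on the simplex within
#'   `tol`).
#' @param max_dim Maximum output width (default 1024).
#' @param seed Seed for the randomized projection matrices.
#' @param tol Simplex tolerance for `g` (default 1e-6).
#' @return Numeric vector `h`; the projection case carries the matrices as
#'   attributes for reuse.
#' @export
multilinear_map <- function(f, g, max_dim = 1024L, seed = 1L, tol = 1e-6) {
  if (length(f) == 0L || length(g) == 0L) stopf("f and g must be non-empty")
  if (abs(sum(g) - 1) > tol || any(g < -tol))
    stopf("g is off the probability simplex (sum = %.6f)", sum(g))
  mm <- mm_fwd(f, g, mm_maps(length(f), length(g), max_dim, seed))
  mm$h
}

mm_maps <- function(nf, ng, max_dim, seed) {
  if (nf * ng <= max_dim) return(list(kind = "outer"))
  with_seed(seed, list(
    kind = "random",
    Rf = matrix(stats::rnorm(max_dim * nf), max_dim, nf),
    Rg = matrix(stats::rnorm(max_dim * ng), max_dim, ng),
    scale = 1 / sqrt(max_dim)))
}
mm_fwd <- function(f, g, maps) {
  if (maps$kind == "outer") {
    # row-major flatten: h = (f1*g, f2*g, ...)
    list(h = as.numeric(t(f %o% g)), cache = list(f = f, g = g, maps = maps))
  } else {
    rf <- drop(maps$Rf %*% f); rg <- drop(maps$Rg %*% g)
    list(h = rf * rg * maps$scale,
         cache = list(f = f, g = g, rf = rf, rg = rg, maps = maps))
  }
}
mm_bwd <- function(dh, cache) {
  maps <- cache$maps
  if (maps$kind == "outer") {
    dH <- matrix(dh, length(cache$g), length(cache$f))   # columns follow f
    list(df = drop(crossprod(dH, cache$g)), dg = drop(dH %*% cache$f))
  } else {
    list(df = drop(crossprod(maps$Rf, dh * cache$rg)) * maps$scale,
         dg = drop(crossprod(maps$Rg, dh * cache$rf)) * maps$scale)
  }
}

#' Initialize an immunogenicity model from a presentation model
#'
#' Transfers the feature extractor and attaches freshly initialized decoder
#' and discriminator parameters, without training. Useful for inspecting
#' losses before adaptation (see [cdan_losses()]).
#'
#' @param el_model Trained `el_model`.
#' @param cdan A [cdan_config()].
#' @return Untrained object of class `cdan_model`.
#' @export
init_im_model <- function(el_model, cdan = cdan_config()) {
  structure(list(params = im_init_params(el_model, cdan), cfg = el_model$cfg,
                 cdan = cdan,
                 maps = mm_maps(el_model$cfg$d_ban, 2L, cdan$max_h_dim, cdan$seed),
                 history = NULL, el_seed = el_model$cfg$seed),
            class = "cdan_model")
}

im_init_params <- function(el_model, cdan_cfg) {
  feat_names <- grep("^(pep|hla|ban)_", names(el_model$params), value = TRUE)
  d <- el_model$cfg$d_ban
  h_dim <- min(d * 2L, cdan_cfg$max_h_dim)
  with_seed(cdan_cfg$seed, {
    c(el_model$params[feat_names],
      mlp_init(c(d, 32L, 2L), "G"),
      mlp_init(c(h_dim, 64L, 32L, 1L), "D"))
  })
}

# Batched forward through F, G, the multilinear map and D for a record
# tibble; chunked to bound memory.
im_forward_batch <- function(params, cfg, maps, records, pseudo, chunk = 64L) {
  ps <- pseudo_lookup(records, pseudo)
  enc <- lapply(seq_len(nrow(records)), function(i)
    el_encode_pair(records$peptide[i], ps[i], cfg))
  n <- length(enc)
  gprob <- matrix(0, n, 2L)
  zD <- numeric(n)
  H <- NULL
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    ft <- el_features_b_fwd(enc, idx, params, cfg)
    gp <- softmax_rows(mlp_fwd(ft$f, params, "G", 2L)$out)
    mm <- mm_b_fwd(ft$f, gp, maps)
    if (is.null(H)) H <- matrix(0, n, ncol(mm$H))
    gprob[idx, ] <- gp
    H[idx, ] <- mm$H
    zD[idx] <- drop(mlp_fwd(mm$H, params, "D", 3L)$out)
  }
  list(gprob = gprob, H = H, zD = zD)
}

# Forward pass for one record through F, G, the multilinear map and D.
cdan_forward_one <- function(params, cfg, Xp, Xa, maps) {
  ft <- el_features_fwd(Xp, Xa, params, cfg)
  gf <- mlp_fwd(matrix(ft$f, 1L), params, "G", 2L)
  g <- drop(softmax_rows(gf$out))
  mm <- mm_fwd(ft$f, g, maps)
  df_ <- mlp_fwd(matrix(mm$h, 1L), params, "D", 3L)
  list(f = ft$f, zG = gf$out, g = g, h = mm$h, zD = drop(df_$out),
       cache = list(ft = ft$cache, gf = gf$cache, mm = mm$cache, df = df_$cache))
}

#' Per-batch CDAN losses
#'
#' Computes the three terms of the adversarial objective on a domain batch:
#' `L_a`, the cross-entropy of the decoder G on labelled antigenic records;
#' `L_i`, the cross-entropy of G on labelled immunogenic records; and
#' `L_adv`, the domain cross-entropy of the discriminator D on the
#' multilinear map h. Both domains must be represented.
#'
#' @param im_model A `cdan_model` (see [train_im()]), or the initialized
#'   state before training.
#' @param antigenic,immunogenic Record tibbles with `peptide`, `allele`,
#'   `label`.
#' @param pseudo Pseudosequence table.
#' @return Named list `L_a`, `L_i`, `L_adv` (means per record).
#' @export
cdan_losses <- function(im_model, antigenic, immunogenic, pseudo) {
  if (nrow(antigenic) == 0L || nrow(immunogenic) == 0L)
    stopf("both domains must be represented in a CDAN batch")
  params <- im_model$params; cfg <- im_model$cfg
  maps <- im_model$maps
  eval_domain <- function(records, dom_label) {
    fw <- im_forward_batch(params, cfg, maps, records, pseudo)
    lab <- records$label
    ce <- NA_real_
    if (any(!is.na(lab))) {
      p_true <- fw$gprob[cbind(seq_along(lab), ifelse(is.na(lab), 1L, lab + 1L))]
      ce <- mean(-log(pmax(p_true[!is.na(lab)], 1e-12)))
    }
    adv <- bce_logits(matrix(fw$zD), rep(dom_label, nrow(records)))$loss
    list(ce = ce, adv = adv)
  }
  a <- eval_domain(antigenic, 0)
  i <- eval_domain(immunogenic, 1)
  list(L_a = a$ce, L_i = i$ce, L_adv = (a$adv + i$adv) / 2)
}

#' Train the immunogenicity model by conditional domain-adversarial transfer
#'
#' Starts from a trained presentation model, transfers its feature extractor
#' and optimizes the minimax objective: F and G minimize the supervised
#' losses while fooling the domain discriminator (gradient reversal with
#' weight omega); D minimizes the domain cross-entropy on the multilinear
#' map of features and predictions. Deterministic given the seed. Training
#' aborts with diagnostics if the loss diverges to NaN.
#'
#' @param el_model Trained `el_model` supplying the feature extractor.
#' @param antigenic Labelled presentation-domain records.
#' @param immunogenic Labelled immunogenicity-domain records.
#' @param pseudo Pseudosequence table.
#' @param cdan A [cdan_config()].
#' @return Object of class `cdan_model` with the adapted parameters, the
#'   config and a per-epoch loss history.
#' @export
train_im <- function(el_model, antigenic, immunogenic, pseudo,
                     cdan = cdan_config()) {
  if (nrow(antigenic) == 0L || nrow(immunogenic) == 0L)
    stopf("both domains must be available for transfer")
  cfg <- el_model$cfg
  params <- im_init_params(el_model, cdan)
  maps <- mm_maps(cfg$d_ban, 2L, cdan$max_h_dim, cdan$seed)

  # canonical ordering: results depend on the seed, never on record order
  antigenic <- dplyr::arrange(antigenic, .data$peptide, .data$allele)
  immunogenic <- dplyr::arrange(immunogenic, .data$peptide, .data$allele)
  ps_a <- pseudo_lookup(antigenic, pseudo)
  ps_i <- pseudo_lookup(immunogenic, pseudo)
  enc_a <- lapply(seq_len(nrow(antigenic)), function(i)
    el_encode_pair(antigenic$peptide[i], ps_a[i], cfg))
  enc_i <- lapply(seq_len(nrow(immunogenic)), function(i)
    el_encode_pair(immunogenic$peptide[i], ps_i[i], cfg))
  lab_a <- antigenic$label; lab_i <- immunogenic$label

  fg_names <- grep("^(pep|hla|ban|G)_|^ban_", names(params), value = TRUE)
  d_names <- grep("^D_", names(params), value = TRUE)

  with_seed(cdan$seed, {
    st_fg <- adamw_init(params[fg_names])
    st_d <- adamw_init(params[d_names])
    n_steps_per_ep <- max(1L, ceiling(max(length(enc_a), length(enc_i)) / cdan$batch_size))
    total_steps <- cdan$epochs * n_steps_per_ep
    step <- 0L
    hist <- vector("list", cdan$epochs)
    for (ep in seq_len(cdan$epochs)) {
      ep_la <- ep_li <- ep_adv <- 0
      for (s in seq_len(n_steps_per_ep)) {
        step <- step + 1L
        wu <- if (cdan$warmup_frac > 0) min(1, step / (cdan$warmup_frac * total_steps)) else 1
        omega_t <- cdan$omega * wu
        ia <- sample.int(length(enc_a), min(cdan$batch_size, length(enc_a)))
        ii <- sample.int(length(enc_i), min(cdan$batch_size, length(enc_i)))
        res <- cdan_step(params, cfg, cdan, maps, enc_a[ia], lab_a[ia],
                         enc_i[ii], lab_i[ii], omega_t)
        if (!is.finite(res$L_a + res$L_adv))
          stopf("CDAN training diverged at epoch %d step %d (L_a=%g, L_adv=%g)",
                ep, s, res$L_a, res$L_adv)
        upd <- adamw_step(params[fg_names], res$g_fg, st_fg, cdan$lr)
        params[fg_names] <- upd$params; st_fg <- upd$state
        upd <- adamw_step(params[d_names], res$g_d, st_d, cdan$lr_d)
        params[d_names] <- upd$params; st_d <- upd$state
        ep_la <- ep_la + res$L_a; ep_li <- ep_li + res$L_i; ep_adv <- ep_adv + res$L_adv
      }
      hist[[ep]] <- tibble::tibble(epoch = ep, L_a = ep_la / n_steps_per_ep,
                                   L_i = ep_li / n_steps_per_ep,
                                   L_adv = ep_adv / n_steps_per_ep)
    }
    structure(list(params = params, cfg = cfg, cdan = cdan, maps = maps,
                   history = dplyr::bind_rows(hist),
                   el_seed = el_model$cfg$seed),
              class = "cdan_model")
  })
}

# One adversarial step over a combined batch (batched path). The supervised
# and (reversed) adversarial contributions to the feature extractor are
# accumulated separately; the adversarial part is rescaled, when necessary,
# so its batch norm never exceeds the supervised batch norm — alignment then
# proceeds as fast as omega allows without ever overwhelming the
# classification signal (which is what collapses the decoder on small
# batches). Per-record weights reproduce per-domain means: classification
# terms weigh 1/n_domain, the domain loss weighs 1/(n_a + n_i).
cdan_step <- function(params, cfg, cdan, maps, enc_a, lab_a, enc_i, lab_i, omega_t) {
  n_a <- length(enc_a); n_i <- length(enc_i); B <- n_a + n_i
  enc <- c(enc_a, enc_i)
  dom <- c(rep(0, n_a), rep(1, n_i))
  labs <- c(lab_a, lab_i)
  sup_mask <- c(rep(TRUE, n_a), rep(cdan$target_supervised, n_i)) & !is.na(labs)

  ft <- el_features_b_fwd(enc, seq_len(B), params, cfg)
  gf <- mlp_fwd(ft$f, params, "G", 2L)
  gprob <- softmax_rows(gf$out)
  mm <- mm_b_fwd(ft$f, gprob, maps)
  dfw <- mlp_fwd(mm$H, params, "D", 3L)
  bl <- bce_logits(dfw$out, dom)                      # mean over B
  db <- mlp_bwd(bl$dlogits, params, "D", 3L, dfw$cache)
  g_d <- db$grads

  # adversarial path, re-weighted to per-domain means
  w_dom <- ifelse(dom == 0, B / n_a, B / n_i)
  mmb <- mm_b_bwd(db$dX * w_dom, mm$cache)
  dF_adv <- -omega_t * mmb$dF
  ga_extra <- NULL
  if (!cdan$detach_conditioning) {
    dzG_adv <- -omega_t * softmax_rows_bwd(mmb$dG, gprob)
    gba <- mlp_bwd(dzG_adv, params, "G", 2L, gf$cache)
    dF_adv <- dF_adv + gba$dX
    ga_extra <- gba$grads
  }
  g_adv <- el_features_b_bwd(dF_adv, params, cfg, ft$cache)
  if (!is.null(ga_extra)) g_adv <- acc_grads(g_adv, ga_extra)

  # supervised path: per-domain-mean cross-entropy on labelled records
  L_a <- L_i <- 0
  dzG_sup <- gprob
  dzG_sup[cbind(seq_len(B), ifelse(is.na(labs), 1L, labs + 1L))] <-
    dzG_sup[cbind(seq_len(B), ifelse(is.na(labs), 1L, labs + 1L))] - 1
  w_sup <- ifelse(sup_mask, ifelse(dom == 0, 1 / n_a, 1 / n_i), 0)
  dzG_sup <- dzG_sup * w_sup
  ce <- -log(pmax(gprob[cbind(seq_len(B), ifelse(is.na(labs), 1L, labs + 1L))], 1e-12))
  L_a <- sum(ce[sup_mask & dom == 0]) / n_a
  if (any(sup_mask & dom == 1)) L_i <- sum(ce[sup_mask & dom == 1]) / n_i
  g_sup <- list()
  if (any(sup_mask)) {
    gbs <- mlp_bwd(dzG_sup, params, "G", 2L, gf$cache)
    g_sup <- acc_grads(gbs$grads,
                       el_features_b_bwd(gbs$dX, params, cfg, ft$cache))
  }

  if (isTRUE(cdan$balance_adversarial) && length(g_sup) > 0L && length(g_adv) > 0L) {
    nrm <- function(g) sqrt(sum(vapply(g, function(x) sum(x^2), numeric(1))))
    ns <- nrm(g_sup); na_ <- nrm(g_adv)
    if (na_ > ns && na_ > 0) g_adv <- scale_grads(g_adv, ns / na_)
  }
  list(g_fg = acc_grads(g_sup, g_adv), g_d = g_d,
       L_a = L_a, L_i = L_i, L_adv = bl$loss)
}

#' @export
print.cdan_model <- function(x, ...) {
  cat(sprintf("<cdan_model> omega = %g, %d epoch(s); final L_a %.4f, L_adv %.4f\n",
              x$cdan$omega, nrow(x$history),
              x$history$L_a[nrow(x$history)], x$history$L_adv[nrow(x$history)]))
  invisible(x)
}

#' Immunogenicity predictions
#'
#' Scores records with the adapted decoder: per-record immunogenicity
#' probability in [0, 1]. Records whose allele has no pseudosequence are
#' flagged (`scored = FALSE`, score `NA`) rather than failing the batch.
#'
#' @param model Trained `cdan_model`.
#' @param records Record tibble with `peptide`, `allele`.
#' @param pseudo Pseudosequence table.
#' @return `records` plus `s_im` (probability) and `scored` (logical).
#' @export
predict_im <- function(model, records, pseudo) {
  known <- records$allele %in% pseudo$allele
  s <- rep(NA_real_, nrow(records))
  if (any(known)) {
    sub <- records[known, , drop = FALSE]
    fw <- im_forward_batch(model$params, model$cfg, model$maps, sub, pseudo)
    s[known] <- fw$gprob[, 2L]
  }
  dplyr::mutate(records, s_im = s, scored = known)
}

#' Accuracy of the trained domain discriminator
#'
#' Classification accuracy of the model's own discriminator D over the
#' given records of both domains. After successful adversarial alignment
#' this should approach chance; trained without the adversarial coupling
#' (`omega = 0`) on genuinely shifted domains it stays high, because D
#' still minimizes the domain loss while F no longer fights it.
#'
#' @param model Trained `cdan_model`.
#' @param antigenic,immunogenic Record tibbles.
#' @param pseudo Pseudosequence table.
#' @return Accuracy in [0, 1].
#' @export
domain_discriminator_accuracy <- function(model, antigenic, immunogenic, pseudo) {
  za <- im_forward_batch(model$params, model$cfg, model$maps, antigenic, pseudo)$zD
  zi <- im_forward_batch(model$params, model$cfg, model$maps, immunogenic, pseudo)$zD
  mean(c(za < 0, zi > 0))
}

#' Domain separability of the learned features
#'
#' Trains a *fresh* probe discriminator on the frozen multilinear
#' representations of both domains and reports its classification accuracy.
#' High accuracy means the domains remain separable in feature space; after
#' successful adversarial alignment the probe should do little better than
#' chance.
#'
#' @param model `cdan_model` whose features are probed.
#' @param antigenic,immunogenic Record tibbles.
#' @param pseudo Pseudosequence table.
#' @param epochs Probe training epochs (default 200, full-batch).
#' @param seed Integer seed.
#' @return Probe accuracy in [0, 1].
#' @export
probe_domain_accuracy <- function(model, antigenic, immunogenic, pseudo,
                                  epochs = 200L, seed = 1L) {
  h_of <- function(records)
    im_forward_batch(model$params, model$cfg, model$maps, records, pseudo)$H
  H <- rbind(h_of(antigenic), h_of(immunogenic))
  y <- c(rep(0, nrow(antigenic)), rep(1, nrow(immunogenic)))
  with_seed(seed, {
    p <- mlp_init(c(ncol(H), 64L, 32L, 1L), "probe")
    st <- adamw_init(p)
    for (ep in seq_len(epochs)) {
      fw <- mlp_fwd(H, p, "probe", 3L)
      ls <- bce_logits(fw$out, y)
      bw <- mlp_bwd(ls$dlogits, p, "probe", 3L, fw$cache)
      upd <- adamw_step(p, bw$grads, st, 1e-3)
      p <- upd$params; st <- upd$state
    }
    pred <- as.numeric(sigmoid(mlp_fwd(H, p, "probe", 3L)$out) > 0.5)
    mean(pred == y)
  })
}
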