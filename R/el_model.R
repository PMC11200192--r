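# Presentation (eluted-ligand) model.
#
# Two sequence branches -- peptide and allele pseudosequence -- each a stack
# of pre-norm transformer encoders with learned positional embeddings, are
# coupled by a low-rank bilinear attention pooling whose joint representation
# feeds a 128-64-32 dense head with a 2-unit softmax output. The positive-
# class probability is the sequence branch score; it is fused with the
# expression, cleavage and binding-core-offset features by fixed
# contribution weights.

#' Configuration for the presentation model
#'
#' @param n_encoders Encoder blocks per branch (default 3).
#' @param n_heads Attention heads (default 12); must divide `d_model`.
#' @param d_model Embedding width (default 96).
#' @param d_ban Rank of the bilinear attention factorization (default 32).
#' @param pad_peptide Peptide rows after padding (default 19, the maximum
#'   ligand length considered).
#' @param pad_allele Pseudosequence rows (fixed 34).
#' @param lr AdamW learning rate; must lie in [1e-5, 1e-2].
#' @param batch_size Minibatch size (default 32).
#' @param epochs Training epochs (default 30).
#' @param seed Integer seed for initialization and shuffling.
#' @return List of class `el_config`. The dense head is fixed at
#'   128-64-32 units.
#' @export
el_config <- function(n_encoders = 3L, n_heads = 12L, d_model = 96L,
                      d_ban = 32L, pad_peptide = 19L, pad_allele = 34L,
                      lr = 1e-3, batch_size = 32L, epochs = 30L, seed = 1L) {
  if (d_model %% n_heads != 0L)
    stopf("n_heads (%d) must divide d_model (%d)", n_heads, d_model)
  if (lr < 1e-5 || lr > 1e-2)
    stopf("learning rate %g outside the tuning range [1e-5, 1e-2]", lr)
  structure(list(n_encoders = as.integer(n_encoders), n_heads = as.integer(n_heads),
                 d_model = as.integer(d_model), d_ban = as.integer(d_ban),
                 head_units = c(128L, 64L, 32L), pad_peptide = as.integer(pad_peptide),
                 pad_allele = as.integer(pad_allele), lr = lr,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 seed = as.integer(seed)),
            class = "el_config")
}

N_CHANNELS <- 42L  # one-hot (21) + scaled BLOSUM62 (21) stacked

branch_init <- function(br, L, cfg) {
  d <- cfg$d_model
  p <- list()
  p[[paste0(br, "_in_W")]] <- nn_dense_init(N_CHANNELS, d)
  p[[paste0(br, "_in_b")]] <- rep(0, d)
  p[[paste0(br, "_pos")]] <- matrix(stats::rnorm(L * d, sd = 0.02), L, d)
  for (i in seq_len(cfg$n_encoders)) {
    pre <- paste0(br, "_blk", i)
    p[[paste0(pre, "_ln1_g")]] <- rep(1, d); p[[paste0(pre, "_ln1_b")]] <- rep(0, d)
    p[[paste0(pre, "_ln2_g")]] <- rep(1, d); p[[paste0(pre, "_ln2_b")]] <- rep(0, d)
    for (w in c("Wq", "Wk", "Wv", "Wo"))
      p[[paste0(pre, "_", w)]] <- nn_dense_init(d, d, scale = sqrt(1 / d))
    p[[paste0(pre, "_ffn_W1")]] <- nn_dense_init(d, 2L * d)
    p[[paste0(pre, "_ffn_b1")]] <- rep(0, 2L * d)
    p[[paste0(pre, "_ffn_W2")]] <- nn_dense_init(2L * d, d)
    p[[paste0(pre, "_ffn_b2")]] <- rep(0, d)
  }
  p
}

#' Build a presentation model
#'
#' Initializes all parameters (deterministically given `cfg$seed`): the two
#' encoder branches, the bilinear attention factors and the dense head.
#'
#' @param cfg An [el_config()].
#' @return Object of class `el_model`.
#' @export
build_el_model <- function(cfg = el_config()) {
  with_seed(cfg$seed, {
    params <- c(
      branch_init("pep", cfg$pad_peptide, cfg),
      branch_init("hla", cfg$pad_allele, cfg),
      list(ban_U = nn_dense_init(cfg$d_model, cfg$d_ban),
           ban_V = nn_dense_init(cfg$d_model, cfg$d_ban)),
      mlp_init(c(cfg$d_ban, cfg$head_units, 2L), "head")
    )
    structure(list(params = params, cfg = cfg, history = NULL),
              class = "el_model")
  })
}

#' @export
print.el_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf(
    "<el_model> %d encoder(s)/branch, %d heads, d_model %d, BAN rank %d; %d parameters\n",
    x$cfg$n_encoders, x$cfg$n_heads, x$cfg$d_model, x$cfg$d_ban, np))
  if (!is.null(x$history))
    cat(sprintf("  trained %d epoch(s); best val loss %.4f\n",
                nrow(x$history), min(x$history$val_loss, na.rm = TRUE)))
  invisible(x)
}

# Joint feature extractor F: encoders + bilinear attention. Returns the
# d_ban joint representation, the attention map and the caches needed for
# backprop. This is also the feature extractor transferred to the
# immunogenicity stage.
el_features_fwd <- function(Xp, Xa, params, cfg) {
  bp <- branch_fwd(Xp, params, "pep", cfg$n_encoders, cfg$n_heads)
  ba <- branch_fwd(Xa, params, "hla", cfg$n_encoders, cfg$n_heads)
  bn <- ban_fwd(bp$out, ba$out, params$ban_U, params$ban_V)
  list(f = bn$f, A = bn$A, cache = list(bp = bp$cache, ba = ba$cache, bn = bn$cache))
}
el_features_bwd <- function(df, params, cfg, cache) {
  bb <- ban_bwd(df, cache$bn)
  g <- list(ban_U = bb$dU, ban_V = bb$dV)
  g <- acc_grads(g, branch_bwd(bb$dHp, params, "pep", cfg$n_encoders, cache$bp))
  acc_grads(g, branch_bwd(bb$dHa, params, "hla", cfg$n_encoders, cache$ba))
}

el_encode_pair <- function(peptide, short_seq, cfg) {
  list(Xp = encode_stacked(peptide, cfg$pad_peptide),
       Xa = encode_stacked(short_seq, cfg$pad_allele),
       akey = short_seq)
}

# Forward through feature extractor + head for one peptide/allele pair.
el_forward_one <- function(params, cfg, Xp, Xa) {
  ft <- el_features_fwd(Xp, Xa, params, cfg)
  hd <- mlp_fwd(matrix(ft$f, 1L), params, "head", 4L)
  probs <- softmax_rows(hd$out)
  list(probs = drop(probs), f = ft$f, A = ft$A,
       cache = list(ft = ft$cache, hd = hd$cache, logits = hd$out))
}

pseudo_lookup <- function(records, pseudo) {
  seqs <- pseudo$short_seq[match(records$allele, pseudo$allele)]
  if (anyNA(seqs))
    stopf("no pseudosequence for allele(s): %s",
          paste(unique(records$allele[is.na(seqs)]), collapse = ", "))
  seqs
}

#' Train the presentation model
#'
#' Minimizes binary cross-entropy with AdamW over minibatches, evaluating a
#' validation set each epoch and keeping the parameters from the epoch with
#' the lowest validation loss. Deterministic given the seed; record order
#' does not affect the result because shuffling is seed-driven.
#'
#' @param model An `el_model` (freshly built or pre-trained).
#' @param train Training record tibble (needs `peptide`, `allele`, `label`).
#' @param pseudo Pseudosequence table (see [read_pseudosequences()]).
#' @param val Validation record tibble; if `NULL`, a 4:1 peptide-level split
#'   of `train` is made.
#' @param epochs,lr,batch_size Override the model config.
#' @param seed Integer seed for shuffling (defaults to the config seed).
#' @return The trained `el_model`, with an epoch-level `history` tibble
#'   (train loss, validation loss, validation AUC).
#' @export
train_el <- function(model, train, pseudo, val = NULL, epochs = NULL,
                     lr = NULL, batch_size = NULL, seed = NULL) {
  cfg <- model$cfg
  epochs <- epochs %||% cfg$epochs
  lr <- lr %||% cfg$lr
  batch_size <- batch_size %||% cfg$batch_size
  seed <- seed %||% cfg$seed
  if (is.null(val)) {
    sp <- split_train_val(train, val_fraction = 0.2, seed = seed)
    train <- sp$train; val <- sp$val
  }
  if (epochs == 0L) return(model)
  if (length(unique(train$label)) < 2L)
    stopf("training set must contain both classes")
  # canonical ordering: results depend on the seed, never on record order
  train <- dplyr::arrange(train, .data$peptide, .data$allele)

  pseqs <- pseudo_lookup(train, pseudo)
  enc <- lapply(seq_len(nrow(train)), function(i)
    el_encode_pair(train$peptide[i], pseqs[i], cfg))
  labels <- train$label + 1L   # 1 = negative, 2 = positive class index

  params <- model$params
  with_seed(seed, {
    state <- adamw_init(params)
    hist <- vector("list", epochs)
    best <- list(loss = Inf, params = params)
    n <- length(enc)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        ft <- el_features_b_fwd(enc, idx, params, cfg)
        hd <- mlp_fwd(ft$f, params, "head", 4L)
        ls <- softmax_xent(hd$out, labels[idx])
        hb <- mlp_bwd(ls$dlogits, params, "head", 4L, hd$cache)
        grads <- acc_grads(hb$grads,
                           el_features_b_bwd(hb$dX, params, cfg, ft$cache))
        upd <- adamw_step(params, grads, state, lr)
        params <- upd$params; state <- upd$state
        ep_loss <- ep_loss + ls$loss * length(idx)
      }
      vm <- el_eval(params, cfg, val, pseudo)
      hist[[ep]] <- tibble::tibble(epoch = ep, train_loss = ep_loss / n,
                                   val_loss = vm$loss, val_auc = vm$auc)
      if (vm$loss < best$loss) best <- list(loss = vm$loss, params = params)
    }
    model$params <- best$params
    model$history <- dplyr::bind_rows(hist)
    model
  })
}

el_eval <- function(params, cfg, records, pseudo) {
  if (nrow(records) == 0L) return(list(loss = NA_real_, auc = NA_real_))
  s <- el_score(params, cfg, records, pseudo)
  p <- pmin(pmax(s, 1e-12), 1 - 1e-12)
  loss <- -mean(records$label * log(p) + (1 - records$label) * log(1 - p))
  a <- if (length(unique(records$label)) == 2L) auc(s, records$label) else NA_real_
  list(loss = loss, auc = a)
}

el_score <- function(params, cfg, records, pseudo, chunk = 64L) {
  pseqs <- pseudo_lookup(records, pseudo)
  enc <- lapply(seq_len(nrow(records)), function(i)
    el_encode_pair(records$peptide[i], pseqs[i], cfg))
  out <- numeric(nrow(records))
  for (start in seq(1L, length(enc), by = chunk)) {
    idx <- start:min(start + chunk - 1L, length(enc))
    ft <- el_features_b_fwd(enc, idx, params, cfg)
    out[idx] <- softmax_rows(mlp_fwd(ft$f, params, "head", 4L)$out)[, 2L]
  }
  out
}

#' Sequence-branch presentation scores
#'
#' @param model Trained `el_model`.
#' @param records Record tibble with `peptide` and `allele`.
#' @param pseudo Pseudosequence table.
#' @return Tibble of `records` plus `s_seq`, the positive-class probability.
#' @export
predict_el <- function(model, records, pseudo) {
  dplyr::mutate(records, s_seq = el_score(model$params, model$cfg, records, pseudo))
}

#' Fixed fusion weights of the presentation score
#'
#' The per-branch contribution weights: peptide sequence 60%, gene
#' expression 12%, cleavability 12%, binding-core offset 16%.
#'
#' @return Named numeric vector summing to 1.
#' @export
fusion_weights <- function() {
  c(seq = 0.60, expr = 0.12, cleave = 0.12, core = 0.16)
}

#' Fuse per-branch scores into the final presentation score
#'
#' Weighted sum of the branch scores with the fixed contribution weights. A
#' record with a missing expression branch (`NA`) has the remaining weights
#' renormalized to sum to 1 (logged via message once per call).
#'
#' @param scores Tibble or data frame with columns `s_seq`, `s_expr`,
#'   `s_cleave`, `s_core`, each in [0, 1] (`s_expr` may be `NA`).
#' @param weights Named weights as from [fusion_weights()].
#' @return Numeric vector of fused scores in [0, 1].
#' @export
fuse <- function(scores, weights = fusion_weights()) {
  stopifnot(abs(sum(weights) - 1) < 1e-9, all(weights >= 0))
  m <- as.matrix(scores[, c("s_seq", "s_expr", "s_cleave", "s_core")])
  rng <- range(m, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) stopf("branch scores must lie in [0, 1]")
  miss <- is.na(m[, "s_expr"])
  if (any(miss))
    message(sprintf("fuse: %d record(s) lack the expression branch; weights renormalized", sum(miss)))
  out <- numeric(nrow(m))
  w <- unname(weights)
  out[!miss] <- m[!miss, , drop = FALSE] %*% w
  if (any(miss)) {
    w3 <- w[-2] / sum(w[-2])
    out[miss] <- m[miss, -2, drop = FALSE] %*% w3
  }
  out
}

#' Percentile rank of a score against an allele background
#'
#' The rank is the percentage of a length-matched random-background score
#' sample that scores strictly higher, so lower ranks mean stronger
#' predicted presentation.
#'
#' @param score Numeric vector of query scores.
#' @param background Non-empty numeric vector of background scores for the
#'   same allele.
#' @return Ranks in [0, 100].
#' @export
percentile_rank <- function(score, background) {
  if (length(background) == 0L) stopf("empty percentile background")
  vapply(score, function(s) 100 * mean(background > s), numeric(1))
}

#' Export the bilinear attention map for a peptide/allele pair
#'
#' Returns the attention weights over (peptide position, pseudosequence
#' residue) -- each peptide row normalized to 1 -- together with the
#' per-residue marginal (column masses normalized to sum to 1), suitable for
#' heatmaps or structure coloring. Optionally written as TSV.
#'
#' @param model An `el_model`; if untrained, a warning is issued and the
#'   initialization-time map is exported.
#' @param peptide Peptide string.
#' @param allele Normalized allele name.
#' @param pseudo Pseudosequence table.
#' @param path Optional TSV output path for the map.
#' @return List with `map` (`pad_peptide x 34` matrix) and `marginal`
#'   (length-34 vector summing to 1).
#' @export
attention_export <- function(model, peptide, allele, pseudo, path = NULL) {
  if (is.null(model$history))
    rlang::warn("attention_export: model is untrained; exporting initialization-time attention")
  rec <- tibble::tibble(peptide = peptide, allele = allele)
  sseq <- pseudo_lookup(rec, pseudo)
  e <- el_encode_pair(peptide, sseq, model$cfg)
  fw <- el_forward_one(model$params, model$cfg, e$Xp, e$Xa)
  A <- fw$A
  dimnames(A) <- list(paste0("pep", seq_len(nrow(A))), paste0("hla", seq_len(ncol(A))))
  marginal <- colSums(A) / sum(A)
  if (!is.null(path))
    readr::write_tsv(tibble::as_tibble(A, rownames = "position"), path)
  list(map = A, marginal = marginal)
}
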