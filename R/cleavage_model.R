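# Flanking-residue cleavage classifier.
#
# Antigen processing enriches particular residues (notably proline and
# alanine) near ligand termini. The classifier takes the two 6-residue
# cleavage windows (12 positions, one-hot with padding channel, flattened to
# 252 features), passes them through two 32-unit dense layers and a logistic
# output, and emits a cleavage score in [0, 1]. Hits are scored against
# length/gene-matched decoys whose window composition defines the background.

encode_windows_flat <- function(n_window, c_window) {
  enc <- function(w) {
    chars <- split_chars(w)
    m <- matrix(0, 6L, 21L)
    known <- chars %in% AA_ALPHABET
    m[cbind(which(known), aa_index[chars[known]])] <- 1
    m[!known, 21L] <- 1
    m
  }
  as.numeric(rbind(enc(n_window), enc(c_window)))
}

records_window_matrix <- function(records, proteome = NULL) {
  win <- windows_for_records(records, proteome)
  X <- t(vapply(seq_len(nrow(win)),
                function(i) encode_windows_flat(win$n_window[i], win$c_window[i]),
                numeric(252L)))
  list(X = X[win$ok, , drop = FALSE], ok = win$ok)
}

#' Train the cleavage-score classifier
#'
#' Fits the two-layer (32 + 32 unit) dense network separating hit cleavage
#' windows from decoy windows, by AdamW on binary cross-entropy. Training is
#' deterministic given `seed` and invariant to record order.
#'
#' @param hits Tibble of presented-peptide records (flanks or proteome
#'   lookup must yield windows).
#' @param decoys Tibble of decoy records (the background class).
#' @param proteome Optional named protein vector for flank lookup.
#' @param epochs Training epochs (default 60).
#' @param lr AdamW learning rate (default 1e-3).
#' @param batch_size Minibatch size (default 64).
#' @param seed Integer seed.
#' @return Object of class `cleavage_model` holding the fitted parameters,
#'   the decoy background frequency table and the training trace.
#' @export
train_cleavage_model <- function(hits, decoys, proteome = NULL, epochs = 60L,
                                 lr = 1e-3, batch_size = 64L, seed = 1L) {
  if (nrow(hits) == 0L || nrow(decoys) == 0L)
    stopf("cleavage training needs non-empty hit and decoy sets")
  hw <- records_window_matrix(hits, proteome)
  dw <- records_window_matrix(decoys, proteome)
  X <- rbind(hw$X, dw$X)
  y <- c(rep(1, nrow(hw$X)), rep(0, nrow(dw$X)))
  # canonical row order: training depends on the seed, not on record order
  ord0 <- order(apply(X, 1L, paste, collapse = ""), y)
  X <- X[ord0, , drop = FALSE]; y <- y[ord0]
  if (length(unique(y)) < 2L) stopf("cleavage training needs both classes")
  background <- cleavage_background(decoys, proteome)

  with_seed(seed, {
    params <- mlp_init(c(252L, 32L, 32L, 1L), "clv")
    state <- adamw_init(params)
    trace <- numeric(epochs)
    n <- nrow(X)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        fwd <- mlp_fwd(X[idx, , drop = FALSE], params, "clv", 3L)
        loss <- bce_logits(fwd$out, y[idx])
        bwd <- mlp_bwd(loss$dlogits, params, "clv", 3L, fwd$cache)
        upd <- adamw_step(params, bwd$grads, state, lr)
        params <- upd$params; state <- upd$state
        ep_loss <- ep_loss + loss$loss * length(idx)
      }
      trace[ep] <- ep_loss / n
    }
    structure(list(params = params, background = background, trace = trace,
                   epochs = epochs, lr = lr, seed = seed),
              class = "cleavage_model")
  })
}

#' Score records with a fitted cleavage model
#'
#' @param object Fitted `cleavage_model`.
#' @param records Tibble of records (or the result of a previous window
#'   extraction).
#' @param proteome Optional named protein vector for flank lookup.
#' @param ... Unused.
#' @return Numeric vector of cleavage scores in [0, 1]; `NA` for records
#'   whose windows cannot be located.
#' @export
predict.cleavage_model <- function(object, records, proteome = NULL, ...) {
  wm <- records_window_matrix(records, proteome)
  out <- rep(NA_real_, nrow(records))
  if (nrow(wm$X) > 0L) {
    fwd <- mlp_fwd(wm$X, object$params, "clv", 3L)
    out[wm$ok] <- as.numeric(sigmoid(fwd$out))
  }
  out
}

#' @export
print.cleavage_model <- function(x, ...) {
  cat(sprintf(
    "<cleavage_model> 252-32-32-1 dense network, %d epochs, final loss %.4f\n",
    x$epochs, x$trace[length(x$trace)]))
  invisible(x)
}
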