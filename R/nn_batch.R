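# Batched training path for the sequence branches, bilinear attention and
# dense heads. Sequences of one branch share a fixed padded length, so a
# minibatch stacks as a (B*L) x C matrix: projections, layer norms and
# feed-forward layers then run as single large operations, and only the
# per-head attention cores loop over samples. Gradients accumulate through
# the stacked matmuls, so a batch costs a handful of BLAS calls instead of
# hundreds of small R operations per record. The per-sample functions in
# nn_core.R remain the reference implementation; equivalence is covered by
# tests.

layernorm_b_fwd <- function(X, g, b) {
  core <- cpp_layernorm_fwd(X, g, b, 1e-5)
  list(out = core$out, cache = list(xhat = core$xhat, istd = core$istd, g = g))
}
layernorm_b_bwd <- function(dY, cache) {
  core <- cpp_layernorm_bwd(dY, cache$xhat, cache$istd, cache$g)
  list(dX = core$dX, dg = drop(core$dg), db = drop(core$db))
}

mhsa_b_fwd <- function(X, B, L, Wq, Wk, Wv, Wo, n_heads) {
  Q <- X %*% Wq; K <- X %*% Wk; V <- X %*% Wv
  core <- cpp_mhsa_fwd(Q, K, V, B, L, n_heads)
  list(out = core$O %*% Wo,
       cache = list(X = X, Q = Q, K = K, V = V, O = core$O,
                    Astack = core$Astack, Wq = Wq, Wk = Wk, Wv = Wv, Wo = Wo,
                    B = B, L = L, n_heads = n_heads))
}

mhsa_b_bwd <- function(dY, cache) {
  cc <- cache
  dWo <- crossprod(cc$O, dY)
  dO <- tcrossprod(dY, cc$Wo)
  core <- cpp_mhsa_bwd(dO, cc$Q, cc$K, cc$V, cc$Astack, cc$B, cc$L, cc$n_heads)
  list(dX = tcrossprod(core$dQ, cc$Wq) + tcrossprod(core$dK, cc$Wk) +
         tcrossprod(core$dV, cc$Wv),
       dWq = crossprod(cc$X, core$dQ), dWk = crossprod(cc$X, core$dK),
       dWv = crossprod(cc$X, core$dV), dWo = dWo)
}

encoder_block_b_fwd <- function(X, B, L, p, prefix, n_heads) {
  ln1 <- layernorm_b_fwd(X, p[[paste0(prefix, "_ln1_g")]], p[[paste0(prefix, "_ln1_b")]])
  att <- mhsa_b_fwd(ln1$out, B, L, p[[paste0(prefix, "_Wq")]], p[[paste0(prefix, "_Wk")]],
                    p[[paste0(prefix, "_Wv")]], p[[paste0(prefix, "_Wo")]], n_heads)
  X1 <- X + att$out
  ln2 <- layernorm_b_fwd(X1, p[[paste0(prefix, "_ln2_g")]], p[[paste0(prefix, "_ln2_b")]])
  f1 <- linear_fwd(ln2$out, p[[paste0(prefix, "_ffn_W1")]], p[[paste0(prefix, "_ffn_b1")]])
  r1 <- relu_fwd(f1$out)
  f2 <- linear_fwd(r1$out, p[[paste0(prefix, "_ffn_W2")]], p[[paste0(prefix, "_ffn_b2")]])
  list(out = X1 + f2$out,
       cache = list(ln1 = ln1, att = att, ln2 = ln2, f1 = f1, r1 = r1, f2 = f2))
}

encoder_block_b_bwd <- function(dY, p, prefix, cache) {
  g <- list()
  b2 <- linear_bwd(dY, p[[paste0(prefix, "_ffn_W2")]], cache$f2$cache)
  g[[paste0(prefix, "_ffn_W2")]] <- b2$dW; g[[paste0(prefix, "_ffn_b2")]] <- b2$db
  dr1 <- relu_bwd(b2$dX, cache$r1$cache)
  b1 <- linear_bwd(dr1, p[[paste0(prefix, "_ffn_W1")]], cache$f1$cache)
  g[[paste0(prefix, "_ffn_W1")]] <- b1$dW; g[[paste0(prefix, "_ffn_b1")]] <- b1$db
  ln2 <- layernorm_b_bwd(b1$dX, cache$ln2$cache)
  g[[paste0(prefix, "_ln2_g")]] <- ln2$dg; g[[paste0(prefix, "_ln2_b")]] <- ln2$db
  dX1 <- dY + ln2$dX
  att <- mhsa_b_bwd(dX1, cache$att$cache)
  g[[paste0(prefix, "_Wq")]] <- att$dWq; g[[paste0(prefix, "_Wk")]] <- att$dWk
  g[[paste0(prefix, "_Wv")]] <- att$dWv; g[[paste0(prefix, "_Wo")]] <- att$dWo
  ln1 <- layernorm_b_bwd(att$dX, cache$ln1$cache)
  g[[paste0(prefix, "_ln1_g")]] <- ln1$dg; g[[paste0(prefix, "_ln1_b")]] <- ln1$db
  list(dX = dX1 + ln1$dX, grads = g)
}

branch_b_fwd <- function(Xstack, B, L, p, br, n_blocks, n_heads) {
  pr <- linear_fwd(Xstack, p[[paste0(br, "_in_W")]], p[[paste0(br, "_in_b")]])
  pos <- p[[paste0(br, "_pos")]]
  X <- pr$out + pos[rep(seq_len(L), B), , drop = FALSE]
  caches <- vector("list", n_blocks)
  for (i in seq_len(n_blocks)) {
    blk <- encoder_block_b_fwd(X, B, L, p, paste0(br, "_blk", i), n_heads)
    X <- blk$out
    caches[[i]] <- blk$cache
  }
  list(out = X, cache = list(proj = pr, blocks = caches, B = B, L = L))
}

branch_b_bwd <- function(dH, p, br, n_blocks, cache) {
  g <- list()
  dX <- dH
  for (i in rev(seq_len(n_blocks))) {
    blk <- encoder_block_b_bwd(dX, p, paste0(br, "_blk", i), cache$blocks[[i]])
    dX <- blk$dX
    g <- c(g, blk$grads)
  }
  # positional embedding gradient: sum over the batch copies
  L <- cache$L
  g[[paste0(br, "_pos")]] <- rowsum(dX, rep(seq_len(L), cache$B))
  pb <- linear_bwd(dX, p[[paste0(br, "_in_W")]], cache$proj$cache)
  g[[paste0(br, "_in_W")]] <- pb$dW; g[[paste0(br, "_in_b")]] <- pb$db
  g
}

ban_b_fwd <- function(Hp, Ha, U, V, B, Lp, La) {
  P <- Hp %*% U; Q <- Ha %*% V
  core <- cpp_ban_fwd(P, Q, B, Lp, La)
  list(f = core$f,
       cache = list(Hp = Hp, Ha = Ha, U = U, V = V, P = P, Q = Q,
                    Astack = core$Astack, Mstack = core$Mstack,
                    B = B, Lp = Lp, La = La))
}

ban_b_bwd <- function(df, cache) {
  cc <- cache
  core <- cpp_ban_bwd(df, cc$P, cc$Q, cc$Astack, cc$Mstack, cc$B, cc$Lp, cc$La)
  list(dHp = tcrossprod(core$dP, cc$U), dHa = tcrossprod(core$dQ, cc$V),
       dU = crossprod(cc$Hp, core$dP), dV = crossprod(cc$Ha, core$dQ))
}

# Batched feature extractor: list of per-record encodings -> (B x d_ban)
# joint features plus caches. Records sharing an allele pseudosequence run
# the allele branch once: the encoder output is gathered per record for the
# bilinear pooling, and gradients scatter-add back onto the unique set.
el_features_b_fwd <- function(enc, idx, params, cfg) {
  B <- length(idx)
  La <- cfg$pad_allele
  Xp <- do.call(rbind, lapply(enc[idx], `[[`, "Xp"))
  keys <- vapply(enc[idx], `[[`, character(1), "akey")
  ukeys <- unique(keys)
  gi <- match(keys, ukeys)
  first <- match(ukeys, keys)
  Xa <- do.call(rbind, lapply(enc[idx][first], `[[`, "Xa"))
  bp <- branch_b_fwd(Xp, B, cfg$pad_peptide, params, "pep", cfg$n_encoders, cfg$n_heads)
  ba <- branch_b_fwd(Xa, length(ukeys), La, params, "hla", cfg$n_encoders, cfg$n_heads)
  gather <- rep((gi - 1L) * La, each = La) + rep.int(seq_len(La), B)
  Ha_full <- ba$out[gather, , drop = FALSE]
  bn <- ban_b_fwd(bp$out, Ha_full, params$ban_U, params$ban_V,
                  B, cfg$pad_peptide, La)
  list(f = bn$f, cache = list(bp = bp$cache, ba = ba$cache, bn = bn$cache,
                              B = B, gather = gather))
}

el_features_b_bwd <- function(df, params, cfg, cache) {
  bb <- ban_b_bwd(df, cache$bn)
  g <- list(ban_U = bb$dU, ban_V = bb$dV)
  g <- acc_grads(g, branch_b_bwd(bb$dHp, params, "pep", cfg$n_encoders, cache$bp))
  # scatter-add gathered allele-branch gradients back to the unique rows
  dHa_u <- rowsum(bb$dHa, cache$gather)
  acc_grads(g, branch_b_bwd(dHa_u, params, "hla", cfg$n_encoders, cache$ba))
}

# Batched multilinear map: rows of Fmat (B x nf) and Gmat (B x ng) map to
# rows of H. Same layouts as mm_fwd/mm_bwd.
mm_b_fwd <- function(Fmat, Gmat, maps) {
  nf <- ncol(Fmat); ng <- ncol(Gmat)
  if (maps$kind == "outer") {
    iidx <- rep(seq_len(nf), each = ng)
    jidx <- rep(seq_len(ng), nf)
    list(H = Fmat[, iidx, drop = FALSE] * Gmat[, jidx, drop = FALSE],
         cache = list(Fmat = Fmat, Gmat = Gmat, maps = maps,
                      iidx = iidx, jidx = jidx))
  } else {
    RF <- Fmat %*% t(maps$Rf); RG <- Gmat %*% t(maps$Rg)
    list(H = RF * RG * maps$scale,
         cache = list(Fmat = Fmat, Gmat = Gmat, RF = RF, RG = RG, maps = maps))
  }
}
mm_b_bwd <- function(dH, cache) {
  maps <- cache$maps
  if (maps$kind == "outer") {
    nf <- ncol(cache$Fmat); ng <- ncol(cache$Gmat)
    dF <- matrix(0, nrow(dH), nf); dG <- matrix(0, nrow(dH), ng)
    dHG <- dH * cache$Gmat[, cache$jidx, drop = FALSE]
    dHF <- dH * cache$Fmat[, cache$iidx, drop = FALSE]
    for (i in seq_len(nf))
      dF[, i] <- rowSums(dHG[, ((i - 1L) * ng + 1L):(i * ng), drop = FALSE])
    for (j in seq_len(ng))
      dG[, j] <- rowSums(dHF[, seq(j, nf * ng, by = ng), drop = FALSE])
    list(dF = dF, dG = dG)
  } else {
    list(dF = (dH * cache$RG) %*% maps$Rf * maps$scale,
         dG = (dH * cache$RF) %*% maps$Rg * maps$scale)
  }
}
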