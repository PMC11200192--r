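# Minimal dense/attention neural-network core with manual backpropagation.
#
# Parameters live in a flat named list of matrices; gradients mirror that
# layout. Every layer is a pure pair of functions: *_fwd returns the output
# plus a cache, *_bwd consumes the upstream gradient and the cache. All
# gradients are checked against finite differences in the test suite.
#
# Conventions: data matrices are (rows = positions or samples, cols =
# features); a dense weight W is (n_in x n_out) so that y = x %*% W + b.

nn_dense_init <- function(n_in, n_out, scale = sqrt(2 / n_in)) {
  matrix(stats::rnorm(n_in * n_out, sd = scale), n_in, n_out)
}

add_bias <- function(X, b) X + rep(1, nrow(X)) %o% b

linear_fwd <- function(X, W, b) {
  list(out = add_bias(X %*% W, b), cache = X)
}
linear_bwd <- function(dY, W, cache) {
  list(dX = tcrossprod(dY, W), dW = crossprod(cache, dY), db = colSums(dY))
}

relu_fwd <- function(X) list(out = pmax(X, 0), cache = X > 0)
relu_bwd <- function(dY, cache) dY * cache

# clamped to avoid overflow and subnormal slowdowns at saturation
sigmoid <- function(x) 1 / (1 + exp(-pmax(pmin(x, 35), -35)))

# Row-wise softmax with the usual max-shift for stability.
softmax_rows <- function(X) {
  e <- exp(X - apply(X, 1L, max))
  e / rowSums(e)
}
# Jacobian-vector product of row-wise softmax: dX = (dY - <dY, Y>_row) * Y.
softmax_rows_bwd <- function(dY, Y) {
  (dY - rowSums(dY * Y)) * Y
}

# Row-wise layer normalization with learned gain g and bias b.
layernorm_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * istd
  list(out = add_bias(xhat * rep(1, nrow(X)) %o% g, b),
       cache = list(xhat = xhat, istd = istd, g = g))
}
layernorm_bwd <- function(dY, cache) {
  xhat <- cache$xhat; istd <- cache$istd; g <- cache$g
  dxhat <- dY * rep(1, nrow(dY)) %o% g
  dX <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * istd
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

# Multi-head self-attention over a single sequence X (L x d).
mhsa_fwd <- function(X, Wq, Wk, Wv, Wo, n_heads) {
  d <- ncol(X); dh <- d %/% n_heads
  Q <- X %*% Wq; K <- X %*% Wk; V <- X %*% Wv
  O <- matrix(0, nrow(X), d)
  heads <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1L) * dh + 1L):(h * dh)
    S <- Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE]) / sqrt(dh)
    A <- softmax_rows(S)
    O[, idx] <- A %*% V[, idx, drop = FALSE]
    heads[[h]] <- A
  }
  list(out = O %*% Wo,
       cache = list(X = X, Q = Q, K = K, V = V, O = O, heads = heads,
                    Wq = Wq, Wk = Wk, Wv = Wv, Wo = Wo, n_heads = n_heads))
}
mhsa_bwd <- function(dY, cache) {
  c2 <- cache
  d <- ncol(c2$X); dh <- d %/% c2$n_heads
  dWo <- t(c2$O) %*% dY
  dO <- dY %*% t(c2$Wo)
  dQ <- dK <- dV <- matrix(0, nrow(c2$X), d)
  for (h in seq_len(c2$n_heads)) {
    idx <- ((h - 1L) * dh + 1L):(h * dh)
    A <- c2$heads[[h]]
    dOh <- dO[, idx, drop = FALSE]
    Vh <- c2$V[, idx, drop = FALSE]
    dA <- dOh %*% t(Vh)
    dV[, idx] <- t(A) %*% dOh
    dS <- softmax_rows_bwd(dA, A) / sqrt(dh)
    dQ[, idx] <- dS %*% c2$K[, idx, drop = FALSE]
    dK[, idx] <- t(dS) %*% c2$Q[, idx, drop = FALSE]
  }
  list(dX = dQ %*% t(c2$Wq) + dK %*% t(c2$Wk) + dV %*% t(c2$Wv),
       dWq = t(c2$X) %*% dQ, dWk = t(c2$X) %*% dK, dWv = t(c2$X) %*% dV,
       dWo = dWo)
}

# Pre-norm transformer encoder block:
#   x1 = x + MHSA(LN1(x));  out = x1 + FFN(LN2(x1)),  FFN = W2(relu(W1 .)).
encoder_block_fwd <- function(X, p, prefix, n_heads) {
  ln1 <- layernorm_fwd(X, p[[paste0(prefix, "_ln1_g")]], p[[paste0(prefix, "_ln1_b")]])
  att <- mhsa_fwd(ln1$out, p[[paste0(prefix, "_Wq")]], p[[paste0(prefix, "_Wk")]],
                  p[[paste0(prefix, "_Wv")]], p[[paste0(prefix, "_Wo")]], n_heads)
  X1 <- X + att$out
  ln2 <- layernorm_fwd(X1, p[[paste0(prefix, "_ln2_g")]], p[[paste0(prefix, "_ln2_b")]])
  f1 <- linear_fwd(ln2$out, p[[paste0(prefix, "_ffn_W1")]], p[[paste0(prefix, "_ffn_b1")]])
  r1 <- relu_fwd(f1$out)
  f2 <- linear_fwd(r1$out, p[[paste0(prefix, "_ffn_W2")]], p[[paste0(prefix, "_ffn_b2")]])
  list(out = X1 + f2$out,
       cache = list(ln1 = ln1, att = att, ln2 = ln2, f1 = f1, r1 = r1, f2 = f2))
}
encoder_block_bwd <- function(dY, p, prefix, cache) {
  g <- list()
  b2 <- linear_bwd(dY, p[[paste0(prefix, "_ffn_W2")]], cache$f2$cache)
  g[[paste0(prefix, "_ffn_W2")]] <- b2$dW; g[[paste0(prefix, "_ffn_b2")]] <- b2$db
  dr1 <- relu_bwd(b2$dX, cache$r1$cache)
  b1 <- linear_bwd(dr1, p[[paste0(prefix, "_ffn_W1")]], cache$f1$cache)
  g[[paste0(prefix, "_ffn_W1")]] <- b1$dW; g[[paste0(prefix, "_ffn_b1")]] <- b1$db
  ln2 <- layernorm_bwd(b1$dX, cache$ln2$cache)
  g[[paste0(prefix, "_ln2_g")]] <- ln2$dg; g[[paste0(prefix, "_ln2_b")]] <- ln2$db
  dX1 <- dY + ln2$dX
  att <- mhsa_bwd(dX1, cache$att$cache)
  g[[paste0(prefix, "_Wq")]] <- att$dWq; g[[paste0(prefix, "_Wk")]] <- att$dWk
  g[[paste0(prefix, "_Wv")]] <- att$dWv; g[[paste0(prefix, "_Wo")]] <- att$dWo
  ln1 <- layernorm_bwd(att$dX, cache$ln1$cache)
  g[[paste0(prefix, "_ln1_g")]] <- ln1$dg; g[[paste0(prefix, "_ln1_b")]] <- ln1$db
  list(dX = dX1 + ln1$dX, grads = g)
}

# A sequence branch: input projection + learned positional embedding + a
# stack of encoder blocks. Prefixes: "{br}_in_W", "{br}_in_b", "{br}_pos",
# "{br}_blk{i}_*".
branch_fwd <- function(Xenc, p, br, n_blocks, n_heads) {
  pr <- linear_fwd(Xenc, p[[paste0(br, "_in_W")]], p[[paste0(br, "_in_b")]])
  X <- pr$out + p[[paste0(br, "_pos")]]
  caches <- vector("list", n_blocks)
  for (i in seq_len(n_blocks)) {
    blk <- encoder_block_fwd(X, p, paste0(br, "_blk", i), n_heads)
    X <- blk$out
    caches[[i]] <- blk$cache
  }
  list(out = X, cache = list(proj = pr, blocks = caches))
}
branch_bwd <- function(dH, p, br, n_blocks, cache) {
  g <- list()
  dX <- dH
  for (i in rev(seq_len(n_blocks))) {
    blk <- encoder_block_bwd(dX, p, paste0(br, "_blk", i), cache$blocks[[i]])
    dX <- blk$dX
    g <- c(g, blk$grads)
  }
  g[[paste0(br, "_pos")]] <- dX
  pb <- linear_bwd(dX, p[[paste0(br, "_in_W")]], cache$proj$cache)
  g[[paste0(br, "_in_W")]] <- pb$dW; g[[paste0(br, "_in_b")]] <- pb$db
  g
}

# Bilinear attention pooling between two encoded sequences Hp (Lp x d) and
# Ha (La x d). Low-rank factors U, V (d x r); attention map A is row-softmax
# over the allele axis; the joint representation is
#   f_r = sum_ij A_ij (Hp U)_ir (Ha V)_jr.
ban_fwd <- function(Hp, Ha, U, V) {
  P <- Hp %*% U; Q <- Ha %*% V
  r <- ncol(U)
  S <- P %*% t(Q) / sqrt(r)
  A <- softmax_rows(S)
  M <- A %*% Q
  f <- colSums(P * M) / nrow(P)   # mean-pool over peptide positions
  list(f = f, A = A,
       cache = list(Hp = Hp, Ha = Ha, U = U, V = V, P = P, Q = Q, A = A, M = M, r = r))
}
ban_bwd <- function(df, cache) {
  P <- cache$P; Q <- cache$Q; A <- cache$A; M <- cache$M; r <- cache$r
  dfm <- rep(1, nrow(P)) %o% (df / nrow(P))
  dP <- M * dfm
  dM <- P * dfm
  dA <- dM %*% t(Q)
  dQ <- t(A) %*% dM
  dS <- softmax_rows_bwd(dA, A) / sqrt(r)
  dP <- dP + dS %*% Q
  dQ <- dQ + t(dS) %*% P
  list(dHp = dP %*% t(cache$U), dHa = dQ %*% t(cache$V),
       dU = t(cache$Hp) %*% dP, dV = t(cache$Ha) %*% dQ)
}

# Generic batched MLP. Layer l uses params "{prefix}_W{l}" / "{prefix}_b{l}";
# hidden activations are relu, the output is linear (losses apply their own
# nonlinearity).
mlp_init <- function(sizes, prefix) {
  p <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    p[[paste0(prefix, "_W", l)]] <- nn_dense_init(sizes[l], sizes[l + 1L])
    p[[paste0(prefix, "_b", l)]] <- rep(0, sizes[l + 1L])
  }
  p
}
mlp_fwd <- function(X, p, prefix, n_layers) {
  caches <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    lin <- linear_fwd(X, p[[paste0(prefix, "_W", l)]], p[[paste0(prefix, "_b", l)]])
    if (l < n_layers) {
      act <- relu_fwd(lin$out)
      X <- act$out
      caches[[l]] <- list(lin = lin$cache, act = act$cache)
    } else {
      X <- lin$out
      caches[[l]] <- list(lin = lin$cache)
    }
  }
  list(out = X, cache = caches)
}
mlp_bwd <- function(dY, p, prefix, n_layers, cache) {
  g <- list()
  for (l in rev(seq_len(n_layers))) {
    if (l < n_layers) dY <- relu_bwd(dY, cache[[l]]$act)
    lb <- linear_bwd(dY, p[[paste0(prefix, "_W", l)]], cache[[l]]$lin)
    g[[paste0(prefix, "_W", l)]] <- lb$dW
    g[[paste0(prefix, "_b", l)]] <- lb$db
    dY <- lb$dX
  }
  list(dX = dY, grads = g)
}

# Softmax cross-entropy over a batch of logits (n x K) with labels in 1..K.
# Returns mean loss and the gradient w.r.t. logits (already averaged).
softmax_xent <- function(logits, labels) {
  P <- softmax_rows(logits)
  n <- nrow(logits)
  idx <- cbind(seq_len(n), labels)
  loss <- -mean(log(pmax(P[idx], 1e-12)))
  dlogits <- P
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, probs = P, dlogits = dlogits / n)
}

# Binary cross-entropy on logits (n x 1) with labels in {0,1}.
bce_logits <- function(logits, labels) {
  p <- sigmoid(logits)
  loss <- -mean(labels * log(pmax(p, 1e-12)) + (1 - labels) * log(pmax(1 - p, 1e-12)))
  list(loss = loss, probs = p, dlogits = (p - labels) / length(labels))
}

# Sum two gradient lists (missing entries are treated as zero).
acc_grads <- function(g1, g2) {
  for (nm in names(g2)) {
    g1[[nm]] <- if (is.null(g1[[nm]])) g2[[nm]] else g1[[nm]] + g2[[nm]]
  }
  g1
}
scale_grads <- function(g, s) lapply(g, function(x) x * s)

# AdamW optimizer with decoupled weight decay.
adamw_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0L)
}
adamw_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 0.01) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    decay <- if (grepl("_b[0-9]*$|_ln[12]_[gb]$", nm)) 0 else weight_decay
    params[[nm]] <- params[[nm]] - lr * (mhat / (sqrt(vhat) + eps) + decay * params[[nm]])
  }
  list(params = params, state = state)
}
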