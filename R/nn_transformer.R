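# Transformer base model: framed input linearly embedded to d_model with
# sinusoidal positional encodings, a stack of encoder layers (2-head
# self-attention + 64-unit feed-forward sublayer, residual connections,
# layer normalization with eps = 1e-6), mean pooling over timesteps and a
# dense sigmoid head.

transformer_init <- function(config, c_in, L) {
  dm <- config$d_model
  p <- list(We = glorot(c_in, dm), be = rep(0, dm))
  for (ly in seq_len(config$n_layers)) {
    pre <- paste0("L", ly, "_")
    p[[paste0(pre, "Wq")]] <- glorot(dm, dm)
    p[[paste0(pre, "Wk")]] <- glorot(dm, dm)
    p[[paste0(pre, "Wv")]] <- glorot(dm, dm)
    p[[paste0(pre, "Wo")]] <- glorot(dm, dm)
    p[[paste0(pre, "bo")]] <- rep(0, dm)
    p[[paste0(pre, "g1")]] <- rep(1, dm)
    p[[paste0(pre, "be1")]] <- rep(0, dm)
    p[[paste0(pre, "W1")]] <- glorot(dm, config$ffn_dim)
    p[[paste0(pre, "b1")]] <- rep(0, config$ffn_dim)
    p[[paste0(pre, "W2")]] <- glorot(config$ffn_dim, dm)
    p[[paste0(pre, "b2")]] <- rep(0, dm)
    p[[paste0(pre, "g2")]] <- rep(1, dm)
    p[[paste0(pre, "be2")]] <- rep(0, dm)
  }
  p$Wh <- glorot(dm, 1L)
  p$bh <- 0
  p
}

sinusoidal_pe <- function(L, dm) {
  pe <- matrix(0, L, dm)
  pos <- seq_len(L) - 1L
  for (j in seq_len(dm)) {
    k <- (j - 1L) %/% 2L
    angle <- pos / 10000^(2 * k / dm)
    pe[, j] <- if (j %% 2 == 1) sin(angle) else cos(angle)
  }
  pe
}

layernorm_forward <- function(X, gamma, beta, eps) {
  mu <- rowMeans(X)
  xc <- X - mu
  va <- rowMeans(xc^2)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  list(out = sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`),
       xhat = xhat, inv = inv)
}

layernorm_backward <- function(dout, cache, gamma) {
  d <- ncol(cache$xhat)
  dxhat <- sweep(dout, 2, gamma, `*`)
  g_gamma <- colSums(dout * cache$xhat)
  g_beta <- colSums(dout)
  dx <- cache$inv * (dxhat - rowMeans(dxhat) -
                       cache$xhat * rowMeans(dxhat * cache$xhat))
  list(dx = dx, g_gamma = g_gamma, g_beta = g_beta)
}

# Multi-head self-attention over the stacked layout ((L*B) x dm). Sample b
# occupies rows (0:(L-1))*B + b.
mha_forward <- function(X, Wq, Wk, Wv, Wo, bo, heads, L, B) {
  dm <- ncol(X)
  dk <- dm %/% heads
  Q <- X %*% Wq; K <- X %*% Wk; V <- X %*% Wv
  O <- matrix(0, nrow(X), dm)
  attn <- vector("list", B)
  for (b in seq_len(B)) {
    rows <- (seq_len(L) - 1L) * B + b
    ab <- vector("list", heads)
    for (h in seq_len(heads)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      Qb <- Q[rows, cols, drop = FALSE]
      Kb <- K[rows, cols, drop = FALSE]
      Vb <- V[rows, cols, drop = FALSE]
      S <- Qb %*% t(Kb) / sqrt(dk)
      S <- S - apply(S, 1, max)
      A <- exp(S); A <- A / rowSums(A)
      O[rows, cols] <- A %*% Vb
      ab[[h]] <- A
    }
    attn[[b]] <- ab
  }
  out <- sweep(O %*% Wo, 2, bo, `+`)
  list(out = out, Q = Q, K = K, V = V, O = O, attn = attn, dk = dk)
}

mha_backward <- function(dout, cache, X, Wq, Wk, Wv, Wo, heads, L, B) {
  dm <- ncol(X)
  dk <- cache$dk
  gWo <- crossprod(cache$O, dout)
  gbo <- colSums(dout)
  dO <- dout %*% t(Wo)
  dQ <- matrix(0, nrow(X), dm)
  dK <- matrix(0, nrow(X), dm)
  dV <- matrix(0, nrow(X), dm)
  for (b in seq_len(B)) {
    rows <- (seq_len(L) - 1L) * B + b
    for (h in seq_len(heads)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      A <- cache$attn[[b]][[h]]
      Vb <- cache$V[rows, cols, drop = FALSE]
      dOb <- dO[rows, cols, drop = FALSE]
      dA <- dOb %*% t(Vb)
      dV[rows, cols] <- crossprod(A, dOb)
      dS <- A * (dA - rowSums(dA * A))
      dS <- dS / sqrt(dk)
      Qb <- cache$Q[rows, cols, drop = FALSE]
      Kb <- cache$K[rows, cols, drop = FALSE]
      dQ[rows, cols] <- dS %*% Kb
      dK[rows, cols] <- crossprod(dS, Qb)
    }
  }
  gWq <- crossprod(X, dQ)
  gWk <- crossprod(X, dK)
  gWv <- crossprod(X, dV)
  dX <- dQ %*% t(Wq) + dK %*% t(Wk) + dV %*% t(Wv)
  list(dX = dX, gWq = gWq, gWk = gWk, gWv = gWv, gWo = gWo, gbo = gbo)
}

transformer_pass <- function(net, Xb, yb, train) {
  p <- net$params
  cfg <- net$config
  B <- nrow(Xb); L <- net$L
  dm <- cfg$d_model
  eps <- cfg$layernorm_eps
  Xf <- frame_stack(Xb, L, net$c)
  pe <- sinusoidal_pe(L, dm)
  X <- sweep(Xf %*% p$We, 2, p$be, `+`)
  # broadcast positional encoding across samples within each block
  X <- X + pe[rep(seq_len(L), each = B), , drop = FALSE]

  caches <- vector("list", cfg$n_layers)
  H <- X
  for (ly in seq_len(cfg$n_layers)) {
    pre <- paste0("L", ly, "_")
    mh <- mha_forward(H, p[[paste0(pre, "Wq")]], p[[paste0(pre, "Wk")]],
                      p[[paste0(pre, "Wv")]], p[[paste0(pre, "Wo")]],
                      p[[paste0(pre, "bo")]], cfg$heads, L, B)
    R1 <- H + mh$out
    ln1 <- layernorm_forward(R1, p[[paste0(pre, "g1")]],
                             p[[paste0(pre, "be1")]], eps)
    Z1 <- sweep(ln1$out %*% p[[paste0(pre, "W1")]], 2, p[[paste0(pre, "b1")]], `+`)
    A1 <- relu(Z1)
    F2 <- sweep(A1 %*% p[[paste0(pre, "W2")]], 2, p[[paste0(pre, "b2")]], `+`)
    R2 <- ln1$out + F2
    ln2 <- layernorm_forward(R2, p[[paste0(pre, "g2")]],
                             p[[paste0(pre, "be2")]], eps)
    caches[[ly]] <- list(H = H, mh = mh, ln1 = ln1, Z1 = Z1, A1 = A1)
    H <- ln2$out
    caches[[ly]]$ln2 <- ln2
  }

  # mean pooling over timesteps
  Pool <- matrix(0, B, dm)
  for (l in seq_len(L)) Pool <- Pool + H[block_rows(l, B), , drop = FALSE]
  Pool <- Pool / L
  z <- Pool %*% p$Wh + p$bh
  probs <- as.vector(sigmoid(z))
  if (is.null(yb)) return(list(probs = probs))

  loss <- bce_loss(probs, yb)
  grads <- stats::setNames(vector("list", length(p)), names(p))
  dz <- matrix((probs - yb) / B, B, 1L)
  grads$Wh <- crossprod(Pool, dz)
  grads$bh <- sum(dz)
  dPool <- dz %*% t(p$Wh)
  dH <- dPool[rep(seq_len(B), L), , drop = FALSE] / L

  for (ly in rev(seq_len(cfg$n_layers))) {
    pre <- paste0("L", ly, "_")
    cc <- caches[[ly]]
    bk2 <- layernorm_backward(dH, cc$ln2, p[[paste0(pre, "g2")]])
    grads[[paste0(pre, "g2")]] <- bk2$g_gamma
    grads[[paste0(pre, "be2")]] <- bk2$g_beta
    dR2 <- bk2$dx
    dF2 <- dR2
    grads[[paste0(pre, "W2")]] <- crossprod(cc$A1, dF2)
    grads[[paste0(pre, "b2")]] <- colSums(dF2)
    dA1 <- dF2 %*% t(p[[paste0(pre, "W2")]])
    dZ1 <- dA1 * (cc$Z1 > 0)
    grads[[paste0(pre, "W1")]] <- crossprod(cc$ln1$out, dZ1)
    grads[[paste0(pre, "b1")]] <- colSums(dZ1)
    dLn1 <- dR2 + dZ1 %*% t(p[[paste0(pre, "W1")]])
    bk1 <- layernorm_backward(dLn1, cc$ln1, p[[paste0(pre, "g1")]])
    grads[[paste0(pre, "g1")]] <- bk1$g_gamma
    grads[[paste0(pre, "be1")]] <- bk1$g_beta
    dR1 <- bk1$dx
    mhb <- mha_backward(dR1, cc$mh, cc$H, p[[paste0(pre, "Wq")]],
                        p[[paste0(pre, "Wk")]], p[[paste0(pre, "Wv")]],
                        p[[paste0(pre, "Wo")]], cfg$heads, L, B)
    grads[[paste0(pre, "Wq")]] <- mhb$gWq
    grads[[paste0(pre, "Wk")]] <- mhb$gWk
    grads[[paste0(pre, "Wv")]] <- mhb$gWv
    grads[[paste0(pre, "Wo")]] <- mhb$gWo
    grads[[paste0(pre, "bo")]] <- mhb$gbo
    dH <- dR1 + mhb$dX
  }

  grads$be <- colSums(dH)
  grads$We <- crossprod(Xf, dH)
  list(probs = probs, loss = loss, grads = grads)
}
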