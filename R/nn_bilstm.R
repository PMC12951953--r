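# Bidirectional LSTM base model: two stacked bidirectional layers (128
# then 64 units per direction), recurrent dropout 0.1 on the recurrent
# connections, batch normalization on the final representation and a
# dense sigmoid head. BPTT is implemented directly over the framed input.

lstm_layer_init <- function(c_in, H, prefix) {
  p <- list()
  for (dir in c("f", "b")) {
    p[[paste0(prefix, dir, "_W")]] <- glorot(c_in, 4L * H)
    p[[paste0(prefix, dir, "_U")]] <- glorot(H, 4L * H)
    b <- rep(0, 4L * H)
    b[(H + 1L):(2L * H)] <- 1  # forget-gate bias
    p[[paste0(prefix, dir, "_b")]] <- b
  }
  p
}

bilstm_init <- function(config, c_in) {
  H1 <- config$units1; H2 <- config$units2
  c(
    lstm_layer_init(c_in, H1, "l1"),
    lstm_layer_init(2L * H1, H2, "l2"),
    list(
      bn_gamma = rep(1, 2L * H2), bn_beta = rep(0, 2L * H2),
      Wo = glorot(2L * H2, 1L), bo = 0
    )
  )
}

# One directional LSTM over a list of timestep matrices (each B x c_in).
# Returns hidden states per timestep and the cache needed for BPTT. The
# input projections x_t W + b for all timesteps are batched into one
# matrix product up front.
lstm_forward <- function(xs, W, U, b, H, rmask = NULL, reverse = FALSE) {
  L <- length(xs)
  B <- nrow(xs[[1]])
  ord <- if (reverse) rev(seq_len(L)) else seq_len(L)
  xproj <- sweep(do.call(rbind, xs) %*% W, 2, b, `+`)
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  hs <- vector("list", L)
  cache <- vector("list", L)
  for (step in seq_len(L)) {
    t <- ord[step]
    hr <- if (is.null(rmask)) h else h * rmask
    G <- xproj[block_rows(t, B), , drop = FALSE] + hr %*% U
    i <- sigmoid(G[, gate_cols(1L, H), drop = FALSE])
    f <- sigmoid(G[, gate_cols(2L, H), drop = FALSE])
    g <- tanh(G[, gate_cols(3L, H), drop = FALSE])
    o <- sigmoid(G[, gate_cols(4L, H), drop = FALSE])
    c_new <- f * cc + i * g
    tc <- tanh(c_new)
    h_new <- o * tc
    cache[[step]] <- list(t = t, x = xs[[t]], h_prev = h, hr = hr,
                          c_prev = cc, i = i, f = f, g = g, o = o, tc = tc)
    h <- h_new; cc <- c_new
    hs[[t]] <- h_new
  }
  list(hs = hs, h_last = h, cache = cache, ord = ord)
}

gate_cols <- function(k, H) ((k - 1L) * H + 1L):(k * H)

# BPTT for one direction. dhs: list of upstream gradients per original
# timestep (may be NULL entries); dh_last: extra gradient on the final
# hidden state. Returns parameter grads and per-timestep input grads.
lstm_backward <- function(fw, W, U, b, H, rmask, dhs, dh_last = NULL) {
  cache <- fw$cache
  L <- length(cache)
  B <- nrow(cache[[1]]$x)
  c_in <- ncol(cache[[1]]$x)
  gU <- matrix(0, H, 4L * H); gb <- rep(0, 4L * H)
  dG_all <- matrix(0, L * B, 4L * H)  # by original timestep blocks
  dh_next <- matrix(0, B, H); dc_next <- matrix(0, B, H)
  for (step in rev(seq_len(L))) {
    cc <- cache[[step]]
    dh <- dh_next
    if (!is.null(dhs[[cc$t]])) dh <- dh + dhs[[cc$t]]
    if (step == L && !is.null(dh_last)) dh <- dh + dh_last
    dc <- dc_next + dh * cc$o * (1 - cc$tc^2)
    do <- dh * cc$tc * cc$o * (1 - cc$o)
    di <- dc * cc$g * cc$i * (1 - cc$i)
    df <- dc * cc$c_prev * cc$f * (1 - cc$f)
    dg <- dc * cc$i * (1 - cc$g^2)
    dG <- cbind(di, df, dg, do)
    dG_all[block_rows(cc$t, B), ] <- dG
    gU <- gU + crossprod(cc$hr, dG)
    gb <- gb + colSums(dG)
    dh_prev <- dG %*% t(U)
    if (!is.null(rmask)) dh_prev <- dh_prev * rmask
    dh_next <- dh_prev
    dc_next <- dc * cc$f
  }
  # batch the input-side products over all timesteps
  X_all <- do.call(rbind, lapply(seq_len(L), function(t) {
    cache[[which(vapply(cache, function(cc) cc$t, integer(1)) == t)]]$x
  }))
  gW <- crossprod(X_all, dG_all)
  dx_all <- dG_all %*% t(W)
  dxs <- lapply(seq_len(L), function(t) dx_all[block_rows(t, B), , drop = FALSE])
  list(gW = gW, gU = gU, gb = gb, dxs = dxs)
}

bilstm_pass <- function(net, Xb, yb, train) {
  p <- net$params
  cfg <- net$config
  B <- nrow(Xb); L <- net$L
  H1 <- cfg$units1; H2 <- cfg$units2
  Xf <- frame_stack(Xb, L, net$c)
  xs <- lapply(seq_len(L), function(l) Xf[block_rows(l, B), , drop = FALSE])

  rmask1f <- rmask1b <- rmask2f <- rmask2b <- NULL
  if (train && cfg$recurrent_dropout > 0) {
    keep <- 1 - cfg$recurrent_dropout
    mk <- function(H) matrix(stats::rbinom(B * H, 1L, keep) / keep, B, H)
    rmask1f <- mk(H1); rmask1b <- mk(H1); rmask2f <- mk(H2); rmask2b <- mk(H2)
  }

  f1 <- lstm_forward(xs, p$l1f_W, p$l1f_U, p$l1f_b, H1, rmask1f, reverse = FALSE)
  b1 <- lstm_forward(xs, p$l1b_W, p$l1b_U, p$l1b_b, H1, rmask1b, reverse = TRUE)
  seq1 <- lapply(seq_len(L), function(l) cbind(f1$hs[[l]], b1$hs[[l]]))

  f2 <- lstm_forward(seq1, p$l2f_W, p$l2f_U, p$l2f_b, H2, rmask2f, reverse = FALSE)
  b2 <- lstm_forward(seq1, p$l2b_W, p$l2b_U, p$l2b_b, H2, rmask2b, reverse = TRUE)
  R <- cbind(f2$h_last, b2$h_last)          # B x 2*H2

  # batch normalization on the final representation
  eps <- 1e-5
  if (train) {
    mu <- colMeans(R)
    va <- colMeans(sweep(R, 2, mu, `-`)^2)
    extra <- net$extra
    mom <- extra$bn_momentum
    extra$bn_mean <- mom * extra$bn_mean + (1 - mom) * mu
    extra$bn_var <- mom * extra$bn_var + (1 - mom) * va
  } else {
    mu <- net$extra$bn_mean
    va <- net$extra$bn_var
    extra <- net$extra
  }
  sd_ <- sqrt(va + eps)
  Rhat <- sweep(sweep(R, 2, mu, `-`), 2, sd_, `/`)
  Rbn <- sweep(sweep(Rhat, 2, p$bn_gamma, `*`), 2, p$bn_beta, `+`)

  z <- Rbn %*% p$Wo + p$bo
  probs <- as.vector(sigmoid(z))
  if (is.null(yb)) return(list(probs = probs))

  loss <- bce_loss(probs, yb)
  dz <- matrix((probs - yb) / B, B, 1L)
  gWo <- crossprod(Rbn, dz)
  gbo <- sum(dz)
  dRbn <- dz %*% t(p$Wo)
  g_gamma <- colSums(dRbn * Rhat)
  g_beta <- colSums(dRbn)
  dRhat <- sweep(dRbn, 2, p$bn_gamma, `*`)
  # batchnorm backward (training statistics)
  dR <- sweep(
    dRhat - matrix(colMeans(dRhat), B, 2L * H2, byrow = TRUE) -
      Rhat * matrix(colMeans(dRhat * Rhat), B, 2L * H2, byrow = TRUE),
    2, sd_, `/`)

  dh2f <- dR[, 1:H2, drop = FALSE]
  dh2b <- dR[, (H2 + 1L):(2L * H2), drop = FALSE]
  none <- vector("list", L)
  bk2f <- lstm_backward(f2, p$l2f_W, p$l2f_U, p$l2f_b, H2, rmask2f, none, dh2f)
  bk2b <- lstm_backward(b2, p$l2b_W, p$l2b_U, p$l2b_b, H2, rmask2b, none, dh2b)

  dseq1 <- lapply(seq_len(L), function(l) bk2f$dxs[[l]] + bk2b$dxs[[l]])
  dh1f <- lapply(dseq1, function(m) m[, 1:H1, drop = FALSE])
  dh1b <- lapply(dseq1, function(m) m[, (H1 + 1L):(2L * H1), drop = FALSE])
  bk1f <- lstm_backward(f1, p$l1f_W, p$l1f_U, p$l1f_b, H1, rmask1f, dh1f)
  bk1b <- lstm_backward(b1, p$l1b_W, p$l1b_U, p$l1b_b, H1, rmask1b, dh1b)

  grads <- list(
    l1f_W = bk1f$gW, l1f_U = bk1f$gU, l1f_b = bk1f$gb,
    l1b_W = bk1b$gW, l1b_U = bk1b$gU, l1b_b = bk1b$gb,
    l2f_W = bk2f$gW, l2f_U = bk2f$gU, l2f_b = bk2f$gb,
    l2b_W = bk2b$gW, l2b_U = bk2b$gU, l2b_b = bk2b$gb,
    bn_gamma = g_gamma, bn_beta = g_beta,
    Wo = gWo, bo = gbo
  )
  list(probs = probs, loss = loss, grads = grads, extra = extra)
}
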