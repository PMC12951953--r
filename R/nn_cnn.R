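# CNN base model: 256 width-1 convolution kernels over the framed input,
# a separable convolution (depthwise width 3 + pointwise, 128 filters),
# global max pooling, dropout 0.3 and a dense sigmoid head, with L2
# weight decay (lambda = 0.001). Forward and backward passes are written
# against the stacked-frame layout ((L*B) x channels).

cnn_init <- function(config, c_in) {
  F1 <- config$filters1
  F2 <- config$sep_filters
  list(
    W1 = glorot(c_in, F1), b1 = rep(0, F1),
    dw1 = stats::runif(F1, -0.5, 0.5), dw2 = stats::runif(F1, -0.5, 0.5),
    dw3 = stats::runif(F1, -0.5, 0.5),
    Wp = glorot(F1, F2), bp = rep(0, F2),
    Wo = glorot(F2, 1L), bo = 0
  )
}

cnn_weight_names <- c("W1", "dw1", "dw2", "dw3", "Wp", "Wo")

cnn_pass <- function(net, Xb, yb, train) {
  p <- net$params
  cfg <- net$config
  B <- nrow(Xb)
  L <- net$L
  F1 <- cfg$filters1; F2 <- cfg$sep_filters
  Xf <- frame_stack(Xb, L, net$c)

  Z1 <- sweep(Xf %*% p$W1, 2, p$b1, `+`)
  A1 <- relu(Z1)
  Sp <- shift_blocks(A1, L, B, -1L)   # A1 at l-1
  Sn <- shift_blocks(A1, L, B, +1L)   # A1 at l+1
  D <- sweep(Sp, 2, p$dw1, `*`) + sweep(A1, 2, p$dw2, `*`) +
       sweep(Sn, 2, p$dw3, `*`)
  Z2 <- sweep(D %*% p$Wp, 2, p$bp, `+`)
  A2 <- relu(Z2)

  # global max pooling over timesteps
  P <- A2[block_rows(1L, B), , drop = FALSE]
  argm <- matrix(1L, B, F2)
  if (L > 1) {
    for (l in 2:L) {
      cand <- A2[block_rows(l, B), , drop = FALSE]
      upd <- cand > P
      P[upd] <- cand[upd]
      argm[upd] <- l
    }
  }

  mask <- NULL
  Pd <- P
  if (train && cfg$dropout > 0) {
    keep <- 1 - cfg$dropout
    mask <- matrix(stats::rbinom(B * F2, 1L, keep) / keep, B, F2)
    Pd <- P * mask
  }
  z <- Pd %*% p$Wo + p$bo
  probs <- as.vector(sigmoid(z))
  if (is.null(yb)) return(list(probs = probs))

  lam <- cfg$l2_lambda
  loss <- bce_loss(probs, yb) + l2_penalty(p, lam, cnn_weight_names)

  dz <- matrix((probs - yb) / B, B, 1L)
  gWo <- crossprod(Pd, dz) + lam * p$Wo
  gbo <- sum(dz)
  dPd <- dz %*% t(p$Wo)
  dP <- if (is.null(mask)) dPd else dPd * mask

  dA2 <- matrix(0, L * B, F2)
  rows_mat <- (argm - 1L) * B + matrix(seq_len(B), B, F2)
  dA2[cbind(as.vector(rows_mat), as.vector(col(argm)))] <- as.vector(dP)

  dZ2 <- dA2 * (Z2 > 0)
  gWp <- crossprod(D, dZ2) + lam * p$Wp
  gbp <- colSums(dZ2)
  dD <- dZ2 %*% t(p$Wp)

  gdw1 <- colSums(Sp * dD) + lam * p$dw1
  gdw2 <- colSums(A1 * dD) + lam * p$dw2
  gdw3 <- colSums(Sn * dD) + lam * p$dw3

  dA1 <- sweep(shift_blocks(dD, L, B, +1L), 2, p$dw1, `*`) +
         sweep(dD, 2, p$dw2, `*`) +
         sweep(shift_blocks(dD, L, B, -1L), 2, p$dw3, `*`)
  dZ1 <- dA1 * (Z1 > 0)
  gW1 <- crossprod(Xf, dZ1) + lam * p$W1
  gb1 <- colSums(dZ1)

  grads <- list(W1 = gW1, b1 = gb1, dw1 = gdw1, dw2 = gdw2, dw3 = gdw3,
                Wp = gWp, bp = gbp, Wo = gWo, bo = gbo)
  list(probs = probs, loss = loss, grads = grads)
}
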