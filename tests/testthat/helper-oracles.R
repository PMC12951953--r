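# Independent brute-force re-implementations of every encoder and metric,
# written as direct definition transcriptions (character loops, no shared
# code with the package internals). Used as oracles in the equivalence
# tests.

o_bases <- c("A", "C", "G", "T")
o_eiip <- c(A = 0.1260, C = 0.1340, G = 0.0806, T = 0.1335)
o_ncp <- list(A = c(1, 1, 1), C = c(0, 1, 0), G = c(1, 0, 0), T = c(0, 0, 1))

o_chars <- function(s) strsplit(s, "")[[1]]

o_binary <- function(s) {
  out <- c()
  for (ch in o_chars(s)) {
    v <- rep(0, 4)
    if (ch %in% o_bases) v[match(ch, o_bases)] <- 1
    out <- c(out, v)
  }
  out
}

o_ncp_enc <- function(s) {
  out <- c()
  for (ch in o_chars(s)) {
    out <- c(out, if (ch %in% o_bases) o_ncp[[ch]] else c(0, 0, 0))
  }
  out
}

o_eiip_enc <- function(s) {
  vapply(o_chars(s), function(ch) if (ch %in% o_bases) o_eiip[[ch]] else 0,
         numeric(1), USE.NAMES = FALSE)
}

o_anf <- function(s) {
  b <- o_chars(s)
  out <- numeric(length(b))
  for (i in seq_along(b)) {
    if (b[i] %in% o_bases) {
      out[i] <- sum(b[seq_len(i)] == b[i]) / i
    } else {
      out[i] <- 0
    }
  }
  out
}

o_enac <- function(s, w = 5) {
  b <- o_chars(s)
  out <- c()
  for (st in seq_len(length(b) - w + 1)) {
    win <- b[st:(st + w - 1)]
    valid <- sum(win %in% o_bases)
    frac <- vapply(o_bases, function(bb) {
      if (valid == 0) 0 else sum(win == bb) / valid
    }, numeric(1))
    out <- c(out, frac)
  }
  out
}

o_all_kmers <- function(k) {
  if (k == 1) return(o_bases)
  sub <- o_all_kmers(k - 1)
  unlist(lapply(sub, function(p) paste0(p, o_bases)))
}

o_kmer <- function(s, k) {
  kms <- o_all_kmers(k)
  cnt <- setNames(rep(0, length(kms)), kms)
  total <- 0
  for (i in seq_len(nchar(s) - k + 1)) {
    km <- substr(s, i, i + k - 1)
    if (!grepl("N", km)) {
      cnt[km] <- cnt[km] + 1
      total <- total + 1
    }
  }
  if (total == 0) return(unname(cnt))
  unname(cnt / total)
}

o_nac <- function(s) o_kmer(s, 1)
o_tnc <- function(s) o_kmer(s, 3)

o_pseeiip <- function(s) {
  f <- o_tnc(s)
  kms <- o_all_kmers(3)
  esum <- vapply(kms, function(t) sum(o_eiip[o_chars(t)]), numeric(1))
  unname(f * esum)
}

o_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[o_chars(s)]), collapse = "")
}

o_rckmer <- function(s, k = 3) {
  kms <- o_all_kmers(k)
  canon <- vapply(kms, function(km) min(km, o_revcomp(km)), character(1))
  classes <- sort(unique(canon))
  cnt <- setNames(rep(0, length(classes)), classes)
  total <- 0
  for (i in seq_len(nchar(s) - k + 1)) {
    km <- substr(s, i, i + k - 1)
    if (!grepl("N", km)) {
      cnt[min(km, o_revcomp(km))] <- cnt[min(km, o_revcomp(km))] + 1
      total <- total + 1
    }
  }
  if (total == 0) return(unname(cnt))
  unname(cnt / total)
}

o_cksnap <- function(s, k_max = 5) {
  b <- o_chars(s)
  pairs <- unlist(lapply(o_bases, function(x) paste0(x, o_bases)))
  out <- c()
  for (g in 0:k_max) {
    cnt <- setNames(rep(0, 16), pairs)
    total <- 0
    for (i in seq_len(length(b) - g - 1)) {
      x <- b[i]; y <- b[i + g + 1]
      if (x %in% o_bases && y %in% o_bases) {
        cnt[paste0(x, y)] <- cnt[paste0(x, y)] + 1
        total <- total + 1
      }
    }
    out <- c(out, if (total == 0) unname(cnt) else unname(cnt / total))
  }
  out
}

# default property table, recomputed independently: EIIP sum and GC count
# per trimer, z-standardised over the 64 trimers
o_props <- function() {
  kms <- o_all_kmers(3)
  p1 <- vapply(kms, function(t) sum(o_eiip[o_chars(t)]), numeric(1))
  p2 <- vapply(kms, function(t) sum(o_chars(t) %in% c("G", "C")), numeric(1))
  std <- function(v) (v - mean(v)) / stats::sd(v)
  m <- cbind(std(p1), std(p2))
  rownames(m) <- kms
  m
}

o_trimer_series <- function(s) {
  n <- nchar(s) - 2
  vapply(seq_len(n), function(i) substr(s, i, i + 2), character(1))
}

o_pcpsetnc <- function(s, lambda = 2, w = 0.1) {
  props <- o_props()
  tri <- o_trimer_series(s)
  ok <- !grepl("N", tri)
  f <- o_tnc(s)
  theta <- numeric(lambda)
  for (j in seq_len(lambda)) {
    vals <- c()
    for (i in seq_len(length(tri) - j)) {
      if (ok[i] && ok[i + j]) {
        d <- mean((props[tri[i], ] - props[tri[i + j], ])^2)
        vals <- c(vals, d)
      }
    }
    theta[j] <- if (length(vals)) mean(vals) else 0
  }
  denom <- sum(f) + w * sum(theta)
  if (denom == 0) denom <- 1
  c(f / denom, w * theta / denom)
}

o_scpsetnc <- function(s, lambda = 2, w = 0.1) {
  props <- o_props()
  tri <- o_trimer_series(s)
  ok <- !grepl("N", tri)
  f <- o_tnc(s)
  tau <- c()
  for (j in seq_len(lambda)) {
    for (u in seq_len(ncol(props))) {
      vals <- c()
      for (i in seq_len(length(tri) - j)) {
        if (ok[i] && ok[i + j]) {
          vals <- c(vals, props[tri[i], u] * props[tri[i + j], u])
        }
      }
      tau <- c(tau, if (length(vals)) mean(vals) else 0)
    }
  }
  denom <- sum(f) + w * sum(tau)
  if (denom == 0) denom <- 1
  c(f / denom, w * tau / denom)
}

o_tac <- function(s, lag = 2) {
  props <- o_props()
  tri <- o_trimer_series(s)
  ok <- !grepl("N", tri)
  out <- c()
  for (u in seq_len(ncol(props))) {
    vals_u <- props[tri[ok], u]
    mu <- if (length(vals_u)) mean(vals_u) else 0
    for (l in seq_len(lag)) {
      vals <- c()
      for (i in seq_len(length(tri) - l)) {
        if (ok[i] && ok[i + l]) {
          vals <- c(vals, (props[tri[i], u] - mu) * (props[tri[i + l], u] - mu))
        }
      }
      out <- c(out, if (length(vals)) mean(vals) else 0)
    }
  }
  out
}

oracle_encoders <- list(
  ENAC = function(s) o_enac(s, 5),
  Binary = o_binary,
  NCP = o_ncp_enc,
  EIIP = o_eiip_enc,
  Kmer = function(s) o_kmer(s, 2),
  CKSNAP = function(s) o_cksnap(s, 5),
  PseEIIP = o_pseeiip,
  TNC = o_tnc,
  RCKmer = function(s) o_rckmer(s, 3),
  SCPseTNC = function(s) o_scpsetnc(s, 2, 0.1),
  PCPseTNC = function(s) o_pcpsetnc(s, 2, 0.1),
  ANF = o_anf,
  NAC = o_nac,
  TAC = function(s) o_tac(s, 2)
)

## ---- metric oracles ---------------------------------------------------

oracle_metrics <- function(y, score, threshold = 0.5) {
  tp <- tn <- fp <- fn <- 0
  for (i in seq_along(y)) {
    pred <- if (score[i] >= threshold) 1 else 0
    if (pred == 1 && y[i] == 1) tp <- tp + 1
    if (pred == 0 && y[i] == 0) tn <- tn + 1
    if (pred == 1 && y[i] == 0) fp <- fp + 1
    if (pred == 0 && y[i] == 1) fn <- fn + 1
  }
  acc <- (tp + tn) / length(y)
  sn <- if (tp + fn > 0) tp / (tp + fn) else 0
  sp <- if (tn + fp > 0) tn / (tn + fp) else 0
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den > 0) (tp * tn - fp * fn) / den else 0
  list(TP = tp, TN = tn, FP = fp, FN = fn,
       ACC = acc, SN = sn, SP = sp, F1 = f1, MCC = mcc)
}

# AUC by exhaustive pairwise comparison (Mann-Whitney), ties count 1/2
oracle_auc <- function(y, score) {
  pos <- score[y == 1]
  neg <- score[y == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

## ---- shared fixtures --------------------------------------------------

random_window <- function(L = 41, n_prob = 0) {
  paste(sample(c("A", "C", "G", "T", if (n_prob > 0) "N"),
               L, replace = TRUE,
               prob = c(rep((1 - n_prob) / 4, 4), if (n_prob > 0) n_prob)),
        collapse = "")
}

fast_protocol <- function(seed = 1L, epochs = 4L) {
  training_protocol(epochs = epochs, batch_size = 32L, patience = Inf,
                    seed = seed)
}

# miniature layer sizes with a faster learning rate, so behavioral tests
# converge in a handful of epochs
tiny_arch <- function(kind) {
  switch(kind,
    CNN = architecture_config("CNN", filters1 = 16L, sep_filters = 8L,
                              frames = 4L, lr = 1e-2),
    BiLSTM = architecture_config("BiLSTM", units1 = 8L, units2 = 4L,
                                 frames = 4L, lr = 1e-2),
    Transformer = architecture_config("Transformer", d_model = 8L,
                                      ffn_dim = 16L, n_layers = 1L,
                                      frames = 4L, lr = 1e-2)
  )
}
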