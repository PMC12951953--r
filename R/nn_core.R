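# Minimal deep-learning core: BLAS-backed forward/backward passes for the
# three base architectures, trained with Adam, exponential learning-rate
# decay and global-norm gradient clipping. Everything is deterministic
# given the protocol seed and single-threaded BLAS.

#' Architecture configuration for a base model
#'
#' Returns the hyperparameter set for one of the three base architectures
#' with the published defaults: CNN with 256 width-1 convolution kernels, a
#' separable convolution of 128 filters (width 3), global max pooling, L2
#' regularization (lambda = 0.001) and dropout 0.3; a two-layer
#' bidirectional LSTM (128 then 64 units) with recurrent dropout 0.1 and
#' batch normalization; a Transformer encoder with 2-head self-attention,
#' a 64-unit feed-forward sublayer and layer normalization (eps = 1e-6).
#' All models end in a sigmoid head and are optimized with Adam
#' (initial learning rate 1e-3, exponential decay factor 0.9 applied
#' every `lr_decay_every` epochs - default 2 - and gradient clipping
#' threshold 1.0).
#'
#' The fused feature vector is reshaped into a short sequence of
#' fixed-width frames (`frames` timesteps, each holding
#' `ceiling(input_dim / frames)` feature channels) before entering the
#' sequence layers; see the methods vignette for the rationale.
#'
#' @param kind One of "CNN", "BiLSTM", "Transformer".
#' @param ... Overrides for any listed hyperparameter (used mainly by unit
#'   tests with miniature layer sizes).
#' @return A list of class `architecture_config`.
#' @export
architecture_config <- function(kind = c("CNN", "BiLSTM", "Transformer"), ...) {
  kind <- match.arg(kind)
  base <- list(kind = kind, lr = 1e-3, lr_decay = 0.9,
               lr_decay_every = 2L, grad_clip = 1.0)
  spec <- switch(kind,
    CNN = list(filters1 = 256L, sep_filters = 128L, dropout = 0.3,
               l2_lambda = 0.001, frames = 16L),
    BiLSTM = list(units1 = 128L, units2 = 64L, recurrent_dropout = 0.1,
                  l2_lambda = 0, frames = 8L),
    Transformer = list(heads = 2L, ffn_dim = 64L, d_model = 32L,
                       n_layers = 2L, layernorm_eps = 1e-6,
                       l2_lambda = 0, frames = 16L)
  )
  cfg <- utils::modifyList(c(base, spec), list(...))
  num <- cfg[vapply(cfg, is.numeric, logical(1))]
  nonneg <- c("l2_lambda", "dropout", "recurrent_dropout")
  if (any(unlist(num[nonneg]) < 0) ||
      any(unlist(num[setdiff(names(num), nonneg)]) <= 0)) {
    abort("numeric hyperparameters must be strictly positive",
          class = "stack4mc_contract_error")
  }
  structure(cfg, class = "architecture_config")
}

#' Training protocol for base models
#'
#' @param folds Cross-validation folds (default 5).
#' @param epochs Training epochs (default 30).
#' @param batch_size Minibatch size (default 256).
#' @param patience Early-stopping patience on validation loss when a
#'   validation split is available; `Inf` disables early stopping.
#' @param seed Integer seed recorded in every trained artifact.
#' @return A list of class `training_protocol`.
#' @export
training_protocol <- function(folds = 5L, epochs = 30L, batch_size = 256L,
                              patience = 5L, seed = 1L) {
  structure(list(folds = as.integer(folds), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), patience = patience,
                 seed = as.integer(seed)),
            class = "training_protocol")
}

## ---- small shared pieces ----------------------------------------------

sigmoid <- function(z) 1 / (1 + exp(-pmin(pmax(z, -30), 30)))

glorot <- function(n_in, n_out) {
  s <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -s, s), n_in, n_out)
}

# frame a batch: B x d -> (L*B) x c stacked by timestep blocks (block l
# holds rows for all samples at timestep l); zero-pads d up to L*c.
frame_stack <- function(X, L, c) {
  B <- nrow(X)
  d <- ncol(X)
  out <- matrix(0, L * B, c)
  for (l in seq_len(L)) {
    lo <- (l - 1L) * c + 1L
    hi <- min(l * c, d)
    if (lo <= d) {
      out[((l - 1L) * B + 1L):(l * B), seq_len(hi - lo + 1L)] <-
        X[, lo:hi, drop = FALSE]
    }
  }
  out
}

block_rows <- function(l, B) ((l - 1L) * B + 1L):(l * B)

# shift timestep blocks: dir = +1 means block l <- block l+1 (zeros at end)
shift_blocks <- function(M, L, B, dir) {
  out <- matrix(0, nrow(M), ncol(M))
  if (dir == 1L) {
    if (L > 1) out[block_rows_range(1L, L - 1L, B), ] <-
        M[block_rows_range(2L, L, B), , drop = FALSE]
  } else {
    if (L > 1) out[block_rows_range(2L, L, B), ] <-
        M[block_rows_range(1L, L - 1L, B), , drop = FALSE]
  }
  out
}

block_rows_range <- function(l1, l2, B) ((l1 - 1L) * B + 1L):(l2 * B)

relu <- function(z) z * (z > 0)

bce_loss <- function(p, y) {
  eps <- 1e-12
  -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
}

# sum of squares over weight matrices (biases and norm params excluded)
l2_penalty <- function(params, lambda, weight_names) {
  if (lambda == 0) return(0)
  lambda / 2 * sum(vapply(weight_names, function(nm) sum(params[[nm]]^2),
                          numeric(1)))
}

flatten_norm <- function(grads) {
  sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
}

clip_grads <- function(grads, threshold) {
  nrm <- flatten_norm(grads)
  if (is.finite(threshold) && nrm > threshold) {
    grads <- lapply(grads, function(g) g * (threshold / nrm))
  }
  grads
}

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_update <- function(params, grads, state, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

## ---- generic network object -------------------------------------------

#' Build an untrained base model
#'
#' @param config An [architecture_config()].
#' @param input_dim Number of input features (columns of the fused feature
#'   matrix), at least 1.
#' @param seed Seed for parameter initialization.
#' @return An object of class `nn_model` holding initialized parameters.
#' @export
nn_build <- function(config, input_dim, seed = 1L) {
  if (!inherits(config, "architecture_config")) {
    abort("config must be an architecture_config", class = "stack4mc_contract_error")
  }
  if (input_dim < 1) abort("input_dim must be >= 1", class = "stack4mc_contract_error")
  L <- min(config$frames, input_dim)
  c <- as.integer(ceiling(input_dim / L))
  old <- .Random.seed_exists(); on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  params <- switch(config$kind,
    CNN = cnn_init(config, c),
    BiLSTM = bilstm_init(config, c),
    Transformer = transformer_init(config, c, L)
  )
  structure(list(config = config, input_dim = as.integer(input_dim),
                 L = as.integer(L), c = c, params = params,
                 extra = nn_init_extra(config), trained = FALSE,
                 history = NULL, seed = as.integer(seed)),
            class = "nn_model")
}

nn_init_extra <- function(config) {
  if (config$kind == "BiLSTM") {
    H <- 2L * config$units2
    list(bn_mean = rep(0, H), bn_var = rep(1, H), bn_momentum = 0.9)
  } else list()
}

nn_batch_pass <- function(net, Xb, yb = NULL, train = FALSE) {
  switch(net$config$kind,
    CNN = cnn_pass(net, Xb, yb, train),
    BiLSTM = bilstm_pass(net, Xb, yb, train),
    Transformer = transformer_pass(net, Xb, yb, train)
  )
}

#' Train a base model
#'
#' Minibatch Adam with per-epoch exponential learning-rate decay (factor
#' `lr_decay` from `lr`) and global-norm gradient clipping. When a
#' validation set is supplied, validation loss is monitored for early
#' stopping and the best-epoch parameters are restored.
#'
#' @param net An `nn_model` from [nn_build()].
#' @param X Numeric feature matrix (rows = samples).
#' @param y Binary labels.
#' @param protocol A [training_protocol()].
#' @param validation Optional `list(X = , y = )` held-out split.
#' @return The trained `nn_model` with a `history` tibble.
#' @export
nn_train <- function(net, X, y, protocol = training_protocol(), validation = NULL) {
  X <- as_plain_matrix(X)
  if (nrow(X) == 0) abort("no training samples", class = "stack4mc_contract_error")
  if (nrow(X) != length(y)) abort("rows(X) != length(y)", class = "stack4mc_contract_error")
  if (length(unique(y)) < 2) abort("training labels contain a single class",
                                   class = "stack4mc_training_error")
  if (ncol(X) != net$input_dim) {
    abort(sprintf("dimension mismatch: model expects %d features, got %d",
                  net$input_dim, ncol(X)), class = "stack4mc_contract_error")
  }
  old <- .Random.seed_exists(); on.exit(restore_rng(old), add = TRUE)
  set.seed(derive_seed(protocol$seed, paste0("train-", net$config$kind)))
  n <- nrow(X)
  state <- adam_state(net$params)
  best <- list(loss = Inf, params = net$params, extra = net$extra, epoch = 0L)
  waited <- 0L
  hist <- vector("list", protocol$epochs)
  for (epoch in seq_len(protocol$epochs)) {
    lr <- net$config$lr *
      net$config$lr_decay^((epoch - 1L) %/% (net$config$lr_decay_every %||% 1L))
    ord <- sample.int(n)
    batch_starts <- seq(1L, n, by = protocol$batch_size)
    ep_loss <- 0
    for (s in batch_starts) {
      idx <- ord[s:min(s + protocol$batch_size - 1L, n)]
      out <- nn_batch_pass(net, X[idx, , drop = FALSE], y[idx], train = TRUE)
      net$extra <- out$extra %||% net$extra
      grads <- clip_grads(out$grads, net$config$grad_clip)
      upd <- adam_update(net$params, grads, state, lr)
      net$params <- upd$params
      state <- upd$state
      ep_loss <- ep_loss + out$loss * length(idx)
    }
    ep_loss <- ep_loss / n
    val_loss <- NA_real_
    if (!is.null(validation)) {
      vp <- nn_predict(net, validation$X)
      val_loss <- bce_loss(vp, validation$y)
      if (val_loss < best$loss - 1e-6) {
        best <- list(loss = val_loss, params = net$params, extra = net$extra,
                     epoch = epoch)
        waited <- 0L
      } else {
        waited <- waited + 1L
      }
    }
    hist[[epoch]] <- tibble(epoch = epoch, lr = lr, train_loss = ep_loss,
                            val_loss = val_loss)
    if (!is.null(validation) && waited >= protocol$patience) break
  }
  if (!is.null(validation) && is.finite(best$loss)) {
    net$params <- best$params
    net$extra <- best$extra
  }
  net$trained <- TRUE
  net$history <- dplyr::bind_rows(hist[!vapply(hist, is.null, logical(1))])
  net
}

#' Predict probabilities from a base model
#'
#' @param net A trained `nn_model`.
#' @param X Feature matrix with the same number of columns the model was
#'   built for.
#' @param chunk Rows per inference chunk.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
nn_predict <- function(net, X, chunk = 1024L) {
  X <- as_plain_matrix(X)
  if (ncol(X) != net$input_dim) {
    abort(sprintf("dimension mismatch: model expects %d features, got %d",
                  net$input_dim, ncol(X)), class = "stack4mc_contract_error")
  }
  if (nrow(X) == 0) return(numeric(0))
  starts <- seq(1L, nrow(X), by = chunk)
  unlist(lapply(starts, function(s) {
    idx <- s:min(s + chunk - 1L, nrow(X))
    nn_batch_pass(net, X[idx, , drop = FALSE], NULL, train = FALSE)$probs
  }))
}

as_plain_matrix <- function(X) {
  if (inherits(X, "feature_matrix")) {
    attr(X, "block_map") <- NULL
    class(X) <- "matrix"
  }
  as.matrix(X)
}
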