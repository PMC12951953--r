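# Unit tests for the three base architectures and the training machinery.
# Gradient correctness is checked by central finite differences on
# miniature layer sizes; behavioral checks use small separable/shuffled
# datasets.

nn_batch_pass <- stack4mc:::nn_batch_pass

grad_check_max_err <- function(cfg, n_per_param = 4L) {
  set.seed(41)
  d <- 7L; B <- 5L
  X <- matrix(rnorm(B * d), B, d)
  y <- c(1, 0, 1, 1, 0)
  net <- nn_build(cfg, d, seed = 2)
  out <- nn_batch_pass(net, X, y, train = TRUE)
  eps <- 1e-5
  maxerr <- 0
  for (nm in names(net$params)) {
    for (i in seq_len(min(length(net$params[[nm]]), n_per_param))) {
      n2 <- net
      n2$params[[nm]][i] <- net$params[[nm]][i] + eps
      lp <- nn_batch_pass(n2, X, y, train = TRUE)$loss
      n2$params[[nm]][i] <- net$params[[nm]][i] - eps
      lm <- nn_batch_pass(n2, X, y, train = TRUE)$loss
      maxerr <- max(maxerr, abs((lp - lm) / (2 * eps) - out$grads[[nm]][i]))
    }
  }
  maxerr
}

test_that("analytic gradients match finite differences for all architectures", {
  expect_lt(grad_check_max_err(
    architecture_config("CNN", filters1 = 6L, sep_filters = 4L, frames = 3L,
                        dropout = 0)), 1e-6)
  expect_lt(grad_check_max_err(
    architecture_config("BiLSTM", units1 = 4L, units2 = 3L, frames = 3L,
                        recurrent_dropout = 0)), 1e-6)
  expect_lt(grad_check_max_err(
    architecture_config("Transformer", d_model = 4L, ffn_dim = 5L,
                        n_layers = 2L, frames = 3L, heads = 2L)), 1e-6)
})

test_that("architecture defaults carry the published hyperparameters", {
  cnn <- architecture_config("CNN")
  expect_equal(cnn$filters1, 256L)
  expect_equal(cnn$sep_filters, 128L)
  expect_equal(cnn$l2_lambda, 0.001)
  expect_equal(cnn$dropout, 0.3)
  bl <- architecture_config("BiLSTM")
  expect_equal(bl$units1, 128L)
  expect_equal(bl$units2, 64L)
  expect_equal(bl$recurrent_dropout, 0.1)
  tf <- architecture_config("Transformer")
  expect_equal(tf$heads, 2L)
  expect_equal(tf$ffn_dim, 64L)
  expect_equal(tf$layernorm_eps, 1e-6)
  for (cfg in list(cnn, bl, tf)) {
    expect_equal(cfg$lr, 1e-3)
    expect_equal(cfg$lr_decay, 0.9)
    expect_equal(cfg$grad_clip, 1.0)
  }
  expect_equal(training_protocol()$folds, 5L)
  expect_error(architecture_config("CNN", filters1 = 0L),
               class = "stack4mc_contract_error")
})

test_that("built models respect their configuration and sigmoid range", {
  net <- nn_build(architecture_config("CNN"), 148L)
  expect_equal(dim(net$params$W1), c(net$c, 256L))
  expect_equal(dim(net$params$Wp), c(256L, 128L))
  tf <- nn_build(architecture_config("Transformer", d_model = 8L), 64L)
  # two heads share d_model columns
  expect_equal(dim(tf$params$L1_Wq), c(8L, 8L))
  for (kind in c("CNN", "BiLSTM", "Transformer")) {
    net <- nn_build(tiny_arch(kind), 12L, seed = 3)
    p <- nn_predict(net, matrix(0, 1, 12))
    expect_true(p >= 0 && p <= 1)
  }
  expect_error(nn_build(architecture_config("CNN"), 0L),
               class = "stack4mc_contract_error")
})

test_that("training errors on degenerate inputs", {
  net <- nn_build(tiny_arch("CNN"), 4L)
  expect_error(nn_train(net, matrix(0, 0, 4), integer(0), fast_protocol()),
               class = "stack4mc_contract_error")
  expect_error(nn_train(net, matrix(rnorm(20), 5, 4), rep(1L, 5),
                        fast_protocol()),
               class = "stack4mc_training_error")
  expect_error(nn_predict(nn_build(tiny_arch("CNN"), 4L),
                          matrix(0, 2, 7)),
               class = "stack4mc_contract_error")
})

make_separable <- function(n = 200, d = 10, seed = 11) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  X <- matrix(rnorm(n * d), n, d)
  X[, 1] <- X[, 1] + 3 * y
  list(X = X, y = y)
}

test_that("each architecture fits a linearly separable toy to >= 0.95 accuracy", {
  toy <- make_separable()
  for (kind in c("CNN", "BiLSTM", "Transformer")) {
    net <- nn_build(tiny_arch(kind), ncol(toy$X), seed = 5)
    net <- nn_train(net, toy$X, toy$y, fast_protocol(epochs = 25L))
    acc <- mean((nn_predict(net, toy$X) >= 0.5) == (toy$y == 1))
    expect_gte(acc, 0.95)
  }
})

test_that("shuffled labels stay at chance on held-out data", {
  set.seed(12)
  toy <- make_separable(n = 300)
  y_shuf <- sample(toy$y)
  tr <- 1:200; te <- 201:300
  net <- nn_build(tiny_arch("CNN"), ncol(toy$X), seed = 5)
  net <- nn_train(net, toy$X[tr, ], y_shuf[tr], fast_protocol(epochs = 8L))
  acc <- mean((nn_predict(net, toy$X[te, ]) >= 0.5) == (y_shuf[te] == 1))
  expect_gte(acc, 0.4)
  expect_lte(acc, 0.6)
})

test_that("training is deterministic under a fixed seed and inference is pure", {
  toy <- make_separable(n = 80)
  accs <- vapply(1:2, function(i) {
    net <- nn_build(tiny_arch("BiLSTM"), ncol(toy$X), seed = 9)
    net <- nn_train(net, toy$X, toy$y, fast_protocol(seed = 9, epochs = 3L))
    mean((nn_predict(net, toy$X) >= 0.5) == (toy$y == 1))
  }, numeric(1))
  expect_equal(accs[1], accs[2], tolerance = 1e-6)
  # identical duplicated rows get identical probabilities
  net <- nn_build(tiny_arch("Transformer"), ncol(toy$X), seed = 9)
  net <- nn_train(net, toy$X, toy$y, fast_protocol(seed = 9, epochs = 2L))
  p <- nn_predict(net, toy$X[c(1, 1, 1), ])
  expect_equal(p[1], p[2])
  expect_equal(p[2], p[3])
})

test_that("fit_base_model records five folds of validation accuracy and predicts in range", {
  w <- synth_generate(synthetic_spec(n_pos = 40, n_neg = 40, seed = 3))
  X <- encode_windows(w, "Kmer")
  bm <- fit_base_model(X, w$label, architecture = tiny_arch("CNN"),
                       protocol = fast_protocol(epochs = 3L))
  expect_length(bm$fold_acc, 5L)
  expect_length(bm$oof, 80L)
  p <- predict(bm, X)
  expect_true(all(p >= 0 & p <= 1))
  expect_length(p, 80L)
})

test_that("min-max scaling is fitted on training folds only", {
  X <- matrix(c(0, 1, 2, 100), 4, 1)
  sc <- stack4mc:::minmax_fit(X[1:3, , drop = FALSE])
  Xs <- stack4mc:::minmax_apply(X, sc)
  expect_equal(Xs[1:3, 1], c(0, 0.5, 1))
  expect_gt(Xs[4, 1], 1)  # out-of-range test data maps outside [0,1]
})
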