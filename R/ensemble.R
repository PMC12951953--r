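# Three-tier stacked probabilistic ensemble. Tier I: out-of-fold
# probabilities from the base models (each encoded with its own selected
# encoding set). Tier II: two gradient-boosted tree learners on the
# tier-I probability vectors. Tier III: an elastic-net logistic
# metalearner on the 5-value meta feature (three base probabilities plus
# the two learner outputs). Out-of-fold discipline is applied at every
# tier so no training input for a sample derives from a model that saw it.

BASE_KIND_ORDER <- c("CNN", "BiLSTM", "Transformer")

#' Tier-II gradient-boosted learner configuration
#'
#' Learner A is a depth-wise gradient-boosted tree model (500 boosting
#' rounds, maximum depth 7). Learner B grows trees leaf-wise
#' (loss-guided, 31 leaves) for 300 rounds with an L1 regularization term
#' of 0.2. Learning rates are the respective library conventions, pinned
#' here for reproducibility.
#'
#' @param a_nrounds,a_max_depth,a_eta Learner A settings.
#' @param b_nrounds,b_reg_alpha,b_max_leaves,b_eta Learner B settings.
#' @return A list of class `tier2_config`.
#' @export
tier2_config <- function(a_nrounds = 500L, a_max_depth = 7L, a_eta = 0.3,
                         b_nrounds = 300L, b_reg_alpha = 0.2,
                         b_max_leaves = 31L, b_eta = 0.1) {
  structure(list(a_nrounds = as.integer(a_nrounds),
                 a_max_depth = as.integer(a_max_depth), a_eta = a_eta,
                 b_nrounds = as.integer(b_nrounds), b_reg_alpha = b_reg_alpha,
                 b_max_leaves = as.integer(b_max_leaves), b_eta = b_eta),
            class = "tier2_config")
}

#' Metalearner configuration
#'
#' Elastic-net logistic regression with L1 ratio 0.5 and inverse
#' regularization strength C = 0.6 (mapped to the glmnet penalty as
#' lambda = 1 / (C * n)).
#'
#' @param l1_ratio Elastic-net mixing parameter in `[0, 1]`.
#' @param C Inverse regularization strength.
#' @return A list of class `meta_config`.
#' @export
meta_config <- function(l1_ratio = 0.5, C = 0.6) {
  structure(list(l1_ratio = l1_ratio, C = C), class = "meta_config")
}

#' Out-of-fold tier-I probabilities
#'
#' For each base model, trains on the training part of each stratified
#' fold and predicts the held-out part, so every sample's probability
#' comes from a model whose training folds excluded it. Column order is
#' fixed (CNN, BiLSTM, Transformer).
#'
#' @param windows Labeled windows tibble.
#' @param encoder_sets Named list (per base kind) of encoding-scheme
#'   vectors; `NULL` uses all fourteen schemes for every model.
#' @param protocol A [training_protocol()].
#' @param base_kinds Base models to include (2 or 3 of the canonical
#'   three).
#' @param classifiers Optional named list of classifier objects overriding
#'   the deep models (e.g. [surrogate_classifier()] for fast checks).
#' @param fold_ids Optional fold assignment override.
#' @return List with `P` (n x length(base_kinds) matrix of out-of-fold
#'   probabilities), `fold_ids`, and `fold_acc` per model.
#' @export
oof_tier1 <- function(windows, encoder_sets = NULL,
                      protocol = training_protocol(),
                      base_kinds = BASE_KIND_ORDER,
                      classifiers = NULL, fold_ids = NULL) {
  y <- check_labels(windows)
  base_kinds <- match.arg(base_kinds, BASE_KIND_ORDER, several.ok = TRUE)
  fold_ids <- fold_ids %||% stratified_folds(y, protocol$folds, protocol$seed)
  P <- matrix(NA_real_, nrow(windows), length(base_kinds),
              dimnames = list(NULL, base_kinds))
  fold_acc <- list()
  for (m in base_kinds) {
    X <- encode_windows(windows, encoder_sets[[m]] %||% ENCODER_NAMES)
    clf <- classifiers[[m]] %||% deep_classifier(m, protocol = protocol)
    res <- cv_evaluate(X, y, clf, seed = derive_seed(protocol$seed, m),
                       fold_ids = fold_ids)
    P[, m] <- res$oof
    fold_acc[[m]] <- res$fold_acc
  }
  list(P = P, fold_ids = fold_ids, fold_acc = fold_acc)
}

fit_xgb <- function(P, y, params, nrounds, seed) {
  dtrain <- xgboost::xgb.DMatrix(as_plain_matrix(P), label = y)
  old <- .Random.seed_exists(); on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  xgboost::xgb.train(
    params = c(list(objective = "binary:logistic", nthread = 1,
                    seed = seed), params),
    data = dtrain, nrounds = nrounds, verbose = 0)
}

predict_xgb <- function(model, P) {
  as.vector(stats::predict(model, xgboost::xgb.DMatrix(as_plain_matrix(P))))
}

#' Train the two tier-II gradient-boosted learners
#'
#' Fits both learners on the tier-I probability matrix. Their training
#' predictions for meta-feature assembly are produced out-of-fold with
#' the same folds used at tier I.
#'
#' @param P n x k matrix of tier-I probabilities.
#' @param y Binary labels.
#' @param config A [tier2_config()].
#' @param fold_ids Fold assignment for the out-of-fold predictions.
#' @param seed Seed.
#' @return List with fitted `learner_a`, `learner_b`, out-of-fold vectors
#'   `qa_oof`, `qb_oof`, and `config`.
#' @export
train_tier2 <- function(P, y, config = tier2_config(), fold_ids = NULL,
                        seed = 1L) {
  P <- as_plain_matrix(P)
  if (nrow(P) != length(y)) abort("rows(P) != length(y)",
                                  class = "stack4mc_contract_error")
  if (length(unique(y)) < 2) abort("single-class labels",
                                   class = "stack4mc_training_error")
  pa <- list(max_depth = config$a_max_depth, eta = config$a_eta)
  pb <- list(max_depth = 0L, grow_policy = "lossguide",
             max_leaves = config$b_max_leaves, alpha = config$b_reg_alpha,
             eta = config$b_eta, tree_method = "hist")
  qa <- qb <- rep(NA_real_, length(y))
  if (!is.null(fold_ids)) {
    for (f in sort(unique(fold_ids))) {
      tr <- fold_ids != f
      a <- fit_xgb(P[tr, , drop = FALSE], y[tr], pa, config$a_nrounds,
                   derive_seed(seed, paste0("xgbA", f)))
      b <- fit_xgb(P[tr, , drop = FALSE], y[tr], pb, config$b_nrounds,
                   derive_seed(seed, paste0("xgbB", f)))
      qa[!tr] <- predict_xgb(a, P[!tr, , drop = FALSE])
      qb[!tr] <- predict_xgb(b, P[!tr, , drop = FALSE])
    }
  }
  learner_a <- fit_xgb(P, y, pa, config$a_nrounds, derive_seed(seed, "xgbA"))
  learner_b <- fit_xgb(P, y, pb, config$b_nrounds, derive_seed(seed, "xgbB"))
  if (is.null(fold_ids)) {
    qa <- predict_xgb(learner_a, P)
    qb <- predict_xgb(learner_b, P)
  }
  list(learner_a = learner_a, learner_b = learner_b,
       qa_oof = qa, qb_oof = qb, config = config)
}

#' Assemble the 5-value meta feature
#'
#' @param P n x k tier-I probability matrix.
#' @param qa,qb Tier-II learner output vectors.
#' @return n x (k + 2) matrix, columns ordered (base probabilities...,
#'   qa, qb).
#' @export
assemble_meta <- function(P, qa, qb) {
  P <- as_plain_matrix(P)
  if (nrow(P) != length(qa) || nrow(P) != length(qb)) {
    abort("length mismatch between P, qa, qb", class = "stack4mc_contract_error")
  }
  M <- cbind(P, qa = qa, qb = qb)
  rownames(M) <- NULL
  M
}

#' Train the elastic-net logistic metalearner
#'
#' @param M Meta-feature matrix.
#' @param y Binary labels.
#' @param config A [meta_config()].
#' @return List with the glmnet `fit`, the penalty `lambda` used, and
#'   retrievable `coefficients`.
#' @export
train_meta <- function(M, y, config = meta_config()) {
  M <- as_plain_matrix(M)
  if (nrow(M) != length(y)) abort("rows(M) != length(y)",
                                  class = "stack4mc_contract_error")
  if (length(unique(y)) < 2) abort("single-class labels",
                                   class = "stack4mc_training_error")
  lambda <- 1 / (config$C * nrow(M))
  if (all(apply(M, 2, stats::var) == 0)) {
    # degenerate all-constant meta features: intercept-only model
    prior <- mean(y == 1)
    co <- matrix(c(stats::qlogis(min(max(prior, 1e-12), 1 - 1e-12)),
                   rep(0, ncol(M))), ncol = 1,
                 dimnames = list(c("(Intercept)", colnames(M) %||%
                                     paste0("V", seq_len(ncol(M)))), NULL))
    return(list(fit = NULL, lambda = lambda, config = config,
                coefficients = co, intercept_only = TRUE, prior = prior))
  }
  fit <- glmnet::glmnet(M, factor(y, levels = c(0, 1)), family = "binomial",
                        alpha = config$l1_ratio, lambda = lambda,
                        standardize = FALSE)
  list(fit = fit, lambda = lambda, config = config,
       coefficients = as.matrix(stats::coef(fit, s = lambda)),
       intercept_only = FALSE)
}

predict_meta <- function(meta, M) {
  if (isTRUE(meta$intercept_only)) return(rep(meta$prior, nrow(M)))
  as.vector(stats::predict(meta$fit, as_plain_matrix(M), s = meta$lambda,
                           type = "response"))
}

#' Fit the full stacked ensemble
#'
#' End-to-end training: per-model encoding with each base model's own
#' selected encoder set, out-of-fold tier-I probabilities, tier-II
#' gradient-boosted learners, and the elastic-net metalearner, followed
#' by a refit of every base model on all training data for inference.
#'
#' @param windows Labeled windows tibble.
#' @param encoder_sets Named list (per base kind) of encoding schemes;
#'   `NULL` uses all fourteen for every model. Typically the `f_opt` of a
#'   [dfs_select()] run per model.
#' @param protocol A [training_protocol()].
#' @param base_kinds Base models to stack (the canonical three, or two of
#'   them for structure-ablation runs).
#' @param tier2 A [tier2_config()].
#' @param meta A [meta_config()].
#' @param oof Use out-of-fold stacking (default). `FALSE` switches to the
#'   naive refit-on-all mode for comparison, which is prone to leakage
#'   and flagged in the result.
#' @param classifiers Optional named list of classifier overrides.
#' @param species Species tag stored with the model.
#' @return A `stacked_4mc` model.
#' @export
fit_stacked <- function(windows, encoder_sets = NULL,
                        protocol = training_protocol(),
                        base_kinds = BASE_KIND_ORDER,
                        tier2 = tier2_config(), meta = meta_config(),
                        oof = TRUE, classifiers = NULL, species = "sp") {
  y <- check_labels(windows)
  base_kinds <- match.arg(base_kinds, BASE_KIND_ORDER, several.ok = TRUE)
  if (length(base_kinds) < 1) abort("at least one base model required",
                                    class = "stack4mc_contract_error")
  fold_ids <- stratified_folds(y, protocol$folds, protocol$seed)
  P <- matrix(NA_real_, nrow(windows), length(base_kinds),
              dimnames = list(NULL, base_kinds))
  base_models <- list()
  fold_acc <- list()
  for (m in base_kinds) {
    schemes <- encoder_sets[[m]] %||% ENCODER_NAMES
    X <- encode_windows(windows, schemes)
    clf <- classifiers[[m]] %||% deep_classifier(m, protocol = protocol)
    if (oof) {
      res <- cv_evaluate(X, y, clf, seed = derive_seed(protocol$seed, m),
                         fold_ids = fold_ids)
      P[, m] <- res$oof
      fold_acc[[m]] <- res$fold_acc
    }
    sp_in <- inner_split(y, seq_along(y),
                         seed = derive_seed(protocol$seed, paste0("refit-", m)))
    fitted <- clf$fit(as_plain_matrix(X)[sp_in$train, , drop = FALSE],
                      y[sp_in$train],
                      seed = derive_seed(protocol$seed, paste0("refit-", m)),
                      validation = list(
                        X = as_plain_matrix(X)[sp_in$val, , drop = FALSE],
                        y = y[sp_in$val]))
    if (!oof) P[, m] <- clf$predict(fitted, as_plain_matrix(X))
    base_models[[m]] <- list(clf = clf, model = fitted, schemes = schemes)
  }
  t2 <- train_tier2(P, y, tier2, fold_ids = if (oof) fold_ids else NULL,
                    seed = protocol$seed)
  M <- assemble_meta(P, t2$qa_oof, t2$qb_oof)
  ml <- train_meta(M, y, meta)
  structure(list(
    species = species,
    base_kinds = base_kinds,
    base_models = base_models,
    tier2 = t2, meta = ml,
    fold_ids = fold_ids, fold_acc = fold_acc,
    tier1_oof = P, meta_features = M,
    oof = oof, protocol = protocol,
    fitted = TRUE
  ), class = "stacked_4mc")
}

#' Predict 4mC probabilities with a stacked ensemble
#'
#' Encodes each window with every base model's own encoder set (feature
#' inheritance), runs the refit base models, the tier-II learners and the
#' metalearner. Hard labels use threshold 0.5.
#'
#' @param object A fitted `stacked_4mc` model.
#' @param windows Windows tibble (labels not required).
#' @param ... Unused.
#' @return Tibble with `source_id`, `source_offset`, per-base-model
#'   probabilities, `probability` (ensemble), `label` (0/1).
#' @export
predict.stacked_4mc <- function(object, windows, ...) {
  if (!isTRUE(object$fitted)) abort("model is not fitted",
                                    class = "stack4mc_contract_error")
  P <- matrix(NA_real_, nrow(windows), length(object$base_kinds),
              dimnames = list(NULL, object$base_kinds))
  for (m in object$base_kinds) {
    bm <- object$base_models[[m]]
    X <- encode_windows(windows, bm$schemes)
    P[, m] <- bm$clf$predict(bm$model, as_plain_matrix(X))
  }
  qa <- predict_xgb(object$tier2$learner_a, P)
  qb <- predict_xgb(object$tier2$learner_b, P)
  M <- assemble_meta(P, qa, qb)
  prob <- predict_meta(object$meta, M)
  out <- tibble(
    source_id = windows$source_id %||% sprintf("w%d", seq_len(nrow(windows))),
    source_offset = windows$source_offset %||% 0L
  )
  for (m in object$base_kinds) out[[paste0("p_", tolower(m))]] <- P[, m]
  out$probability <- prob
  out$label <- as.integer(prob >= 0.5)
  out
}

#' @export
print.stacked_4mc <- function(x, ...) {
  cat(sprintf("<stacked_4mc: %s | %s stacking | species %s>\n",
              paste(x$base_kinds, collapse = " + "),
              if (x$oof) "out-of-fold" else "naive", x$species))
  for (m in x$base_kinds) {
    cat(sprintf("  %s: %s\n", m,
                paste(x$base_models[[m]]$schemes, collapse = " + ")))
  }
  invisible(x)
}

#' Cross-validated evaluation of the full stack
#'
#' Evaluates base models and the stacked ensemble with fivefold
#' cross-validation on one dataset: every reported probability (tier I,
#' tier II and the metalearner's) is out-of-fold, so the AUCs estimate
#' held-out performance on all n samples without a separate test split.
#'
#' @inheritParams fit_stacked
#' @return List with `base_auc` (named), `ensemble_auc`, `base_acc`,
#'   `ensemble_metrics` (full metrics tibble), `tier1` and
#'   `meta_oof` probabilities.
#' @export
stacked_cv_evaluate <- function(windows, encoder_sets = NULL,
                                protocol = training_protocol(),
                                base_kinds = BASE_KIND_ORDER,
                                tier2 = tier2_config(), meta = meta_config(),
                                classifiers = NULL) {
  y <- check_labels(windows)
  t1 <- oof_tier1(windows, encoder_sets, protocol, base_kinds, classifiers)
  t2 <- train_tier2(t1$P, y, tier2, fold_ids = t1$fold_ids,
                    seed = protocol$seed)
  M <- assemble_meta(t1$P, t2$qa_oof, t2$qb_oof)
  # metalearner out-of-fold predictions with the same folds
  meta_oof <- rep(NA_real_, length(y))
  for (f in sort(unique(t1$fold_ids))) {
    tr <- t1$fold_ids != f
    ml <- train_meta(M[tr, , drop = FALSE], y[tr], meta)
    meta_oof[!tr] <- predict_meta(ml, M[!tr, , drop = FALSE])
  }
  base_auc <- vapply(colnames(t1$P), function(m) auc_score(y, t1$P[, m]),
                     numeric(1))
  base_acc <- vapply(colnames(t1$P), function(m) {
    mean((t1$P[, m] >= 0.5) == (y == 1))
  }, numeric(1))
  list(base_auc = base_auc, base_acc = base_acc,
       ensemble_auc = auc_score(y, meta_oof),
       ensemble_metrics = compute_metrics(y, meta_oof),
       tier1 = t1$P, meta_oof = meta_oof, fold_ids = t1$fold_ids)
}
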