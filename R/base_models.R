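# Base-model layer: classifier interface shared by the deep models and the
# fast surrogate, per-feature min-max scaling fitted on training folds only,
# stratified cross-validation, and the public train/predict surface.

minmax_fit <- function(X) {
  mn <- apply(X, 2, min)
  mx <- apply(X, 2, max)
  rg <- mx - mn
  rg[rg == 0] <- 1
  list(min = mn, range = rg)
}

minmax_apply <- function(X, sc) {
  sweep(sweep(X, 2, sc$min, `-`), 2, sc$range, `/`)
}

#' Stratified cross-validation fold assignment
#'
#' @param y Binary labels.
#' @param k Number of folds.
#' @param seed Seed controlling the assignment.
#' @return Integer vector of fold ids in `1..k`.
#' @export
stratified_folds <- function(y, k = 5L, seed = 1L) {
  old <- .Random.seed_exists(); on.exit(restore_rng(old), add = TRUE)
  set.seed(derive_seed(seed, "folds"))
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    if (length(idx) < k) {
      abort(sprintf("class %s has fewer samples (%d) than folds (%d)",
                    cls, length(idx), k), class = "stack4mc_stratification_error")
    }
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Deep classifier adapter
#'
#' Wraps one of the three base architectures behind the uniform
#' fit/predict contract used by the feature-selection and ensemble layers.
#' Min-max scaling to `[0, 1]` is fitted on the training rows inside
#' `fit` and replayed at prediction time, so held-out data never
#' influences the scaling.
#'
#' @param kind Architecture kind.
#' @param architecture Optional [architecture_config()] override.
#' @param protocol Optional [training_protocol()] override.
#' @return A `classifier` list with `fit(X, y, seed, validation)` and
#'   `predict(model, X)`.
#' @export
deep_classifier <- function(kind = c("CNN", "BiLSTM", "Transformer"),
                            architecture = NULL, protocol = NULL) {
  kind <- match.arg(kind)
  architecture <- architecture %||% architecture_config(kind)
  protocol <- protocol %||% training_protocol()
  structure(list(
    name = kind,
    fit = function(X, y, seed = protocol$seed, validation = NULL) {
      X <- as_plain_matrix(X)
      sc <- minmax_fit(X)
      Xs <- minmax_apply(X, sc)
      prot <- protocol; prot$seed <- seed
      net <- nn_build(architecture, ncol(X), seed = derive_seed(seed, kind))
      if (!is.null(validation)) {
        validation$X <- minmax_apply(as_plain_matrix(validation$X), sc)
      }
      net <- nn_train(net, Xs, y, prot, validation = validation)
      list(net = net, scaler = sc)
    },
    predict = function(model, X) {
      nn_predict(model$net, minmax_apply(as_plain_matrix(X), model$scaler))
    }
  ), class = "classifier")
}

#' Fast surrogate classifier
#'
#' A ridge-regularized logistic regression honoring the same fit/predict
#' contract as the deep models; deterministic and fast, used to exercise
#' the feature-selection logic and as a pluggable stand-in where a
#' dynamic-selection run does not need deep training.
#'
#' @param lambda Ridge penalty.
#' @return A `classifier` list.
#' @export
surrogate_classifier <- function(lambda = 1e-3) {
  structure(list(
    name = "surrogate",
    fit = function(X, y, seed = 1L, validation = NULL) {
      X <- as_plain_matrix(X)
      sc <- minmax_fit(X)
      Xs <- minmax_apply(X, sc)
      pad <- ncol(Xs) < 2
      if (pad) Xs <- cbind(Xs, 0)
      fit <- glmnet::glmnet(Xs, factor(y, levels = c(0, 1)),
                            family = "binomial", alpha = 0,
                            lambda = lambda, standardize = FALSE)
      list(fit = fit, scaler = sc, pad = pad, lambda = lambda)
    },
    predict = function(model, X) {
      Xs <- minmax_apply(as_plain_matrix(X), model$scaler)
      if (model$pad) Xs <- cbind(Xs, 0)
      as.vector(stats::predict(model$fit, Xs, s = model$lambda,
                               type = "response"))
    }
  ), class = "classifier")
}

resolve_classifier <- function(classifier, architecture = NULL, protocol = NULL) {
  if (inherits(classifier, "classifier")) return(classifier)
  if (is.character(classifier) && length(classifier) == 1) {
    if (classifier == "surrogate") return(surrogate_classifier())
    return(deep_classifier(classifier, architecture, protocol))
  }
  abort("classifier must be a kind name, \"surrogate\", or a classifier object",
        class = "stack4mc_contract_error")
}

# Stratified inner split of a training index set, used for early-stopping
# validation so the held-out fold never influences epoch selection.
inner_split <- function(y, idx, frac = 0.15, seed = 1L) {
  old <- .Random.seed_exists(); on.exit(restore_rng(old), add = TRUE)
  set.seed(derive_seed(seed, "inner"))
  val <- unlist(lapply(unique(y[idx]), function(cls) {
    cand <- idx[y[idx] == cls]
    sample(cand, max(1L, floor(frac * length(cand))))
  }))
  list(train = setdiff(idx, val), val = val)
}

# Cross-validated evaluation of one classifier on one feature matrix.
# Returns per-fold held-out accuracy, out-of-fold probabilities and,
# optionally, the fold models. Early stopping (when the classifier uses a
# validation set) monitors an inner split of the training part only.
cv_evaluate <- function(X, y, classifier, folds = 5L, seed = 1L,
                        keep_models = FALSE, fold_ids = NULL,
                        use_validation = TRUE) {
  X <- as_plain_matrix(X)
  fold_ids <- fold_ids %||% stratified_folds(y, folds, seed)
  k <- max(fold_ids)
  oof <- rep(NA_real_, length(y))
  acc <- numeric(k)
  models <- if (keep_models) vector("list", k) else NULL
  for (f in seq_len(k)) {
    tr_idx <- which(fold_ids != f)
    va <- which(fold_ids == f)
    val <- NULL
    if (use_validation) {
      sp <- inner_split(y, tr_idx, seed = derive_seed(seed, paste0("fold", f)))
      tr_idx <- sp$train
      val <- list(X = X[sp$val, , drop = FALSE], y = y[sp$val])
    }
    m <- classifier$fit(X[tr_idx, , drop = FALSE], y[tr_idx],
                        seed = derive_seed(seed, paste0("fold", f)),
                        validation = val)
    p <- classifier$predict(m, X[va, , drop = FALSE])
    oof[va] <- p
    acc[f] <- mean((p >= 0.5) == (y[va] == 1))
    if (keep_models) models[[f]] <- m
  }
  list(fold_acc = acc, mean_acc = mean(acc), oof = oof,
       fold_ids = fold_ids, models = models)
}

#' Train a base model with fivefold cross-validation
#'
#' Trains one deep base architecture on an encoded feature matrix using
#' stratified fivefold cross-validation (per-fold held-out accuracy is
#' recorded), then refits on all data for inference.
#'
#' @param X Feature matrix (e.g. from [encode_windows()]).
#' @param y Binary labels.
#' @param architecture An [architecture_config()] or kind name.
#' @param protocol A [training_protocol()].
#' @param cv Run the cross-validation pass (set `FALSE` to refit only).
#' @return A `base_model` object with elements `classifier_name`,
#'   `fold_acc`, `oof`, `model`, `encoder_set`, `protocol`.
#' @export
fit_base_model <- function(X, y, architecture = "CNN",
                           protocol = training_protocol(), cv = TRUE) {
  if (is.character(architecture)) architecture <- architecture_config(architecture)
  clf <- deep_classifier(architecture$kind, architecture, protocol)
  cvres <- NULL
  if (cv) {
    cvres <- cv_evaluate(X, y, clf, folds = protocol$folds, seed = protocol$seed)
  }
  full <- clf$fit(as_plain_matrix(X), y, seed = protocol$seed)
  structure(list(
    classifier_name = architecture$kind,
    architecture = architecture,
    protocol = protocol,
    fold_acc = cvres$fold_acc,
    mean_cv_acc = cvres$mean_acc,
    oof = cvres$oof,
    fold_ids = cvres$fold_ids,
    model = full,
    clf = clf,
    encoder_set = attr(X, "block_map")$scheme %||% NULL
  ), class = "base_model")
}

#' Predict probabilities from a trained base model
#' @param object A `base_model` from [fit_base_model()].
#' @param X Feature matrix with matching columns.
#' @param ... Unused.
#' @return Probabilities in `[0, 1]`, one per row of `X`.
#' @export
predict.base_model <- function(object, X, ...) {
  object$clf$predict(object$model, X)
}

#' @export
print.base_model <- function(x, ...) {
  cat(sprintf("<base_model %s>\n", x$classifier_name))
  if (!is.null(x$fold_acc)) {
    cat(sprintf("  CV accuracy: %.4f (folds: %s)\n", x$mean_cv_acc,
                paste(sprintf("%.3f", x$fold_acc), collapse = ", ")))
  }
  invisible(x)
}
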