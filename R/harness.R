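# Evaluation harnesses: leave-one-encoding and leave-one-base-model
# ablation, zero-shot cross-species prediction under the strict
# feature-inheritance protocol, and cross-group k-mer enrichment.

evaluate_stacked <- function(model, windows) {
  y <- check_labels(windows)
  preds <- stats::predict(model, windows)
  compute_metrics(y, preds$probability)
}

metric_delta <- function(full, ablated) {
  metrics <- c("ACC", "SN", "SP", "MCC", "AUC", "F1")
  v_full <- unlist(full[1, metrics])
  v_abl <- unlist(ablated[1, metrics])
  tibble(metric = metrics, full = unname(v_full), ablated = unname(v_abl),
         delta = unname(v_abl - v_full))
}

#' Leave-one-encoding ablation
#'
#' Removes one encoding scheme from every base model whose selected set
#' contains it, retrains the affected stack on the training windows, and
#' reports metric deltas (ablated minus full) on the evaluation split. If
#' the encoding is absent from every base model's set the call is a
#' flagged no-op with exact zero deltas.
#'
#' @param model A fitted `stacked_4mc`.
#' @param windows_train Labeled training windows (the data the model was
#'   fitted on).
#' @param windows_test Labeled evaluation windows.
#' @param encoding Scheme name to remove.
#' @return Tibble with columns `metric`, `full`, `ablated`, `delta`;
#'   attribute `noop` marks the flagged no-op case.
#' @export
ablate_encoding <- function(model, windows_train, windows_test, encoding) {
  encoding <- match.arg(encoding, ENCODER_NAMES)
  full <- evaluate_stacked(model, windows_test)
  uses <- vapply(model$base_kinds, function(m) {
    encoding %in% scheme_names(model$base_models[[m]]$schemes)
  }, logical(1))
  if (!any(uses)) {
    warn(sprintf("encoding %s is not used by any base model; no-op", encoding))
    out <- metric_delta(full, full)
    attr(out, "noop") <- TRUE
    return(out)
  }
  sets <- lapply(model$base_kinds, function(m) {
    sch <- model$base_models[[m]]$schemes
    kept <- sch[scheme_names(sch) != encoding]
    if (length(kept) == 0) {
      abort(sprintf("removing %s would leave base model %s without features",
                    encoding, m), class = "stack4mc_contract_error")
    }
    kept
  })
  names(sets) <- model$base_kinds
  clfs <- lapply(model$base_models, function(b) b$clf)
  refit <- fit_stacked(windows_train, encoder_sets = sets,
                       protocol = model$protocol,
                       base_kinds = model$base_kinds,
                       tier2 = model$tier2$config,
                       meta = model$meta$config,
                       oof = model$oof, classifiers = clfs,
                       species = model$species)
  ablated <- evaluate_stacked(refit, windows_test)
  out <- metric_delta(full, ablated)
  attr(out, "noop") <- FALSE
  out
}

scheme_names <- function(schemes) {
  vapply(lapply(as.list(schemes), as_encoder_spec), function(s) s$name,
         character(1))
}

#' Leave-one-base-model ablation
#'
#' Retrains the stack without one base model: the tier-I matrix then has
#' one column fewer and the meta feature four columns instead of five.
#' Reports metric deltas (ablated minus full) on the evaluation split.
#'
#' @inheritParams ablate_encoding
#' @param excluded One of the fitted model's base kinds.
#' @return Tibble as in [ablate_encoding()]; the refit model is attached
#'   as attribute `refit`.
#' @export
ablate_base_model <- function(model, windows_train, windows_test, excluded) {
  if (length(excluded) != 1 || !excluded %in% model$base_kinds) {
    abort("exactly one fitted base model must be excluded",
          class = "stack4mc_contract_error")
  }
  keep <- setdiff(model$base_kinds, excluded)
  if (length(keep) < 1) {
    abort("exclusion would leave no base model", class = "stack4mc_contract_error")
  }
  full <- evaluate_stacked(model, windows_test)
  sets <- lapply(model$base_models[keep], function(b) b$schemes)
  clfs <- lapply(model$base_models[keep], function(b) b$clf)
  refit <- fit_stacked(windows_train, encoder_sets = sets,
                       protocol = model$protocol, base_kinds = keep,
                       tier2 = model$tier2$config, meta = model$meta$config,
                       oof = model$oof, classifiers = clfs,
                       species = model$species)
  ablated <- evaluate_stacked(refit, windows_test)
  out <- metric_delta(full, ablated)
  attr(out, "refit") <- refit
  out
}

#' Zero-shot cross-species prediction
#'
#' Applies a fitted source-species model to target-species windows with no
#' retraining and no target-specific feature selection: the target
#' sequences are encoded exclusively with the encoding sets optimized for
#' the source species (feature inheritance). The source model is never
#' mutated.
#'
#' @param model Fitted `stacked_4mc` for the source species.
#' @param windows_target Labeled target-species windows.
#' @param target Target species tag recorded in the output.
#' @return One-row tibble: `source`, `target`, `AUC`, `ACC`, and the
#'   inherited `encodings` (list column, per base model).
#' @export
cross_predict <- function(model, windows_target, target = "target") {
  if (!isTRUE(model$fitted)) abort("source model is not fitted",
                                   class = "stack4mc_contract_error")
  y <- windows_target$label
  if (any(is.na(y)) || length(unique(y)) < 2) {
    abort("target windows must contain both classes",
          class = "stack4mc_evaluation_error")
  }
  mets <- evaluate_stacked(model, windows_target)
  tibble(
    source = model$species, target = target,
    AUC = mets$AUC, ACC = mets$ACC,
    encodings = list(lapply(model$base_models, function(b) b$schemes))
  )
}

#' Cross-prediction matrix over a set of species datasets
#'
#' @param models Named list of fitted `stacked_4mc` models (one per source
#'   species).
#' @param datasets Named list of labeled windows tibbles (targets).
#' @return Tibble grid with one row per (source, target) pair.
#' @export
cross_prediction_grid <- function(models, datasets) {
  rows <- purrr::imap(models, function(m, src) {
    purrr::imap(datasets, function(d, tgt) {
      cross_predict(m, d, target = tgt)
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(rows)
}

#' k-mer enrichment between two groups of windows
#'
#' For each k in `k_range` and each k-mer, reports the mean per-sequence
#' frequency in each group, their difference, a two-sided two-proportion
#' z-test on the pooled k-mer counts, and Benjamini-Hochberg q-values
#' corrected within each k family.
#'
#' @param group1,group2 Windows tibbles (non-empty).
#' @param k_range k values, default 3:5.
#' @return Tibble with columns `k`, `kmer`, `freq_group1`, `freq_group2`,
#'   `freq_diff`, `p_value`, `q_value`, sorted by `|freq_diff|` within k.
#' @export
kmer_enrichment <- function(group1, group2, k_range = 3:5) {
  if (nrow(group1) == 0 || nrow(group2) == 0) {
    abort("both groups must be non-empty", class = "stack4mc_contract_error")
  }
  B1 <- window_base_matrix(group1)
  B2 <- window_base_matrix(group2)
  out <- purrr::map(k_range, function(k) {
    c1 <- kmer_counts(B1, k)
    c2 <- kmer_counts(B2, k)
    f1 <- colMeans(normalize_rows(c1))
    f2 <- colMeans(normalize_rows(c2))
    x1 <- colSums(c1); n1 <- sum(x1)
    x2 <- colSums(c2); n2 <- sum(x2)
    p <- vapply(seq_along(x1), function(j) {
      two_prop_z(x1[j], n1, x2[j], n2)
    }, numeric(1))
    tibble(k = k, kmer = kmer_alphabet(k),
           freq_group1 = unname(f1), freq_group2 = unname(f2),
           freq_diff = unname(f1 - f2),
           p_value = p, q_value = stats::p.adjust(p, method = "BH")) |>
      dplyr::arrange(dplyr::desc(abs(.data$freq_diff)))
  })
  dplyr::bind_rows(out)
}

# two-sided two-proportion z-test on pooled counts
two_prop_z <- function(x1, n1, x2, n2) {
  if (n1 == 0 || n2 == 0) return(1)
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  if (se == 0) return(1)
  z <- (x1 / n1 - x2 / n2) / se
  2 * stats::pnorm(-abs(z))
}
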