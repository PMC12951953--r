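# Dynamic feature selection: per (species, model) pair, score every
# candidate encoding by cross-validated single-encoding accuracy, rank
# descending, then evaluate the nested prefix unions F_1..F_n and keep the
# smallest prefix attaining the maximum validation accuracy. The search
# space is exactly |candidates| nested subsets, never 2^|candidates|.

#' Score each candidate encoding by cross-validated accuracy
#'
#' For every candidate scheme, trains the given classifier on that single
#' encoding's features under stratified fivefold cross-validation and
#' records the mean held-out accuracy (the fraction of correct
#' predictions, averaged over folds).
#'
#' @param windows Labeled windows tibble.
#' @param model Classifier: "CNN", "BiLSTM", "Transformer", "surrogate",
#'   or a classifier object.
#' @param candidates Ordered list of scheme names or `encoder_spec`s
#'   (default: the full 14-scheme registry).
#' @param protocol A [training_protocol()].
#' @param species Species tag recorded in the output.
#' @param fold_ids Optional precomputed fold assignment (reused across
#'   candidates; computed from the protocol seed otherwise).
#' @return A tibble of accuracy cells: `species`, `model`, `encoding`,
#'   `acc`, `fold_acc` (list column).
#' @export
score_single_encodings <- function(windows, model = "surrogate",
                                   candidates = ENCODER_NAMES,
                                   protocol = training_protocol(),
                                   species = "sp", fold_ids = NULL) {
  specs <- lapply(as.list(candidates), as_encoder_spec)
  if (length(specs) == 0) abort("candidates must be non-empty",
                                class = "stack4mc_contract_error")
  y <- check_labels(windows)
  clf <- resolve_classifier(model, protocol = protocol)
  fold_ids <- fold_ids %||% stratified_folds(y, protocol$folds, protocol$seed)
  cells <- purrr::map(specs, function(sp) {
    X <- encode_windows(windows, list(sp))
    res <- tryCatch(
      cv_evaluate(X, y, clf, seed = protocol$seed, fold_ids = fold_ids),
      error = function(e) abort(
        sprintf("training failed for candidate %s: %s", sp$name,
                conditionMessage(e)),
        class = "stack4mc_training_error"))
    tibble(species = species, model = clf$name, encoding = sp$name,
           acc = res$mean_acc, fold_acc = list(res$fold_acc),
           spec = list(sp))
  })
  dplyr::bind_rows(cells)
}

check_labels <- function(windows) {
  y <- windows$label
  if (any(is.na(y))) abort("all windows must be labeled",
                           class = "stack4mc_contract_error")
  if (length(unique(y)) < 2) abort("both classes must be present",
                                   class = "stack4mc_training_error")
  as.integer(y)
}

#' Rank encodings by accuracy
#'
#' Stable sort by accuracy descending; ties are broken by registry order
#' (ENAC first, TAC last).
#'
#' @param cells Accuracy-cell tibble from [score_single_encodings()].
#' @return The cells reordered, with a `rank` column; class `dfs_ranking`.
#' @export
rank_encodings <- function(cells) {
  if (anyDuplicated(cells$encoding)) {
    abort("duplicate candidate encodings", class = "stack4mc_contract_error")
  }
  reg_pos <- match(cells$encoding, ENCODER_NAMES)
  ord <- order(-cells$acc, reg_pos)
  out <- cells[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  class(out) <- c("dfs_ranking", class(out))
  out
}

#' Incremental prefix-union feature selection
#'
#' Builds the nested feature subsets F_n (union of the top-n ranked
#' encodings), evaluates each with the same cross-validation folds used
#' for ranking, and selects the smallest n attaining the maximum mean
#' held-out accuracy.
#'
#' @param ranking A `dfs_ranking` covering the candidate set.
#' @param windows Labeled windows tibble (the same data the ranking was
#'   computed on).
#' @param model Classifier specification, as in
#'   [score_single_encodings()].
#' @inheritParams score_single_encodings
#' @return A `dfs_selection` list: `species`, `model`, `trace` (tibble
#'   with `n`, `encoding`, `acc`), `n_star`, `f_opt` (character vector of
#'   the selected encodings, in ranking order), `acc_opt`.
#' @export
incremental_select <- function(ranking, windows, model = "surrogate",
                               protocol = training_protocol(),
                               fold_ids = NULL) {
  y <- check_labels(windows)
  clf <- resolve_classifier(model, protocol = protocol)
  fold_ids <- fold_ids %||% stratified_folds(y, protocol$folds, protocol$seed)
  specs <- lapply(ranking$encoding, encoder_spec_from_cells, cells = ranking)
  blocks <- lapply(specs, function(sp) encode_windows(windows, list(sp)))
  accs <- numeric(length(specs))
  for (n in seq_along(specs)) {
    X <- do.call(cbind, lapply(blocks[seq_len(n)], as_plain_matrix))
    res <- cv_evaluate(X, y, clf, seed = protocol$seed, fold_ids = fold_ids)
    accs[n] <- res$mean_acc
  }
  n_star <- which.max(accs)   # smallest n attaining the maximum
  structure(list(
    species = ranking$species[1],
    model = clf$name,
    trace = tibble(n = seq_along(accs), encoding = ranking$encoding,
                   acc = accs),
    n_star = as.integer(n_star),
    f_opt = ranking$encoding[seq_len(n_star)],
    acc_opt = accs[n_star]
  ), class = "dfs_selection")
}

encoder_spec_from_cells <- function(name, cells) {
  if (!is.null(cells$spec)) {
    hit <- which(cells$encoding == name)
    sp <- cells$spec[[hit[1]]]
    if (inherits(sp, "encoder_spec")) return(sp)
  }
  encoder_spec(name)
}

#' Run dynamic feature selection for one (species, model) pair
#'
#' Convenience wrapper: scores all candidates, ranks them, and runs the
#' incremental prefix search, reusing one stratified fold assignment
#' throughout.
#'
#' @inheritParams score_single_encodings
#' @return A `dfs_selection`; the full accuracy cells are attached as
#'   attribute `cells` and the ranking as attribute `ranking`.
#' @examples
#' \donttest{
#' w <- synth_generate(synthetic_spec(n_pos = 100, n_neg = 100, seed = 1))
#' sel <- dfs_select(w, model = "surrogate",
#'                   candidates = c("Kmer", "NAC", "EIIP"))
#' sel$f_opt
#' }
#' @export
dfs_select <- function(windows, model = "surrogate",
                       candidates = ENCODER_NAMES,
                       protocol = training_protocol(), species = "sp") {
  y <- check_labels(windows)
  fold_ids <- stratified_folds(y, protocol$folds, protocol$seed)
  cells <- score_single_encodings(windows, model, candidates, protocol,
                                  species, fold_ids = fold_ids)
  ranking <- rank_encodings(cells)
  sel <- incremental_select(ranking, windows, model, protocol,
                            fold_ids = fold_ids)
  attr(sel, "cells") <- cells
  attr(sel, "ranking") <- ranking
  sel
}

#' Joint selection objective
#'
#' Sum of the optimal-prefix accuracies over (species, model) pairs. The
#' objective is additive, so pairs optimized independently already attain
#' its maximum; the sum equals `sum over pairs of max(trace accuracy)`.
#'
#' @param results List of `dfs_selection` objects.
#' @return A single number.
#' @export
joint_objective <- function(results) {
  if (length(results) == 0) return(0)
  sum(vapply(results, function(r) r$acc_opt, numeric(1)))
}

#' @export
print.dfs_selection <- function(x, ...) {
  cat(sprintf("<dfs_selection %s / %s>\n", x$species, x$model))
  cat(sprintf("  n* = %d, acc = %.4f\n", x$n_star, x$acc_opt))
  cat("  F_opt:", paste(x$f_opt, collapse = " + "), "\n")
  invisible(x)
}
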