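# Dynamic feature selection logic, exercised with the fast surrogate
# classifier so the tests isolate the selection mechanics from deep
# training.

test_that("scoring yields one accuracy cell per candidate", {
  w <- synth_generate(synthetic_spec(n_pos = 60, n_neg = 60, seed = 31))
  cells <- score_single_encodings(w, candidates = c("Kmer", "NAC", "EIIP"),
                                  protocol = training_protocol(seed = 1))
  expect_equal(nrow(cells), 3L)
  expect_true(all(cells$acc >= 0 & cells$acc <= 1))
  expect_equal(cells$encoding, c("Kmer", "NAC", "EIIP"))
  expect_error(score_single_encodings(w, candidates = list()),
               class = "stack4mc_contract_error")
})

test_that("chance-level and separable oracles bracket the accuracy scale", {
  set.seed(32)
  w <- synth_generate(synthetic_spec(n_pos = 150, n_neg = 150, seed = 33))
  # shuffled labels: every encoding drops to chance
  ws <- w
  ws$label <- sample(ws$label)
  cells <- score_single_encodings(ws, candidates = c("Kmer", "Binary"),
                                  protocol = training_protocol(seed = 2))
  expect_true(all(abs(cells$acc - 0.5) <= 0.1))
  # perfectly informative encoding: label determined by the first base,
  # which the one-hot encoding represents exactly
  w2 <- synth_generate(synthetic_spec(n_pos = 150, n_neg = 150, seed = 34))
  substr(w2$bases, 1, 1) <- ifelse(w2$label == 1, "A", "G")
  cells2 <- score_single_encodings(w2, candidates = "Binary",
                                   protocol = training_protocol(seed = 2))
  expect_gte(cells2$acc, 0.95)
})

test_that("ranking sorts by accuracy with registry-order tie-breaks", {
  cells <- tibble::tibble(
    species = "s", model = "m",
    encoding = c("TAC", "Kmer", "ENAC"),
    acc = c(0.7, 0.9, 0.8))
  r <- rank_encodings(cells)
  expect_equal(r$encoding, c("Kmer", "ENAC", "TAC"))
  expect_equal(r$rank, 1:3)
  # exact ties fall back to registry order (ENAC first ... TAC last)
  tied <- tibble::tibble(species = "s", model = "m",
                         encoding = c("TAC", "NAC", "ENAC"),
                         acc = c(0.5, 0.5, 0.5))
  expect_equal(rank_encodings(tied)$encoding, c("ENAC", "NAC", "TAC"))
  # single candidate
  one <- rank_encodings(cells[2, ])
  expect_equal(one$encoding, "Kmer")
  expect_error(rank_encodings(rbind(cells, cells[1, ])),
               class = "stack4mc_contract_error")
})

test_that("incremental selection breaks ties toward the smallest prefix", {
  w <- synth_generate(synthetic_spec(n_pos = 30, n_neg = 30, seed = 35))
  # a constant classifier makes every prefix accuracy identical, so the
  # parsimony tie-break must select n* = 1
  constant_clf <- structure(list(
    name = "constant",
    fit = function(X, y, seed = 1, validation = NULL) list(),
    predict = function(model, X) rep(0.4, nrow(X))
  ), class = "classifier")
  cells <- score_single_encodings(w, model = constant_clf,
                                  candidates = c("Kmer", "NAC", "EIIP"),
                                  protocol = training_protocol(seed = 6))
  sel <- incremental_select(rank_encodings(cells), w, model = constant_clf,
                            protocol = training_protocol(seed = 6))
  expect_equal(length(unique(sel$trace$acc)), 1L)
  expect_equal(sel$n_star, 1L)
  expect_length(sel$f_opt, 1L)
})

test_that("full DFS equals the exhaustive prefix oracle on a 5-encoding instance", {
  w <- synth_generate(synthetic_spec(n_pos = 250, n_neg = 250, seed = 36))
  candidates <- c("ENAC", "Kmer", "CKSNAP", "NAC", "ANF")
  prot <- training_protocol(seed = 3)
  sel <- dfs_select(w, model = "surrogate", candidates = candidates,
                    protocol = prot)

  # independent oracle: recompute every prefix accuracy from scratch with
  # its own CV loop and take the argmax over all 5 prefixes
  clf <- surrogate_classifier()
  y <- w$label
  fold_ids <- stratified_folds(y, 5, prot$seed)
  ranking <- attr(sel, "ranking")$encoding
  oracle_acc <- vapply(seq_along(ranking), function(n) {
    X <- stack4mc:::as_plain_matrix(encode_windows(w, ranking[seq_len(n)]))
    accs <- vapply(1:5, function(f) {
      tr <- fold_ids != f
      sp <- stack4mc:::inner_split(y, which(tr), seed = stack4mc:::derive_seed(prot$seed, paste0("fold", f)))
      m <- clf$fit(X[sp$train, , drop = FALSE], y[sp$train])
      mean((clf$predict(m, X[!tr, , drop = FALSE]) >= 0.5) == (y[!tr] == 1))
    }, numeric(1))
    mean(accs)
  }, numeric(1))
  expect_equal(sel$trace$acc, oracle_acc, tolerance = 1e-10)
  expect_equal(sel$n_star, which.max(oracle_acc))
  expect_equal(sel$f_opt, ranking[seq_len(sel$n_star)])
  # the invariant Acc(F_n*) >= Acc(F_n) holds on the trace
  expect_true(all(sel$acc_opt >= sel$trace$acc))
  # search space is exactly |candidates| nested subsets
  expect_equal(nrow(sel$trace), length(candidates))
})

test_that("joint objective sums the per-pair optima", {
  r1 <- structure(list(acc_opt = 0.9), class = "dfs_selection")
  r2 <- structure(list(acc_opt = 0.8), class = "dfs_selection")
  expect_equal(joint_objective(list(r1, r2)), 1.7)
  expect_equal(joint_objective(list()), 0)
  # consistency with incremental_select outputs
  w <- synth_generate(synthetic_spec(n_pos = 60, n_neg = 60, seed = 37))
  sel <- dfs_select(w, candidates = c("Kmer", "NAC"),
                    protocol = training_protocol(seed = 4))
  expect_equal(joint_objective(list(sel)), max(sel$trace$acc))
})

test_that("tidy/glance/autoplot expose the selection result", {
  w <- synth_generate(synthetic_spec(n_pos = 40, n_neg = 40, seed = 38))
  sel <- dfs_select(w, candidates = c("Kmer", "NAC"),
                    protocol = training_protocol(seed = 5))
  td <- tidy(sel)
  expect_equal(nrow(td), 2L)
  expect_true(all(c("n", "encoding", "acc", "selected") %in% names(td)))
  gl <- glance(sel)
  expect_equal(gl$n_candidates, 2L)
  p <- autoplot(sel)
  expect_s3_class(p, "ggplot")
})
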