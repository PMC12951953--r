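# Ablation, cross-prediction and k-mer enrichment harnesses, run with the
# surrogate classifiers for speed.

surrogate_trio <- function() {
  list(CNN = surrogate_classifier(), BiLSTM = surrogate_classifier(),
       Transformer = surrogate_classifier())
}

fit_small_stack <- function(windows, schemes = c("Kmer", "ENAC"), seed = 2,
                            species = "synthA") {
  fit_stacked(windows,
              encoder_sets = list(CNN = schemes, BiLSTM = schemes,
                                  Transformer = schemes),
              protocol = training_protocol(seed = seed),
              classifiers = surrogate_trio(), species = species)
}

test_that("removing the informative encoding hurts; unused encodings are no-ops", {
  w <- synth_generate(synthetic_spec(n_pos = 120, n_neg = 120, seed = 61))
  set.seed(62)
  idx <- sample(240, 160)
  model <- fit_small_stack(w[idx, ], schemes = c("ENAC", "NAC"))
  # ENAC carries the planted positional signal; NAC is composition-only
  d <- ablate_encoding(model, w[idx, ], w[-idx, ], "ENAC")
  expect_lt(d$delta[d$metric == "ACC"], 0)
  # encoding absent from every base model: flagged no-op with zero deltas
  expect_warning(d0 <- ablate_encoding(model, w[idx, ], w[-idx, ], "TAC"))
  expect_true(attr(d0, "noop"))
  expect_true(all(d0$delta == 0))
  # removing the last remaining encoding is refused
  m1 <- fit_small_stack(w[idx, ], schemes = "Kmer")
  expect_error(ablate_encoding(m1, w[idx, ], w[-idx, ], "Kmer"),
               class = "stack4mc_contract_error")
})

test_that("base-model ablation shrinks the meta feature to four columns", {
  w <- synth_generate(synthetic_spec(n_pos = 80, n_neg = 80, seed = 63))
  set.seed(64)
  idx <- sample(160, 110)
  model <- fit_small_stack(w[idx, ])
  d <- ablate_base_model(model, w[idx, ], w[-idx, ], "Transformer")
  refit <- attr(d, "refit")
  expect_equal(ncol(refit$meta_features), 4L)
  expect_equal(refit$base_kinds, c("CNN", "BiLSTM"))
  # with three identical surrogates the stack is redundant: dropping one
  # base model must not cost much
  expect_gte(d$delta[d$metric == "AUC"], -0.02)
  expect_error(ablate_base_model(model, w[idx, ], w[-idx, ], "nope"),
               class = "stack4mc_contract_error")
})

test_that("cross-prediction inherits source encodings and never retrains", {
  w <- synth_generate(synthetic_spec(n_pos = 100, n_neg = 100, seed = 65))
  set.seed(66)
  idx <- sample(200, 140)
  model <- fit_small_stack(w[idx, ], species = "src")
  before <- serialize(model, NULL)
  # self-transfer equals standard evaluation on the same split
  cell <- cross_predict(model, w[-idx, ], target = "self")
  mets <- compute_metrics(w$label[-idx], predict(model, w[-idx, ])$probability)
  expect_equal(cell$AUC, mets$AUC)
  expect_equal(cell$ACC, mets$ACC)
  expect_equal(cell$source, "src")
  expect_identical(serialize(model, NULL), before)  # source model unchanged
  expect_equal(unname(vapply(cell$encodings[[1]], function(s) s[1],
                             character(1))),
               rep("Kmer", 3))
  # a target without both classes is an evaluation error
  t1 <- w[-idx, ][w$label[-idx] == 1, ]
  expect_error(cross_predict(model, t1), class = "stack4mc_evaluation_error")
})

test_that("shared-motif species transfer well; unrelated motifs do not", {
  base <- synthetic_spec(n_pos = 150, n_neg = 150, seed = 67)
  fam <- synth_species_family(base, n_species = 4)
  model <- fit_small_stack(fam$sp01, schemes = c("ENAC", "Kmer", "CKSNAP"),
                           species = "sp01")
  within <- cross_predict(model, fam$sp02, target = "sp02")$AUC
  across <- cross_predict(model, fam$sp03, target = "sp03")$AUC
  expect_gt(within, across)
})

test_that("k-mer enrichment flags a constructed extreme and behaves symmetrically", {
  set.seed(68)
  g1 <- synth_generate(synthetic_spec(n_pos = 0, n_neg = 60, seed = 69))
  g2 <- synth_generate(synthetic_spec(n_pos = 0, n_neg = 60, seed = 70))
  # plant GGC into every group-1 window far from the pinned center
  substr(g1$bases, 3, 5) <- "GGC"
  rows <- kmer_enrichment(g1, g2, k_range = 3)
  top <- rows[1, ]
  expect_equal(top$kmer, "GGC")
  expect_gt(top$freq_diff, 0)
  expect_lt(top$q_value, 0.05)
  # swapped groups negate the differences but keep the p-values
  rows_sw <- kmer_enrichment(g2, g1, k_range = 3)
  m <- match(rows$kmer, rows_sw$kmer)
  expect_equal(rows$freq_diff, -rows_sw$freq_diff[m], tolerance = 1e-12)
  expect_equal(rows$p_value, rows_sw$p_value[m], tolerance = 1e-12)
  # identical groups: all differences zero
  rows_id <- kmer_enrichment(g1, g1, k_range = 3:4)
  expect_true(all(rows_id$freq_diff == 0))
  expect_true(all(rows_id$p_value == 1))
})

test_that("enrichment frequencies sum to one per k and q >= p under BH", {
  g1 <- synth_generate(synthetic_spec(n_pos = 30, n_neg = 30, seed = 71))
  g2 <- synth_generate(synthetic_spec(n_pos = 30, n_neg = 30, seed = 72))
  rows <- kmer_enrichment(g1, g2)
  expect_setequal(unique(rows$k), 3:5)
  for (kk in 3:5) {
    sub <- rows[rows$k == kk, ]
    expect_equal(nrow(sub), 4^kk)
    expect_equal(sum(sub$freq_group1), 1, tolerance = 1e-9)
    expect_equal(sum(sub$freq_group2), 1, tolerance = 1e-9)
    expect_true(all(sub$q_value >= sub$p_value - 1e-12))
  }
  # the pooled two-proportion z-test matches prop.test without correction
  pt <- stats::prop.test(c(30, 10), c(100, 120), correct = FALSE)$p.value
  expect_equal(stack4mc:::two_prop_z(30, 100, 10, 120), pt, tolerance = 1e-12)
  expect_error(kmer_enrichment(g1[0, ], g2), class = "stack4mc_contract_error")
})

test_that("enrichment plot builds", {
  g1 <- synth_generate(synthetic_spec(n_pos = 0, n_neg = 20, seed = 73))
  g2 <- synth_generate(synthetic_spec(n_pos = 0, n_neg = 20, seed = 74))
  p <- plot_enrichment(kmer_enrichment(g1, g2, k_range = 3))
  expect_s3_class(p, "ggplot")
})
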