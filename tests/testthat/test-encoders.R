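# internal single-scheme encoder, aliased for direct comparisons
encode_block <- stack4mc:::encode_block
window_base_matrix <- stack4mc:::window_base_matrix

test_that("registry holds exactly the 14 schemes with correct dimensions", {
  reg <- encoder_registry()
  expect_equal(nrow(reg), 14L)
  expect_setequal(reg$name, c("ENAC", "Binary", "NCP", "EIIP", "Kmer",
                              "CKSNAP", "PseEIIP", "TNC", "RCKmer",
                              "SCPseTNC", "PCPseTNC", "ANF", "NAC", "TAC"))
  expected <- c(ENAC = 148L, Binary = 164L, NCP = 123L, EIIP = 41L,
                Kmer = 16L, CKSNAP = 96L, PseEIIP = 64L, TNC = 64L,
                RCKmer = 32L, SCPseTNC = 68L, PCPseTNC = 66L, ANF = 41L,
                NAC = 4L, TAC = 4L)
  expect_equal(setNames(reg$dim, reg$name)[names(expected)], expected)
})

test_that("toy encoding examples match hand-derived values", {
  expect_equal(encode_block(window_base_matrix("ACGT"),
                            encoder_spec("Binary"))[1, ],
               c(1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 1))
  expect_equal(encode_block(window_base_matrix("AACA"),
                            encoder_spec("ANF"))[1, ],
               c(1, 1, 1 / 3, 3 / 4))
  expect_equal(encode_block(window_base_matrix("ACGT"),
                            encoder_spec("NAC"))[1, ],
               rep(0.25, 4))
  km <- encode_block(window_base_matrix("AAAA"),
                     encoder_spec("Kmer"))[1, ]
  expect_equal(km[1], 1)
  expect_equal(sum(km[-1]), 0)
  ck <- encode_block(window_base_matrix("ACAC"),
                     encoder_spec("CKSNAP", k_max = 0))[1, ]
  # adjacent pairs: AC, CA, AC
  expect_equal(ck[2], 2 / 3)   # AC
  expect_equal(ck[5], 1 / 3)   # CA
  expect_equal(sum(ck), 1)
  expect_equal(encode_block(window_base_matrix("A"),
                            encoder_spec("EIIP"))[1, ], 0.1260)
})

test_that("all 14 encoders match independent brute-force oracles", {
  set.seed(101)
  seqs <- replicate(100, random_window(41))
  B <- window_base_matrix(seqs)
  for (nm in names(oracle_encoders)) {
    got <- encode_block(B, encoder_spec(nm))
    want <- t(vapply(seqs, oracle_encoders[[nm]],
                     numeric(encoding_dim(nm)), USE.NAMES = FALSE))
    expect_lt(max(abs(got - want)), 1e-9, label = paste(nm, "max abs diff"))
  }
})

test_that("encoders match oracles on windows containing N", {
  set.seed(102)
  seqs <- replicate(25, random_window(41, n_prob = 0.1))
  B <- window_base_matrix(seqs)
  for (nm in names(oracle_encoders)) {
    got <- encode_block(B, encoder_spec(nm))
    want <- t(vapply(seqs, oracle_encoders[[nm]],
                     numeric(encoding_dim(nm)), USE.NAMES = FALSE))
    expect_lt(max(abs(got - want)), 1e-9, label = paste(nm, "with N"))
  }
})

test_that("frequency blocks sum to one on N-free windows", {
  set.seed(103)
  seqs <- replicate(20, random_window(41))
  B <- window_base_matrix(seqs)
  for (nm in c("NAC", "Kmer", "TNC", "RCKmer")) {
    X <- encode_block(B, encoder_spec(nm))
    expect_equal(rowSums(X), rep(1, 20), tolerance = 1e-9)
  }
  enac <- encode_block(B, encoder_spec("ENAC"))
  for (s in seq_len(ncol(enac) / 4)) {
    expect_equal(rowSums(enac[, 4 * (s - 1) + 1:4]), rep(1, 20),
                 tolerance = 1e-9)
  }
  ck <- encode_block(B, encoder_spec("CKSNAP"))
  for (g in 0:5) {
    expect_equal(rowSums(ck[, 16 * g + 1:16]), rep(1, 20), tolerance = 1e-9)
  }
})

test_that("ANF values lie in (0, 1] and start at 1 on N-free windows", {
  set.seed(104)
  seqs <- replicate(20, random_window(41))
  X <- encode_block(window_base_matrix(seqs), encoder_spec("ANF"))
  expect_true(all(X > 0 & X <= 1))
  expect_equal(X[, 1], rep(1, 20))
})

test_that("RCKmer is invariant under reverse complement", {
  set.seed(105)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in 1:20) {
    s <- random_window(41)
    rc <- paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
    a <- encode_block(window_base_matrix(s), encoder_spec("RCKmer"))
    b <- encode_block(window_base_matrix(rc), encoder_spec("RCKmer"))
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("homopolymer windows yield zero correlation factors", {
  B <- window_base_matrix(strrep("A", 41))
  expect_equal(encode_block(B, encoder_spec("TAC"))[1, ], rep(0, 4))
  pc <- encode_block(B, encoder_spec("PCPseTNC"))[1, ]
  expect_equal(pc[65:66], rep(0, 2))
})

test_that("dimension() agrees with actual output over a parameter grid", {
  set.seed(106)
  B <- window_base_matrix(replicate(3, random_window(41)))
  grid <- list(
    encoder_spec("ENAC", w = 3), encoder_spec("ENAC", w = 7),
    encoder_spec("Kmer", k = 1), encoder_spec("Kmer", k = 3),
    encoder_spec("Kmer", k = 4), encoder_spec("RCKmer", k = 2),
    encoder_spec("RCKmer", k = 4), encoder_spec("CKSNAP", k_max = 0),
    encoder_spec("CKSNAP", k_max = 8), encoder_spec("PCPseTNC", lambda = 5),
    encoder_spec("SCPseTNC", lambda = 3), encoder_spec("TAC", lag = 4)
  )
  for (sp in grid) {
    expect_equal(ncol(encode_block(B, sp)), encoding_dim(sp),
                 label = format(sp))
  }
})

test_that("fusion concatenates blocks in order with a correct block map", {
  w <- synth_generate(synthetic_spec(n_pos = 3, n_neg = 3, seed = 2))
  X <- encode_windows(w, c("NAC", "EIIP"))
  expect_equal(dim(X), c(6L, 45L))
  bm <- feature_blocks(X)
  expect_equal(bm$scheme, c("NAC", "EIIP"))
  expect_equal(bm$start, c(1L, 5L))
  expect_equal(bm$end, c(4L, 45L))
  # blocks equal standalone encodings
  expect_equal(unclass(X)[, 1:4],
               unclass(encode_windows(w, "NAC"))[, , drop = FALSE],
               ignore_attr = TRUE)
  # all 14 at defaults: column count equals the dimension audit
  Xall <- encode_windows(w)
  expect_equal(ncol(Xall), sum(encoder_registry()$dim))
  bm_all <- feature_blocks(Xall)
  expect_true(all(bm_all$start == dplyr::lag(bm_all$end, default = 0) + 1))
})

test_that("fusion rejects duplicates and empty selections", {
  w <- synth_generate(synthetic_spec(n_pos = 2, n_neg = 2, seed = 2))
  expect_error(encode_windows(w, c("NAC", "NAC")), class = "stack4mc_contract_error")
  expect_error(encode_windows(w, character(0)), class = "stack4mc_contract_error")
})

test_that("empty window list yields a 0-row matrix with intact block map", {
  w <- synth_generate(synthetic_spec(n_pos = 1, n_neg = 1, seed = 2))[0, ]
  X <- encode_windows(w, c("NAC", "Kmer"))
  expect_equal(nrow(X), 0L)
  expect_equal(ncol(X), 20L)
  expect_equal(feature_blocks(X)$scheme, c("NAC", "Kmer"))
})

test_that("parameter validation rejects out-of-range settings", {
  expect_error(encoder_spec("Kmer", k = 7), class = "stack4mc_parameter_error")
  expect_error(encoder_spec("ENAC", w = 0), class = "stack4mc_parameter_error")
  expect_error(encoder_spec("CKSNAP", k_max = 11), class = "stack4mc_parameter_error")
  expect_error(encoder_spec("TAC", lag = 40), class = "stack4mc_parameter_error")
})
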