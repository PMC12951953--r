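#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# Canonical registry order; also the tie-break order used by the feature
# ranking (first entry wins ties).
ENCODER_NAMES <- c(
  "ENAC", "Binary", "NCP", "EIIP", "Kmer", "CKSNAP", "PseEIIP",
  "TNC", "RCKmer", "SCPseTNC", "PCPseTNC", "ANF", "NAC", "TAC"
)

BASES <- c("A", "C", "G", "T")

# EIIP (electron-ion interaction pseudopotential) per nucleotide.
EIIP_VALUES <- c(A = 0.1260, C = 0.1340, G = 0.0806, T = 0.1335)

# Nucleotide chemical property code: (ring structure, hydrogen bond,
# chemical functionality).
NCP_TABLE <- rbind(
  A = c(1, 1, 1),
  C = c(0, 1, 0),
  G = c(1, 0, 0),
  T = c(0, 0, 1)
)

#' Default trinucleotide physicochemical property scales
#'
#' Correlation-type encoders (TAC, PCPseTNC, SCPseTNC) need one numeric value
#' per trinucleotide and per physicochemical property. The package default is
#' a 64 x 2 matrix of two simply defined scales: the summed EIIP potential of
#' the three bases and the G+C count of the trimer. Both are z-standardised
#' over the 64 trinucleotides before any correlation is computed, so only
#' their relative pattern matters. Pass a custom 64 x P numeric matrix (rows
#' in lexicographic trimer order AAA, AAC, ..., TTT) through the scheme
#' parameters to use other property sets.
#'
#' @param standardize Logical; z-standardise each column over the 64 trimers.
#' @return A 64 x 2 numeric matrix with rownames AAA..TTT.
#' @export
default_trinucleotide_properties <- function(standardize = TRUE) {
  trimers <- kmer_alphabet(3)
  spl <- strsplit(trimers, "")
  eiip_sum <- vapply(spl, function(b) sum(EIIP_VALUES[b]), numeric(1))
  gc_count <- vapply(spl, function(b) sum(b %in% c("G", "C")), numeric(1))
  props <- cbind(eiip_sum = eiip_sum, gc_count = gc_count)
  rownames(props) <- trimers
  if (standardize) props <- scale(props)[, , drop = FALSE]
  props
}

#' All k-mers over {A,C,G,T} in lexicographic order
#' @param k k-mer length.
#' @return Character vector of length `4^k`.
#' @export
kmer_alphabet <- function(k) {
  stopifnot(k >= 1)
  out <- BASES
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      out <- as.vector(t(outer(out, BASES, paste0)))
    }
  }
  out
}

default_encoder_params <- function(name) {
  switch(name,
    ENAC     = list(w = 5L),
    Kmer     = list(k = 2L),
    RCKmer   = list(k = 3L),
    CKSNAP   = list(k_max = 5L),
    PCPseTNC = list(lambda = 2L, w_pse = 0.1, properties = NULL),
    SCPseTNC = list(lambda = 2L, w_pse = 0.1, properties = NULL),
    TAC      = list(lag = 2L, properties = NULL),
    list()
  )
}

#' Create an encoder specification
#'
#' @param name One of the fourteen registered scheme names (see
#'   [encoder_registry()]).
#' @param ... Scheme parameters overriding the defaults: `w` (ENAC sliding
#'   sub-window), `k` (Kmer/RCKmer), `k_max` (CKSNAP maximum gap), `lambda`
#'   and `w_pse` (pseudo-composition encoders), `lag` (TAC), `properties`
#'   (64 x P trinucleotide property matrix).
#' @return An object of class `encoder_spec`.
#' @export
encoder_spec <- function(name, ...) {
  name <- match.arg(name, ENCODER_NAMES)
  params <- utils::modifyList(default_encoder_params(name), list(...))
  spec <- structure(list(name = name, params = params), class = "encoder_spec")
  validate_encoder_spec(spec)
  spec
}

validate_encoder_spec <- function(spec, L = 41L) {
  p <- spec$params
  bad <- function(msg) abort(sprintf("invalid parameters for %s: %s", spec$name, msg),
                             class = "stack4mc_parameter_error")
  if (spec$name == "ENAC" && (p$w < 1 || p$w > L)) bad(sprintf("w=%s outside 1..%d", p$w, L))
  if (spec$name %in% c("Kmer", "RCKmer") && (p$k < 1 || p$k > 6)) bad("k outside 1..6")
  if (spec$name == "CKSNAP" && (p$k_max < 0 || p$k_max > 10)) bad("k_max outside 0..10")
  if (spec$name %in% c("PCPseTNC", "SCPseTNC")) {
    if (p$lambda < 1 || p$lambda > L - 3) bad(sprintf("lambda outside 1..%d", L - 3))
    if (p$w_pse < 0) bad("w_pse must be non-negative")
  }
  if (spec$name == "TAC" && (p$lag < 1 || p$lag > L - 3)) bad(sprintf("lag outside 1..%d", L - 3))
  invisible(spec)
}

as_encoder_spec <- function(x) {
  if (inherits(x, "encoder_spec")) return(x)
  if (is.character(x) && length(x) == 1) return(encoder_spec(x))
  abort("expected an encoder name or an encoder_spec", class = "stack4mc_contract_error")
}

#' @export
format.encoder_spec <- function(x, ...) {
  pars <- x$params[!vapply(x$params, is.null, logical(1))]
  pars <- pars[!names(pars) %in% "properties"]
  if (length(pars) == 0) return(x$name)
  sprintf("%s(%s)", x$name, paste(names(pars), unlist(pars), sep = "=", collapse = ", "))
}

#' @export
print.encoder_spec <- function(x, ...) cat(format(x), "\n")

#' The encoder registry
#'
#' Lists the fourteen candidate feature encoding schemes with their default
#' parameters and output dimension on 41-bp windows.
#'
#' @param L Window length used for the dimension column.
#' @return A tibble with columns `name`, `family`, `params`, `dim`.
#' @export
encoder_registry <- function(L = 41L) {
  family <- c(
    ENAC = "positional", Binary = "positional", NCP = "positional",
    EIIP = "positional", Kmer = "composition", CKSNAP = "composition",
    PseEIIP = "composition", TNC = "composition", RCKmer = "composition",
    SCPseTNC = "correlation", PCPseTNC = "correlation", ANF = "positional",
    NAC = "composition", TAC = "correlation"
  )
  specs <- lapply(ENCODER_NAMES, encoder_spec)
  tibble(
    name = ENCODER_NAMES,
    family = unname(family[ENCODER_NAMES]),
    params = lapply(specs, function(s) s$params),
    dim = vapply(specs, encoding_dim, integer(1), L = L)
  )
}

rckmer_canonical_map <- function(k) {
  kmers <- kmer_alphabet(k)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- vapply(strsplit(kmers, ""), function(b) paste(rev(comp[b]), collapse = ""),
               character(1))
  canon <- pmin(kmers, rc)
  classes <- sort(unique(canon))
  list(classes = classes, index = match(canon, classes))
}

#' Output dimension of an encoding scheme
#'
#' Closed-form feature-vector length for a scheme applied to windows of
#' length `L`; always equals the length of the vector the encoder emits.
#'
#' @param spec An `encoder_spec` or scheme name.
#' @param L Window length (default 41).
#' @return Integer dimension.
#' @export
encoding_dim <- function(spec, L = 41L) {
  spec <- as_encoder_spec(spec)
  validate_encoder_spec(spec, L = L)
  p <- spec$params
  n_props <- function() ncol(p$properties %||% default_trinucleotide_properties())
  out <- switch(spec$name,
    ENAC     = (L - p$w + 1L) * 4L,
    Binary   = 4L * L,
    NCP      = 3L * L,
    EIIP     = L,
    Kmer     = 4L^p$k,
    CKSNAP   = 16L * (p$k_max + 1L),
    PseEIIP  = 64L,
    TNC      = 64L,
    RCKmer   = length(rckmer_canonical_map(p$k)$classes),
    SCPseTNC = 64L + p$lambda * n_props(),
    PCPseTNC = 64L + p$lambda,
    ANF      = L,
    NAC      = 4L,
    TAC      = p$lag * n_props()
  )
  as.integer(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Integer base matrix (A=1, C=2, G=3, T=4, N=NA) from a windows tibble or a
# character vector of equal-length sequences.
window_base_matrix <- function(windows) {
  bases <- if (is.data.frame(windows)) windows$bases else windows
  if (length(bases) == 0) return(matrix(integer(0), nrow = 0, ncol = 41))
  L <- unique(nchar(bases))
  if (length(L) != 1) abort("windows must all have the same length",
                            class = "stack4mc_contract_error")
  chars <- matrix(unlist(strsplit(bases, ""), use.names = FALSE),
                  nrow = length(bases), ncol = L, byrow = TRUE)
  m <- match(chars, BASES)        # N -> NA
  dim(m) <- dim(chars)
  m
}

# Row-wise cumulative sums across columns via one matrix product.
row_cumsum <- function(m) {
  L <- ncol(m)
  if (L == 0) return(m)
  tri <- upper.tri(matrix(0, L, L), diag = TRUE) * 1
  m %*% tri
}

## ---- positional encoders ----------------------------------------------

enc_binary <- function(B) {
  n <- nrow(B); L <- ncol(B)
  out <- matrix(0, n, 4L * L)
  if (n == 0) return(out)
  for (j in seq_len(L)) {
    ok <- which(!is.na(B[, j]))
    if (length(ok)) out[cbind(ok, 4L * (j - 1L) + B[ok, j])] <- 1
  }
  out
}

enc_ncp <- function(B) {
  n <- nrow(B); L <- ncol(B)
  out <- matrix(0, n, 3L * L)
  if (n == 0) return(out)
  tab <- rbind(NCP_TABLE, N = c(0, 0, 0))
  Bn <- B; Bn[is.na(Bn)] <- 5L
  for (j in seq_len(L)) {
    out[, 3L * (j - 1L) + 1:3] <- tab[Bn[, j], , drop = FALSE]
  }
  out
}

enc_eiip <- function(B) {
  vals <- c(unname(EIIP_VALUES), 0)
  Bn <- B; Bn[is.na(Bn)] <- 5L
  out <- matrix(vals[Bn], nrow(B), ncol(B))
  out
}

enc_anf <- function(B) {
  n <- nrow(B); L <- ncol(B)
  out <- matrix(0, n, L)
  if (n == 0) return(out)
  counts <- matrix(0L, n, 4)
  rows <- seq_len(n)
  for (i in seq_len(L)) {
    b <- B[, i]
    ok <- which(!is.na(b))
    if (length(ok)) {
      idx <- cbind(ok, b[ok])
      counts[idx] <- counts[idx] + 1L
      out[ok, i] <- counts[idx] / i
    }
  }
  out
}

enc_enac <- function(B, w) {
  n <- nrow(B); L <- ncol(B)
  nwin <- L - w + 1L
  out <- matrix(0, n, 4L * nwin)
  if (n == 0) return(out)
  # cumulative per-base indicator sums -> O(1) window counts
  cums <- lapply(1:4, function(b) {
    ind <- (B == b); ind[is.na(ind)] <- FALSE
    cbind(0, row_cumsum(ind * 1))
  })
  for (s in seq_len(nwin)) {
    cnt <- vapply(1:4, function(b) cums[[b]][, s + w] - cums[[b]][, s], numeric(n))
    cnt <- matrix(cnt, n, 4)
    tot <- rowSums(cnt)
    frac <- cnt / ifelse(tot > 0, tot, 1)
    frac[tot == 0, ] <- 0
    out[, 4L * (s - 1L) + 1:4] <- frac
  }
  out
}

## ---- composition encoders ---------------------------------------------

# Integer k-mer ids (1-based, lexicographic) per position; NA where any base
# in the k-mer is N.
kmer_id_matrix <- function(B, k) {
  n <- nrow(B); L <- ncol(B)
  npos <- L - k + 1L
  ids <- matrix(0L, n, npos)
  for (t in seq_len(k)) {
    ids <- ids + (B[, t:(t + npos - 1L), drop = FALSE] - 1L) * 4L^(k - t)
  }
  ids + 1L
}

kmer_counts <- function(B, k) {
  n <- nrow(B)
  out <- matrix(0, n, 4L^k)
  if (n == 0 || ncol(B) < k) return(out)
  ids <- kmer_id_matrix(B, k)
  rows <- seq_len(n)
  for (j in seq_len(ncol(ids))) {
    ok <- which(!is.na(ids[, j]))
    if (length(ok)) {
      idx <- cbind(ok, ids[ok, j])
      out[idx] <- out[idx] + 1
    }
  }
  out
}

normalize_rows <- function(cnt) {
  tot <- rowSums(cnt)
  out <- cnt / ifelse(tot > 0, tot, 1)
  out[tot == 0, ] <- 0
  out
}

enc_kmer <- function(B, k) normalize_rows(kmer_counts(B, k))

enc_nac <- function(B) enc_kmer(B, 1L)

enc_tnc <- function(B) enc_kmer(B, 3L)

enc_pseeiip <- function(B) {
  f <- enc_tnc(B)
  trimers <- kmer_alphabet(3)
  esum <- vapply(strsplit(trimers, ""), function(b) sum(EIIP_VALUES[b]), numeric(1))
  sweep(f, 2, esum, `*`)
}

enc_rckmer <- function(B, k) {
  cnt <- kmer_counts(B, k)
  map <- rckmer_canonical_map(k)
  folded <- matrix(0, nrow(cnt), length(map$classes))
  for (j in seq_len(ncol(cnt))) {
    folded[, map$index[j]] <- folded[, map$index[j]] + cnt[, j]
  }
  normalize_rows(folded)
}

enc_cksnap <- function(B, k_max) {
  n <- nrow(B); L <- ncol(B)
  out <- matrix(0, n, 16L * (k_max + 1L))
  if (n == 0) return(out)
  rows <- seq_len(n)
  for (g in 0:k_max) {
    cnt <- matrix(0, n, 16)
    npair <- L - g - 1L
    for (j in seq_len(npair)) {
      id <- (B[, j] - 1L) * 4L + B[, j + g + 1L]
      ok <- which(!is.na(id))
      if (length(ok)) {
        idx <- cbind(ok, id[ok])
        cnt[idx] <- cnt[idx] + 1
      }
    }
    out[, 16L * g + 1:16] <- normalize_rows(cnt)
  }
  out
}

## ---- correlation encoders ---------------------------------------------

resolve_properties <- function(params) {
  props <- params$properties %||% default_trinucleotide_properties()
  if (!is.matrix(props) || nrow(props) != 64) {
    abort("properties must be a 64 x P numeric matrix",
          class = "stack4mc_parameter_error")
  }
  props
}

# Property value matrices per trimer position: list over properties of
# n x (L-2) matrices, NA where the trimer is undetermined.
trimer_property_series <- function(B, props) {
  ids <- kmer_id_matrix(B, 3L)
  lapply(seq_len(ncol(props)), function(u) {
    v <- props[, u][ids]
    dim(v) <- dim(ids)
    v
  })
}

enc_pcpsetnc <- function(B, lambda, w_pse, props) {
  n <- nrow(B)
  out <- matrix(0, n, 64L + lambda)
  if (n == 0) return(out)
  f <- enc_tnc(B)
  series <- trimer_property_series(B, props)
  theta <- matrix(0, n, lambda)
  for (j in seq_len(lambda)) {
    acc <- matrix(0, n, ncol(series[[1]]) - j)
    cnt <- matrix(0, n, ncol(series[[1]]) - j)
    for (u in seq_along(series)) {
      a <- series[[u]][, seq_len(ncol(series[[u]]) - j), drop = FALSE]
      b <- series[[u]][, (j + 1L):ncol(series[[u]]), drop = FALSE]
      d2 <- (a - b)^2
      ok <- !is.na(d2)
      d2[!ok] <- 0
      acc <- acc + d2
      cnt <- cnt + ok
    }
    # mean over properties, then over valid lagged pairs
    valid <- rowSums(cnt > 0)
    theta[, j] <- ifelse(valid > 0,
                         rowSums(acc / length(series)) / pmax(valid, 1), 0)
  }
  denom <- rowSums(f) + w_pse * rowSums(theta)
  denom[denom == 0] <- 1
  out[, 1:64] <- f / denom
  out[, 64L + seq_len(lambda)] <- w_pse * theta / denom
  out
}

enc_scpsetnc <- function(B, lambda, w_pse, props) {
  n <- nrow(B)
  P <- ncol(props)
  out <- matrix(0, n, 64L + lambda * P)
  if (n == 0) return(out)
  f <- enc_tnc(B)
  series <- trimer_property_series(B, props)
  tau <- matrix(0, n, lambda * P)
  for (j in seq_len(lambda)) {
    for (u in seq_len(P)) {
      a <- series[[u]][, seq_len(ncol(series[[u]]) - j), drop = FALSE]
      b <- series[[u]][, (j + 1L):ncol(series[[u]]), drop = FALSE]
      pr <- a * b
      ok <- !is.na(pr)
      pr[!ok] <- 0
      valid <- rowSums(ok)
      tau[, (j - 1L) * P + u] <- ifelse(valid > 0, rowSums(pr) / pmax(valid, 1), 0)
    }
  }
  denom <- rowSums(f) + w_pse * rowSums(tau)
  denom[denom == 0] <- 1
  out[, 1:64] <- f / denom
  out[, 64L + seq_len(lambda * P)] <- w_pse * tau / denom
  out
}

enc_tac <- function(B, lag, props) {
  n <- nrow(B)
  P <- ncol(props)
  out <- matrix(0, n, P * lag)
  if (n == 0) return(out)
  series <- trimer_property_series(B, props)
  for (u in seq_len(P)) {
    s <- series[[u]]
    mu <- rowMeans(s, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    centered <- s - mu
    for (l in seq_len(lag)) {
      a <- centered[, seq_len(ncol(s) - l), drop = FALSE]
      b <- centered[, (l + 1L):ncol(s), drop = FALSE]
      pr <- a * b
      ok <- !is.na(pr)
      pr[!ok] <- 0
      valid <- rowSums(ok)
      out[, (u - 1L) * lag + l] <- ifelse(valid > 0, rowSums(pr) / pmax(valid, 1), 0)
    }
  }
  out
}

## ---- dispatch and fusion ----------------------------------------------

encode_block <- function(B, spec) {
  spec <- as_encoder_spec(spec)
  validate_encoder_spec(spec, L = ncol(B))
  p <- spec$params
  switch(spec$name,
    ENAC     = enc_enac(B, p$w),
    Binary   = enc_binary(B),
    NCP      = enc_ncp(B),
    EIIP     = enc_eiip(B),
    Kmer     = enc_kmer(B, p$k),
    CKSNAP   = enc_cksnap(B, p$k_max),
    PseEIIP  = enc_pseeiip(B),
    TNC      = enc_tnc(B),
    RCKmer   = enc_rckmer(B, p$k),
    SCPseTNC = enc_scpsetnc(B, p$lambda, p$w_pse, resolve_properties(p)),
    PCPseTNC = enc_pcpsetnc(B, p$lambda, p$w_pse, resolve_properties(p)),
    ANF      = enc_anf(B),
    NAC      = enc_nac(B),
    TAC      = enc_tac(B, p$lag, resolve_properties(p))
  )
}

#' Encode sample windows into a fused feature matrix
#'
#' Applies the selected encoding schemes to every window and concatenates
#' the per-scheme blocks column-wise, in the order given. The returned
#' matrix carries a block map recording which columns belong to which
#' scheme, so convolutional models see a deterministic spatial layout.
#'
#' @param windows A windows tibble (see [extract_windows()]) or character
#'   vector of equal-length sequences over A/C/G/T/N.
#' @param schemes Ordered list of scheme names or `encoder_spec` objects;
#'   no duplicates.
#' @return A numeric matrix of class `feature_matrix` with attribute
#'   `block_map`, a tibble with columns `scheme`, `start`, `end` (1-based,
#'   inclusive).
#' @examples
#' w <- synth_generate(synthetic_spec(n_pos = 5, n_neg = 5))
#' X <- encode_windows(w, c("NAC", "EIIP"))
#' dim(X)
#' feature_blocks(X)
#' @export
encode_windows <- function(windows, schemes = ENCODER_NAMES) {
  if (!is.list(schemes) || inherits(schemes, "encoder_spec")) {
    schemes <- if (inherits(schemes, "encoder_spec")) list(schemes) else as.list(schemes)
  }
  specs <- lapply(schemes, as_encoder_spec)
  nms <- vapply(specs, function(s) s$name, character(1))
  if (length(nms) == 0) abort("at least one scheme required",
                              class = "stack4mc_contract_error")
  if (anyDuplicated(nms)) abort(sprintf("duplicate scheme(s): %s",
                                        paste(unique(nms[duplicated(nms)]), collapse = ", ")),
                                class = "stack4mc_contract_error")
  B <- window_base_matrix(windows)
  blocks <- lapply(specs, function(s) encode_block(B, s))
  dims <- vapply(blocks, ncol, integer(1))
  ends <- cumsum(dims)
  starts <- ends - dims + 1L
  X <- do.call(cbind, blocks)
  if (is.null(X)) X <- matrix(numeric(0), nrow(B), 0)
  structure(
    X,
    block_map = tibble(scheme = nms, start = starts, end = ends),
    class = c("feature_matrix", class(X))
  )
}

#' Block map of a fused feature matrix
#' @param X A `feature_matrix` from [encode_windows()].
#' @return Tibble with columns `scheme`, `start`, `end`.
#' @export
feature_blocks <- function(X) {
  bm <- attr(X, "block_map")
  if (is.null(bm)) abort("not a feature_matrix", class = "stack4mc_contract_error")
  bm
}

#' @export
print.feature_matrix <- function(x, ...) {
  bm <- attr(x, "block_map")
  cat(sprintf("<feature_matrix: %d samples x %d features, %d block(s)>\n",
              nrow(x), ncol(x), nrow(bm)))
  print(bm)
  invisible(x)
}

#' Write a feature matrix to disk
#'
#' Writes the values as a headered TSV and the block map as a JSON sidecar
#' (`<path>.blocks.json`).
#'
#' @param X A `feature_matrix`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(X, path) {
  bm <- feature_blocks(X)
  df <- as.data.frame(unclass(X))
  names(df) <- unlist(lapply(seq_len(nrow(bm)), function(i) {
    paste0(bm$scheme[i], "_", seq_len(bm$end[i] - bm$start[i] + 1L))
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(bm, paste0(path, ".blocks.json"), auto_unbox = FALSE)
  invisible(path)
}
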