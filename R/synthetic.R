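#' Specification for a synthetic planted-motif dataset
#'
#' Defines a balanced set of 41-bp windows with a cytosine pinned at the
#' central position (1-based 21). Positive windows carry a degenerate copy
#' of a consensus motif planted at a uniformly drawn offset inside a narrow
#' placement range near the center; negative windows are pure background.
#' Offsets at which a non-C consensus base would land on the central
#' position are clamped out of the placement range so the central C is
#' never overwritten.
#'
#' @param n_pos,n_neg Numbers of positive and negative windows.
#' @param consensus Motif consensus over A/C/G/T, length 4-8.
#' @param motif_offsets Candidate 0-based start offsets for the motif.
#' @param mutation_prob Per-base probability that a planted motif base is
#'   replaced by a uniformly drawn different base, in `[0, 0.5)`.
#' @param background Named per-base sampling probabilities (A, C, G, T).
#' @param seed Integer seed; generation is fully reproducible from it.
#' @param species_tag Identifier recorded in `source_id`.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_pos = 1000L, n_neg = 1000L,
                           consensus = "GGCCA",
                           motif_offsets = 16:22,
                           mutation_prob = 0.1,
                           background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                           seed = 7L, species_tag = "synthA") {
  if (n_pos < 0 || n_neg < 0) abort("n_pos and n_neg must be >= 0",
                                    class = "stack4mc_contract_error")
  if (!grepl("^[ACGT]{4,8}$", consensus)) {
    abort("consensus must be 4-8 bases over A/C/G/T",
          class = "stack4mc_spec_error")
  }
  if (mutation_prob < 0 || mutation_prob >= 0.5) {
    abort("mutation_prob must be in [0, 0.5)", class = "stack4mc_spec_error")
  }
  background <- background[BASES] / sum(background[BASES])
  valid <- valid_motif_offsets(consensus, motif_offsets)
  if (length(valid) == 0) {
    abort("no valid motif offset preserves the central C",
          class = "stack4mc_spec_error")
  }
  structure(list(
    n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
    consensus = consensus, motif_offsets = as.integer(valid),
    requested_offsets = as.integer(motif_offsets),
    mutation_prob = mutation_prob, background = background,
    seed = as.integer(seed), species_tag = species_tag
  ), class = "synthetic_spec")
}

# Offsets (0-based starts) at which the motif either misses the central
# position (0-based 20) or puts a consensus C on it.
valid_motif_offsets <- function(consensus, offsets) {
  len <- nchar(consensus)
  keep <- vapply(offsets, function(o) {
    covers <- o <= 20 && 20 <= o + len - 1
    if (!covers) return(o >= 0 && o + len <= 41)
    substr(consensus, 20 - o + 1, 20 - o + 1) == "C" && o >= 0 && o + len <= 41
  }, logical(1))
  offsets[keep]
}

#' Generate a synthetic planted-motif dataset
#'
#' @param spec A [synthetic_spec()].
#' @return A windows tibble (`source_id`, `source_offset`, `bases`,
#'   `label`) with `n_pos + n_neg` rows; positives first. The central base
#'   of every window is C.
#' @examples
#' w <- synth_generate(synthetic_spec(n_pos = 3, n_neg = 3, seed = 1))
#' substr(w$bases, 21, 21)
#' @export
synth_generate <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_pos + spec$n_neg
  old <- .Random.seed_exists()
  on.exit(restore_rng(old), add = TRUE)
  set.seed(spec$seed)
  B <- matrix(sample(BASES, n * 41L, replace = TRUE, prob = spec$background),
              nrow = n, ncol = 41L)
  B[, 21] <- "C"
  if (spec$n_pos > 0) {
    len <- nchar(spec$consensus)
    motif <- strsplit(spec$consensus, "")[[1]]
    starts <- sample(spec$motif_offsets, spec$n_pos, replace = TRUE)
    for (i in seq_len(spec$n_pos)) {
      planted <- motif
      mut <- stats::runif(len) < spec$mutation_prob
      if (any(mut)) {
        planted[mut] <- vapply(planted[mut], function(b) {
          sample(setdiff(BASES, b), 1L)
        }, character(1))
      }
      B[i, (starts[i] + 1L):(starts[i] + len)] <- planted
    }
    # the central C is an invariant of the window design, not of the motif
    B[, 21] <- "C"
  }
  bases <- apply(B, 1, paste, collapse = "")
  labels <- c(rep(1L, spec$n_pos), rep(0L, spec$n_neg))
  tibble(
    source_id = sprintf("%s_%s_%04d", spec$species_tag,
                        ifelse(labels == 1, "pos", "neg"), seq_len(n)),
    source_offset = 0L,
    bases = bases,
    label = labels
  )
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Derive a bounded child seed from a base seed and a stage label, keeping
# the result well inside 32-bit integer range.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 1103 + h) %% .Machine$integer.max)
}

#' Generate a family of synthetic "species" for cross-species transfer
#'
#' The first `ceiling(n_species / 2)` species share Hamming-near variants of
#' one consensus motif (within-group transfer should succeed); the
#' remaining species carry an unrelated motif (cross-group transfer should
#' degrade). Each species gets its own derived seed, so the family is
#' reproducible from the base spec alone.
#'
#' @param spec Base [synthetic_spec()]; per-species sample sizes and
#'   mutation rate are taken from it.
#' @param n_species Number of species, at least 2.
#' @param motif_divergence Per-base probability that a shared-group
#'   species' consensus differs from the base consensus.
#' @return Named list of windows tibbles; attribute `groups` maps species
#'   tag to "A" (shared motif) or "B" (unrelated motif), and attribute
#'   `motifs` records each species' consensus.
#' @export
synth_species_family <- function(spec, n_species = 4L, motif_divergence = 0.1) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (n_species < 2) abort("n_species must be >= 2", class = "stack4mc_contract_error")
  old <- .Random.seed_exists()
  on.exit(restore_rng(old), add = TRUE)
  set.seed(derive_seed(spec$seed, "family"))
  n_shared <- ceiling(n_species / 2)
  base_motif <- strsplit(spec$consensus, "")[[1]]
  len <- length(base_motif)
  # unrelated motif: maximally distant where the base motif is not C at a
  # center-covering position (the C is re-pinned anyway)
  unrelated <- vapply(base_motif, function(b) sample(setdiff(BASES, b), 1L),
                      character(1))
  motifs <- character(n_species)
  for (i in seq_len(n_species)) {
    if (i <= n_shared) {
      m <- base_motif
      flip <- stats::runif(len) < motif_divergence
      if (i > 1 && any(flip)) {
        m[flip] <- vapply(m[flip], function(b) sample(setdiff(BASES, b), 1L),
                          character(1))
      }
      motifs[i] <- paste(m, collapse = "")
    } else {
      motifs[i] <- paste(unrelated, collapse = "")
    }
  }
  tags <- sprintf("sp%02d", seq_len(n_species))
  datasets <- lapply(seq_len(n_species), function(i) {
    sp <- synthetic_spec(
      n_pos = spec$n_pos, n_neg = spec$n_neg, consensus = motifs[i],
      motif_offsets = spec$requested_offsets,
      mutation_prob = spec$mutation_prob,
      background = spec$background,
      seed = derive_seed(spec$seed, tags[i]),
      species_tag = tags[i])
    synth_generate(sp)
  })
  names(datasets) <- tags
  attr(datasets, "groups") <- stats::setNames(
    ifelse(seq_len(n_species) <= n_shared, "A", "B"), tags)
  attr(datasets, "motifs") <- stats::setNames(motifs, tags)
  datasets
}
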