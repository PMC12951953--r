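#' Read a FASTA file of DNA sequences
#'
#' Sequences are uppercased and RNA-style U is mapped to T. Any character
#' outside A/C/G/T/N is rejected with an error naming the offending record
#' and position. Labels may be attached from a named vector or from a
#' two-column TSV sidecar (id, label in 0/1) via [read_label_sidecar()].
#'
#' @param path FASTA file (wrapped or unwrapped lines).
#' @param labels Optional named vector/list mapping record id to 0/1.
#' @return A tibble with columns `id`, `sequence`, `label` (NA when no label
#'   is supplied for a record).
#' @export
read_fasta <- function(path, labels = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("FASTA file not found: %s", path), class = "stack4mc_io_error")
  }
  if (file.size(path) == 0) {
    warn(sprintf("FASTA file is empty: %s", path))
    return(tibble(id = character(), sequence = character(), label = integer()))
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(
      sprintf("malformed FASTA in %s: %s", path, conditionMessage(e)),
      class = "stack4mc_parse_error")
  )
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  for (i in seq_along(seqs)) {
    bad <- regexpr("[^ACGTN]", seqs[i])
    if (bad > 0) {
      abort(sprintf(
        "illegal character '%s' in record '%s' at position %d",
        substr(seqs[i], bad, bad), ids[i], as.integer(bad)),
        class = "stack4mc_validation_error")
    }
    if (nchar(seqs[i]) == 0) {
      abort(sprintf("record '%s' has an empty sequence", ids[i]),
            class = "stack4mc_validation_error")
    }
  }
  lab <- rep(NA_integer_, length(ids))
  if (!is.null(labels)) {
    hit <- match(ids, names(labels))
    lab[!is.na(hit)] <- as.integer(unlist(labels)[hit[!is.na(hit)]])
    if (any(!lab %in% c(0L, 1L, NA_integer_))) {
      abort("labels must be 0 or 1", class = "stack4mc_validation_error")
    }
  }
  tibble(id = ids, sequence = unname(seqs), label = lab)
}

#' Write sequences to FASTA
#'
#' @param records A tibble with `id` and `sequence` columns (as returned by
#'   [read_fasta()]), or a windows tibble (columns `source_id`, `bases`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (all(c("source_id", "bases") %in% names(records))) {
    ids <- records$source_id
    seqs <- records$bases
  } else {
    ids <- records$id
    seqs <- records$sequence
  }
  set <- Biostrings::BStringSet(seqs)
  names(set) <- ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a two-column label sidecar (TSV: id, label in {0,1})
#' @param path TSV path, no header.
#' @return Named integer vector of labels.
#' @export
read_label_sidecar <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("id", "label"),
                          colClasses = c("character", "integer"))
  if (!all(df$label %in% c(0L, 1L))) {
    abort("labels must be 0 or 1", class = "stack4mc_validation_error")
  }
  stats::setNames(df$label, df$id)
}

#' Write windows and their labels as FASTA plus TSV sidecar
#' @param windows A windows tibble.
#' @param fasta_path Output FASTA path.
#' @param labels_path Output TSV path (id, label), written only for windows
#'   with non-missing labels.
#' @return `fasta_path`, invisibly.
#' @export
write_windows <- function(windows, fasta_path, labels_path = NULL) {
  ids <- sprintf("%s|%d", windows$source_id, windows$source_offset)
  set <- Biostrings::BStringSet(windows$bases)
  names(set) <- ids
  Biostrings::writeXStringSet(set, fasta_path)
  if (!is.null(labels_path)) {
    keep <- !is.na(windows$label)
    utils::write.table(
      data.frame(id = ids[keep], label = windows$label[keep]),
      labels_path, sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  }
  invisible(fasta_path)
}

#' Convert sequences into fixed-length sample windows
#'
#' Sequences exactly `window` bases long pass through unchanged. Shorter
#' sequences are symmetrically padded with N (the extra N goes on the right
#' when the deficit is odd) and reported at a negative offset. Longer
#' sequences are cut into overlapping sliding windows at offsets
#' 0, `step`, 2*`step`, ... All offsets are 0-based starts in the source
#' sequence.
#'
#' @param records Tibble with `id`, `sequence` and optional `label`
#'   columns, or a character vector of sequences.
#' @param window Odd window length, default 41.
#' @param step Sliding step for sequences longer than `window`.
#' @param require_center_c Keep only windows whose central base (1-based
#'   position `(window+1)/2`) is C.
#' @return A windows tibble: `source_id`, `source_offset`, `bases`, `label`.
#' @examples
#' extract_windows(tibble::tibble(id = "s", sequence = strrep("A", 45)))
#' @export
extract_windows <- function(records, window = 41L, step = 1L,
                            require_center_c = FALSE) {
  if (window < 1 || window %% 2 == 0) {
    abort("window must be odd and >= 1", class = "stack4mc_contract_error")
  }
  if (step < 1) abort("step must be >= 1", class = "stack4mc_contract_error")
  if (is.character(records)) {
    records <- tibble(id = paste0("seq", seq_along(records)), sequence = records)
  }
  if (!"label" %in% names(records)) records$label <- NA_integer_
  center <- (window + 1L) %/% 2L
  out <- purrr::pmap(
    list(records$id, records$sequence, records$label),
    function(id, seq, label) {
      L <- nchar(seq)
      if (L < window) {
        deficit <- window - L
        left <- deficit %/% 2L
        right <- deficit - left
        bases <- paste0(strrep("N", left), seq, strrep("N", right))
        tibble(source_id = id, source_offset = -left, bases = bases,
               label = label)
      } else {
        offsets <- seq(0L, L - window, by = step)
        bases <- substring(seq, offsets + 1L, offsets + window)
        tibble(source_id = id, source_offset = as.integer(offsets),
               bases = bases, label = label)
      }
    })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    out <- tibble(source_id = character(), source_offset = integer(),
                  bases = character(), label = integer())
  }
  if (require_center_c && nrow(out) > 0) {
    out <- dplyr::filter(out, substr(.data$bases, center, center) == "C")
  }
  out
}

#' Remove exact-duplicate windows
#'
#' Keeps the first occurrence of each distinct base string, preserving the
#' original order otherwise. This is a plain exact-string filter; no
#' similarity-threshold clustering is performed.
#'
#' @param windows A windows tibble.
#' @return The deduplicated windows tibble.
#' @export
deduplicate_windows <- function(windows) {
  dplyr::distinct(windows, .data$bases, .keep_all = TRUE) |>
    dplyr::select(dplyr::all_of(names(windows)))
}
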