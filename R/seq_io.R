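#' Read protein records from a FASTA file
#'
#' Parses a (wrapped or unwrapped) multi-record FASTA file into a tibble of
#' protein records. The first whitespace-delimited token of each header is the
#' record id; the remainder is kept as the description. Sequences are
#' uppercased and validated against the canonical 20-letter alphabet.
#'
#' @param path Path to a FASTA file.
#' @param strict If `TRUE` (default) a record containing a non-canonical
#'   residue (B, J, O, U, X, Z, ...) is an error naming the record and
#'   position; if `FALSE` the record is dropped with a warning.
#' @return A tibble with columns `id`, `description`, `sequence`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 demo", "GPVRGPF"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, strict = TRUE) {
  if (!file.exists(path)) {
    stop_dpp(sprintf("FASTA file '%s' does not exist", path), "dpp_format_error")
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop_dpp(sprintf("malformed FASTA '%s': %s", path, conditionMessage(e)),
               "dpp_format_error")
    }
  )
  if (length(set) == 0L) {
    stop_dpp(sprintf("FASTA file '%s' contains no records", path),
             "dpp_format_error")
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(ids))) {
    stop_dpp(sprintf("malformed header in '%s': record %d has an empty id",
                     path, which(!nzchar(ids))[1L]), "dpp_format_error")
  }
  if (anyDuplicated(ids)) {
    stop_dpp(sprintf("duplicate record id '%s' in '%s'",
                     ids[duplicated(ids)][1L], path), "dpp_format_error")
  }
  seqs <- toupper(gsub("[[:space:]]", "", as.character(set)))
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop_dpp(sprintf("record '%s': empty sequence", ids[empty][1L]),
             "dpp_format_error")
  }
  if (strict) {
    seqs <- validate_sequences(seqs, ids)
  } else {
    ok <- vapply(seqs, function(s) {
      all(strsplit(s, "", fixed = TRUE)[[1L]] %in% AA_ALPHABET)
    }, logical(1))
    if (!all(ok)) {
      warning(sprintf("dropping %d record(s) with non-canonical residues: %s",
                      sum(!ok), paste(ids[!ok], collapse = ", ")))
      ids <- ids[ok]; desc <- desc[ok]; seqs <- seqs[ok]
    }
    if (length(seqs) == 0L) {
      stop_dpp(sprintf("no valid records left in '%s'", path),
               "dpp_format_error")
    }
  }
  tibble::tibble(id = unname(ids), description = unname(desc),
                 sequence = unname(seqs))
}

#' Write protein records to a FASTA file
#'
#' Inverse of [read_fasta()]: `read_fasta(write_fasta(x, f))` reproduces `x`
#' up to line wrapping.
#'
#' @param proteins Tibble with columns `id`, `sequence` and optionally
#'   `description`.
#' @param path Output file path.
#' @param width Line-wrap width for sequences (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  stopifnot(all(c("id", "sequence") %in% names(proteins)))
  desc <- if ("description" %in% names(proteins)) proteins$description else ""
  headers <- ifelse(nzchar(desc), paste(proteins$id, desc), proteins$id)
  set <- Biostrings::AAStringSet(proteins$sequence)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  invisible(path)
}

#' Read a labeled peptide dataset from CSV
#'
#' Reads a `sequence,label` CSV (UTF-8, header required) into a labeled
#' peptide set. Labels must be 0 (non-inhibitory) or 1 (inhibitory).
#' Sequences are uppercased and validated; identical duplicate rows are
#' collapsed with a message, and duplicate sequences carrying conflicting
#' labels are an error.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `sequence`, `label` (integer 0/1).
#' @export
read_labeled_csv <- function(path) {
  if (!file.exists(path)) {
    stop_dpp(sprintf("dataset '%s' does not exist", path), "dpp_format_error")
  }
  df <- tryCatch(
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE),
    error = function(e) {
      stop_dpp(sprintf("malformed CSV '%s': %s", path, conditionMessage(e)),
               "dpp_format_error")
    }
  )
  if (!all(c("sequence", "label") %in% names(df))) {
    stop_dpp(sprintf("'%s' must have columns `sequence` and `label`", path),
             "dpp_format_error")
  }
  lab <- df$label
  if (!all(lab %in% c("0", "1"))) {
    stop_dpp(sprintf("unknown label value(s): %s (only 0/1 accepted)",
                     paste(unique(lab[!lab %in% c("0", "1")]), collapse = ", ")),
             "dpp_format_error")
  }
  out <- tibble::tibble(
    sequence = validate_sequences(df$sequence),
    label = as.integer(lab)
  )
  n_in <- nrow(out)
  out <- dplyr::distinct(out)
  if (nrow(out) < n_in) {
    message(sprintf("collapsed %d duplicate identical row(s)", n_in - nrow(out)))
  }
  conflict <- out$sequence[duplicated(out$sequence)]
  if (length(conflict) > 0L) {
    stop_dpp(sprintf("conflicting labels for sequence(s): %s",
                     paste(unique(conflict), collapse = ", ")),
             "dpp_data_error")
  }
  out
}

#' Write a labeled peptide dataset to CSV
#'
#' @param dataset Tibble with columns `sequence`, `label`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_labeled_csv <- function(dataset, path) {
  stopifnot(all(c("sequence", "label") %in% names(dataset)))
  readr::write_csv(dataset[, c("sequence", "label")], path, progress = FALSE)
  invisible(path)
}

#' Packaged bovine milk protein panel
#'
#' Convenience loader for the packaged six-protein bovine milk panel
#' (alpha-S1-, alpha-S2-, beta- and kappa-casein, beta-lactoglobulin,
#' alpha-lactalbumin; mature chains, fixture v1).
#'
#' @return A tibble of protein records, as from [read_fasta()].
#' @export
milk_proteins <- function() {
  read_fasta(dpp_extdata("milk_proteins.fasta"))
}
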