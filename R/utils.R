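#' @keywords internal
#' @importFrom rlang %||% .data abort
#' @importFrom stats predict setNames
"_PACKAGE"

## The 20 canonical amino acids, alphabetical one-letter order. Every sequence
## admitted by the package is validated against this alphabet once, at ingest.
AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

stop_dpp <- function(message, class, call = NULL) {
  rlang::abort(message, class = c(class, "dpp_error"), call = call)
}

## Run expr with a private RNG stream; the caller's .Random.seed is untouched.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_dpp("`seed` must be a single integer.", "dpp_argument_error")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

## Locate a packaged fixture under inst/extdata.
dpp_extdata <- function(file) {
  path <- system.file("extdata", file, package = "dppscreen")
  if (identical(path, "")) {
    stop_dpp(sprintf("packaged fixture '%s' not found", file), "dpp_lookup_error")
  }
  path
}

#' Validate peptide or protein sequences against the canonical alphabet
#'
#' Checks that each sequence is a non-empty string over the 20 canonical
#' one-letter amino-acid codes. Ambiguity and non-standard codes
#' (B, J, O, U, X, Z) are rejected because the physicochemical property
#' scales behind the PseAAC descriptor are defined only for the canonical
#' residues.
#'
#' @param sequences Character vector of sequences (case-insensitive).
#' @param ids Optional identifiers used in error messages; defaults to the
#'   sequence position.
#' @return The uppercased sequences, invisibly valid.
#' @export
validate_sequences <- function(sequences, ids = NULL) {
  if (length(sequences) == 0L) return(character(0))
  if (is.null(ids)) ids <- as.character(seq_along(sequences))
  up <- toupper(sequences)
  for (i in seq_along(up)) {
    s <- up[[i]]
    if (is.na(s) || !nzchar(s)) {
      stop_dpp(sprintf("record '%s': empty sequence", ids[[i]]),
               "dpp_validation_error")
    }
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    bad <- which(!chars %in% AA_ALPHABET)
    if (length(bad) > 0L) {
      stop_dpp(sprintf(
        "record '%s': non-canonical residue '%s' at position %d",
        ids[[i]], chars[bad[1L]], bad[1L]
      ), "dpp_validation_error")
    }
  }
  up
}
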