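#' Standardize a property scale over the 20 canonical residues
#'
#' Centers and scales a raw amino-acid property scale to zero mean and unit
#' population standard deviation over the 20 canonical residues, the
#' standard preprocessing for pseudo amino acid composition. A constant
#' scale carries no information and is rejected.
#'
#' @param raw Named numeric vector with one finite value per canonical
#'   residue.
#' @return Named numeric vector, mean 0 and population SD 1.
#' @export
normalize_scale <- function(raw) {
  if (!all(sort(names(raw)) == AA_ALPHABET)) {
    stop_dpp("`raw` must have exactly one value per canonical residue",
             "dpp_argument_error")
  }
  raw <- raw[AA_ALPHABET]
  if (!all(is.finite(raw))) {
    stop_dpp("`raw` must be finite for all 20 residues", "dpp_argument_error")
  }
  mu <- mean(raw)
  sd_pop <- sqrt(mean((raw - mu)^2))
  if (sd_pop == 0) {
    stop_dpp("degenerate property scale: all 20 values identical",
             "dpp_argument_error")
  }
  (raw - mu) / sd_pop
}

#' Load amino-acid property scales
#'
#' Reads a property-scale table (CSV: `residue` column plus one numeric
#' column per scale) and standardizes each scale with [normalize_scale()].
#' The packaged fixture provides the six scales used by the descriptor:
#' hydrophobicity, hydrophilicity, side-chain mass, pK1 (alpha-COOH),
#' pK2 (NH3) and isoelectric point at 25 C.
#'
#' @param path Path to a scale table, or `NULL` for the packaged fixture.
#' @return List with elements `raw` and `normalized` (20 x n matrices,
#'   residues in rows) and `source`.
#' @export
load_property_scales <- function(path = NULL) {
  if (is.null(path)) path <- dpp_extdata("property_scales.csv")
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  if (!"residue" %in% names(df)) {
    stop_dpp(sprintf("'%s' must have a `residue` column", path),
             "dpp_format_error")
  }
  scales <- setdiff(names(df), "residue")
  if (length(scales) == 0L) {
    stop_dpp(sprintf("'%s' contains no property columns", path),
             "dpp_format_error")
  }
  raw <- as.matrix(df[, scales])
  rownames(raw) <- df$residue
  if (!setequal(rownames(raw), AA_ALPHABET) || nrow(raw) != 20L) {
    stop_dpp(sprintf("'%s' must list each canonical residue exactly once",
                     path), "dpp_format_error")
  }
  raw <- raw[AA_ALPHABET, , drop = FALSE]
  normalized <- apply(raw, 2L, function(col) {
    names(col) <- AA_ALPHABET
    normalize_scale(col)
  })
  rownames(normalized) <- AA_ALPHABET
  list(raw = raw, normalized = normalized, source = path)
}

#' PseAAC featurization configuration
#'
#' Bundles the parameters of the type-2 (amphiphilic) pseudo amino acid
#' composition descriptor: the correlation rank `k` (maximum sequence lag),
#' the weight factor `omega` balancing composition against sequence-order
#' components, and the property scales. The defaults (`k = 1`,
#' `omega = 0.05`, six packaged scales) give the 26-dimensional descriptor
#' used throughout the package.
#'
#' @param k Positive integer correlation rank.
#' @param omega Non-negative weight factor.
#' @param scales Property scales from [load_property_scales()].
#' @return A `pseaac_config` object.
#' @export
pseaac_config <- function(k = 1L, omega = 0.05, scales = load_property_scales()) {
  if (!(is.numeric(k) && length(k) == 1L && k >= 1 && k == as.integer(k))) {
    stop_dpp("`k` must be a positive integer", "dpp_argument_error")
  }
  if (!(is.numeric(omega) && length(omega) == 1L && omega >= 0)) {
    stop_dpp("`omega` must be a non-negative number", "dpp_argument_error")
  }
  structure(
    list(k = as.integer(k), n = ncol(scales$normalized), omega = omega,
         scales = scales),
    class = "pseaac_config"
  )
}

#' @export
print.pseaac_config <- function(x, ...) {
  cat(sprintf(
    "<pseaac_config> type-2 PseAAC: k = %d, n = %d scales, omega = %g -> %d dims\n",
    x$k, x$n, x$omega, 20L + x$n * x$k))
  cat("  scales:", paste(colnames(x$scales$normalized), collapse = ", "), "\n")
  invisible(x)
}

#' Lag-j sequence-correlation factor for one property scale
#'
#' The type-2 (amphiphilic) order term: the mean product of standardized
#' property values over all residue pairs at lag `j`,
#' `tau = mean(H(R_i) * H(R_(i+j)))` for `i = 1 .. L-j`.
#'
#' @param sequence Peptide sequence.
#' @param scale_values Standardized property values, named by residue.
#' @param j Lag, `1 <= j <= L-1`.
#' @return The correlation factor (finite scalar).
#' @export
correlation_factor <- function(sequence, scale_values, j = 1L) {
  sequence <- validate_sequences(sequence, ids = "peptide")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  if (L <= j) {
    stop_dpp(sprintf("sequence '%s' too short for lag j = %d", sequence, j),
             "dpp_validation_error")
  }
  H <- scale_values[chars]
  mean(H[seq_len(L - j)] * H[seq_len(L - j) + j])
}

#' Type-2 pseudo amino acid composition of a peptide
#'
#' Computes the `20 + n*k` dimensional type-2 PseAAC descriptor. With
#' residue counts `f_1..f_20` and correlation factors `tau_(s,j)` for each
#' scale `s` and lag `j` (scale-major order), the components are
#' `f_i / D` for the first 20 and `omega * tau / D` for the rest, with the
#' shared normalizer `D = sum(f) + omega * sum(tau)`, so the full vector
#' sums to exactly 1. With `omega = 0` the descriptor reduces to the
#' relative amino-acid composition.
#'
#' @param sequence Peptide sequence of length at least `k + 1`.
#' @param config A [pseaac_config()].
#' @return Named numeric vector of length `20 + n*k`.
#' @examples
#' cfg <- pseaac_config()
#' v <- pseaac_vector("GPVRGPF", cfg)
#' length(v)  # 26
#' sum(v)     # 1
#' @export
pseaac_vector <- function(sequence, config = pseaac_config()) {
  stopifnot(inherits(config, "pseaac_config"))
  sequence <- validate_sequences(sequence, ids = "peptide")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  if (L < config$k + 1L) {
    stop_dpp(sprintf("sequence '%s' (L = %d) too short for k = %d",
                     sequence, L, config$k), "dpp_validation_error")
  }
  f <- vapply(AA_ALPHABET, function(a) sum(chars == a), numeric(1))
  H <- config$scales$normalized
  tau <- numeric(config$n * config$k)
  labels <- character(config$n * config$k)
  pos <- 1L
  for (s in seq_len(config$n)) {
    Hs <- H[, s]
    vals <- Hs[chars]
    for (j in seq_len(config$k)) {
      tau[pos] <- mean(vals[seq_len(L - j)] * vals[seq_len(L - j) + j])
      labels[pos] <- sprintf("tau_%s_%d", colnames(H)[s], j)
      pos <- pos + 1L
    }
  }
  denom <- sum(f) + config$omega * sum(tau)
  if (!is.finite(denom) || denom <= 0) {
    stop_dpp(sprintf("degenerate PseAAC normalizer for '%s'", sequence),
             "dpp_validation_error")
  }
  out <- c(f, config$omega * tau) / denom
  names(out) <- c(paste0("f_", AA_ALPHABET), labels)
  out
}

#' Featurize many peptides into a PseAAC matrix
#'
#' @param sequences Character vector of peptide sequences.
#' @param config A [pseaac_config()].
#' @return Numeric matrix, one row per peptide, `20 + n*k` named columns.
#' @export
pseaac_matrix <- function(sequences, config = pseaac_config()) {
  dim <- 20L + config$n * config$k
  out <- t(vapply(sequences, pseaac_vector, numeric(dim), config = config))
  rownames(out) <- NULL
  out
}

#' Per-class amino-acid frequency profile of a labeled set
#'
#' Pools all residues of each class and reports relative frequencies, the
#' diagnostic used to see compositional enrichment (e.g. the A/G/L/P/V
#' excess expected in DPP-4 inhibitory peptides) against a uniform 0.05
#' baseline.
#'
#' @param dataset Tibble with columns `sequence`, `label`.
#' @return Tibble with columns `label`, `residue`, `frequency`; per class
#'   the frequencies sum to 1. An empty class yields no rows, with a
#'   warning.
#' @export
aa_frequency_profile <- function(dataset) {
  if (is.null(dataset) || nrow(dataset) == 0L) {
    stop_dpp("`dataset` must be non-empty", "dpp_argument_error")
  }
  labs <- sort(unique(dataset$label))
  for (l in c(0L, 1L)) {
    if (!l %in% labs) warning(sprintf("class %d is empty; no profile", l))
  }
  purrr::map_dfr(labs, function(l) {
    seqs <- dataset$sequence[dataset$label == l]
    chars <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
    counts <- vapply(AA_ALPHABET, function(a) sum(chars == a), numeric(1))
    tibble::tibble(label = l, residue = AA_ALPHABET,
                   frequency = unname(counts / sum(counts)))
  })
}

#' Two-component PCA projection of a feature matrix
#'
#' Mean-centers the feature matrix and projects it onto its first
#' `n_components` principal axes, the diagnostic scatter used to inspect
#' class separation of the featurized sets. Uses the singular value
#' decomposition via [stats::prcomp()].
#'
#' @param features Numeric matrix (rows = samples), e.g. from
#'   [pseaac_matrix()].
#' @param n_components Number of components to keep (default 2).
#' @return List with `scores` (n x n_components matrix) and
#'   `explained_variance` (fractions in `[0, 1]`, non-increasing).
#' @export
pca_project <- function(features, n_components = 2L) {
  features <- as.matrix(features)
  if (nrow(features) < max(3L, n_components)) {
    stop_dpp("need at least 3 samples (and >= n_components)",
             "dpp_argument_error")
  }
  total_var <- sum(apply(features, 2L, stats::var))
  if (total_var == 0) {
    ## all points identical: projection collapses to the origin
    return(list(
      scores = matrix(0, nrow(features), n_components),
      explained_variance = rep(0, n_components)
    ))
  }
  fit <- stats::prcomp(features, center = TRUE, scale. = FALSE)
  nc <- min(n_components, ncol(fit$x))
  scores <- fit$x[, seq_len(nc), drop = FALSE]
  ev <- (fit$sdev^2 / sum(fit$sdev^2))[seq_len(nc)]
  if (nc < n_components) {  # rank-deficient input: pad with zero components
    scores <- cbind(scores, matrix(0, nrow(features), n_components - nc))
    ev <- c(ev, rep(0, n_components - nc))
  }
  list(scores = scores, explained_variance = ev)
}
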