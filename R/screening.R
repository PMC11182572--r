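#' Train a screening model artifact on a labeled peptide set
#'
#' Featurizes the dataset with the given PseAAC configuration, fits the
#' classifier, and bundles fit and featurization config into one artifact,
#' so a screen can never silently featurize differently from training.
#'
#' @param dataset Tibble with columns `sequence`, `label`.
#' @param spec A [model_spec()] (default: the LightGBM-style configuration).
#' @param config A [pseaac_config()].
#' @return A `dpp_model` artifact embedding the fit and `config`.
#' @export
train_screen_model <- function(dataset, spec = model_spec("lightgbm"),
                               config = pseaac_config()) {
  X <- pseaac_matrix(dataset$sequence, config)
  fit <- train_model(spec, X, dataset$label)
  structure(list(fit = fit, spec = spec, pseaac_config = config),
            class = "dpp_model")
}

#' Predict inhibitory probability for peptide sequences
#'
#' @param model A `dpp_model` from [train_screen_model()].
#' @param sequences Character vector of peptides.
#' @return Probabilities in `[0, 1]`.
#' @export
predict_peptides <- function(model, sequences) {
  stopifnot(inherits(model, "dpp_model"))
  predict_proba(model$fit, pseaac_matrix(sequences, model$pseaac_config))
}

same_pseaac_config <- function(a, b) {
  identical(a$k, b$k) && identical(a$omega, b$omega) &&
    identical(a$n, b$n) &&
    isTRUE(all.equal(a$scales$normalized, b$scales$normalized))
}

#' Construct a post-prediction filter
#'
#' Post filters stand in for the external adjudication tools of a
#' screening campaign (bioactivity score, intestinal absorption, toxicity
#' class). Each filter is a deterministic predicate on the peptide
#' sequence, optionally carrying a numeric or categorical value for the
#' report. Filters are conjunctive: a candidate must pass all of them.
#'
#' `post_filter()` builds a filter from an arbitrary function;
#' [always_pass_filter()] is the neutral stub;
#' [load_external_filter_table()] ingests a table of externally computed
#' values.
#'
#' @param name Filter name (report column prefix).
#' @param apply Function `sequence -> list(pass = logical, value = ...)`.
#' @param kind `"builtin-stub"` or `"external-table"`.
#' @return A `post_filter` object.
#' @export
post_filter <- function(name, apply, kind = "builtin-stub") {
  stopifnot(is.function(apply))
  structure(list(name = name, apply = apply, kind = kind),
            class = "post_filter")
}

#' @rdname post_filter
#' @export
always_pass_filter <- function(name = "always_pass") {
  post_filter(name, function(sequence) list(pass = TRUE, value = NA_real_))
}

#' Load an external adjudication table as a post filter
#'
#' The external web tools of a screening campaign are not reimplemented;
#' their per-peptide outputs are ingested as a CSV keyed by `sequence`.
#' A numeric column is gated by `cutoff` (strictly greater passes, the
#' same strict semantics as the probability gate); a categorical column is
#' gated by membership in `pass_values`. Sequences absent from the table
#' fail closed, with a warning.
#'
#' @param path CSV file with a `sequence` column and the value column.
#' @param column Name of the value column.
#' @param cutoff Numeric cutoff (value must be `> cutoff` to pass).
#' @param pass_values Character vector of passing values for categorical
#'   columns. Exactly one of `cutoff`/`pass_values` must be given.
#' @param name Filter name; defaults to the column name.
#' @return A `post_filter` of kind `"external-table"`.
#' @export
load_external_filter_table <- function(path, column, cutoff = NULL,
                                       pass_values = NULL, name = column) {
  if (!file.exists(path)) {
    stop_dpp(sprintf("filter table '%s' does not exist", path),
             "dpp_format_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sequence", column) %in% names(df))) {
    stop_dpp(sprintf("'%s' must have columns `sequence` and `%s`",
                     path, column), "dpp_format_error")
  }
  if (is.null(cutoff) == is.null(pass_values)) {
    stop_dpp("give exactly one of `cutoff` or `pass_values`",
             "dpp_argument_error")
  }
  values <- df[[column]]
  names(values) <- toupper(df$sequence)
  post_filter(name, kind = "external-table", apply = function(sequence) {
    sequence <- toupper(sequence)
    if (!sequence %in% names(values)) {
      warning(sprintf("filter '%s': no entry for '%s'; failing closed",
                      name, sequence))
      return(list(pass = FALSE, value = NA))
    }
    v <- values[[sequence]]
    pass <- if (!is.null(cutoff)) {
      is.finite(as.numeric(v)) && as.numeric(v) > cutoff
    } else {
      as.character(v) %in% pass_values
    }
    list(pass = pass, value = v)
  })
}

#' End-to-end virtual screen
#'
#' Runs the full pipeline: virtual proteolysis of the proteins with every
#' enzyme, length filtering and redundancy removal
#' ([build_prediction_set()]), PseAAC featurization with the model's
#' embedded configuration, probability prediction, the strict
#' `probability > threshold` gate, the conjunctive post-filter chain, and
#' ranking by descending probability (ties broken lexicographically).
#' Every retained candidate carries full provenance and per-filter
#' results; the stage log records the candidate count surviving each
#' stage.
#'
#' @param proteins Tibble of protein records.
#' @param rules An `enzyme_ruleset` or list of `enzyme_rule`s.
#' @param model A `dpp_model` artifact.
#' @param min_len,max_len Peptide length window (defaults 3 and 15).
#' @param threshold Probability gate (default 0.5, strict).
#' @param filters List of [post_filter()] objects (may be empty).
#' @param pseaac_config Optional config cross-check: if supplied it must
#'   equal the artifact's embedded config, otherwise the screen aborts
#'   rather than risk feature skew.
#' @return List with `candidates` (ranked tibble: `rank`, `sequence`,
#'   `probability`, per-filter columns, `provenance` list-column) and
#'   `stage_log` (tibble `stage`, `n`).
#' @export
screen_peptides <- function(proteins, rules, model, min_len = 3L,
                            max_len = 15L, threshold = 0.5,
                            filters = list(), pseaac_config = NULL) {
  stopifnot(inherits(model, "dpp_model"))
  if (!is.null(pseaac_config) &&
      !same_pseaac_config(pseaac_config, model$pseaac_config)) {
    stop_dpp(paste0("featurization config mismatch between model artifact ",
                    "and request"), "dpp_validation_error")
  }
  stage <- function(name, n) tibble::tibble(stage = name, n = as.integer(n))
  if (is.null(proteins) || nrow(proteins) == 0L) {
    empty <- tibble::tibble(rank = integer(0), sequence = character(0),
                            probability = numeric(0), provenance = list())
    log <- dplyr::bind_rows(stage("digested", 0), stage("predicted", 0),
                            stage("above_threshold", 0),
                            stage("post_filtered", 0))
    return(list(candidates = empty, stage_log = log))
  }
  peps <- build_prediction_set(proteins, rules, min_len, max_len)
  log <- stage("digested", nrow(peps))
  prob <- predict_peptides(model, peps$sequence)
  peps$probability <- prob
  log <- dplyr::bind_rows(log, stage("predicted", nrow(peps)))
  peps <- peps[peps$probability > threshold, , drop = FALSE]
  log <- dplyr::bind_rows(log, stage("above_threshold", nrow(peps)))
  keep <- rep(TRUE, nrow(peps))
  for (fl in filters) {
    stopifnot(inherits(fl, "post_filter"))
    res <- lapply(peps$sequence, fl$apply)
    pass <- vapply(res, function(r) isTRUE(r$pass), logical(1))
    vals <- vapply(res, function(r) {
      v <- r$value
      if (is.null(v) || length(v) != 1L) NA_character_ else as.character(v)
    }, character(1))
    peps[[paste0(fl$name, "_value")]] <- vals
    peps[[paste0(fl$name, "_pass")]] <- pass
    keep <- keep & pass
    log <- dplyr::bind_rows(log, stage(paste0("filter:", fl$name), sum(keep)))
  }
  peps <- peps[keep, , drop = FALSE]
  log <- dplyr::bind_rows(log, stage("post_filtered", nrow(peps)))
  peps <- peps[order(-peps$probability, peps$sequence), , drop = FALSE]
  peps$rank <- seq_len(nrow(peps))
  cols <- c("rank", "sequence", "probability",
            setdiff(names(peps), c("rank", "sequence", "probability",
                                   "length", "provenance")),
            "provenance")
  list(candidates = peps[, cols], stage_log = log)
}

#' Write a screening report
#'
#' Flattens the ranked candidates into a TSV mirroring the campaign's
#' result table: one row per (candidate, provenance) pair with columns
#' `rank`, `sequence`, `probability`, any per-filter columns, then
#' `protein_id`, `enzyme`, `start`, `end`. Ordering is deterministic. The
#' stage-survival log can be written alongside as JSON.
#'
#' @param screen Result of [screen_peptides()].
#' @param path Output TSV path.
#' @param summary_path Optional JSON path for the stage log.
#' @return `path`, invisibly.
#' @export
write_screen_report <- function(screen, path, summary_path = NULL) {
  cand <- screen$candidates
  flat <- if (nrow(cand) == 0L) {
    tibble::tibble(rank = integer(0), sequence = character(0),
                   probability = numeric(0), protein_id = character(0),
                   enzyme = character(0), start = integer(0),
                   end = integer(0))
  } else {
    tidyr::unnest(cand, "provenance")
  }
  readr::write_tsv(flat, path, progress = FALSE)
  if (!is.null(summary_path)) {
    jsonlite::write_json(
      list(stages = screen$stage_log), summary_path, auto_unbox = TRUE,
      digits = NA
    )
  }
  invisible(path)
}
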