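## Position labels recognized in rule tables, as offsets from the scissile
## bond. For a cut after (1-based) residue k: P1 = k, P2 = k-1, ..., P1p = k+1.
RULE_OFFSETS <- c(P4 = -3L, P3 = -2L, P2 = -1L, P1 = 0L, P1p = 1L, P2p = 2L)

parse_residue_set <- function(x, enzyme, where) {
  if (is.null(x) || identical(x, "")) return(character(0))
  chars <- strsplit(toupper(as.character(x)), "", fixed = TRUE)[[1L]]
  bad <- setdiff(chars, AA_ALPHABET)
  if (length(bad) > 0L) {
    stop_dpp(sprintf("enzyme '%s': %s set contains non-canonical '%s'",
                     enzyme, where, bad[1L]), "dpp_format_error")
  }
  unique(chars)
}

new_enzyme_rule <- function(name, specs, class = "unspecified",
                            dialect = "custom") {
  constrained <- vapply(specs, function(sp) {
    length(sp$allow$P1 %||% character(0)) > 0L ||
      length(sp$allow$P1p %||% character(0)) > 0L
  }, logical(1))
  if (!all(constrained)) {
    stop_dpp(sprintf("enzyme '%s': every site spec must constrain P1 or P1'",
                     name), "dpp_format_error")
  }
  structure(
    list(name = name, class = class, specs = specs, dialect = dialect),
    class = "enzyme_rule"
  )
}

#' @export
print.enzyme_rule <- function(x, ...) {
  cat(sprintf("<enzyme_rule> %s (%s protease, dialect '%s'), %d site spec(s)\n",
              x$name, x$class, x$dialect, length(x$specs)))
  for (sp in x$specs) {
    al <- vapply(names(sp$allow), function(p)
      sprintf("%s:%s", p, paste(sp$allow[[p]], collapse = "")), character(1))
    dn <- vapply(names(sp$deny), function(p)
      sprintf("%s:!%s", p, paste(sp$deny[[p]], collapse = "")), character(1))
    cat("  ", paste(c(al, dn), collapse = " "), "\n")
  }
  invisible(x)
}

#' Load an enzyme cleavage-rule table
#'
#' Reads a YAML rule table describing protease specificities as context
#' grammars around the scissile bond. Each enzyme has one or more site
#' specs; a peptide bond is cut iff at least one spec matches, i.e. every
#' `allow` position holds a listed residue and no `deny` position does.
#' Context positions that fall outside the protein never satisfy an `allow`
#' constraint and never violate a `deny` constraint.
#'
#' Two rule tables ship with the package: dialect `"milk_panel"`
#' (chymotrypsin "not before proline" exception disabled, matching the
#' hydrolysate provenance the screen is validated against) and dialect
#' `"expasy"` (conventional PeptideCutter-style exception enabled).
#'
#' @param path Path to a YAML rule table, or `NULL` to use a packaged
#'   dialect.
#' @param dialect Packaged dialect name when `path` is `NULL`:
#'   `"milk_panel"` (default) or `"expasy"`.
#' @return A named list of `enzyme_rule` objects (class `enzyme_ruleset`).
#' @examples
#' rules <- load_enzyme_rules()
#' names(rules)
#' @export
load_enzyme_rules <- function(path = NULL, dialect = c("milk_panel", "expasy")) {
  if (is.null(path)) {
    dialect <- match.arg(dialect)
    path <- dpp_extdata(sprintf("enzyme_rules_%s.yaml", dialect))
  }
  if (!file.exists(path)) {
    stop_dpp(sprintf("rule table '%s' does not exist", path), "dpp_format_error")
  }
  doc <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop_dpp(sprintf("malformed rule table '%s': %s", path,
                     conditionMessage(e)), "dpp_format_error")
  })
  if (is.null(doc$enzymes) || length(doc$enzymes) == 0L) {
    stop_dpp(sprintf("rule table '%s' lists no enzymes", path),
             "dpp_format_error")
  }
  tag <- doc$dialect %||% "custom"
  rules <- lapply(names(doc$enzymes), function(nm) {
    entry <- doc$enzymes[[nm]]
    specs <- lapply(entry$specs, function(sp) {
      allow <- lapply(sp$allow %||% list(), parse_residue_set,
                      enzyme = nm, where = "allow")
      deny <- lapply(sp$deny %||% list(), parse_residue_set,
                     enzyme = nm, where = "deny")
      bad <- setdiff(c(names(allow), names(deny)), names(RULE_OFFSETS))
      if (length(bad) > 0L) {
        stop_dpp(sprintf("enzyme '%s': unknown context position '%s'",
                         nm, bad[1L]), "dpp_format_error")
      }
      list(allow = allow, deny = deny)
    })
    new_enzyme_rule(nm, specs, class = entry$class %||% "unspecified",
                    dialect = tag)
  })
  names(rules) <- names(doc$enzymes)
  structure(rules, class = "enzyme_ruleset", dialect = tag,
            source = path)
}

resolve_rules <- function(rules, enzymes = NULL) {
  if (inherits(rules, "enzyme_rule")) rules <- list(rules)
  if (is.null(names(rules)) || any(!nzchar(names(rules)))) {
    names(rules) <- vapply(rules, `[[`, character(1), "name")
  }
  if (!is.null(enzymes) && !identical(enzymes, "all")) {
    missing <- setdiff(enzymes, names(rules))
    if (length(missing) > 0L) {
      stop_dpp(sprintf("unknown enzyme(s) %s; available: %s",
                       paste(missing, collapse = ", "),
                       paste(names(rules), collapse = ", ")),
               "dpp_lookup_error")
    }
    rules <- rules[enzymes]
  }
  rules
}

as_protein_record <- function(protein) {
  if (is.character(protein) && length(protein) == 1L) {
    return(list(id = "protein", sequence = validate_sequences(protein)))
  }
  if (is.data.frame(protein)) {
    if (nrow(protein) != 1L) {
      stop_dpp("expected a single protein record", "dpp_argument_error")
    }
    return(list(id = protein$id[[1L]], sequence = protein$sequence[[1L]]))
  }
  if (is.list(protein) && !is.null(protein$sequence)) {
    return(list(id = protein$id %||% "protein", sequence = protein$sequence))
  }
  stop_dpp("`protein` must be a sequence string or a protein record",
           "dpp_argument_error")
}

#' Cleavage sites of an enzyme on a protein
#'
#' Scans every peptide bond of the protein against the enzyme's site specs
#' and returns the cut positions. Positions are 0-based bond indices in
#' half-open coordinates: position `k` is the bond between residues `k-1`
#' and `k` (0-based), i.e. the bond after the k-th residue, so all cuts lie
#' in `[1, L-1]`.
#'
#' @param protein A protein record (one-row tibble from [read_fasta()], a
#'   `list(id=, sequence=)`, or a bare sequence string).
#' @param rule An `enzyme_rule` object.
#' @return Strictly increasing integer vector of cut positions.
#' @examples
#' rules <- load_enzyme_rules()
#' cleavage_sites("AKRPAARKA", rules$trypsin)  # 2, 7, 8
#' @export
cleavage_sites <- function(protein, rule) {
  if (!inherits(rule, "enzyme_rule")) {
    stop_dpp("`rule` must be an enzyme_rule (see load_enzyme_rules())",
             "dpp_argument_error")
  }
  p <- as_protein_record(protein)
  chars <- strsplit(p$sequence, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  if (L < 2L) return(integer(0))
  k <- seq_len(L - 1L)  # candidate bonds, after 1-based residue k
  hit <- rep(FALSE, L - 1L)
  for (sp in rule$specs) {
    ok <- rep(TRUE, L - 1L)
    for (pos in names(sp$allow)) {
      set <- sp$allow[[pos]]
      if (length(set) == 0L) next
      idx <- k + RULE_OFFSETS[[pos]]
      inb <- idx >= 1L & idx <= L
      res <- rep(NA_character_, L - 1L)
      res[inb] <- chars[idx[inb]]
      ok <- ok & inb & res %in% set
    }
    for (pos in names(sp$deny)) {
      set <- sp$deny[[pos]]
      if (length(set) == 0L) next
      idx <- k + RULE_OFFSETS[[pos]]
      inb <- idx >= 1L & idx <= L
      res <- rep(NA_character_, L - 1L)
      res[inb] <- chars[idx[inb]]
      ok <- ok & !(inb & res %in% set)
    }
    hit <- hit | ok
  }
  which(hit)
}

#' Complete in-silico digestion of a protein
#'
#' Simulates exhaustive hydrolysis (zero missed cleavages): the released
#' peptides are the maximal fragments between consecutive cleavage sites,
#' in N-to-C order. Concatenating the fragments reconstructs the protein
#' exactly. Each fragment carries provenance as 0-based half-open
#' coordinates on the source protein.
#'
#' @inheritParams cleavage_sites
#' @return Tibble with columns `sequence`, `protein_id`, `enzyme`,
#'   `start`, `end`.
#' @examples
#' rules <- load_enzyme_rules()
#' digest("AKRPAARKA", rules$trypsin)$sequence  # "AK" "RPAAR" "K" "A"
#' @export
digest <- function(protein, rule) {
  p <- as_protein_record(protein)
  cuts <- cleavage_sites(p, rule)
  L <- nchar(p$sequence)
  bounds <- c(0L, cuts, L)
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1L]
  tibble::tibble(
    sequence = substring(p$sequence, starts + 1L, ends),
    protein_id = p$id,
    enzyme = rule$name,
    start = starts,
    end = ends
  )
}

#' Build the unique-peptide prediction set from a protein and enzyme panel
#'
#' Digests every protein with every enzyme, keeps fragments within the
#' requested length window, and collapses to unique sequences with merged
#' provenance across all (protein, enzyme) origins. Output rows are ordered
#' lexicographically by sequence, so the set is deterministic.
#'
#' @param proteins Tibble of protein records ([read_fasta()]).
#' @param rules An `enzyme_ruleset` or list of `enzyme_rule` objects.
#' @param min_len,max_len Inclusive length window (defaults 3 and 15, the
#'   window used for the milk-protein screen).
#' @return Tibble with columns `sequence`, `length`, and `provenance` (a
#'   list-column of tibbles with `protein_id`, `enzyme`, `start`, `end`).
#' @export
build_prediction_set <- function(proteins, rules, min_len = 3L, max_len = 15L) {
  if (is.null(proteins) || nrow(proteins) == 0L) {
    stop_dpp("`proteins` must contain at least one record", "dpp_argument_error")
  }
  rules <- resolve_rules(rules)
  if (length(rules) == 0L) {
    stop_dpp("`rules` must contain at least one enzyme", "dpp_argument_error")
  }
  if (!(min_len >= 1L && min_len <= max_len)) {
    stop_dpp("need 1 <= min_len <= max_len", "dpp_argument_error")
  }
  frags <- purrr::map_dfr(seq_len(nrow(proteins)), function(i) {
    purrr::map_dfr(rules, function(rule) digest(proteins[i, ], rule))
  })
  frags <- dplyr::distinct(frags)  # duplicate inputs collapse to one origin
  frags <- frags[nchar(frags$sequence) >= min_len &
                   nchar(frags$sequence) <= max_len, , drop = FALSE]
  if (nrow(frags) == 0L) {
    return(tibble::tibble(sequence = character(0), length = integer(0),
                          provenance = list()))
  }
  frags <- dplyr::arrange(frags, .data$sequence, .data$protein_id,
                          .data$enzyme, .data$start)
  nested <- tidyr::nest(frags, provenance = c("protein_id", "enzyme",
                                              "start", "end"))
  nested$length <- nchar(nested$sequence)
  nested[, c("sequence", "length", "provenance")]
}

#' Retrace a peptide to the hydrolysis parameters that produce it
#'
#' Finds every (protein, enzyme) pair whose complete digest releases the
#' peptide, i.e. the hydrolysis parameters a practitioner would use to
#' obtain it. Returns one row per digest occurrence with the fragment
#' coordinates.
#'
#' @param peptide Peptide sequence (canonical alphabet).
#' @param proteins Tibble of protein records.
#' @param rules An `enzyme_ruleset` or list of `enzyme_rule` objects.
#' @return Tibble with columns `protein_id`, `enzyme`, `start`, `end`;
#'   zero rows when nothing generates the peptide.
#' @examples
#' \donttest{
#' retrace("GPVRGPF", milk_proteins(), load_enzyme_rules())
#' }
#' @export
retrace <- function(peptide, proteins, rules) {
  peptide <- validate_sequences(peptide, ids = "peptide")
  rules <- resolve_rules(rules)
  hits <- purrr::map_dfr(seq_len(nrow(proteins)), function(i) {
    ## cheap pre-screen: a fragment must be a substring of its source
    if (!grepl(peptide, proteins$sequence[[i]], fixed = TRUE)) {
      return(NULL)
    }
    purrr::map_dfr(rules, function(rule) {
      d <- digest(proteins[i, ], rule)
      d[d$sequence == peptide, c("protein_id", "enzyme", "start", "end")]
    })
  })
  if (nrow(hits) == 0L) {
    return(tibble::tibble(protein_id = character(0), enzyme = character(0),
                          start = integer(0), end = integer(0)))
  }
  dplyr::arrange(dplyr::distinct(hits), .data$protein_id, .data$enzyme,
                 .data$start)
}
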