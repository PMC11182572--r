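#' Configuration for the synthetic labeled-set generator
#'
#' The generator emulates the statistical structure of a curated
#' inhibitory-peptide training set: positives are drawn residue-wise from a
#' background distribution with a subset of residues enriched by a
#' multiplicative factor (hydrophobic A/G/L/P/V by default, the enrichment
#' observed in DPP-4 inhibitory peptides), negatives from the unmodified
#' background (uniform by default, emulating randomly sampled database
#' peptides). Defaults are the emulated study conditions: 1,103 positives,
#' an equally sized negative class, lengths 3-15, enrichment factor 3.
#'
#' @param n_pos,n_neg Class sizes.
#' @param length_range Inclusive `(min, max)` peptide length, within
#'   `[2, 50]`.
#' @param enriched_residues Residues enriched in positives.
#' @param enrichment_factor Multiplier (`>= 1`) on the background frequency
#'   of enriched residues; `1` plants no signal.
#' @param background Named probability vector over the 20 residues, or
#'   `NULL` for uniform.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return A `synth_config` object.
#' @export
synth_config <- function(n_pos = 1103L, n_neg = 1103L,
                         length_range = c(3L, 15L),
                         enriched_residues = c("A", "G", "L", "P", "V"),
                         enrichment_factor = 3,
                         background = NULL, seed = 1L) {
  if (n_pos < 0L || n_neg < 0L || (n_pos == 0L && n_neg == 0L)) {
    stop_dpp("need n_pos + n_neg > 0", "dpp_argument_error")
  }
  if (length(length_range) != 2L || length_range[1L] < 2L ||
      length_range[2L] > 50L || length_range[1L] > length_range[2L]) {
    stop_dpp("`length_range` must be (min, max) within [2, 50]",
             "dpp_argument_error")
  }
  if (enrichment_factor < 1) {
    stop_dpp("`enrichment_factor` must be >= 1", "dpp_argument_error")
  }
  enriched_residues <- validate_sequences(enriched_residues)
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20L), AA_ALPHABET)
  }
  if (!setequal(names(background), AA_ALPHABET) || any(background < 0)) {
    stop_dpp("`background` must be a non-negative vector over the 20 residues",
             "dpp_argument_error")
  }
  background <- background[AA_ALPHABET] / sum(background)
  structure(list(
    n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
    length_range = as.integer(length_range),
    enriched_residues = enriched_residues,
    enrichment_factor = enrichment_factor,
    background = background, seed = as.integer(seed)
  ), class = "synth_config")
}

sample_peptides <- function(n, probs, length_range) {
  lens <- sample(seq(length_range[1L], length_range[2L]), n, replace = TRUE)
  vapply(lens, function(L) {
    paste(sample(AA_ALPHABET, L, replace = TRUE, prob = probs), collapse = "")
  }, character(1))
}

#' Generate a synthetic labeled peptide set
#'
#' Draws positives from the enriched residue distribution and negatives
#' from the background, with lengths uniform over the configured range.
#' The output is a deterministic function of the config (including its
#' seed). Sequences that happen to arise in both classes would carry
#' conflicting labels and are removed from both, with a message.
#'
#' @param config A [synth_config()].
#' @return Tibble with columns `sequence`, `label`.
#' @export
generate_labeled_set <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  pos_probs <- config$background
  pos_probs[config$enriched_residues] <-
    pos_probs[config$enriched_residues] * config$enrichment_factor
  pos_probs <- pos_probs / sum(pos_probs)
  out <- with_seed(config$seed, {
    pos <- sample_peptides(config$n_pos, pos_probs, config$length_range)
    neg <- sample_peptides(config$n_neg, config$background,
                           config$length_range)
    tibble::tibble(
      sequence = c(pos, neg),
      label = rep(c(1L, 0L), c(config$n_pos, config$n_neg))
    )
  })
  conflicted <- intersect(out$sequence[out$label == 1L],
                          out$sequence[out$label == 0L])
  if (length(conflicted) > 0L) {
    message(sprintf("dropped %d sequence(s) sampled into both classes",
                    length(conflicted)))
    out <- out[!out$sequence %in% conflicted, , drop = FALSE]
  }
  out
}

rule_p1_allow <- function(rule) {
  sort(unique(unlist(lapply(rule$specs, function(sp) sp$allow$P1))))
}

rule_p1p_allow <- function(rule) {
  sort(unique(unlist(lapply(rule$specs, function(sp) sp$allow$P1p))))
}

## Residues that can never trigger a cut from either side of a bond.
rule_inert_residues <- function(rule) {
  inert <- setdiff(AA_ALPHABET, union(rule_p1_allow(rule),
                                      rule_p1p_allow(rule)))
  if (length(inert) == 0L) {
    stop_dpp(sprintf("enzyme '%s' leaves no inert residues to build filler",
                     rule$name), "dpp_argument_error")
  }
  inert
}

## Find flank residues (cutter before, follower after) under which a complete
## digest releases `pep` exactly, testing in a filler context.
find_flanks <- function(pep, rule, filler) {
  ctx <- paste(rep(filler[1L], 3L), collapse = "")
  for (cutter in rule_p1_allow(rule)) {
    for (follower in c(filler, AA_ALPHABET)) {
      trial <- paste0(ctx, cutter, pep, follower, ctx)
      if (pep %in% digest(trial, rule)$sequence) {
        return(c(cutter = cutter, follower = follower))
      }
    }
  }
  NULL
}

#' Generate a protein with planted cleavage-released peptides
#'
#' Constructs a seed-deterministic random substrate in which each planted
#' peptide is flanked by residues that create cleavage sites exactly at
#' its boundaries, so a complete digest with `rule` releases every planted
#' peptide intact. Filler is drawn from residues inert under the rule.
#' Peptides that cannot survive digestion (an internal residue matches the
#' rule's P1 allow-set, or no boundary context can cut them free) are an
#' argument error.
#'
#' @param length Total protein length (padded with inert filler).
#' @param rule An `enzyme_rule`.
#' @param planted_peptides Character vector of peptides to plant.
#' @param seed Integer seed.
#' @return A `list(id =, sequence =)` protein record (also a one-row
#'   tibble via `tibble::as_tibble`-compatible fields).
#' @export
generate_protein_with_planted_sites <- function(length, rule,
                                                planted_peptides = character(0),
                                                seed = 1L) {
  stopifnot(inherits(rule, "enzyme_rule"))
  planted_peptides <- validate_sequences(planted_peptides)
  p1 <- rule_p1_allow(rule)
  for (pep in planted_peptides) {
    chars <- strsplit(pep, "", fixed = TRUE)[[1L]]
    internal <- chars[-base::length(chars)]
    bad <- which(internal %in% p1)
    if (base::length(bad) > 0L) {
      stop_dpp(sprintf(
        "peptide '%s' cannot survive digestion by %s: internal residue '%s' at position %d matches the P1 allow-set",
        pep, rule$name, internal[bad[1L]], bad[1L]), "dpp_argument_error")
    }
  }
  filler <- rule_inert_residues(rule)
  blocks <- character(0)
  for (pep in planted_peptides) {
    fl <- find_flanks(pep, rule, filler)
    if (is.null(fl)) {
      stop_dpp(sprintf(
        "peptide '%s' cannot be cut free by %s: no boundary context creates both cleavage sites",
        pep, rule$name), "dpp_argument_error")
    }
    blocks <- c(blocks, paste0(fl[["cutter"]], pep, fl[["follower"]]))
  }
  core_len <- sum(nchar(blocks))
  n_gaps <- base::length(blocks) + 1L
  if (length < core_len + n_gaps) {
    stop_dpp(sprintf(
      "`length` = %d too small: need >= %d for %d planted peptide(s)",
      length, core_len + n_gaps, base::length(blocks)), "dpp_argument_error")
  }
  protein <- with_seed(seed, {
    assembled <- NULL
    for (attempt in seq_len(25L)) {
      spare <- length - core_len
      gap_len <- rep(spare %/% n_gaps, n_gaps)
      extra <- spare - sum(gap_len)
      if (extra > 0L) {
        gap_len[seq_len(extra)] <- gap_len[seq_len(extra)] + 1L
      }
      gaps <- vapply(gap_len, function(L) {
        paste(sample(filler, L, replace = TRUE), collapse = "")
      }, character(1))
      parts <- character(0)
      for (i in seq_along(blocks)) {
        parts <- c(parts, gaps[i], blocks[i])
      }
      candidate <- paste(c(parts, gaps[n_gaps]), collapse = "")
      frags <- digest(candidate, rule)$sequence
      if (all(planted_peptides %in% frags)) {
        assembled <- candidate
        break
      }
    }
    if (is.null(assembled)) {
      stop_dpp("failed to assemble a substrate releasing all planted peptides",
               "dpp_argument_error")
    }
    assembled
  })
  list(id = sprintf("synthetic_%s_seed%d", rule$name, as.integer(seed)),
       sequence = protein)
}

#' Brute-force reference digestion (test oracle)
#'
#' A deliberately naive re-derivation of complete digestion: every peptide
#' bond is tested against every site spec with literal per-position loops
#' and no vectorization. Used as the independent reference for
#' [cleavage_sites()] and [digest()] in property tests; not intended for
#' production use.
#'
#' @inheritParams cleavage_sites
#' @return Character vector of released fragments in N-to-C order.
#' @export
oracle_digest <- function(protein, rule) {
  p <- as_protein_record(protein)
  chars <- strsplit(p$sequence, "", fixed = TRUE)[[1L]]
  L <- base::length(chars)
  cuts <- integer(0)
  if (L >= 2L) {
    for (k in seq_len(L - 1L)) {
      cut_here <- FALSE
      for (sp in rule$specs) {
        ok <- TRUE
        for (pos in names(sp$allow)) {
          set <- sp$allow[[pos]]
          if (base::length(set) == 0L) next
          idx <- k + RULE_OFFSETS[[pos]]
          if (idx < 1L || idx > L || !(chars[idx] %in% set)) {
            ok <- FALSE
            break
          }
        }
        if (ok) {
          for (pos in names(sp$deny)) {
            set <- sp$deny[[pos]]
            idx <- k + RULE_OFFSETS[[pos]]
            if (idx >= 1L && idx <= L && chars[idx] %in% set) {
              ok <- FALSE
              break
            }
          }
        }
        if (ok) {
          cut_here <- TRUE
          break
        }
      }
      if (cut_here) cuts <- c(cuts, k)
    }
  }
  bounds <- c(0L, cuts, L)
  out <- character(base::length(bounds) - 1L)
  for (i in seq_len(base::length(bounds) - 1L)) {
    out[i] <- paste(chars[(bounds[i] + 1L):bounds[i + 1L]], collapse = "")
  }
  out
}

#' Generate a random protein panel
#'
#' Random substrates drawn residue-wise from a background distribution,
#' used by the `simulate` entry point and screening tests.
#'
#' @param n Number of proteins.
#' @param length Length of each protein.
#' @param background Residue distribution (`NULL` = uniform).
#' @param seed Integer seed.
#' @return Tibble of protein records (`id`, `description`, `sequence`).
#' @export
generate_protein_panel <- function(n = 6L, length = 200L, background = NULL,
                                   seed = 1L) {
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20L), AA_ALPHABET)
  }
  background <- background[AA_ALPHABET] / sum(background)
  with_seed(seed, {
    tibble::tibble(
      id = sprintf("synth_prot_%02d", seq_len(n)),
      description = sprintf("synthetic random substrate (seed %d)",
                            as.integer(seed)),
      sequence = vapply(seq_len(n), function(i) {
        paste(sample(AA_ALPHABET, length, replace = TRUE, prob = background),
              collapse = "")
      }, character(1))
    )
  })
}
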