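rules <- load_enzyme_rules()

test_that("trypsin cleavage matches hand enumeration and boundary contract", {
  ## AKRPAARKA: cut after K2 (K|R), not after R3 (R|P), after R7 and K8
  expect_equal(cleavage_sites("AKRPAARKA", rules$trypsin), c(2L, 7L, 8L))
  expect_equal(digest("AKRPAARKA", rules$trypsin)$sequence,
               c("AK", "RPAAR", "K", "A"))

  ## an enzyme with no matching residue cuts nothing
  expect_equal(cleavage_sites("AAAAGGGG", rules$trypsin), integer(0))
  d <- digest("AAAAGGGG", rules$trypsin)
  expect_equal(d$sequence, "AAAAGGGG")
  expect_equal(c(d$start, d$end), c(0L, 8L))

  ## cut positions always interior
  for (s in random_peptides(50, 2, 60, seed = 42)) {
    for (r in rules) {
      cuts <- cleavage_sites(s, r)
      expect_true(all(cuts >= 1L & cuts <= nchar(s) - 1L))
      expect_true(all(diff(cuts) > 0))
    }
  }
})

test_that("digest fragments reconstruct the substrate and carry exact coordinates", {
  subs <- random_peptides(60, 5, 120, seed = 7)
  for (s in subs) {
    for (r in rules) {
      d <- digest(s, r)
      expect_equal(paste(d$sequence, collapse = ""), s)
      expect_equal(substring(s, d$start + 1L, d$end), d$sequence)
    }
  }
})

test_that("prediction set applies the length window, dedups, and merges provenance", {
  prot <- tibble::tibble(id = "p1", description = "", sequence = "AKRPAARKA")
  ps <- build_prediction_set(prot, rules["trypsin"], min_len = 3, max_len = 15)
  expect_equal(ps$sequence, "RPAAR")  # AK, K, A filtered by length
  expect_equal(ps$provenance[[1]]$start, 2L)

  ## supplying the same protein twice changes nothing
  ps2 <- build_prediction_set(prot[c(1, 1), ], rules["trypsin"])
  expect_equal(ps2, ps)

  ## lexicographic, unique output on the milk panel
  milk <- milk_proteins()
  full <- build_prediction_set(milk, rules)
  expect_false(is.unsorted(full$sequence))
  expect_equal(anyDuplicated(full$sequence), 0L)
  expect_true(all(full$length >= 3 & full$length <= 15))

  expect_error(build_prediction_set(prot[0, ], rules),
               class = "dpp_argument_error")
  expect_error(build_prediction_set(prot, rules, min_len = 9, max_len = 3),
               class = "dpp_argument_error")
})

test_that("retrace returns exactly the digests that emit the peptide", {
  prots <- tibble::tibble(
    id = c("a", "b"),
    description = "",
    sequence = c("AKRPAARKA", "GGRPAARGG")
  )
  hits <- retrace("RPAAR", prots, rules)
  ## trypsin releases RPAAR from protein a; no enzyme releases it from b
  expect_true(any(hits$protein_id == "a" & hits$enzyme == "trypsin"))
  expect_false(any(hits$protein_id == "b" & hits$enzyme == "trypsin"))
  expect_equal(nrow(retrace("WWWWW", prots, rules)), 0L)

  ## digest/retrace consistency on random substrates
  for (s in random_peptides(15, 20, 80, seed = 11)) {
    prot <- tibble::tibble(id = "x", description = "", sequence = s)
    for (r in rules[c("trypsin", "pepsin_pH1.3", "papain")]) {
      d <- digest(prot, r)
      for (i in seq_len(nrow(d))) {
        h <- retrace(d$sequence[i], prot, list(r))
        expect_true(any(h$start == d$start[i] & h$end == d$end[i] &
                          h$enzyme == r$name))
      }
    }
  }
})

test_that("widening a P1 allow-set never removes cut positions", {
  base_specs <- list(list(allow = list(P1 = c("K")), deny = list(P1p = "P")))
  narrow <- dppscreen:::new_enzyme_rule("narrow", base_specs)
  wide_specs <- list(list(allow = list(P1 = c("K", "R", "L")),
                          deny = list(P1p = "P")))
  wide <- dppscreen:::new_enzyme_rule("wide", wide_specs)
  for (s in random_peptides(100, 5, 80, seed = 5)) {
    expect_true(all(cleavage_sites(s, narrow) %in% cleavage_sites(s, wide)))
  }
})

test_that("rule tables validate and unknown enzymes are a lookup error", {
  expect_s3_class(rules$trypsin, "enzyme_rule")
  expect_equal(attr(rules, "dialect"), "milk_panel")
  err <- expect_error(
    build_prediction_set(milk_proteins(),
                         dppscreen:::resolve_rules(rules, "elastase")),
    class = "dpp_lookup_error")
  expect_match(conditionMessage(err), "trypsin")  # lists available rules

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("dialect: broken", "enzymes:", "  e1:", "    specs:",
               "      - allow: {P2: A}"), bad)
  expect_error(load_enzyme_rules(bad), class = "dpp_format_error")
})

test_that("the chymotrypsin proline exception distinguishes the two dialects", {
  strict <- load_enzyme_rules(dialect = "expasy")
  ## F|P bond: cut in the milk_panel dialect, suppressed in the expasy one
  expect_true(5L %in% cleavage_sites("AAGGFPAAA", rules$chymotrypsin))
  expect_false(5L %in% cleavage_sites("AAGGFPAAA", strict$chymotrypsin))
})
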