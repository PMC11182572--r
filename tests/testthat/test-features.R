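scales <- load_property_scales()
cfg <- pseaac_config()

test_that("property scales standardize to zero mean and unit population SD", {
  for (s in colnames(scales$normalized)) {
    v <- scales$normalized[, s]
    expect_equal(mean(v), 0, tolerance = 1e-9)
    expect_equal(sqrt(mean((v - mean(v))^2)), 1, tolerance = 1e-9)
  }

  ## idempotence: a standardized scale is its own fixed point
  v <- scales$normalized[, 1]
  expect_equal(normalize_scale(v), v, tolerance = 1e-12)

  ## direct computation on an index scale
  raw <- stats::setNames(as.numeric(1:20), sort(AA20))
  nz <- normalize_scale(raw)
  expect_equal(mean(nz), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(nz^2)), 1, tolerance = 1e-12)

  expect_error(normalize_scale(stats::setNames(rep(7, 20), sort(AA20))),
               class = "dpp_argument_error")
})

test_that("correlation factors match closed forms and a naive loop", {
  H <- scales$normalized[, "hydrophobicity"]
  expect_equal(correlation_factor("GGGG", H, 1), H[["G"]]^2)
  expect_equal(correlation_factor("AG", H, 1), H[["A"]] * H[["G"]])
  ## independent naive loop
  s <- "GPVRGPF"
  chars <- strsplit(s, "")[[1]]
  tot <- 0
  for (i in 1:6) tot <- tot + H[[chars[i]]] * H[[chars[i + 1]]]
  expect_equal(correlation_factor(s, H, 1), tot / 6)

  err <- expect_error(correlation_factor("AG", H, 2),
                      class = "dpp_validation_error")
  expect_match(conditionMessage(err), "j = 2")
})

test_that("PseAAC vectors have the right dimension, normalization and limits", {
  v <- pseaac_vector("GPVRGPF", cfg)
  expect_length(v, 26L)
  expect_equal(sum(v), 1, tolerance = 1e-9)
  expect_true(all(v[1:20] >= 0))

  ## omega = 0 reduces to relative amino-acid composition
  cfg0 <- pseaac_config(omega = 0)
  v0 <- pseaac_vector("AAAA", cfg0)
  expect_equal(unname(v0[["f_A"]]), 1)
  expect_equal(unname(sum(abs(v0[21:26]))), 0)
  v0 <- pseaac_vector("GPVRGPF", cfg0)
  expect_equal(unname(v0[1:20]),
               as.vector(table(factor(strsplit("GPVRGPF", "")[[1]],
                                      levels = sort(AA20)))) / 7)

  ## normalization identity holds across random peptides
  for (s in random_peptides(40, 2, 30, seed = 3)) {
    expect_equal(sum(pseaac_vector(s, cfg)), 1, tolerance = 1e-9)
  }

  expect_error(pseaac_vector("A", cfg), class = "dpp_validation_error")
  expect_error(pseaac_vector("AXA", cfg), class = "dpp_validation_error")
})

test_that("PseAAC agrees with an independently coded brute-force oracle", {
  for (s in c("GPVRGPF", "HPHPHL", "FVAPFPEV",
              random_peptides(20, 2, 25, seed = 17))) {
    expect_equal(unname(pseaac_vector(s, cfg)),
                 oracle_pseaac(s, scales$raw, k = 1L, omega = 0.05),
                 tolerance = 1e-12)
  }
})

test_that("composition block ignores order; pseudo block is order-sensitive", {
  ## note: a full reversal ("GPA") would NOT do here — lag products are
  ## reversal-symmetric — so compare against a non-reversal permutation
  a <- pseaac_vector("APG", cfg)
  b <- pseaac_vector("PAG", cfg)
  ## identical composition: tau sums differ, so compare the f ratios
  expect_equal(unname(a[1:20] / sum(a[1:20])),
               unname(b[1:20] / sum(b[1:20])), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(unname(a[21:26]), unname(b[21:26]))))
})

test_that("affine rescaling of a raw scale leaves the descriptor unchanged", {
  raw2 <- scales$raw
  raw2[, "mass"] <- 3.7 * raw2[, "mass"] + 11
  tmp <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(residue = rownames(raw2), raw2, check.names = FALSE)
  write.csv(df, tmp, row.names = FALSE, quote = FALSE)
  cfg2 <- pseaac_config(scales = load_property_scales(tmp))
  expect_equal(pseaac_vector("GPVRGPF", cfg2), pseaac_vector("GPVRGPF", cfg),
               tolerance = 1e-12)
})

test_that("amino-acid frequency profiles are per-class simplices", {
  d <- tibble::tibble(sequence = c("AAG", "GGG"), label = c(1L, 0L))
  prof <- aa_frequency_profile(d)
  pos <- prof[prof$label == 1L, ]
  expect_equal(pos$frequency[pos$residue == "A"], 2 / 3)
  expect_equal(pos$frequency[pos$residue == "G"], 1 / 3)
  for (l in 0:1) {
    expect_equal(sum(prof$frequency[prof$label == l]), 1, tolerance = 1e-9)
  }
  expect_warning(aa_frequency_profile(d[d$label == 1L, ]), "class 0")
})

test_that("PCA projection matches an eigendecomposition oracle", {
  ## identical vectors collapse to the origin with zero explained variance
  X <- matrix(rep(c(1, 2, 3), each = 5), nrow = 5)
  pr <- pca_project(X)
  expect_equal(pr$scores, matrix(0, 5, 2))
  expect_equal(pr$explained_variance, c(0, 0))

  ## rank-1 data: first component captures ~100% of variance
  set.seed(2)
  t <- rnorm(30)
  X <- cbind(t, 2 * t, -t) + 0
  pr <- pca_project(X)
  expect_equal(pr$explained_variance[1], 1, tolerance = 1e-9)

  ## random cloud: agree with eigen() of the covariance matrix
  set.seed(4)
  X <- matrix(rnorm(200 * 6), 200, 6)
  pr <- pca_project(X)
  eg <- eigen(stats::cov(X), symmetric = TRUE)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  for (j in 1:2) {
    expect_equal(abs(pr$scores[, j]), abs(Xc %*% eg$vectors[, j])[, 1],
                 tolerance = 1e-8)
  }
  expect_equal(pr$explained_variance,
               (eg$values / sum(eg$values))[1:2], tolerance = 1e-8)

  expect_error(pca_project(X[1:2, ]), class = "dpp_argument_error")
})
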