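## Independent reference implementations used as test oracles. These are
## deliberately naive (literal loops, no shared code with the package paths
## they check).

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_peptides <- function(n, lmin, lmax, seed) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(AA20, sample(lmin:lmax, 1L), replace = TRUE), collapse = "")
  }, character(1))
}

## Exhaustive concordant-pair AUC (ties count one half).
oracle_auc <- function(y, p) {
  pos <- p[y == 1L]
  neg <- p[y == 0L]
  s <- 0
  for (a in pos) {
    for (b in neg) {
      s <- s + (a > b) + 0.5 * (a == b)
    }
  }
  s / (length(pos) * length(neg))
}

## Naive type-2 PseAAC: standardize scales, accumulate lag products with
## explicit loops, normalize by counts + omega * sum(tau).
oracle_pseaac <- function(sequence, raw_scales, k = 1L, omega = 0.05) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  H <- apply(raw_scales, 2L, function(x) {
    (x - mean(x)) / sqrt(sum((x - mean(x))^2) / length(x))
  })
  rownames(H) <- rownames(raw_scales)
  f <- vapply(AA20, function(a) sum(chars == a), numeric(1))
  taus <- numeric(0)
  for (s in seq_len(ncol(H))) {
    for (j in seq_len(k)) {
      tot <- 0
      for (i in seq_len(L - j)) {
        tot <- tot + H[chars[i], s] * H[chars[i + j], s]
      }
      taus <- c(taus, tot / (L - j))
    }
  }
  unname(c(f, omega * taus) / (sum(f) + omega * sum(taus)))
}

## Tiny labeled CSV on disk.
write_csv_fixture <- function(rows) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(c("sequence,label", vapply(rows, paste, character(1),
                                        collapse = ",")), path)
  path
}
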