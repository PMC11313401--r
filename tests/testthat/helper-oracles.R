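# Independent oracles used across the suite. Each is deliberately naive
# (scan/enumerate) and shares no code with the package implementation.

# brute-force restriction digest: scan every substring for the site word
oracle_digest <- function(seq, site, offset) {
  n <- nchar(seq)
  w <- nchar(site)
  if (n < w) return(n)
  starts <- which(substring(seq, 1:(n - w + 1), w:n) == site)
  cuts <- starts + offset - 1
  cuts <- sort(unique(cuts[cuts >= 1 & cuts < n]))
  as.integer(diff(c(0, cuts, n)))
}

# exhaustive global-alignment enumeration for tiny strings: returns the set
# of identity percentages achieved by the optimal-score alignments
oracle_identity_set <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  rec <- function(i, j) {
    if (i > nchar(a) && j > nchar(b))
      return(list(c(score = 0, matches = 0, len = 0)))
    out <- list()
    if (i <= nchar(a) && j <= nchar(b)) {
      hit <- substr(a, i, i) == substr(b, j, j)
      s <- if (hit) match else mismatch
      out <- c(out, lapply(rec(i + 1, j + 1), function(x)
        x + c(s, as.integer(hit), 1)))
    }
    if (i <= nchar(a))
      out <- c(out, lapply(rec(i + 1, j), function(x) x + c(gap, 0, 1)))
    if (j <= nchar(b))
      out <- c(out, lapply(rec(i, j + 1), function(x) x + c(gap, 0, 1)))
    out
  }
  res <- do.call(rbind, rec(1, 1))
  best <- res[res[, "score"] == max(res[, "score"]), , drop = FALSE]
  sort(unique(100 * best[, "matches"] / best[, "len"]))
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# substitute exactly k distinct positions, each to a different base
mutate_test <- function(seq, k) {
  chars <- strsplit(seq, "")[[1]]
  idx <- sample(length(chars), k)
  for (i in idx) chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  paste(chars, collapse = "")
}

# abundance table straight from a site/taxon assignment, for tests that
# need a small literal table
toy_abundance <- function(counts_by_site) {
  rows <- lapply(names(counts_by_site), function(s) {
    x <- counts_by_site[[s]]
    data.frame(isolate = paste0(s, "_", seq_len(sum(x))),
               taxon = rep(names(x), x), site = s, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  build_abundance(df[c("isolate", "taxon")], df[c("isolate", "site")])
}
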