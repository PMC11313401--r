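DNA_BASES <- c("A", "C", "G", "T")

#' Round half away from zero
#'
#' Fixed-decimal rounding where .5 always rounds up, matching how survey
#' percentages are conventionally printed (e.g. 28.75 -> 28.8). Base
#' `round()` rounds half to even, which would print 28.7 here.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(c(0.25, 0.35), 1)
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

check_dna <- function(x, what = "sequence") {
  bad <- regexpr("[^ACGT]", x)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop(sprintf("%s contains a non-ACGT character ('%s') at position %d",
                 what, substr(x[i], bad[i], bad[i]), bad[i]), call. = FALSE)
  }
  invisible(x)
}

stopifnot_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x > max)
    stop(sprintf("'%s' must be a single number in [%s, %s]", name, min, max),
         call. = FALSE)
  invisible(x)
}

# random DNA sequence as a single string
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# substitute `k` random positions (restricted to `positions` when given),
# each to a uniformly chosen different base
mutate_dna <- function(seq, k, positions = NULL) {
  if (k <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  pool <- if (is.null(positions)) seq_along(chars) else positions
  k <- min(k, length(pool))
  idx <- sample(pool, k)
  for (i in idx) {
    chars[i] <- sample(setdiff(DNA_BASES, chars[i]), 1)
  }
  paste(chars, collapse = "")
}

# substitute exactly the given positions (used for planting species-defining
# differences on disjoint position blocks)
mutate_at <- function(seq, positions) {
  if (length(positions) == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  for (i in positions) {
    chars[i] <- sample(setdiff(DNA_BASES, chars[i]), 1)
  }
  paste(chars, collapse = "")
}

# connected components of an undirected adjacency matrix (logical, symmetric);
# returns integer component membership in input order
adjacency_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}
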