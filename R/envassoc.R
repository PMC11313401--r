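#' Transform an abundance table for ordination
#'
#' `proportion` row-normalises each site (rows sum to 1);
#' `hellinger` takes square roots of the proportions (rows have unit sum of
#' squares). The proportion transform is a fixed point of itself.
#'
#' @param table an [build_abundance()] table (the total row is dropped).
#' @param method `"proportion"` or `"hellinger"`.
#' @return numeric site-by-taxon matrix.
#' @export
transform_composition <- function(table, method = c("proportion", "hellinger")) {
  method <- match.arg(method)
  m <- site_rows(table)
  if (sum(m) == 0) stop("grand total is zero", call. = FALSE)
  if (any(rowSums(m) == 0))
    stop("empty site row(s): ",
         paste(rownames(m)[rowSums(m) == 0], collapse = ", "), call. = FALSE)
  out <- vegan::decostand(m, method = switch(method, proportion = "total",
                                             hellinger = "hellinger"))
  matrix(as.numeric(out), nrow(out), ncol(out), dimnames = dimnames(m))
}

#' Principal component analysis of community composition
#'
#' Column-centred singular value decomposition (via [stats::prcomp()],
#' unscaled). Axis `k` explains `sigma_k^2 / sum(sigma^2)` of the variance.
#' Axis signs follow the convention that the first nonzero taxon loading on
#' each axis is positive.
#'
#' @param mat numeric site-by-taxon matrix, e.g. from
#'   [transform_composition()] (>= 2 sites, >= 2 taxa).
#' @param n_axes number of axes to retain (default 2, capped at the rank).
#' @return an object of class `ordination`: list with `site_scores`,
#'   `taxon_loadings`, `variance_explained` (fractions, all axes),
#'   `n_axes`, `centered` (the centred data matrix).
#' @export
pca_ordination <- function(mat, n_axes = 2) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2) stop("ordination needs at least 2 sites", call. = FALSE)
  if (ncol(mat) < 2) stop("ordination needs at least 2 taxa", call. = FALSE)
  p <- prcomp(mat, center = TRUE, scale. = FALSE)
  totvar <- sum(p$sdev^2)
  varfrac <- if (totvar > 0) p$sdev^2 / totvar else rep(0, length(p$sdev))
  k <- min(n_axes, ncol(p$rotation))
  scores <- p$x[, seq_len(k), drop = FALSE]
  loadings <- p$rotation[, seq_len(k), drop = FALSE]
  for (ax in seq_len(k)) {
    nz <- which(abs(loadings[, ax]) > 1e-12)
    if (length(nz) && loadings[nz[1], ax] < 0) {
      loadings[, ax] <- -loadings[, ax]
      scores[, ax] <- -scores[, ax]
    }
  }
  structure(list(site_scores = scores, taxon_loadings = loadings,
                 variance_explained = varfrac, n_axes = k,
                 centered = scale(mat, center = TRUE, scale = FALSE)),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("<ordination> %d sites x %d taxa, %d axes (%.1f%% variance)\n",
              nrow(x$site_scores), nrow(x$taxon_loadings), x$n_axes,
              100 * sum(x$variance_explained[seq_len(x$n_axes)])))
  invisible(x)
}

#' Correlate environmental variables with ordination axes
#'
#' Environmental variables enter passively: each variable is standardised
#' (zero mean, unit variance) and its Pearson correlation with the site
#' scores of each retained axis gives the biplot arrow; arrow length is
#' `sqrt(sum of squared correlations)`. Constant variables get zero-length
#' arrows with a warning.
#'
#' @param ordination an [pca_ordination()] result.
#' @param env data.frame or matrix of environmental variables; rows must
#'   align with the ordination's sites (matched by rowname when available).
#' @return data.frame: `variable`, one `r_<axis>` column per axis,
#'   `arrow_length`.
#' @export
variable_arrows <- function(ordination, env) {
  stopifnot(inherits(ordination, "ordination"))
  scores <- ordination$site_scores
  env <- as.data.frame(env)
  if (!is.null(rownames(env)) && all(rownames(scores) %in% rownames(env))) {
    env <- env[rownames(scores), , drop = FALSE]
  } else if (nrow(env) != nrow(scores)) {
    stop("environment rows do not align with ordination sites", call. = FALSE)
  }
  rows <- lapply(names(env), function(v) {
    x <- as.numeric(env[[v]])
    if (sd(x) == 0) {
      warning(sprintf("variable '%s' is constant; correlation set to 0", v),
              call. = FALSE)
      r <- rep(0, ncol(scores))
    } else {
      z <- as.numeric(scale(x))
      r <- vapply(seq_len(ncol(scores)), function(ax) {
        s <- scores[, ax]
        if (sd(s) == 0) 0 else cor(z, s)
      }, numeric(1))
    }
    out <- data.frame(variable = v, stringsAsFactors = FALSE)
    for (ax in seq_along(r)) out[[paste0("r_", colnames(scores)[ax])]] <- r[ax]
    out$arrow_length <- sqrt(sum(r^2))
    out
  })
  do.call(rbind, rows)
}

#' Bray-Curtis dissimilarity between sites
#'
#' `BC(s, t) = sum |x_si - x_ti| / sum (x_si + x_ti)`: 0 for identical
#' sites, 1 for sites with disjoint taxa.
#'
#' @param table an [build_abundance()] table (the total row is dropped). At
#'   most one site row may be empty; a pair of empty sites is undefined and
#'   raises an error.
#' @return symmetric site-by-site matrix in `[0, 1]` with zero diagonal.
#' @export
bray_curtis <- function(table) {
  m <- site_rows(table)
  if (sum(m) == 0) stop("grand total is zero", call. = FALSE)
  if (sum(rowSums(m) == 0) >= 2)
    stop("Bray-Curtis is undefined between two empty sites", call. = FALSE)
  as.matrix(vegan::vegdist(m, method = "bray"))
}
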