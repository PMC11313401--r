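#' Build a site-by-taxon abundance table
#'
#' Cross-tabulates isolate counts by site and taxon label (species or IGS
#' type) and appends an all-sites total row named `"All"`. Cell `(s, t)` is
#' the number of isolates at site `s` carrying label `t`; the grand total
#' equals the isolate count.
#'
#' @param assignments data.frame with columns `isolate`, `taxon`.
#' @param metadata data.frame with columns `isolate`, `site` (no site may be
#'   named `"All"`).
#' @return integer matrix of class `abundance_table`, rows = sites plus
#'   `"All"`, columns = taxa.
#' @export
build_abundance <- function(assignments, metadata) {
  stopifnot(all(c("isolate", "taxon") %in% names(assignments)),
            all(c("isolate", "site") %in% names(metadata)))
  if (nrow(assignments) == 0) stop("no isolates", call. = FALSE)
  site <- setNames(as.character(metadata$site), metadata$isolate)
  miss <- assignments$isolate[is.na(site[assignments$isolate]) |
                                is.na(assignments$taxon)]
  if (length(miss))
    stop("isolates missing a site or taxon label: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (any(metadata$site == "All"))
    stop("'All' is reserved for the total row", call. = FALSE)
  tab <- table(site = site[assignments$isolate],
               taxon = as.character(assignments$taxon))
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab), dimnames = dimnames(tab))
  m <- rbind(m, All = colSums(m))
  class(m) <- c("abundance_table", class(m))
  m
}

# site rows of an abundance table (drop the total row if present)
site_rows <- function(table) {
  m <- unclass(table)
  m[rownames(m) != "All", , drop = FALSE]
}

#' Relative abundances as printed percentages
#'
#' `100 * count / grand total`, rounded half-up to one decimal (the
#' conventional printed style); the total row gives each taxon's overall
#' relative abundance.
#'
#' @param table an [build_abundance()] table (grand total must be > 0).
#' @return numeric matrix of percentages, same shape as `table`.
#' @export
relative_abundance <- function(table) {
  m <- site_rows(table)
  total <- sum(m)
  if (total == 0) stop("grand total is zero", call. = FALSE)
  p <- 100 * unclass(table) / total
  round_half_up(p, 1)
}

#' Hill-number diversity of a count vector
#'
#' Effective numbers of species of order 0, 1 and 2: `q0` is richness,
#' `q1 = exp(H)` with Shannon entropy `H` in natural log units, and `q2` is
#' the inverse Simpson concentration. `q0 >= q1 >= q2 >= 1` for any
#' non-empty community, with equality iff abundances are uniform.
#'
#' @param counts non-negative counts, sum > 0.
#' @return named numeric vector `c(q0, q1, q2)`.
#' @examples
#' hill_numbers(c(3, 1)) # 2, 1.7548, 1.6
#' @export
hill_numbers <- function(counts) {
  if (any(counts < 0) || any(is.na(counts)))
    stop("counts must be non-negative", call. = FALSE)
  if (sum(counts) == 0) stop("all counts are zero", call. = FALSE)
  counts <- counts[counts > 0]
  c(q0 = length(counts),
    q1 = exp(vegan::diversity(counts, index = "shannon")),
    q2 = vegan::diversity(counts, index = "invsimpson"))
}

#' Per-site alpha-diversity profile
#'
#' @param table an [build_abundance()] table.
#' @return data.frame: `site`, `q0`, `q1`, `q2` (one row per site plus the
#'   all-sites pool).
#' @export
diversity_profile <- function(table) {
  m <- unclass(table)
  rows <- lapply(rownames(m), function(s) {
    h <- hill_numbers(m[s, ])
    data.frame(site = s, q0 = h[["q0"]], q1 = h[["q1"]], q2 = h[["q2"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Dominant taxa per site
#'
#' The most abundant taxon at each site with its within-site share;
#' co-dominant taxa (count ties) are all listed.
#'
#' @param table an [build_abundance()] table; every site must hold at least
#'   one isolate.
#' @return data.frame: `site`, `taxon`, `share` (percent of the site's
#'   isolates, half-up 1 decimal).
#' @export
dominant_taxa <- function(table) {
  m <- site_rows(table)
  if (any(rowSums(m) == 0))
    stop("site(s) without isolates: ",
         paste(rownames(m)[rowSums(m) == 0], collapse = ", "), call. = FALSE)
  rows <- lapply(rownames(m), function(s) {
    x <- m[s, ]
    top <- names(x)[x == max(x)]
    data.frame(site = s, taxon = top,
               share = round_half_up(100 * max(x) / sum(x), 1),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
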