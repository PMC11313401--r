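#' Pairwise percent identity from global alignment
#'
#' Aligns two nucleotide sequences with a Needleman-Wunsch global alignment
#' (end gaps penalised) under a simple scoring scheme (defaults: match +1,
#' mismatch -1, gap -2, linear) and reports
#' `100 * matched columns / alignment length`. By default the denominator is
#' the full alignment length including terminal gap columns - one
#' unambiguous convention; set `include_terminal_gaps = FALSE` to exclude
#' terminal gap runs from both counts.
#'
#' The input pair is canonicalised (lexicographically ordered) before
#' alignment, so the function is exactly symmetric even when co-optimal
#' alignments with different match counts exist.
#'
#' @param a,b non-empty ACGT sequences.
#' @param match,mismatch,gap alignment scores (gap is per gapped column).
#' @param include_terminal_gaps count terminal gap columns in the
#'   denominator (default TRUE).
#' @return identity as a percentage in `[0, 100]`.
#' @examples
#' percent_identity("ACGT", "ACGA") # 75
#' percent_identity("ACGT", "AC")   # 50
#' @export
percent_identity <- function(a, b, match = 1, mismatch = -1, gap = -2,
                             include_terminal_gaps = TRUE) {
  for (s in list(a, b))
    if (!is.character(s) || length(s) != 1 || !nzchar(s))
      stop("both sequences must be single non-empty strings", call. = FALSE)
  check_dna(a, "sequence 'a'")
  check_dna(b, "sequence 'b'")
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  aln <- .nw_align_cpp(a, b, match, mismatch, gap)
  if (include_terminal_gaps) {
    100 * aln$matches / aln$length
  } else {
    if (aln$core_length == 0) return(0)
    100 * aln$core_matches / aln$core_length
  }
}

#' Pairwise identity matrix
#'
#' @param sequences named character vector of sequences.
#' @param ... passed to [percent_identity()].
#' @return symmetric matrix of percent identities (diagonal 100).
#' @export
pairwise_identity <- function(sequences, ...) {
  n <- length(sequences)
  ids <- names(sequences)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  if (n < 2) return(m)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- percent_identity(sequences[[i]], sequences[[j]], ...)
    }
  }
  m
}

MLSA_LOCI <- c("recA", "atpD", "rpoB")

#' Concatenate housekeeping loci for MLSA
#'
#' Concatenates each strain's recA, atpD and rpoB sequences in that fixed
#' order. The concatenation length is the sum of the locus lengths (289 +
#' 297 + 599 = 1185 nt for the standard amplicon trims).
#'
#' @param locus_set named list of per-locus named character vectors
#'   (`locus_set$recA["strainA"]` etc.); must contain all of
#'   `recA`, `atpD`, `rpoB`.
#' @param strains strains to concatenate (default: strains of the recA
#'   table).
#' @return named character vector of concatenated sequences.
#' @export
concat_mlsa <- function(locus_set, strains = names(locus_set$recA)) {
  missing_locus <- setdiff(MLSA_LOCI, names(locus_set))
  if (length(missing_locus))
    stop("locus set is missing: ", paste(missing_locus, collapse = ", "),
         call. = FALSE)
  vapply(setNames(strains, strains), function(s) {
    parts <- vapply(MLSA_LOCI, function(l) {
      x <- locus_set[[l]][s]
      if (is.na(x) || !nzchar(x))
        stop(sprintf("strain '%s' is missing locus %s", s, l), call. = FALSE)
      x
    }, character(1))
    paste(parts, collapse = "")
  }, character(1))
}

#' Assign species by best identity against a type-strain panel
#'
#' Each query is compared to every panel species by [percent_identity()] on
#' the concatenated MLSA sequence. The best-scoring species is reported; a
#' query is `assigned` when its best identity is at or above `threshold`
#' (a boundary hit counts as assigned) and `novel` otherwise. Best-identity
#' ties go to the alphabetically first species name and are flagged.
#'
#' @param queries named character vector of concatenated query sequences.
#' @param panel named character vector: species name -> concatenated
#'   type-strain sequence (>= 1 species).
#' @param threshold species-boundary identity, percent (default 97.0).
#' @param ... passed to [percent_identity()].
#' @return data.frame: `strain`, `label` (species name, or NA for novel
#'   strains until genospecies are clustered), `best_species`,
#'   `best_identity`, `status` (`assigned`/`novel`), `ambiguous`.
#' @export
assign_species <- function(queries, panel, threshold = 97.0, ...) {
  if (length(panel) == 0 || is.null(names(panel)))
    stop("'panel' must be a named vector of type-strain sequences", call. = FALSE)
  res <- lapply(names(queries), function(q) {
    idt <- vapply(panel, function(p) percent_identity(queries[[q]], p, ...),
                  numeric(1))
    best <- max(idt)
    hits <- sort(names(panel)[idt == best])
    assigned <- best >= threshold
    data.frame(strain = q,
               label = if (assigned) hits[1] else NA_character_,
               best_species = hits[1],
               best_identity = best,
               status = if (assigned) "assigned" else "novel",
               ambiguous = length(hits) > 1,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Cluster novel strains into numbered genospecies
#'
#' Single-linkage clustering of below-threshold ("novel") strains: two
#' strains fall in the same genospecies when they are connected by a chain
#' of pairwise identities at or above `intra_threshold`. Clusters are
#' numbered by decreasing size, ties by first appearance, and labelled with
#' Roman numerals ("genosp. I", "genosp. II", ...).
#'
#' @param sequences named character vector of concatenated MLSA sequences of
#'   the novel strains.
#' @param intra_threshold within-genospecies identity, percent (default 97).
#' @param ... passed to [percent_identity()].
#' @return data.frame: `strain`, `genospecies` (label), `cluster` (integer).
#' @export
cluster_genospecies <- function(sequences, intra_threshold = 97.0, ...) {
  ids <- names(sequences)
  if (length(sequences) == 0)
    return(data.frame(strain = character(0), genospecies = character(0),
                      cluster = integer(0), stringsAsFactors = FALSE))
  idm <- pairwise_identity(sequences, ...)
  comp <- adjacency_components(idm >= intra_threshold)
  sizes <- as.integer(table(comp)[as.character(seq_len(max(comp)))])
  first <- match(seq_len(max(comp)), comp)
  ord <- order(-sizes, first)
  newnum <- integer(max(comp))
  newnum[ord] <- seq_along(ord)
  cl <- newnum[comp]
  data.frame(strain = ids,
             genospecies = paste0("genosp. ", as.character(as.roman(cl))),
             cluster = cl,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Assign a symbiovar from a nodulation-gene sequence
#'
#' Nearest-reference classification of nodC (or nifH) sequences: each query
#' takes the symbiovar of its highest-identity reference, provided the
#' identity reaches `min_identity`; otherwise the call is "unresolved".
#'
#' @param queries named character vector of nodC (or nifH) sequences.
#' @param references data.frame with columns `name`, `symbiovar`, `seq`
#'   (>= 1 reference per symbiovar of interest).
#' @param min_identity minimum identity for a call, percent (default 90).
#' @param ... passed to [percent_identity()].
#' @return data.frame: `strain`, `symbiovar`, `nearest_reference`,
#'   `identity`.
#' @export
assign_symbiovar <- function(queries, references, min_identity = 90.0, ...) {
  stopifnot(all(c("name", "symbiovar", "seq") %in% names(references)),
            nrow(references) >= 1)
  res <- lapply(names(queries), function(q) {
    idt <- vapply(references$seq, function(r)
      percent_identity(queries[[q]], r, ...), numeric(1))
    i <- which.max(idt)
    data.frame(strain = q,
               symbiovar = if (idt[i] >= min_identity)
                 references$symbiovar[i] else "unresolved",
               nearest_reference = references$name[i],
               identity = idt[i],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Neighbour-joining tree from a distance matrix
#'
#' Standard neighbour-joining agglomeration (via \pkg{ape}); for an
#' additive distance matrix the generating topology is recovered. Negative
#' branch lengths are clamped to zero (with a message). The 2-taxon case is
#' a single edge split evenly between the two pendants.
#'
#' @param d symmetric numeric matrix with zero diagonal and >= 2 labelled
#'   taxa (asymmetric or negative-diagonal input is an error).
#' @param newick_file optional path; when given, the tree is also written
#'   as newick text.
#' @return an \pkg{ape} `phylo` tree (unrooted).
#' @export
nj_tree <- function(d, newick_file = NULL) {
  d <- as.matrix(d)
  if (nrow(d) < 2) stop("need at least 2 taxa", call. = FALSE)
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix must be symmetric", call. = FALSE)
  if (any(diag(d) != 0) || any(d < 0))
    stop("distance matrix must have zero diagonal and non-negative entries",
         call. = FALSE)
  if (nrow(d) == 2) {
    tr <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
               edge.length = rep(d[1, 2] / 2, 2),
               tip.label = rownames(d), Nnode = 1L)
    class(tr) <- "phylo"
  } else {
    tr <- ape::nj(stats::as.dist(d))
  }
  if (any(tr$edge.length < 0)) {
    message("nj_tree: clamped ", sum(tr$edge.length < 0),
            " negative branch length(s) to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  if (!is.null(newick_file)) ape::write.tree(tr, file = newick_file)
  tr
}

#' Group strains by cutting a 16S rRNA distance tree
#'
#' Builds a neighbour-joining tree on 16S percent-identity distances
#' (`100 - identity`) and groups leaves whose tree (cophenetic) distance is
#' within `depth`, by single linkage. The grouping is descriptive only - it
#' carries no weight in species assignment, where MLSA is the decisive
#' marker.
#'
#' @param sequences named character vector of 16S sequences (>= 2).
#' @param depth grouping depth on the percent-identity distance scale
#'   (default 1, i.e. sequences linked within 1\% tree distance).
#' @param ... passed to [percent_identity()].
#' @return data.frame: `strain`, `group` (integer, numbered by decreasing
#'   group size then first appearance).
#' @export
group_16s <- function(sequences, depth = 1, ...) {
  stopifnot(length(sequences) >= 2)
  d <- 100 - pairwise_identity(sequences, ...)
  tr <- nj_tree(d)
  coph <- ape::cophenetic.phylo(tr)[names(sequences), names(sequences)]
  comp <- adjacency_components(coph <= depth)
  sizes <- as.integer(table(comp)[as.character(seq_len(max(comp)))])
  first <- match(seq_len(max(comp)), comp)
  newnum <- integer(max(comp))
  newnum[order(-sizes, first)] <- seq_len(max(comp))
  data.frame(strain = names(sequences), group = newnum[comp],
             row.names = NULL, stringsAsFactors = FALSE)
}
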