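#' Define a restriction endonuclease
#'
#' @param name enzyme name, e.g. `"HaeIII"`.
#' @param site recognition site, an ACGT word (all three default enzymes have
#'   palindromic sites, so single-strand scanning is sufficient).
#' @param offset cut offset: the duplex is cut after `offset` bases of the
#'   recognition site on the scanned strand (`0 <= offset <= nchar(site)`).
#' @return an object of class `restriction_enzyme`.
#' @examples
#' restriction_enzyme("HaeIII", "GGCC", 2) # GG^CC
#' @export
restriction_enzyme <- function(name, site, offset) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  check_dna(site, sprintf("recognition site of %s", name))
  stopifnot_scalar_number(offset, "offset", 0, nchar(site))
  structure(list(name = name, site = site, offset = as.integer(offset)),
            class = "restriction_enzyme")
}

#' @export
print.restriction_enzyme <- function(x, ...) {
  cut <- paste0(substr(x$site, 1, x$offset), "^",
                substr(x$site, x$offset + 1, nchar(x$site)))
  cat(sprintf("<restriction_enzyme> %s (%s)\n", x$name, cut))
  invisible(x)
}

#' The three IGS-typing enzymes
#'
#' HaeIII (GG^CC), MspI (C^CGG) and HhaI (GCG^C), the enzyme set used for
#' 16S-23S rRNA intergenic-spacer PCR-RFLP fingerprinting of rhizobia. The
#' list order is the fixed enzyme order used in pattern keys.
#'
#' @return named list of [restriction_enzyme()] objects.
#' @export
default_enzymes <- function() {
  list(HaeIII = restriction_enzyme("HaeIII", "GGCC", 2),
       MspI   = restriction_enzyme("MspI",   "CCGG", 1),
       HhaI   = restriction_enzyme("HhaI",   "GCGC", 3))
}

#' In-silico restriction digest of a linear amplicon
#'
#' Scans the (single) given strand for every occurrence of the recognition
#' site, cuts after `site start + offset - 1`, and returns the fragment
#' lengths between successive cuts. Overlapping site occurrences all cut
#' (complete digest). The molecule is treated as linear; fragment lengths
#' always sum to the amplicon length.
#'
#' @param sequence amplicon sequence, uppercase ACGT (ambiguity codes are
#'   rejected with the offending position named).
#' @param enzyme a [restriction_enzyme()].
#' @return integer vector of fragment lengths in molecule order, with
#'   attribute `enzyme` (the enzyme name).
#' @examples
#' digest_amplicon("CCGGCCGG", default_enzymes()$MspI) # 1, 4, 3
#' @export
digest_amplicon <- function(sequence, enzyme) {
  stopifnot(inherits(enzyme, "restriction_enzyme"))
  if (!is.character(sequence) || length(sequence) != 1 || !nzchar(sequence))
    stop("'sequence' must be a single non-empty string", call. = FALSE)
  check_dna(sequence, "sequence")
  n <- nchar(sequence)
  hits <- Biostrings::matchPattern(enzyme$site, Biostrings::DNAString(sequence))
  starts <- Biostrings::start(hits)
  # cut after base (start + offset - 1); keep cuts strictly inside the molecule
  cuts <- starts + enzyme$offset - 1L
  cuts <- sort(unique(cuts[cuts >= 1L & cuts < n]))
  frags <- diff(c(0L, cuts, n))
  structure(as.integer(frags), enzyme = enzyme$name)
}

#' Virtual gel model
#'
#' Governs how in-silico fragments are turned into the band pattern that
#' would be read off an agarose gel: fragments below the visibility limit
#' are dropped, and fragments whose lengths are indistinguishable at gel
#' resolution are merged into one band.
#'
#' @param min_visible smallest visible fragment, nt (default 100).
#' @param bin_tolerance relative co-migration tolerance: two fragments
#'   co-bin when `|a - b| <= bin_tolerance * max(a, b)` (default 0.05).
#' @return an object of class `gel_model`.
#' @export
gel_model <- function(min_visible = 100, bin_tolerance = 0.05) {
  stopifnot_scalar_number(min_visible, "min_visible", 0)
  stopifnot_scalar_number(bin_tolerance, "bin_tolerance", 0, 1 - 1e-12)
  structure(list(min_visible = min_visible, bin_tolerance = bin_tolerance),
            class = "gel_model")
}

# one agglomerative pass over sorted lengths; a length joins the open bin
# when its distance to the bin's running mean is within tolerance
bin_pass <- function(lengths, tol) {
  lengths <- sort(lengths)
  out <- numeric(0)
  bin <- lengths[1]
  for (l in lengths[-1]) {
    if (l - mean(bin) <= tol * l) {
      bin <- c(bin, l)
    } else {
      out <- c(out, floor(mean(bin) + 0.5))
      bin <- l
    }
  }
  c(out, floor(mean(bin) + 0.5))
}

bin_fragments <- function(lengths, gel) {
  lengths <- lengths[lengths >= gel$min_visible]
  if (length(lengths) == 0) return(integer(0))
  cur <- as.numeric(lengths)
  # iterate the agglomerative pass to a fixed point so that binning is
  # idempotent even when a rounded bin mean lands near the next bin
  repeat {
    nxt <- bin_pass(cur, gel$bin_tolerance)
    if (length(nxt) == length(cur) && all(nxt == cur)) break
    cur <- nxt
  }
  as.integer(cur)
}

#' Combine per-enzyme digests into an IGS fingerprint key
#'
#' Applies the gel model (visibility filter, band binning) to each enzyme's
#' fragment set and assembles the binned band lengths, ascending, in the
#' fixed enzyme order of `enzymes`. Two isolates have the same IGS
#' fingerprint iff their keys are identical. Binning is idempotent:
#' re-keying a key's band lengths is a fixed point.
#'
#' @param fragment_sets named list (one entry per enzyme in `enzymes`) of
#'   integer fragment-length vectors, as returned by [digest_amplicon()].
#' @param gel a [gel_model()].
#' @param enzymes enzyme set defining the required names and their order.
#' @return an object of class `pattern_key`: a named list of ascending
#'   integer band lengths, with a canonical single-string form available via
#'   `format()`.
#' @export
make_pattern_key <- function(fragment_sets, gel = gel_model(),
                             enzymes = default_enzymes()) {
  missing <- setdiff(names(enzymes), names(fragment_sets))
  if (length(missing))
    stop("missing fragment set for enzyme(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  key <- lapply(names(enzymes), function(e)
    bin_fragments(fragment_sets[[e]], gel))
  names(key) <- names(enzymes)
  structure(key, class = "pattern_key")
}

#' @export
format.pattern_key <- function(x, ...) {
  paste(vapply(names(x), function(e)
    paste0(e, ":", paste(x[[e]], collapse = ",")), character(1)),
    collapse = "|")
}

#' @export
print.pattern_key <- function(x, ...) {
  cat("<pattern_key>", format(x), "\n")
  invisible(x)
}

#' Digest a set of IGS amplicons into fingerprint keys
#'
#' @param sequences named character vector of IGS amplicon sequences
#'   (names are isolate ids).
#' @param enzymes enzyme set (default [default_enzymes()]).
#' @param gel a [gel_model()].
#' @return named list of [make_pattern_key()] keys, one per isolate.
#' @export
igs_pattern_keys <- function(sequences, enzymes = default_enzymes(),
                             gel = gel_model()) {
  stopifnot(length(sequences) >= 1, !is.null(names(sequences)))
  lapply(setNames(names(sequences), names(sequences)), function(id) {
    frags <- lapply(enzymes, function(e) digest_amplicon(sequences[[id]], e))
    make_pattern_key(frags, gel, enzymes)
  })
}

#' Group isolates into numbered IGS types
#'
#' Isolates with identical fingerprint keys share an IGS type. Types are
#' numbered 1..K by descending member count; ties are broken by first
#' appearance in the input order, so type 1 is always (one of) the most
#' abundant fingerprint(s).
#'
#' @param keys named list of `pattern_key` objects (names = isolate ids),
#'   e.g. from [igs_pattern_keys()].
#' @return list with `assignment` (data.frame: `isolate`, `igs_type`) and
#'   `types` (data.frame: `igs_type`, `pattern`, `count`).
#' @export
assign_igs_types <- function(keys) {
  stopifnot(length(keys) >= 1, !is.null(names(keys)))
  pat <- vapply(keys, format, character(1))
  first_seen <- match(unique(pat), pat)
  counts <- as.integer(table(pat)[unique(pat)])
  ord <- order(-counts, first_seen)
  labels <- setNames(seq_along(ord), unique(pat)[ord])
  assignment <- data.frame(isolate = names(keys),
                           igs_type = as.integer(labels[pat]),
                           row.names = NULL, stringsAsFactors = FALSE)
  types <- data.frame(igs_type = seq_along(ord),
                      pattern = unique(pat)[ord],
                      count = counts[ord],
                      row.names = NULL, stringsAsFactors = FALSE)
  list(assignment = assignment, types = types)
}

#' Pick representative isolates per IGS type
#'
#' For each IGS type, one representative is drawn from the type's
#' most-populated site; `extra_site_quota` further representatives may come
#' from the next most-populated sites (one per site). Within a (type, site)
#' cell the representative is the lexicographically smallest isolate id, so
#' the choice is deterministic. Site count ties are broken by site name.
#'
#' @param assignment data.frame with columns `isolate`, `igs_type`
#'   (from [assign_igs_types()]).
#' @param metadata data.frame with columns `isolate`, `site`.
#' @param extra_site_quota additional representatives allowed per type from
#'   further sites (default 0).
#' @return data.frame: `igs_type`, `site`, `representative`.
#' @export
select_representatives <- function(assignment, metadata, extra_site_quota = 0) {
  stopifnot(all(c("isolate", "igs_type") %in% names(assignment)),
            all(c("isolate", "site") %in% names(metadata)))
  site <- setNames(as.character(metadata$site), metadata$isolate)
  if (any(is.na(site[assignment$isolate])))
    stop("isolates without a site: ",
         paste(assignment$isolate[is.na(site[assignment$isolate])], collapse = ", "),
         call. = FALSE)
  out <- lapply(sort(unique(assignment$igs_type)), function(tp) {
    iso <- assignment$isolate[assignment$igs_type == tp]
    tab <- table(site[iso])
    site_order <- names(tab)[order(-as.integer(tab), names(tab))]
    take <- site_order[seq_len(min(1 + extra_site_quota, length(site_order)))]
    data.frame(igs_type = tp, site = take,
               representative = vapply(take, function(s)
                 min(iso[site[iso] == s]), character(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
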