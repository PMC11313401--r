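#' Configuration for the synthetic rhizobial community generator
#'
#' Defines the planted ground truth of a simulated multi-site isolate
#' collection: how many sites and isolates, how many panel (named) and
#' novel species, sequence lengths, and the divergence geometry. Species
#' consensus sequences are planted on disjoint mutation blocks of a common
#' ancestor, so any two species differ by at least
#' `between_species_divergence` (novel clusters by at least
#' `novel_divergence` from every panel member), while strains mutate their
#' species consensus at no more than half `within_species_divergence`, so
#' within-species pairs stay within that divergence. One designated panel
#' species carries the sv. viciae nodulation genes; all other strains are
#' sv. phaseoli.
#'
#' @param n_sites number of sampling sites (>= 2).
#' @param isolates_per_site isolates trapped per site; scalar or a vector
#'   of length `n_sites` (default 4 at the first site, 3 elsewhere: 46
#'   isolates over 15 sites).
#' @param n_species total planted species, including `n_novel`.
#' @param n_novel planted novel clusters (below-threshold genospecies).
#' @param igs_length IGS amplicon length, nt (default 900).
#' @param locus_lengths named lengths for recA, atpD, rpoB, nodC, nifH and
#'   the 16S gene `rrs`.
#' @param within_species_divergence max pairwise divergence within a
#'   species (fraction; default 0.01).
#' @param between_species_divergence min pairwise divergence between panel
#'   species (fraction; default 0.06; must exceed
#'   `within_species_divergence`).
#' @param novel_divergence min divergence of novel clusters from every
#'   panel member (fraction; default 0.06).
#' @param igs_divergence per-strain IGS mutation fraction; mutations avoid
#'   the planted restriction-site windows so all members of an IGS class
#'   share one fingerprint.
#' @param nodc_divergence per-strain nodulation-gene mutation fraction.
#' @param viciae_species index of the panel species carrying sv. viciae
#'   (default 5; planted with exactly 2 strains by the default allocation).
#' @param species_counts optional explicit per-species strain counts
#'   (length `n_species`, summing to the total isolate count); when NULL a
#'   decreasing allocation is derived that keeps species 1 strictly most
#'   abundant and the viciae species at 2 strains.
#' @param n_efficient number of strains planted as symbiotically
#'   "efficient" (default 8); the rest are "neutral".
#' @param include_16s also generate 16S rRNA sequences structured into
#'   three coarse groups (default TRUE).
#' @param seed integer seed fixing all randomness of [gen_community()].
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_sites = 15,
                         isolates_per_site = c(4, rep(3, 14)),
                         n_species = 16, n_novel = 5,
                         igs_length = 900,
                         locus_lengths = c(recA = 289, atpD = 297, rpoB = 599,
                                           nodC = 376, nifH = 300, rrs = 1400),
                         within_species_divergence = 0.01,
                         between_species_divergence = 0.06,
                         novel_divergence = 0.06,
                         igs_divergence = 0.005,
                         nodc_divergence = 0.01,
                         viciae_species = 5,
                         species_counts = NULL,
                         n_efficient = 8,
                         include_16s = TRUE,
                         seed = 1) {
  if (n_sites < 2) stop("need at least 2 sites", call. = FALSE)
  if (length(isolates_per_site) == 1)
    isolates_per_site <- rep(isolates_per_site, n_sites)
  if (length(isolates_per_site) != n_sites)
    stop("isolates_per_site must have length 1 or n_sites", call. = FALSE)
  if (any(locus_lengths <= 0)) stop("locus lengths must be positive", call. = FALSE)
  for (d in c(within_species_divergence, between_species_divergence,
              novel_divergence, igs_divergence, nodc_divergence))
    stopifnot_scalar_number(d, "divergence", 0, 1 - 1e-9)
  if (within_species_divergence >= between_species_divergence)
    stop("impossible divergence geometry: within_species_divergence must be ",
         "smaller than between_species_divergence", call. = FALSE)
  n_named <- n_species - n_novel
  if (n_named < 1 || n_novel < 0) stop("invalid species split", call. = FALSE)
  if (viciae_species > n_named)
    stop("viciae_species must index a named (panel) species", call. = FALSE)
  structure(list(n_sites = n_sites, isolates_per_site = isolates_per_site,
                 n_species = n_species, n_novel = n_novel, n_named = n_named,
                 igs_length = igs_length, locus_lengths = locus_lengths,
                 within_species_divergence = within_species_divergence,
                 between_species_divergence = between_species_divergence,
                 novel_divergence = novel_divergence,
                 igs_divergence = igs_divergence,
                 nodc_divergence = nodc_divergence,
                 viciae_species = viciae_species,
                 species_counts = species_counts,
                 n_efficient = n_efficient,
                 include_16s = include_16s, seed = seed),
            class = "synth_config")
}

# decreasing default allocation: every species >= 1 strain, the viciae
# species exactly 2, species 1 strictly most abundant, remainder spread over
# the other named species by 1/i^1.2 weights (largest-remainder rounding)
default_species_counts <- function(n_total, n_named, n_novel, viciae) {
  n_species <- n_named + n_novel
  counts <- rep(1L, n_species)
  counts[viciae] <- 2L
  rest <- setdiff(seq_len(n_named), viciae)
  r <- n_total - sum(counts)
  if (r < 0) stop("too few isolates for the species count", call. = FALSE)
  if (r > 0) {
    w <- (seq_along(rest))^-1.2
    share <- r * w / sum(w)
    add <- floor(share)
    left <- r - sum(add)
    if (left > 0) {
      ord <- order(-(share - add), seq_along(rest))
      add[ord[seq_len(left)]] <- add[ord[seq_len(left)]] + 1
    }
    counts[rest] <- counts[rest] + as.integer(add)
  }
  # keep species 1 strictly dominant (ties break the "type 1" bookkeeping)
  repeat {
    rival <- which.max(counts[-1]) + 1L
    if (counts[1] > counts[rival]) break
    counts[1] <- counts[1] + 1L
    counts[rival] <- counts[rival] - 1L
  }
  counts
}

# planted restriction-site layout of IGS class k: one HaeIII site whose
# position encodes the class, plus fixed MspI and HhaI sites shared by all
# classes
igs_site_plan <- function(k, igs_length) {
  p_hae <- 150 + 40 * (k - 1)
  if (p_hae + 3 > igs_length - 100)
    stop("igs_length too short to plant distinct fingerprints for ",
         k, " classes", call. = FALSE)
  data.frame(site = c("GGCC", "CCGG", "GCGC"),
             start = c(p_hae, 450, 600), stringsAsFactors = FALSE)
}

ALL_SITES <- c("GGCC", "CCGG", "GCGC")

# positions covered by the planted site words (with a 3-nt guard margin so
# strain mutations cannot create or destroy a planted site)
planned_windows <- function(plan, margin = 0) {
  unlist(lapply(seq_len(nrow(plan)), function(i)
    max(1, plan$start[i] - margin):(plan$start[i] + 3 + margin)))
}

# random IGS backbone with the class's sites planted and every accidental
# recognition-site occurrence scrubbed
build_igs_base <- function(plan, igs_length) {
  chars <- strsplit(random_dna(igs_length), "")[[1]]
  for (i in seq_len(nrow(plan)))
    chars[plan$start[i]:(plan$start[i] + 3)] <- strsplit(plan$site[i], "")[[1]]
  windows <- planned_windows(plan)
  for (iter in 1:500) {
    seqstr <- paste(chars, collapse = "")
    hit <- NULL
    for (w in ALL_SITES) {
      occ <- gregexpr(w, seqstr, fixed = TRUE)[[1]]
      occ <- occ[occ > 0]
      occ <- occ[!occ %in% plan$start[plan$site == w]]
      if (length(occ)) { hit <- occ[1]; break }
    }
    if (is.null(hit)) return(seqstr)
    fixable <- setdiff(hit:(hit + 3), windows)
    pos <- fixable[1]
    chars[pos] <- sample(setdiff(DNA_BASES, chars[pos]), 1)
  }
  stop("could not scrub accidental restriction sites", call. = FALSE)
}

# strain-level IGS mutations outside the planted windows, rejecting any
# substitution that creates a new recognition site
mutate_igs <- function(base, k, plan, igs_length) {
  if (k <= 0) return(base)
  chars <- strsplit(base, "")[[1]]
  forbidden <- planned_windows(plan, margin = 3)
  pool <- setdiff(seq_len(igs_length), forbidden)
  done <- 0L
  tries <- 0L
  while (done < k && tries < 50 * k) {
    tries <- tries + 1L
    pos <- sample(pool, 1)
    old <- chars[pos]
    chars[pos] <- sample(setdiff(DNA_BASES, old), 1)
    lo <- max(1, pos - 3)
    hi <- min(igs_length, pos + 3)
    ctx <- paste(chars[lo:hi], collapse = "")
    if (any(vapply(ALL_SITES, grepl, logical(1), x = ctx, fixed = TRUE))) {
      chars[pos] <- old # would create a site: reject
    } else {
      done <- done + 1L
    }
  }
  paste(chars, collapse = "")
}

split_loci <- function(concat, lengths) {
  ends <- cumsum(lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  setNames(substring(concat, starts, ends), names(lengths))
}

#' Generate a synthetic multi-site rhizobial community with planted truth
#'
#' Simulates FASTA-ready sequences (IGS amplicon; recA/atpD/rpoB; nodC and
#' nifH; optionally 16S) for every isolate of a multi-site collection,
#' together with a type-strain panel, symbiovar references, isolate
#' metadata and the planted truth table. All randomness flows from
#' `config$seed`; identical configs give byte-identical output. Each
#' planted species carries a distinct IGS restriction-site layout, so IGS
#' class and species coincide by construction.
#'
#' @param config a [synth_config()].
#' @param soil optional soil table from [gen_soil_env()] (rows = sites in
#'   order); when given, the allocation of the first species' strains to
#'   sites is biased towards high-pH sites with strength
#'   `ph_coupling_beta`, planting a pH gradient in that taxon's abundance.
#' @param ph_coupling_beta log-linear coupling strength (default 1.5).
#' @return list with `sequences` (`igs` plus per-locus named vectors),
#'   `metadata` (isolate, site, variety), `truth` (strain, site, variety,
#'   true_species, true_igs_class, true_symbiovar, true_effect_class),
#'   `panel` (species -> concatenated MLSA sequence), `panel_loci`,
#'   `symbiovar_references` and `nifh_references` data.frames, `sites`,
#'   and the `config`.
#' @export
gen_community <- function(config, soil = NULL, ph_coupling_beta = 1.5) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, {
    n_total <- sum(config$isolates_per_site)
    n_named <- config$n_named
    species <- c(sprintf("Species_%02d", seq_len(n_named)),
                 sprintf("Novel_%02d", seq_len(config$n_novel)))
    counts <- config$species_counts
    if (is.null(counts))
      counts <- default_species_counts(n_total, n_named, config$n_novel,
                                       config$viciae_species)
    if (length(counts) != config$n_species || sum(counts) != n_total)
      stop("species_counts must have length n_species and sum to the total ",
           "isolate count", call. = FALSE)

    ## --- MLSA loci -------------------------------------------------------
    mlsa_len <- config$locus_lengths[MLSA_LOCI]
    L <- sum(mlsa_len)
    d_named <- ceiling(config$between_species_divergence / 2 * L)
    d_novel <- ceiling(config$novel_divergence / 2 * L)
    block_sizes <- c(rep(d_named, n_named), rep(d_novel, config$n_novel))
    if (sum(block_sizes) > L)
      stop("impossible divergence geometry: species mutation blocks exceed ",
           "the MLSA length", call. = FALSE)
    pos_perm <- sample(L)
    ends <- cumsum(block_sizes)
    blocks <- lapply(seq_along(block_sizes), function(k)
      pos_perm[(c(0, ends)[k] + 1):ends[k]])
    ancestor <- random_dna(L)
    consensus <- vapply(blocks, function(b) mutate_at(ancestor, b), character(1))
    names(consensus) <- species
    panel <- consensus[seq_len(n_named)]

    ## --- strain allocation to sites and species --------------------------
    sites <- sprintf("S%02d", seq_len(config$n_sites))
    slot_site <- rep(sites, config$isolates_per_site)
    species_pool <- rep(species, counts)
    slot_species <- rep(NA_character_, n_total)
    open <- seq_len(n_total)
    if (!is.null(soil)) {
      if (!all(c("site", "pH") %in% names(soil)) || nrow(soil) != config$n_sites)
        stop("soil must have one row per site with columns site and pH",
             call. = FALSE)
      ph <- setNames(soil$pH, soil$site)
      z <- as.numeric(scale(ph[slot_site]))
      if (all(is.finite(z))) {
        k1 <- sum(species_pool == species[1])
        pick <- sample(open, k1, prob = exp(ph_coupling_beta * z))
        slot_species[pick] <- species[1]
        open <- setdiff(open, pick)
        species_pool <- species_pool[species_pool != species[1]]
      }
    }
    slot_species[open] <- sample(species_pool)
    ids <- unlist(lapply(sites, function(s)
      sprintf("%s-%02d", s, seq_len(sum(slot_site == s)))))
    metadata <- data.frame(isolate = ids, site = slot_site,
                           variety = sample(c("v1", "v2"), n_total, TRUE),
                           stringsAsFactors = FALSE)
    strain_species <- setNames(slot_species, ids)

    ## --- per-strain MLSA sequences ---------------------------------------
    m_within <- floor(config$within_species_divergence / 2 * L)
    concat <- vapply(ids, function(id)
      mutate_dna(consensus[[strain_species[[id]]]], m_within), character(1))
    strain_loci <- lapply(concat, split_loci, lengths = mlsa_len)
    loci <- lapply(setNames(MLSA_LOCI, MLSA_LOCI), function(l)
      vapply(strain_loci, `[[`, character(1), l))
    panel_loci <- lapply(setNames(MLSA_LOCI, MLSA_LOCI), function(l)
      vapply(panel, function(s) split_loci(s, mlsa_len)[[l]], character(1)))

    ## --- IGS amplicons ----------------------------------------------------
    class_of <- setNames(match(strain_species, species), ids)
    plans <- lapply(seq_len(config$n_species), igs_site_plan,
                    igs_length = config$igs_length)
    bases <- vapply(plans, build_igs_base, character(1),
                    igs_length = config$igs_length)
    m_igs <- floor(config$igs_divergence * config$igs_length)
    igs <- vapply(ids, function(id) {
      k <- class_of[[id]]
      mutate_igs(bases[k], m_igs, plans[[k]], config$igs_length)
    }, character(1))

    ## --- symbiosis genes --------------------------------------------------
    viciae_name <- species[config$viciae_species]
    symbio <- function(len, div) {
      ref_ph <- random_dna(len)
      ref_vic <- mutate_dna(ref_ph, round(0.15 * len))
      m <- floor(div * len)
      seqs <- vapply(ids, function(id) {
        ref <- if (strain_species[[id]] == viciae_name) ref_vic else ref_ph
        mutate_dna(ref, m)
      }, character(1))
      list(seqs = seqs, ph = ref_ph, vic = ref_vic)
    }
    nodc <- symbio(config$locus_lengths[["nodC"]], config$nodc_divergence)
    nifh <- symbio(config$locus_lengths[["nifH"]], config$nodc_divergence)
    loci$nodC <- nodc$seqs
    loci$nifH <- nifh$seqs
    symbiovar_references <- data.frame(
      name = c("nodC_sv_phaseoli_ref", "nodC_sv_viciae_ref"),
      symbiovar = c("sv. phaseoli", "sv. viciae"),
      seq = c(nodc$ph, nodc$vic), stringsAsFactors = FALSE)
    nifh_references <- data.frame(
      name = c("nifH_sv_phaseoli_ref", "nifH_sv_viciae_ref"),
      symbiovar = c("sv. phaseoli", "sv. viciae"),
      seq = c(nifh$ph, nifh$vic), stringsAsFactors = FALSE)

    ## --- 16S rRNA ---------------------------------------------------------
    if (config$include_16s) {
      len16 <- config$locus_lengths[["rrs"]]
      anc16 <- random_dna(len16)
      d16 <- ceiling(0.01 * len16)
      perm16 <- sample(len16)
      grp_cons <- vapply(1:3, function(g)
        mutate_at(anc16, perm16[((g - 1) * d16 + 1):(g * d16)]), character(1))
      sp16 <- vapply(seq_along(species), function(k)
        mutate_dna(grp_cons[(k - 1) %% 3 + 1], 2), character(1))
      loci$rrs <- vapply(ids, function(id)
        mutate_dna(sp16[class_of[[id]]], 1), character(1))
    }

    ## --- planted phenotype classes ---------------------------------------
    eff <- sample(ids, min(config$n_efficient, n_total))
    truth <- data.frame(strain = ids, site = slot_site,
                        variety = metadata$variety,
                        true_species = unname(strain_species),
                        true_igs_class = unname(class_of),
                        true_symbiovar = ifelse(strain_species == viciae_name,
                                                "sv. viciae", "sv. phaseoli"),
                        true_effect_class = ifelse(ids %in% eff, "efficient",
                                                   "neutral"),
                        stringsAsFactors = FALSE)
    list(sequences = c(list(igs = igs), loci),
         metadata = metadata, truth = truth,
         panel = panel, panel_loci = panel_loci,
         symbiovar_references = symbiovar_references,
         nifh_references = nifh_references,
         sites = sites, config = config)
  })
}

#' Planted phenotype effect multipliers from a truth table
#'
#' Efficient strains get the stated multipliers (defaults: nodules and SPAD
#' x1.3, biomass x2.8); neutral strains x1.0 throughout.
#'
#' @param truth the `truth` table of [gen_community()] (or any data.frame
#'   with `strain` and `true_effect_class`).
#' @param multipliers named vector with `nodule`, `spad`, `biomass`.
#' @return data.frame: `strain`, `nodule_mult`, `spad_mult`, `biomass_mult`.
#' @export
planted_effects <- function(truth,
                            multipliers = c(nodule = 1.3, spad = 1.3,
                                            biomass = 2.8)) {
  eff <- truth$true_effect_class == "efficient"
  data.frame(strain = truth$strain,
             nodule_mult = ifelse(eff, multipliers[["nodule"]], 1),
             spad_mult = ifelse(eff, multipliers[["spad"]], 1),
             biomass_mult = ifelse(eff, multipliers[["biomass"]], 1),
             stringsAsFactors = FALSE)
}

#' Generate replicated plant phenotypes under planted effects
#'
#' Produces the inoculation-assay table: for each treatment (every strain
#' in `effects` plus the uninoculated control CK), bean variety and
#' replicate, nodule count, SPAD and shoot/root dry weights are drawn as
#' `baseline x multiplier x (1 + N(0, noise_sd))`, truncated at zero.
#' CK has zero nodules in every replicate and multiplier 1 elsewhere; at
#' zero noise a multiplier of 1 reproduces the baselines exactly.
#'
#' @param effects data.frame from [planted_effects()] (columns `strain`,
#'   `nodule_mult`, `spad_mult`, `biomass_mult`; all must be >= 0).
#' @param n_reps replicates per treatment x variety (>= 2, default 3).
#' @param noise_sd relative noise standard deviation (default 0.1).
#' @param baselines named vector: `nodules`, `spad`, `shoot_dw`, `root_dw`.
#' @param varieties bean variety labels (default v1, v2).
#' @param seed integer seed.
#' @return phenotype data.frame (see [standardize_indices()]).
#' @export
gen_phenotypes <- function(effects, n_reps = 3, noise_sd = 0.1,
                           baselines = c(nodules = 55, spad = 30,
                                         shoot_dw = 1.5, root_dw = 0.5),
                           varieties = c("v1", "v2"), seed = 1) {
  if (n_reps < 2) stop("n_reps must be >= 2", call. = FALSE)
  mults <- as.matrix(effects[c("nodule_mult", "spad_mult", "biomass_mult")])
  if (any(mults < 0)) stop("effect multipliers must be >= 0", call. = FALSE)
  withr::with_seed(seed, {
    treatments <- c("CK", effects$strain)
    rows <- expand.grid(rep = seq_len(n_reps), variety = varieties,
                        treatment = treatments, stringsAsFactors = FALSE)
    rows <- rows[c("treatment", "variety", "rep")]
    draw <- function(base, mult) {
      pmax(0, base * mult * (1 + rnorm(length(mult), 0, noise_sd)))
    }
    i <- match(rows$treatment, effects$strain) # NA for CK
    nodm <- ifelse(is.na(i), 0, effects$nodule_mult[i])
    spadm <- ifelse(is.na(i), 1, effects$spad_mult[i])
    biom <- ifelse(is.na(i), 1, effects$biomass_mult[i])
    rows$nodules <- ifelse(nodm == 0, 0,
                           round(draw(baselines[["nodules"]], nodm)))
    rows$spad <- draw(baselines[["spad"]], spadm)
    rows$shoot_dw <- draw(baselines[["shoot_dw"]], biom)
    rows$root_dw <- draw(baselines[["root_dw"]], biom)
    rows
  })
}

#' Planted per-level stress tolerance fractions
#'
#' The default fraction of strains passing each condition level, taken from
#' the screening outcome of a 46-strain representative survey: e.g. none
#' grow at pH 5 or at 4/10 degC, all grow at the control levels, 21/46 at
#' pH 6, 9/46 at pH 11, 3/46 at 45 degC.
#'
#' @return data.frame: `family`, `level`, `frac`.
#' @export
default_stress_fractions <- function() {
  rbind(
    data.frame(family = "pH", level = c(5, 6, 7, 8, 9, 10, 11),
               frac = c(0, 21, 46, 46, 40, 20, 9) / 46),
    data.frame(family = "NaCl", level = c(0.01, 1, 2, 3, 4),
               frac = c(46, 17, 2, 0, 0) / 46),
    data.frame(family = "temperature", level = c(4, 10, 28, 37, 45),
               frac = c(0, 0, 46, 12, 3) / 46),
    data.frame(family = "PEG", level = c(0, 3, 5, 7, 10, 15),
               frac = c(46, 46, 46, 31, 11, 0) / 46),
    data.frame(family = "glyphosate", level = c(0, 0.6, 1.2, 1.8),
               frac = c(46, 46, 38, 27) / 46))
}

#' Plant per-strain stress tolerance envelopes
#'
#' For each condition family a random strain order is drawn and the first
#' `round(frac * n)` strains pass each level, so tolerance is nested within
#' a family (a strain passing a harsh level passes the milder ones whose
#' planted count is larger). Control levels always pass.
#'
#' @param strains strain ids.
#' @param fractions per-level pass fractions (default
#'   [default_stress_fractions()]); must cover all five families.
#' @param top_strain optional strain id placed first in every family's
#'   order, planting one maximally tolerant strain.
#' @param seed integer seed.
#' @return data.frame: `strain`, `family`, `level`, `pass` (logical).
#' @export
planted_envelopes <- function(strains, fractions = default_stress_fractions(),
                              top_strain = NULL, seed = 1) {
  grids <- condition_grids()
  missing_fam <- setdiff(names(grids), unique(fractions$family))
  if (length(missing_fam))
    stop("fractions must cover all condition families; missing: ",
         paste(missing_fam, collapse = ", "), call. = FALSE)
  n <- length(strains)
  withr::with_seed(seed, {
    out <- lapply(names(grids), function(f) {
      ord <- sample(strains)
      if (!is.null(top_strain) && top_strain %in% ord)
        ord <- c(top_strain, setdiff(ord, top_strain))
      ff <- fractions[fractions$family == f, ]
      do.call(rbind, lapply(seq_len(nrow(ff)), function(i) {
        lvl <- ff$level[i]
        n_pass <- if (lvl == grids[[f]]$control) n else round(ff$frac[i] * n)
        data.frame(strain = strains, family = f, level = lvl,
                   pass = strains %in% ord[seq_len(n_pass)],
                   stringsAsFactors = FALSE)
      }))
    })
    do.call(rbind, out)
  })
}

#' Generate a replicated stress growth matrix from planted envelopes
#'
#' One growth observation per strain x condition level x replicate:
#' passing cells draw around `pass_mean`, failing cells around
#' `fail_mean`, each with relative noise `noise_sd` (truncated at zero).
#' Control levels must pass in the envelopes (error otherwise), so every
#' strain grows at pH 7, 0.01\% NaCl, 28 degC, 0\% PEG and 0 glyphosate.
#'
#' @param envelopes data.frame from [planted_envelopes()].
#' @param n_reps replicates per cell (default 3).
#' @param noise_sd relative noise (default 0.02).
#' @param pass_mean,fail_mean planted growth levels (defaults 1 and 0.05).
#' @param seed integer seed.
#' @return data.frame: `strain`, `family`, `level`, `rep`, `growth`.
#' @export
gen_stress_matrix <- function(envelopes, n_reps = 3, noise_sd = 0.02,
                              pass_mean = 1, fail_mean = 0.05, seed = 1) {
  grids <- condition_grids()
  bad <- setdiff(unique(envelopes$family), names(grids))
  if (length(bad))
    stop("unknown condition family: ", paste(bad, collapse = ", "), call. = FALSE)
  for (f in unique(envelopes$family)) {
    lv <- unique(envelopes$level[envelopes$family == f])
    badl <- setdiff(lv, grids[[f]]$levels)
    if (length(badl))
      stop(sprintf("unknown %s level(s): %s", f, paste(badl, collapse = ", ")),
           call. = FALSE)
    ctrl <- envelopes$pass[envelopes$family == f &
                             envelopes$level == grids[[f]]$control]
    if (length(ctrl) && !all(ctrl))
      stop(sprintf("control level of %s must pass for every strain", f),
           call. = FALSE)
  }
  withr::with_seed(seed, {
    out <- envelopes[rep(seq_len(nrow(envelopes)), each = n_reps),
                     c("strain", "family", "level")]
    out$rep <- rep(seq_len(n_reps), nrow(envelopes))
    mu <- ifelse(envelopes$pass, pass_mean, fail_mean)
    mu <- rep(mu, each = n_reps)
    out$growth <- pmax(0, mu * (1 + rnorm(nrow(out), 0, noise_sd)))
    rownames(out) <- NULL
    out
  })
}

#' Default soil and climate variable ranges
#'
#' Plausible ranges for a subtropical highland bean-growing region: soil pH,
#' electrical conductivity (EC, uS/kg), organic matter (OM, g/kg), alkaline
#' hydrolysable nitrogen (AN, mg/kg), available phosphorus (AP, mg/kg),
#' available potassium (AK, mg/kg), altitude (m), annual precipitation (mm)
#' and average minimum/maximum temperature (degC).
#'
#' @return named list of `c(min, max)` ranges.
#' @export
default_soil_ranges <- function() {
  list(pH = c(4.5, 8.5), EC = c(69, 820), OM = c(15, 63), AN = c(60, 389),
       AP = c(5, 389), AK = c(50, 358), Alt = c(1033, 2967),
       AvePrecp = c(870, 1350), AveTmin = c(2, 10), AveTmax = c(20, 28))
}

#' Generate a per-site soil and environment table
#'
#' @param n_sites number of sites (>= 2; ordination is undefined below
#'   that).
#' @param ranges named list of `c(min, max)` per variable (default
#'   [default_soil_ranges()]); a degenerate range yields a constant column.
#' @param seed integer seed.
#' @return data.frame with a `site` column and one column per variable.
#' @export
gen_soil_env <- function(n_sites, ranges = default_soil_ranges(), seed = 1) {
  if (n_sites < 2) stop("need at least 2 sites", call. = FALSE)
  withr::with_seed(seed, {
    out <- data.frame(site = sprintf("S%02d", seq_len(n_sites)),
                      stringsAsFactors = FALSE)
    for (v in names(ranges)) {
      r <- ranges[[v]]
      if (length(r) != 2 || r[2] < r[1])
        stop(sprintf("invalid range for %s", v), call. = FALSE)
      out[[v]] <- round(runif(n_sites, r[1], r[2]), 2)
    }
    out
  })
}

#' Write a synthetic community to FASTA and CSV files
#'
#' One multi-record FASTA per locus (headers `>strainID|locus`), the IGS
#' amplicons, plus metadata and truth CSVs.
#'
#' @param community a [gen_community()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_community <- function(community, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (locus in names(community$sequences)) {
    seqs <- community$sequences[[locus]]
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- paste(names(seqs), locus, sep = "|")
    p <- file.path(dir, paste0(locus, ".fasta"))
    Biostrings::writeXStringSet(x, p)
    paths <- c(paths, p)
  }
  for (tab in c("metadata", "truth", "symbiovar_references")) {
    p <- file.path(dir, paste0(tab, ".csv"))
    write.csv(community[[tab]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
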