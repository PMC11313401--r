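#' Load the packaged IGS-type survey table
#'
#' The packaged bookkeeping table of a published 15-site *Phaseolus
#' vulgaris* rhizobium survey: one row per IGS PCR-RFLP type with its
#' isolate count, representative strain id(s), MLSA clade (C1-C16) and
#' species label (named species or provisional genospecies). Three types
#' carry two representatives (selected per site of origin), giving 46
#' representatives over 43 types.
#'
#' @param path CSV path (defaults to the packaged fixture).
#' @return validated data.frame: `igs_type`, `isolate_count`,
#'   `representatives` (list column of ids), `clade`, `species`.
#' @export
load_table1 <- function(path = system.file("extdata", "igs_type_survey.csv",
                                           package = "rhizotyper")) {
  fx <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("igs_type", "isolate_count", "representatives", "clade", "species")
  miss <- setdiff(need, names(fx))
  if (length(miss))
    stop("fixture missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  fx$representatives <- strsplit(fx$representatives, ";", fixed = TRUE)
  validate_table1(fx)
}

validate_table1 <- function(fx) {
  if (anyDuplicated(fx$igs_type))
    stop("fixture invariant violated: duplicated IGS types", call. = FALSE)
  if (anyDuplicated(unlist(fx$representatives)))
    stop("fixture invariant violated: duplicated representative ids",
         call. = FALSE)
  if (any(fx$isolate_count < 1))
    stop("fixture invariant violated: non-positive isolate count", call. = FALSE)
  clade_species <- unique(fx[c("clade", "species")])
  if (anyDuplicated(clade_species$clade))
    stop("fixture invariant violated: a clade maps to several species",
         call. = FALSE)
  fx
}

#' Replay the survey bookkeeping from the packaged table
#'
#' Recomputes, from the packaged IGS-type table alone, the survey's
#' headline bookkeeping: total isolates, number of IGS types,
#' representatives and species, per-species isolate counts with relative
#' abundances (half-up, 1 decimal), and the symbiovar split of the
#' representatives under the rule that clade C6 carries sv. viciae and
#' every other clade sv. phaseoli.
#'
#' @param fixture a [load_table1()] table.
#' @param viciae_clade clade whose representatives are sv. viciae
#'   (default `"C6"`).
#' @return list: `total_isolates`, `n_igs_types`, `n_representatives`,
#'   `n_species`, `species_counts` (data.frame `species`, `isolates`,
#'   `percent`, sorted by count), `symbiovar_representatives` (named
#'   counts).
#' @export
replay_table1 <- function(fixture = load_table1(), viciae_clade = "C6") {
  validate_table1(fixture)
  total <- sum(fixture$isolate_count)
  per_species <- stats::aggregate(isolate_count ~ species, data = fixture, sum)
  per_species <- per_species[order(-per_species$isolate_count,
                                   per_species$species), ]
  species_counts <- data.frame(
    species = per_species$species,
    isolates = per_species$isolate_count,
    percent = round_half_up(100 * per_species$isolate_count / total, 1),
    row.names = NULL, stringsAsFactors = FALSE)
  n_rep <- lengths(fixture$representatives)
  sv <- ifelse(fixture$clade == viciae_clade, "sv. viciae", "sv. phaseoli")
  sv_counts <- tapply(n_rep, sv, sum)
  list(total_isolates = total,
       n_igs_types = nrow(fixture),
       n_representatives = sum(n_rep),
       n_species = length(unique(fixture$species)),
       species_counts = species_counts,
       symbiovar_representatives = c(
         `sv. phaseoli` = unname(sv_counts["sv. phaseoli"]),
         `sv. viciae` = unname(sv_counts["sv. viciae"])))
}

#' Default end-to-end run configuration
#'
#' Bundles the stage parameters of [run_all()]: the synthetic community
#' config, gel model, classification thresholds, score weights, the
#' significance level and top-k cut. Unknown parameter names are rejected.
#'
#' @param ... overrides for `synth` ([synth_config()]), `gel`
#'   ([gel_model()]), `enzymes`, `species_threshold`, `symbiovar_min_identity`,
#'   `alpha`, `k_elite`, `extra_site_quota`, `transform`, `n_axes`,
#'   `phenotype_noise_sd`, `stress_noise_sd`, `seed`.
#' @return a `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(synth = NULL, gel = gel_model(), enzymes = default_enzymes(),
              species_threshold = 97.0, symbiovar_min_identity = 90.0,
              alpha = 0.001, k_elite = 5, extra_site_quota = 0,
              transform = "proportion", n_axes = 2,
              phenotype_noise_sd = 0.1, stress_noise_sd = 0.02, seed = 1)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown run_config parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(dots)] <- dots
  if (is.null(cfg$synth)) cfg$synth <- synth_config(seed = cfg$seed)
  structure(cfg, class = "run_config")
}

write_config_provenance <- function(cfg, path) {
  lines <- c("[run]",
             paste0("seed = ", cfg$seed),
             paste0("species_threshold = ", cfg$species_threshold),
             paste0("symbiovar_min_identity = ", cfg$symbiovar_min_identity),
             paste0("alpha = ", cfg$alpha),
             paste0("k_elite = ", cfg$k_elite),
             paste0("extra_site_quota = ", cfg$extra_site_quota),
             paste0("transform = ", cfg$transform),
             paste0("n_axes = ", cfg$n_axes),
             "[gel]",
             paste0("min_visible = ", cfg$gel$min_visible),
             paste0("bin_tolerance = ", cfg$gel$bin_tolerance),
             "[enzymes]",
             vapply(cfg$enzymes, function(e)
               paste0(e$name, " = ", e$site, ",", e$offset), character(1)),
             "[synth]")
  sc <- cfg$synth
  for (f in setdiff(names(sc), c("locus_lengths", "isolates_per_site",
                                 "species_counts")))
    lines <- c(lines, paste0(f, " = ", sc[[f]]))
  lines <- c(lines,
             paste0("isolates_per_site = ",
                    paste(sc$isolates_per_site, collapse = ",")),
             paste0("locus_lengths = ",
                    paste(names(sc$locus_lengths), sc$locus_lengths,
                          sep = ":", collapse = ",")))
  writeLines(lines, path)
}

#' Run the full typing, diversity and screening pipeline on synthetic data
#'
#' Executes every stage end to end on a generated community with planted
#' truth: soil/environment generation, community generation, IGS PCR-RFLP
#' typing and representative selection, MLSA species assignment of the
#' representatives (propagated to all isolates via their IGS type),
#' genospecies clustering of novel representatives, symbiovar calling,
#' abundance/diversity summaries, ordination with environmental arrows,
#' symbiotic performance scoring of the representatives on two bean
#' varieties, stress screening and tolerance ranking, and elite selection.
#' The run is fully deterministic for a fixed config.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, stage outputs are written
#'   as CSV/FASTA/newick plus a provenance copy of the configuration.
#' @return list of stage results: `community`, `soil`, `igs` (typing),
#'   `representatives`, `species` (per-representative assignment),
#'   `genospecies`, `symbiovars`, `isolate_labels`, `abundance`,
#'   `diversity`, `dominance`, `ordination`, `arrows`, `bray_curtis`,
#'   `scores` (per variety), `stress` (calls, summary, ranking), `elite`,
#'   `summary` (headline counts).
#' @export
run_all <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  sc <- config$synth

  ## synth
  soil <- gen_soil_env(sc$n_sites, seed = sc$seed + 1)
  comm <- gen_community(sc, soil = soil)
  meta <- comm$metadata

  ## rflp
  keys <- igs_pattern_keys(comm$sequences$igs, config$enzymes, config$gel)
  typing <- assign_igs_types(keys)
  reps <- select_representatives(typing$assignment, meta,
                                 config$extra_site_quota)
  rep_ids <- reps$representative

  ## mlsa on representatives, propagated by IGS type
  concat <- concat_mlsa(comm$sequences, rep_ids)
  species <- assign_species(concat, comm$panel,
                            threshold = config$species_threshold)
  novel_ids <- species$strain[species$status == "novel"]
  geno <- cluster_genospecies(concat[novel_ids],
                              intra_threshold = config$species_threshold)
  if (nrow(geno))
    species$label[match(geno$strain, species$strain)] <- geno$genospecies
  sv <- assign_symbiovar(comm$sequences$nodC[rep_ids],
                         comm$symbiovar_references,
                         min_identity = config$symbiovar_min_identity)
  sv_nifh <- assign_symbiovar(comm$sequences$nifH[rep_ids],
                              comm$nifh_references,
                              min_identity = config$symbiovar_min_identity)
  sv$nifh_symbiovar <- sv_nifh$symbiovar[match(sv$strain, sv_nifh$strain)]
  sv$concordant <- sv$symbiovar == sv$nifh_symbiovar

  ## propagate representative labels to every isolate via its IGS type
  rep_type <- reps$igs_type[match(species$strain, reps$representative)]
  type_label <- tapply(species$label, rep_type, function(x) x[1])
  isolate_labels <- data.frame(
    isolate = typing$assignment$isolate,
    igs_type = typing$assignment$igs_type,
    taxon = unname(type_label[as.character(typing$assignment$igs_type)]),
    stringsAsFactors = FALSE)

  ## community summaries
  abundance <- build_abundance(
    data.frame(isolate = isolate_labels$isolate, taxon = isolate_labels$taxon),
    meta)
  diversity <- diversity_profile(abundance)
  dominance <- dominant_taxa(abundance)

  ## environment association
  comp <- transform_composition(abundance, config$transform)
  ord <- pca_ordination(comp, n_axes = config$n_axes)
  rownames(soil) <- soil$site
  arrows <- variable_arrows(ord, soil[setdiff(names(soil), "site")])
  bc <- bray_curtis(abundance)

  ## symbiosis on representatives
  rep_truth <- comm$truth[comm$truth$strain %in% rep_ids, ]
  pheno <- gen_phenotypes(planted_effects(rep_truth),
                          noise_sd = config$phenotype_noise_sd,
                          seed = sc$seed + 2)
  cards <- score_card(pheno, alpha = config$alpha)
  scores <- split(cards, cards$variety)

  ## stress on representatives
  top <- sort(rep_truth$strain[rep_truth$true_effect_class == "efficient"])
  env <- planted_envelopes(rep_ids,
                           top_strain = if (length(top)) top[1] else NULL,
                           seed = sc$seed + 3)
  obs <- gen_stress_matrix(env, noise_sd = config$stress_noise_sd,
                           seed = sc$seed + 4)
  calls <- call_growth(obs)
  tol <- summarize_tolerance(calls)
  ranking <- rank_tolerance(tol)

  elite <- select_elite(scores$v1, scores$v2, ranking, k = config$k_elite)

  summary <- list(
    n_isolates = nrow(meta),
    n_sites = sc$n_sites,
    n_igs_types = nrow(typing$types),
    n_representatives = length(rep_ids),
    n_assigned_species = length(unique(species$label[species$status == "assigned"])),
    n_genospecies = length(unique(geno$genospecies)),
    symbiovar_counts = table(sv$symbiovar),
    n_elite = length(elite))

  res <- list(community = comm, soil = soil, igs = typing,
              representatives = reps, species = species, genospecies = geno,
              symbiovars = sv, isolate_labels = isolate_labels,
              abundance = abundance, diversity = diversity,
              dominance = dominance, ordination = ord, arrows = arrows,
              bray_curtis = bc, scores = scores,
              stress = list(calls = calls, summary = tol, ranking = ranking),
              elite = elite, summary = summary, config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_community(comm, file.path(out_dir, "community"))
    write.csv(typing$assignment, file.path(out_dir, "igs_types.csv"),
              row.names = FALSE)
    write.csv(reps, file.path(out_dir, "representatives.csv"), row.names = FALSE)
    write.csv(species, file.path(out_dir, "species_assignments.csv"),
              row.names = FALSE)
    write.csv(sv, file.path(out_dir, "symbiovars.csv"), row.names = FALSE)
    write.csv(as.data.frame(unclass(abundance)),
              file.path(out_dir, "abundance.csv"))
    write.csv(diversity, file.path(out_dir, "diversity.csv"), row.names = FALSE)
    write.csv(dominance, file.path(out_dir, "dominance.csv"), row.names = FALSE)
    write.csv(arrows, file.path(out_dir, "env_arrows.csv"), row.names = FALSE)
    write.csv(as.data.frame(bc), file.path(out_dir, "bray_curtis.csv"))
    write.csv(cards, file.path(out_dir, "score_cards.csv"), row.names = FALSE)
    write.csv(tol$per_level, file.path(out_dir, "stress_per_level.csv"),
              row.names = FALSE)
    write.csv(ranking, file.path(out_dir, "stress_ranking.csv"),
              row.names = FALSE)
    writeLines(elite, file.path(out_dir, "elite_strains.txt"))
    d <- 100 - pairwise_identity(concat)
    nj_tree(d, newick_file = file.path(out_dir, "mlsa_nj.nwk"))
    write_config_provenance(config, file.path(out_dir, "run_config.txt"))
  }
  res
}
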