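test_that("community generation is deterministic under a fixed seed", {
  cfg <- synth_config(seed = 99)
  c1 <- gen_community(cfg)
  c2 <- gen_community(cfg)
  expect_identical(c1$sequences, c2$sequences)
  expect_identical(c1$metadata, c2$metadata)
  expect_identical(c1$truth, c2$truth)
})

test_that("planted novel clusters sit below 97% identity to every panel member", {
  cfg <- synth_config(seed = 3)
  comm <- gen_community(cfg)
  concat <- concat_mlsa(comm$sequences)
  novel_strains <- comm$truth$strain[grepl("^Novel", comm$truth$true_species)]
  expect_length(unique(comm$truth$true_species[grepl("^Novel", comm$truth$true_species)]), 5)
  for (s in novel_strains) {
    ids <- vapply(comm$panel, function(p) percent_identity(concat[[s]], p),
                  numeric(1))
    expect_true(all(ids < 97), info = s)
  }
})

test_that("zero within-species divergence gives identical MLSA sequences", {
  cfg <- synth_config(within_species_divergence = 0, seed = 4)
  comm <- gen_community(cfg)
  concat <- concat_mlsa(comm$sequences)
  for (sp in unique(comm$truth$true_species)) {
    members <- comm$truth$strain[comm$truth$true_species == sp]
    expect_length(unique(concat[members]), 1)
    if (length(members) >= 2)
      expect_equal(percent_identity(concat[[members[1]]],
                                    concat[[members[2]]]), 100)
  }
})

test_that("impossible divergence geometry is a config error", {
  expect_error(synth_config(within_species_divergence = 0.07,
                            between_species_divergence = 0.06),
               "impossible divergence geometry")
})

test_that("strains of one IGS class share a fingerprint; classes differ", {
  comm <- gen_community(synth_config(seed = 5))
  keys <- igs_pattern_keys(comm$sequences$igs)
  pat <- vapply(keys, format, character(1))
  by_class <- split(pat[comm$truth$strain], comm$truth$true_igs_class)
  expect_true(all(lengths(lapply(by_class, unique)) == 1))
  expect_length(unique(vapply(by_class, `[`, character(1), 1)),
                length(by_class))
})

test_that("phenotype generator honours control, zero-noise and planted effects", {
  eff <- data.frame(strain = c("sA", "sB"), nodule_mult = c(1.3, 1),
                    spad_mult = c(1.3, 1), biomass_mult = c(2.8, 1))
  ph0 <- gen_phenotypes(eff, noise_sd = 0, seed = 8)
  ck <- ph0[ph0$treatment == "CK", ]
  expect_true(all(ck$nodules == 0))
  # neutral strain at zero noise reproduces the baselines exactly
  sB <- ph0[ph0$treatment == "sB", ]
  expect_true(all(sB$spad == 30 & sB$shoot_dw == 1.5 & sB$root_dw == 0.5))
  rat0 <- efficiency_ratios(ph0)
  expect_equal(rat0$biomass_ratio[rat0$treatment == "sA"], c(2.8, 2.8))
  expect_equal(rat0$chlorophyll_ratio[rat0$treatment == "sA"], c(1.3, 1.3))
  expect_equal(rat0$biomass_ratio[rat0$treatment == "sB"], c(1, 1))
  # with noise the planted 2.8x biomass effect is recovered within sampling error
  ph <- gen_phenotypes(eff, noise_sd = 0.1, seed = 9)
  rat <- efficiency_ratios(ph)
  expect_true(all(abs(rat$biomass_ratio[rat$treatment == "sA"] - 2.8) < 0.6))
  expect_error(gen_phenotypes(data.frame(strain = "s", nodule_mult = -1,
                                         spad_mult = 1, biomass_mult = 1)),
               ">= 0")
})

test_that("stress envelopes are planted at the stated per-level counts", {
  strains <- sprintf("st%02d", 1:46)
  env <- planted_envelopes(strains, seed = 10)
  frac <- default_stress_fractions()
  for (i in seq_len(nrow(frac))) {
    got <- sum(env$pass[env$family == frac$family[i] &
                          env$level == frac$level[i]])
    expect_equal(got, round(frac$frac[i] * 46),
                 info = paste(frac$family[i], frac$level[i]))
  }
  # nested within family: harsher levels pass subsets of milder ones
  ph11 <- env$strain[env$family == "pH" & env$level == 11 & env$pass]
  ph10 <- env$strain[env$family == "pH" & env$level == 10 & env$pass]
  expect_true(all(ph11 %in% ph10))
})

test_that("stress matrix round-trips through growth calls at zero noise", {
  strains <- sprintf("st%02d", 1:46)
  env <- planted_envelopes(strains, seed = 11)
  obs <- gen_stress_matrix(env, noise_sd = 0, seed = 12)
  calls <- call_growth(obs)
  tol <- summarize_tolerance(calls)
  planted <- stats::aggregate(pass ~ family + level, data = env, FUN = sum)
  merged <- merge(planted, tol$per_level)
  expect_equal(merged$n_normal, merged$pass)
  # no strain grows at 4 or 10 degC; all grow at 28 degC
  expect_equal(tol$per_level$n_normal[tol$per_level$family == "temperature"],
               c(0, 0, 46, 12, 3))
  bad <- env
  bad$level[1] <- 99
  expect_error(gen_stress_matrix(bad), "unknown pH level")
})

test_that("soil generator respects ranges, degeneracy and determinism", {
  soil <- gen_soil_env(15, seed = 13)
  expect_equal(nrow(soil), 15)
  expect_true(all(soil$pH >= 4.5 & soil$pH <= 8.5))
  expect_identical(soil, gen_soil_env(15, seed = 13))
  point <- gen_soil_env(3, ranges = list(pH = c(7, 7)), seed = 14)
  expect_true(all(point$pH == 7))
  expect_error(gen_soil_env(1), "at least 2 sites")
})

test_that("community files round-trip through FASTA", {
  comm <- gen_community(synth_config(seed = 6))
  dir <- withr::local_tempdir()
  write_community(comm, dir)
  fa <- Biostrings::readDNAStringSet(file.path(dir, "igs.fasta"))
  expect_length(fa, nrow(comm$metadata))
  expect_true(all(grepl("\\|igs$", names(fa))))
  expect_equal(unname(as.character(fa[1])),
               unname(comm$sequences$igs[1]))
})
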