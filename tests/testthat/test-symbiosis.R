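make_pheno <- function(spec, variety = "v1", reps = 3) {
  # spec: named list treatment -> c(nod, spad, shoot, root)
  do.call(rbind, lapply(names(spec), function(tr) {
    v <- spec[[tr]]
    data.frame(treatment = tr, variety = variety, rep = seq_len(reps),
               nodules = v[1], spad = v[2], shoot_dw = v[3], root_dw = v[4],
               stringsAsFactors = FALSE)
  }))
}

test_that("indices standardise against the best mean, CK included", {
  ph <- make_pheno(list(CK = c(0, 20, 1, 0.5),
                        s1 = c(60, 40, 2, 1),
                        s2 = c(30, 20, 1, 0.5)))
  idx <- standardize_indices(ph)
  s1 <- idx[idx$treatment == "s1", ]
  s2 <- idx[idx$treatment == "s2", ]
  ck <- idx[idx$treatment == "CK", ]
  expect_equal(s1$nodule_index, 1)
  expect_equal(s1$chlorophyll_index, 1)
  expect_equal(s1$biomass_index, 1)
  expect_equal(s2$nodule_index, 0.5)
  expect_equal(s2$biomass_index, 0.5)
  expect_equal(ck$nodule_index, 0) # uninoculated control never nodulates
})

test_that("composite score is the stated weighted sum and validates inputs", {
  expect_equal(composite_score(1, 1, 1), 100)
  expect_equal(composite_score(0.8, 0.5, 0.6), 62.5)
  expect_equal(composite_score(0, 0, 0), 0)
  expect_error(composite_score(1.2, 0.5, 0.5), "\\[0, 1\\]")
  # monotone in each index
  expect_gt(composite_score(0.9, 0.5, 0.6), composite_score(0.8, 0.5, 0.6))
  expect_gt(composite_score(0.8, 0.5, 0.7), composite_score(0.8, 0.5, 0.6))
})

test_that("scores are invariant to positive rescaling of all replicates", {
  ph <- make_pheno(list(CK = c(0, 20, 1, 0.5), s1 = c(60, 40, 2, 1),
                        s2 = c(30, 25, 1.4, 0.6)))
  idx1 <- standardize_indices(ph)
  ph2 <- ph
  for (col in c("nodules", "spad", "shoot_dw", "root_dw"))
    ph2[[col]] <- ph2[[col]] * 3.7
  idx2 <- standardize_indices(ph2)
  expect_equal(idx2[3:5], idx1[3:5])
  s1 <- composite_score(idx1$nodule_index, idx1$chlorophyll_index,
                        idx1$biomass_index)
  s2 <- composite_score(idx2$nodule_index, idx2$chlorophyll_index,
                        idx2$biomass_index)
  expect_equal(s2, s1)
})

test_that("ANOVA + LSD letters separate exactly the significant pairs", {
  # identical groups: a single letter
  same <- anova_lsd(rep(c(10, 10.1, 9.9), 3), rep(c("a", "b", "c"), each = 3))
  expect_length(unique(same$letters), 1)

  # means 10 vs 20 at sd 0.1, n = 3: t = 10/(0.1*sqrt(2/3)) ~ 122, far above
  # the alpha = 0.001 critical value -> different letters
  set.seed(41)
  v <- c(rnorm(3, 10, 0.1), rnorm(3, 20, 0.1))
  two <- anova_lsd(v, rep(c("g1", "g2"), each = 3))
  expect_false(two$letters[1] == two$letters[2])

  # means 10, 10.05, 20 at sd 0.1: close pair shares, far group differs
  v3 <- c(rnorm(3, 10, 0.1), rnorm(3, 10.05, 0.1), rnorm(3, 20, 0.1))
  g3 <- rep(c("lo1", "lo2", "hi"), each = 3)
  res <- anova_lsd(v3, g3)
  lt <- setNames(res$letters, res$group)
  expect_equal(unname(lt["lo1"]), unname(lt["lo2"]))
  expect_false(lt["hi"] %in% lt[c("lo1", "lo2")])

  # degenerate: zero variance everywhere falls back to exact equality
  expect_message(
    dg <- anova_lsd(rep(c(1, 1, 2), each = 2), rep(c("a", "b", "c"), each = 2)),
    "zero within-group variance")
  expect_equal(dg$letters[dg$group == "a"], dg$letters[dg$group == "b"])
  expect_false(dg$letters[dg$group == "c"] == dg$letters[dg$group == "a"])

  expect_error(anova_lsd(1:3, c("a", "a", "b")), ">= 2 replicates")
})

test_that("efficiency ratios are treatment over control means per variety", {
  ph <- rbind(make_pheno(list(CK = c(0, 20, 1, 0.5), s1 = c(50, 26, 2.3, 0.5)),
                         variety = "v1"),
              make_pheno(list(CK = c(0, 20, 1, 0.5), s1 = c(50, 20, 1, 0.5)),
                         variety = "v2"))
  rat <- efficiency_ratios(ph)
  expect_equal(rat$biomass_ratio[rat$treatment == "s1" & rat$variety == "v1"],
               2.8 / 1.5)
  expect_equal(rat$chlorophyll_ratio[rat$treatment == "s1" & rat$variety == "v1"],
               1.3)
  expect_equal(rat$biomass_ratio[rat$treatment == "s1" & rat$variety == "v2"], 1)
  # zero control mean leaves the ratio undefined and flagged
  ph0 <- make_pheno(list(CK = c(0, 0, 0, 0), s1 = c(50, 26, 2.3, 0.5)))
  expect_message(idx <- standardize_indices(ph0), NA) # indices still fine here
  r0 <- efficiency_ratios(ph0)
  expect_true(all(is.na(r0$biomass_ratio)))
  expect_true(all(r0$undefined))
})

test_that("score cards rank planted efficient strains on top", {
  truth <- data.frame(strain = sprintf("s%02d", 1:12),
                      true_effect_class = rep(c("efficient", "neutral"),
                                              c(3, 9)))
  ph <- gen_phenotypes(planted_effects(truth), noise_sd = 0.1, seed = 42)
  cards <- score_card(ph)
  top3 <- cards$treatment[cards$variety == "v1"][1:3]
  expect_setequal(top3, truth$strain[1:3])
  # letters exist for every treatment
  expect_false(any(is.na(cards$letters)) || any(cards$letters == ""))
})
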