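toy_obs <- function(frac_of_control, strain = "s1", family = "pH",
                    level = 9, control_level = 7) {
  rbind(data.frame(strain = strain, family = family, level = control_level,
                   rep = 1:3, growth = 1),
        data.frame(strain = strain, family = family, level = level,
                   rep = 1:3, growth = frac_of_control))
}

test_that("growth calls follow the control-relative thresholds", {
  expect_equal(call_growth(toy_obs(1))$call, c("normal", "normal"))
  calls <- call_growth(toy_obs(0.1))
  expect_equal(calls$call[calls$level == 9], "none")
  calls <- call_growth(toy_obs(0.5))
  expect_equal(calls$call[calls$level == 9], "weak")
  # boundary: exactly normal_frac counts as normal
  calls <- call_growth(toy_obs(0.8))
  expect_equal(calls$call[calls$level == 9], "normal")
  expect_error(call_growth(toy_obs(1, level = 12)), "unknown pH level")
  expect_error(call_growth(toy_obs(1, family = "uv")), "unknown condition family")
  expect_warning(
    out <- call_growth(rbind(toy_obs(0.5),
                             transform(toy_obs(0.5, strain = "s2"),
                                       growth = 0))),
    "control mean is 0")
  expect_false("s2" %in% out$strain)
})

test_that("raising normal_frac never increases per-level normal counts", {
  strains <- sprintf("st%02d", 1:20)
  env <- planted_envelopes(strains, seed = 51)
  obs <- gen_stress_matrix(env, noise_sd = 0.3, seed = 52)
  lo <- summarize_tolerance(call_growth(obs, normal_frac = 0.6))
  hi <- summarize_tolerance(call_growth(obs, normal_frac = 0.9))
  m <- merge(lo$per_level, hi$per_level, by = c("family", "level"))
  expect_true(all(m$n_normal.y <= m$n_normal.x))
})

test_that("tolerance ranking orders by breadth then extremes then id", {
  grids <- condition_grids()
  full_calls <- function(strain, pass_levels, extreme_only = character(0)) {
    do.call(rbind, lapply(names(grids), function(f) {
      lv <- grids[[f]]$levels
      data.frame(strain = strain, family = f, level = lv,
                 mean_growth = 1,
                 call = ifelse(lv %in% pass_levels[[f]], "normal", "none"),
                 stringsAsFactors = FALSE)
    }))
  }
  all_pass <- lapply(grids, function(g) g$levels)
  ctrl_only <- lapply(grids, function(g) g$control)
  # sAll passes everything; sA and sB pass the same number of levels but
  # only sA passes the 45 degC extreme
  some_a <- ctrl_only
  some_a$temperature <- c(28, 45)
  some_b <- ctrl_only
  some_b$temperature <- c(28, 37)
  calls <- rbind(full_calls("sAll", all_pass),
                 full_calls("sB", some_b),
                 full_calls("sA", some_a))
  rk <- rank_tolerance(summarize_tolerance(calls))
  expect_equal(rk$strain, c("sAll", "sA", "sB"))
  expect_equal(rk$breadth[1], sum(lengths(lapply(grids, `[[`, "levels"))) - 5)
  # input order does not matter
  rk2 <- rank_tolerance(summarize_tolerance(
    calls[sample(nrow(calls)), ]))
  expect_equal(rk2$strain, rk$strain)
})

test_that("elite selection intersects the three top-k sets", {
  sc <- function(ord) data.frame(treatment = c("CK", names(ord)),
                                 score = c(10, unname(ord)))
  v1 <- sc(c(sA = 90, sB = 80, sC = 40, sD = 30))
  v2 <- sc(c(sA = 85, sC = 70, sB = 30, sD = 20))
  ranking <- data.frame(rank = 1:4, strain = c("sA", "sD", "sB", "sC"))
  expect_equal(select_elite(v1, v2, ranking, k = 2), "sA")
  # efficient on one variety only: not elite
  expect_false("sB" %in% select_elite(v1, v2, ranking, k = 2))
  # k covering everything selects everything
  expect_setequal(select_elite(v1, v2, ranking, k = 4),
                  c("sA", "sB", "sC", "sD"))
  # empty intersection is an empty set, not an error
  v2_flip <- sc(c(sD = 90, sC = 80, sB = 10, sA = 5))
  expect_length(select_elite(v1, v2_flip,
                             data.frame(rank = 1:4,
                                        strain = c("sB", "sC", "sD", "sA")),
                             k = 1), 0)
})

test_that("a planted efficient + fully tolerant strain is selected elite", {
  truth <- data.frame(strain = sprintf("s%02d", 1:10),
                      true_effect_class = rep(c("efficient", "neutral"),
                                              c(2, 8)))
  ph <- gen_phenotypes(planted_effects(truth), noise_sd = 0.05, seed = 53)
  cards <- score_card(ph)
  env <- planted_envelopes(truth$strain, top_strain = "s01", seed = 54)
  obs <- gen_stress_matrix(env, noise_sd = 0, seed = 55)
  ranking <- rank_tolerance(summarize_tolerance(call_growth(obs)))
  expect_equal(ranking$strain[1], "s01")
  elite <- select_elite(cards[cards$variety == "v1", ],
                        cards[cards$variety == "v2", ], ranking, k = 3)
  expect_true("s01" %in% elite)
})
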