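test_that("percent identity matches exhaustive alignment enumeration", {
  expect_equal(percent_identity("ACGT", "ACGT"), 100)
  expect_equal(percent_identity("ACGT", "ACGA"), 75)
  expect_equal(percent_identity("ACGT", "AC"), 50)
  expect_equal(oracle_identity_set("ACGT", "ACGA"), 75)
  expect_equal(oracle_identity_set("ACGT", "AC"), 50)
  set.seed(11)
  for (i in 1:25) {
    a <- random_seq(sample(2:5, 1))
    b <- random_seq(sample(2:5, 1))
    expect_true(percent_identity(a, b) %in% oracle_identity_set(a, b),
                info = paste(a, b))
  }
  expect_error(percent_identity("", "ACGT"), "non-empty")
})

test_that("alignment scores agree with the Biostrings aligner on random pairs", {
  set.seed(12)
  mat <- Biostrings::nucleotideSubstitutionMatrix(1, -1, baseOnly = TRUE)
  for (i in 1:40) {
    a <- random_seq(sample(30:120, 1))
    b <- random_seq(sample(30:120, 1))
    ref <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                         substitutionMatrix = mat,
                                         gapOpening = 0, gapExtension = 2)
    mine <- rhizotyper:::.nw_align_cpp(a, b, 1, -1, -2)
    expect_equal(mine$score, Biostrings::score(ref))
  }
})

test_that("percent identity is symmetric and 100 on self", {
  set.seed(13)
  for (i in 1:200) {
    a <- random_seq(sample(10:80, 1))
    b <- random_seq(sample(10:80, 1))
    expect_identical(percent_identity(a, b), percent_identity(b, a))
  }
  a <- random_seq(50)
  expect_equal(percent_identity(a, a), 100)
})

test_that("MLSA concatenation keeps order and length", {
  ls <- list(recA = c(s1 = "AA"), atpD = c(s1 = "CC"), rpoB = c(s1 = "GG"))
  expect_equal(unname(concat_mlsa(ls)), "AACCGG")
  set.seed(14)
  ls2 <- list(recA = c(s1 = random_seq(289)), atpD = c(s1 = random_seq(297)),
              rpoB = c(s1 = random_seq(599)))
  expect_equal(nchar(concat_mlsa(ls2)[["s1"]]), 1185)
  expect_error(concat_mlsa(ls[c("recA", "atpD")]), "rpoB")
  expect_error(concat_mlsa(list(recA = c(s1 = "AA", s2 = "AA"),
                                atpD = c(s1 = "CC", s2 = "CC"),
                                rpoB = c(s1 = "GG")), c("s1", "s2")), "s2")
})

test_that("species assignment respects the 97% boundary", {
  set.seed(15)
  base <- random_seq(1000)
  panel <- c(Alpha = base, Beta = mutate_test(base, 100))
  # identical query
  r <- assign_species(c(q = base), panel)
  expect_equal(r$label, "Alpha")
  expect_equal(r$best_identity, 100)
  expect_equal(r$status, "assigned")
  # exactly at the boundary: 30 substitutions in 1000 nt = 97.0% -> assigned
  q97 <- mutate_test(base, 30)
  r97 <- assign_species(c(q = q97), panel, threshold = 97)
  expect_equal(r97$best_identity, 97)
  expect_equal(r97$status, "assigned")
  # clearly below threshold to everything -> novel, label deferred
  qn <- mutate_test(base, 300)
  rn <- assign_species(c(q = qn), panel)
  expect_equal(rn$status, "novel")
  expect_true(is.na(rn$label))
  expect_true(rn$best_identity < 97)
})

test_that("genospecies clustering is single linkage with size-ranked numerals", {
  set.seed(16)
  a <- random_seq(500)
  b <- mutate_test(a, 10)   # 98% to a -> same cluster
  c_ <- mutate_test(a, 150) # far from both -> own cluster
  one <- cluster_genospecies(c(x = a))
  expect_equal(one$genospecies, "genosp. I")
  res <- cluster_genospecies(c(x = c_, y = a, z = b))
  expect_equal(res$genospecies[res$strain == "y"],
               res$genospecies[res$strain == "z"])
  expect_equal(sort(unique(res$genospecies)), c("genosp. I", "genosp. II"))
  # the larger cluster takes numeral I regardless of input order
  expect_equal(res$genospecies[res$strain == "y"], "genosp. I")
})

test_that("symbiovar calls go to the nearest reference above the floor", {
  set.seed(17)
  ph <- random_seq(400)
  vic <- mutate_test(ph, 60)
  refs <- data.frame(name = c("ph_ref", "vic_ref"),
                     symbiovar = c("sv. phaseoli", "sv. viciae"),
                     seq = c(ph, vic), stringsAsFactors = FALSE)
  expect_equal(assign_symbiovar(c(q = ph), refs)$symbiovar, "sv. phaseoli")
  near_vic <- mutate_test(vic, 16) # 96% to viciae ref
  r <- assign_symbiovar(c(q = near_vic), refs)
  expect_equal(r$symbiovar, "sv. viciae")
  far <- random_seq(400) # ~random: ~25% identity region, unresolved
  expect_equal(assign_symbiovar(c(q = far), refs)$symbiovar, "unresolved")
})

test_that("neighbour joining recovers quartets, closed forms and edge cases", {
  # 2 taxa: single edge split evenly
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  t2 <- nj_tree(d2)
  expect_equal(sort(t2$tip.label), c("a", "b"))
  expect_equal(unname(t2$edge.length), c(0.2, 0.2))

  # ultrametric 3-taxon matrix: pendant lengths from the closed form
  d3 <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- nj_tree(d3)
  pend <- setNames(t3$edge.length[match(1:3, t3$edge[, 2])], t3$tip.label)
  expect_equal(unname(pend[c("a", "b", "c")]), c(1, 1, 5))

  # all three unrooted quartet topologies from additive matrices
  skip_if_not_installed("phangorn")
  quartet_dist <- function(pair) {
    taxa <- c("a", "b", "c", "d")
    d <- matrix(5, 4, 4, dimnames = list(taxa, taxa)) # across the split: 1+3+1
    diag(d) <- 0
    other <- setdiff(taxa, pair)
    d[pair[1], pair[2]] <- d[pair[2], pair[1]] <- 2 # cherries: 1+1
    d[other[1], other[2]] <- d[other[2], other[1]] <- 2
    d
  }
  for (pair in list(c("a", "b"), c("a", "c"), c("a", "d"))) {
    truth <- ape::read.tree(text = sprintf("((%s,%s),(%s,%s));",
                                           pair[1], pair[2],
                                           setdiff(c("a", "b", "c", "d"), pair)[1],
                                           setdiff(c("a", "b", "c", "d"), pair)[2]))
    expect_equal(phangorn::RF.dist(nj_tree(quartet_dist(pair)), truth), 0)
  }

  # identical rows join first at distance zero
  d0 <- matrix(c(0, 0, 3, 0, 0, 3, 3, 3, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t0 <- nj_tree(d0)
  pend0 <- setNames(t0$edge.length[match(1:3, t0$edge[, 2])], t0$tip.label)
  expect_equal(unname(pend0["a"]), 0)
  expect_equal(unname(pend0["b"]), 0)

  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2)), "symmetric")
  dneg <- matrix(c(1, 2, 2, 0), 2)
  expect_error(nj_tree(dneg), "diagonal")
})

test_that("16S grouping recovers planted coarse groups", {
  set.seed(18)
  anc <- random_seq(600)
  groups <- c(mutate_test(anc, 0), mutate_test(anc, 30), mutate_test(anc, 60))
  seqs <- unlist(lapply(1:3, function(g)
    setNames(vapply(1:3, function(i) mutate_test(groups[g], 2), character(1)),
             paste0("g", g, "_", 1:3))))
  res <- group_16s(seqs, depth = 2)
  lab <- setNames(res$group, res$strain)
  for (g in 1:3) {
    members <- paste0("g", g, "_", 1:3)
    expect_length(unique(lab[members]), 1)
  }
  expect_length(unique(lab), 3)
})
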