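test_that("NJ recovers additive four-taxon trees exactly", {
  # tree ((A:1,B:2):1,(C:1,D:1)): additive path distances
  D <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  D["A", "B"] <- D["B", "A"] <- 3
  D["A", "C"] <- D["C", "A"] <- 3
  D["A", "D"] <- D["D", "A"] <- 3
  D["B", "C"] <- D["C", "B"] <- 4
  D["B", "D"] <- D["D", "B"] <- 4
  D["C", "D"] <- D["D", "C"] <- 2
  st <- nj_tree(D)
  expect_true(oracle_monophyletic(st$phy, c("A", "B")))
  expect_true(oracle_monophyletic(st$phy, c("C", "D")))
  C <- ape::cophenetic.phylo(st$phy)[rownames(D), colnames(D)]
  expect_equal(C, D, tolerance = 1e-9)
})

test_that("three taxa give the unique unrooted topology", {
  D <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  st <- nj_tree(D)
  expect_equal(length(st$phy$tip.label), 3)
  expect_equal(st$phy$Nnode, 1)
  expect_error(nj_tree(matrix(c(0, Inf, Inf, 0), 2)), "finite")
})

test_that("NJ equals UPGMA topology on ultrametric input", {
  set.seed(71)
  for (trial in 1:20) {
    n <- 7
    # build an ultrametric matrix from a random coalescent-style tree
    phy <- ape::rcoal(n, tip.label = paste0("t", 1:n))
    D <- ape::cophenetic.phylo(phy)
    nj_bip <- oracle_bipartitions(nj_tree(D)$phy)
    up_phy <- ape::as.phylo(upgma_cluster(D))
    up_bip <- oracle_bipartitions(up_phy)
    canon <- function(sets, tips) {
      # nontrivial bipartitions only: a rooted tree's root split is trivial
      # once unrooted
      keys <- vapply(sets, function(s) {
        if (tips[1] %in% s) s <- setdiff(tips, s)
        if (length(s) < 2 || length(s) > length(tips) - 2) return("")
        paste(sort(s), collapse = "|")
      }, character(1))
      sort(unique(keys[keys != ""]))
    }
    tips <- sort(phy$tip.label)
    expect_equal(canon(nj_bip, tips), canon(up_bip, tips))
  }
})

test_that("bootstrap supports are deterministic and bounded", {
  sim <- simulate_scenario(standard_scenario(n_pools = 2, n_hybrids = 0,
                                             F = 0.3, sites = 400,
                                             n_pops = 3,
                                             samples_per_pop = 2, seed = 2))
  st1 <- bootstrap_supports(sim$genotypes, n_reps = 25, seed = 7)
  st2 <- bootstrap_supports(sim$genotypes, n_reps = 25, seed = 7)
  expect_identical(st1$ufboot, st2$ufboot)
  expect_identical(write_support_tree(st1), write_support_tree(st2))
  ok <- !is.na(st1$ufboot)
  expect_true(all(st1$ufboot[ok] >= 0 & st1$ufboot[ok] <= 100))
  expect_identical(st1$sh_alrt, st1$ufboot)

  one <- bootstrap_supports(sim$genotypes, n_reps = 1, seed = 3)
  expect_true(all(one$ufboot[!is.na(one$ufboot)] %in% c(0, 100)))
})

test_that("deep divergence earns high stem support", {
  sim <- simulate_scenario(standard_scenario(n_pools = 2, n_hybrids = 0,
                                             F = 0.3, sites = 800,
                                             n_pops = 5,
                                             samples_per_pop = 1, seed = 9))
  st <- bootstrap_supports(sim$genotypes, n_reps = 200, seed = 11)
  grp1 <- sim$map$sample[sim$map$taxon == "taxon_P1"]
  res <- assess_monophyly(st, grp1)
  expect_true(res$is_monophyletic)
  expect_gte(res$ufboot, 95)
})

test_that("monophyly assessment reads stem supports and applies thresholds", {
  st <- parse_support_tree("((g1,g2)99.8/100,(x,y));")
  res <- assess_monophyly(st, c("g1", "g2"))
  expect_true(res$is_monophyletic)
  expect_equal(res$sh_alrt, 99.8)
  expect_equal(res$ufboot, 100)
  expect_true(res$passes_thresholds)

  bad <- assess_monophyly(st, c("g1", "x"))
  expect_false(bad$is_monophyletic)
  expect_false(bad$passes_thresholds)

  # absent support fails closed
  st2 <- parse_support_tree("((g1,g2),(x,y));")
  res2 <- assess_monophyly(st2, c("g1", "g2"))
  expect_true(res2$is_monophyletic)
  expect_false(res2$passes_thresholds)

  # support below either threshold fails
  st3 <- parse_support_tree("((g1,g2)79/100,(x,y));")
  expect_false(assess_monophyly(st3, c("g1", "g2"))$passes_thresholds)

  expect_error(assess_monophyly(st, c("g1", "nope")), "nope")
})

test_that("singleton targets pass only under the waiver", {
  st <- parse_support_tree("((g1,g2)99/100,(x,y));")
  s <- assess_monophyly(st, "g1")
  expect_true(s$is_monophyletic)
  expect_true(s$passes_thresholds)
  strict <- assess_monophyly(st, "g1", waive_singletons = FALSE)
  expect_false(strict$passes_thresholds)
})

test_that("monophyly verdicts equal exhaustive bipartition enumeration", {
  set.seed(101)
  for (trial in 1:40) {
    ntip <- sample(5:10, 1)
    phy <- random_tree(ntip)
    st <- support_tree(phy)
    target <- sample(phy$tip.label, sample(2:(ntip - 1), 1))
    got <- assess_monophyly(st, target)$is_monophyletic
    expect_equal(got, oracle_monophyletic(phy, target))
    # complement has the same verdict (unrooted semantics)
    comp <- setdiff(phy$tip.label, target)
    if (length(comp) >= 2) {
      expect_equal(assess_monophyly(st, comp)$is_monophyletic, got)
    }
  }
})

test_that("backbone clades resolve exemplar blocks and flag conflicts", {
  st <- parse_support_tree("(((a1,a2),a3),(b1,(b2,b3)));")
  cm <- assign_backbone_clades(st, list(A = c("a1", "a3"),
                                        B = c("b1", "b3")))
  expect_equal(cm$clade[match(paste0("a", 1:3), cm$population)],
               rep("A", 3))
  expect_equal(cm$clade[match(paste0("b", 1:3), cm$population)],
               rep("B", 3))

  # exemplars from interleaved positions cannot be separated
  st2 <- parse_support_tree("((a1,b1),(a2,b2),(a3,b3));")
  expect_error(assign_backbone_clades(st2, list(A = c("a1", "a2", "a3"),
                                                B = c("b1", "b2", "b3"))),
               "separable")
  expect_error(assign_backbone_clades(st, list(A = c("a1"), B = c("a1"))),
               "disjoint")
})

test_that("backbone clades equal the minimal-containing-bipartition search", {
  set.seed(61)
  for (trial in 1:15) {
    phy <- random_tree(8)
    st <- support_tree(phy)
    tips <- phy$tip.label
    # choose two exemplar pairs that are separable by construction
    sides <- oracle_bipartitions(phy)
    sides <- sides[vapply(sides, length, 1L) >= 2]
    if (length(sides) < 2) next
    s1 <- sides[[1]]
    rest <- setdiff(tips, s1)
    if (length(rest) < 2) next
    seeds <- list(A = s1[1:2], B = rest[1:2])
    cm <- assign_backbone_clades(st, seeds)
    # oracle: smallest bipartition side (either orientation) containing the
    # exemplars of one label and none of the other
    all_sides <- c(sides, lapply(sides, function(s) setdiff(tips, s)),
                   as.list(tips))
    for (lab in names(seeds)) {
      other <- setdiff(unlist(seeds), seeds[[lab]])
      ok <- Filter(function(s) all(seeds[[lab]] %in% s) &&
                     !any(other %in% s), all_sides)
      best <- ok[[which.min(vapply(ok, length, 1L))]]
      got <- cm$population[!is.na(cm$clade) & cm$clade == lab]
      expect_setequal(got, best)
    }
  }
})

test_that("discordance uses the agreement-maximizing correspondence", {
  pops <- paste0("p", 1:9)
  nuc <- clade_map(pops, rep(c("NA", "NB", "NC"), each = 3))
  M <- sample_map(pops, pops, paste0("tax", rep(1:9)))
  same <- detect_cytonuclear_discordance(
    nuc, clade_map(pops, rep(c("PA", "PB", "PC"), each = 3)), M)
  expect_equal(same$n_discordant_populations, 0)
  expect_equal(unname(same$correspondence),
               c("PA", "PB", "PC"))

  # one population moves: NB population in PA under NB<->PB is discordant
  pl <- rep(c("PA", "PB", "PC"), each = 3)
  pl[4] <- "PA"
  rep2 <- detect_cytonuclear_discordance(nuc, clade_map(pops, pl), M)
  expect_equal(rep2$n_discordant_populations, 1)
  expect_equal(rep2$populations$population[rep2$populations$discordant],
               "p4")
  expect_equal(rep2$n_discordant_species, 1)
})

test_that("label correspondence equals exhaustive search over assignments", {
  set.seed(91)
  for (trial in 1:15) {
    n <- 12
    pops <- paste0("p", 1:n)
    nuc_lab <- sample(c("NA", "NB", "NC"), n, TRUE)
    pla_lab <- sample(c("PA", "PB", "PC"), n, TRUE)
    nuc <- clade_map(pops, nuc_lab)
    pla <- clade_map(pops, pla_lab)
    M <- sample_map(pops, pops, pops)
    rep <- detect_cytonuclear_discordance(nuc, pla, M)
    conf <- table(factor(nuc_lab, c("NA", "NB", "NC")),
                  factor(pla_lab, c("PA", "PB", "PC")))
    best <- oracle_best_assignment(unclass(conf))
    expect_equal(n - rep$n_discordant_populations, best$value)
    expect_lte(rep$n_discordant_species, rep$n_discordant_populations)
  }
})
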