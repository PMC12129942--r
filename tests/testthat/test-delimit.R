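mk_mono <- function(mono = TRUE, sh = 99, uf = 100, pass = NULL) {
  if (is.null(pass)) pass <- mono && !is.na(sh) && sh >= 80 && uf >= 95
  structure(list(leaves = "x", is_monophyletic = mono, sh_alrt = sh,
                 ufboot = uf, passes_thresholds = pass),
            class = "monophyly_result")
}

mk_purity <- function(q_star, class, dominant = 1) {
  structure(list(taxon = "t", dominant = dominant, q_star = q_star,
                 class = class, contributing = dominant,
                 profile = q_star), class = "purity_call")
}

test_that("the cascade assigns each status by its rule", {
  cfg <- delim_config()
  # pure, supported monophyly, diagnosable vs its shared-pool partner
  r1 <- evaluate_taxon("a", "species", mk_mono(), mk_purity(0.98, "PURE"),
                       diag_partners = c(b = 3), diag_parents = numeric(0),
                       plastid_discordant = FALSE, junior_to = character(0),
                       config = cfg)
  expect_equal(r1$status, "VALID")

  # identical pools, no diagnostic difference, junior name collapses
  r2 <- evaluate_taxon("junior", "species", mk_mono(FALSE, NA, NA),
                       mk_purity(0.97, "PURE"),
                       diag_partners = c(senior = 0),
                       diag_parents = numeric(0),
                       plastid_discordant = FALSE, junior_to = "senior",
                       config = cfg)
  expect_equal(r2$status, "SYNONYM_CANDIDATE")
  # ... while the senior passes rule 1, its junior not blocking
  r2s <- evaluate_taxon("senior", "species", mk_mono(),
                        mk_purity(0.97, "PURE"),
                        diag_partners = c(junior = 0),
                        diag_parents = numeric(0),
                        plastid_discordant = FALSE,
                        junior_to = character(0), config = cfg)
  expect_equal(r2s$status, "VALID")

  # subthreshold override: supported monophyly + diagnosable
  r3 <- evaluate_taxon("f", "species", mk_mono(TRUE, 100, 100),
                       mk_purity(0.72, "SUBTHRESHOLD"),
                       diag_partners = numeric(0),
                       diag_parents = numeric(0),
                       plastid_discordant = TRUE,
                       junior_to = character(0), config = cfg)
  expect_equal(r3$status, "VALID_BY_OVERRIDE")

  # admixed + discordant + intermediate morphology
  r4 <- evaluate_taxon("h", "species", mk_mono(TRUE, 99, 100),
                       mk_purity(0.55, "ADMIXED"),
                       diag_partners = numeric(0),
                       diag_parents = c(p1 = 0, p2 = 3),
                       plastid_discordant = TRUE,
                       junior_to = character(0), config = cfg)
  expect_equal(r4$status, "HYBRID")

  # admixed but concordant plastid: unresolved
  r5 <- evaluate_taxon("u", "species", mk_mono(FALSE, NA, NA),
                       mk_purity(0.55, "ADMIXED"),
                       diag_partners = numeric(0),
                       diag_parents = c(p1 = 0),
                       plastid_discordant = FALSE,
                       junior_to = character(0), config = cfg)
  expect_equal(r5$status, "UNRESOLVED")
  expect_true(all(vapply(list(r1, r2, r3, r4, r5),
                         function(r) length(r$evidence) > 0, logical(1))))
})

test_that("an admixed, discordant but diagnosable monophyletic taxon stays unresolved", {
  r <- evaluate_taxon("x", "species", mk_mono(TRUE, 99, 100),
                      mk_purity(0.5, "ADMIXED"),
                      diag_partners = numeric(0),
                      diag_parents = c(p1 = 2, p2 = 4),
                      plastid_discordant = TRUE, junior_to = character(0))
  expect_equal(r$status, "UNRESOLVED")
})

test_that("disabling the override rule demotes exactly those taxa", {
  cfg_no3 <- delim_config(rules = c(1, 2, 4))
  r <- evaluate_taxon("f", "species", mk_mono(TRUE, 100, 100),
                      mk_purity(0.72, "SUBTHRESHOLD"),
                      diag_partners = numeric(0), diag_parents = numeric(0),
                      plastid_discordant = FALSE, junior_to = character(0),
                      config = cfg_no3)
  expect_equal(r$status, "UNRESOLVED")
  r1 <- evaluate_taxon("a", "species", mk_mono(), mk_purity(0.98, "PURE"),
                       diag_partners = numeric(0),
                       diag_parents = numeric(0),
                       plastid_discordant = FALSE, junior_to = character(0),
                       config = cfg_no3)
  expect_equal(r1$status, "VALID")
})

test_that("config rejects inconsistent thresholds", {
  expect_error(delim_config(pure_threshold = 0.6, override_floor = 0.7),
               "exceed")
})

test_that("a planted hybrid is the only HYBRID verdict in its scenario", {
  S <- standard_scenario(n_pools = 3, n_hybrids = 1, F = 0.2, sites = 1500,
                         seed = 23)
  sim <- simulate_scenario(S)
  fit <- em_admixture(sim$genotypes, K = 3, seed = stage_seed(23, "em"))
  groups <- setNames(sim$map$population, sim$map$sample)
  tree <- bootstrap_supports(sim$genotypes, n_reps = 100,
                             seed = stage_seed(23, "boot"), groups = groups)
  rep <- run_delimitation(fit$Q, sim$map, tree, sim$plastid, sim$traits)
  status <- vapply(rep$records, function(r) r$status, character(1))
  expect_equal(names(status)[status == "HYBRID"], "taxon_H1")
  expect_equal(sum(status == "VALID"), 3)
  expect_equal(rep$summary$gene_pools, 3)
})

test_that("an all-pure scenario yields no hybrids and full validity", {
  S <- standard_scenario(n_pools = 3, n_hybrids = 0, F = 0.25, sites = 1200,
                         seed = 29)
  sim <- simulate_scenario(S)
  fit <- em_admixture(sim$genotypes, K = 3, seed = stage_seed(29, "em"))
  groups <- setNames(sim$map$population, sim$map$sample)
  tree <- bootstrap_supports(sim$genotypes, n_reps = 100,
                             seed = stage_seed(29, "boot"), groups = groups)
  rep <- run_delimitation(fit$Q, sim$map, tree, sim$plastid, sim$traits)
  expect_equal(rep$summary$hybrid_species, 0)
  expect_equal(rep$summary$valid_species, 3)
})

test_that("delimitation reports are deterministic given inputs and config", {
  S <- standard_scenario(n_pools = 2, n_hybrids = 1, F = 0.25, sites = 800,
                         seed = 17)
  sim <- simulate_scenario(S)
  fit <- em_admixture(sim$genotypes, K = 2, seed = 41)
  groups <- setNames(sim$map$population, sim$map$sample)
  tree <- bootstrap_supports(sim$genotypes, n_reps = 50, seed = 41,
                             groups = groups)
  r1 <- run_delimitation(fit$Q, sim$map, tree, sim$plastid, sim$traits)
  r2 <- run_delimitation(fit$Q, sim$map, tree, sim$plastid, sim$traits)
  expect_identical(vapply(r1$records, `[[`, "", "status"),
                   vapply(r2$records, `[[`, "", "status"))
  expect_identical(r1$summary, r2$summary)
})

test_that("hybrid removal drops exactly the admixed taxa before rebuilding", {
  S <- standard_scenario(n_pools = 3, n_hybrids = 2, F = 0.25, sites = 1000,
                         seed = 37)
  sim <- simulate_scenario(S)
  fit <- em_admixture(sim$genotypes, K = 3, seed = stage_seed(37, "em"))
  groups <- setNames(sim$map$population, sim$map$sample)
  tree <- bootstrap_supports(sim$genotypes, n_reps = 60,
                             seed = stage_seed(37, "boot"), groups = groups)
  rep <- run_delimitation(fit$Q, sim$map, tree, sim$plastid, sim$traits)
  rebuilt <- rebuild_without_hybrids(rep, sim$genotypes, sim$map,
                                     n_reps = 60, seed = 5)
  pure_pops <- unique(sim$map$population[grepl("_P", sim$map$taxon)])
  expect_setequal(rebuilt$phy$tip.label, pure_pops)
  # each pure pool is a supported clade in the rebuilt tree
  for (t in paste0("taxon_P", 1:3)) {
    pops_t <- unique(sim$map$population[sim$map$taxon == t])
    res <- assess_monophyly(rebuilt, pops_t)
    expect_true(res$passes_thresholds)
  }

  # no hybrids: identical leaf set before and after
  S0 <- standard_scenario(n_pools = 3, n_hybrids = 0, F = 0.25, sites = 600,
                          seed = 43)
  sim0 <- simulate_scenario(S0)
  fit0 <- em_admixture(sim0$genotypes, K = 3, seed = 43)
  tree0 <- bootstrap_supports(sim0$genotypes, n_reps = 30, seed = 43,
                              groups = setNames(sim0$map$population,
                                                sim0$map$sample))
  rep0 <- run_delimitation(fit0$Q, sim0$map, tree0, sim0$plastid,
                           sim0$traits)
  rebuilt0 <- rebuild_without_hybrids(rep0, sim0$genotypes, sim0$map,
                                      n_reps = 20, seed = 5)
  expect_setequal(rebuilt0$phy$tip.label, unique(sim0$map$population))
})
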