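#' Delimitation thresholds and options
#'
#' One configuration object holds every threshold of the decision cascade
#' and the upstream filters, so a whole run is reproducible from its config.
#'
#' @param pure_threshold Ancestry purity threshold (default 0.95).
#' @param override_floor Lower edge of the subthreshold-override window
#'   (default 0.70).
#' @param minor_threshold Minimum mean ancestry for a pool to count as
#'   contributing (default 0.05).
#' @param sh_min,uf_min Branch-support minima, percent (defaults 80 / 95).
#' @param min_traits Diagnosability threshold in discontinuous traits
#'   (default 2).
#' @param max_missing,min_mac,min_maf Site-filter thresholds.
#' @param ld_window,ld_step,ld_r2 LD-pruning parameters.
#' @param waive_singletons Singleton-taxon monophyly passes without stem
#'   support (default TRUE).
#' @param rules Integer vector of enabled cascade rules (default 1:4; rule
#'   5, UNRESOLVED, is always the fallback).
#' @param seniority Optional character vector of taxon ids in decreasing
#'   nomenclatural priority for synonym calls; defaults to map order.
#' @param seed Master seed fanned out per stage via [stage_seed()].
#' @return A list of class `delim_config`.
#' @export
delim_config <- function(pure_threshold = 0.95, override_floor = 0.70,
                         minor_threshold = 0.05, sh_min = 80, uf_min = 95,
                         min_traits = 2, max_missing = 0.15, min_mac = 3,
                         min_maf = 0.05, ld_window = 50, ld_step = 10,
                         ld_r2 = 0.1, waive_singletons = TRUE, rules = 1:4,
                         seniority = NULL, seed = 1) {
  assert_that(pure_threshold > override_floor,
              "pure_threshold must exceed override_floor")
  assert_that(override_floor > minor_threshold,
              "override_floor must exceed minor_threshold")
  structure(as.list(environment()), class = "delim_config")
}

#' Evaluate one taxon through the decision cascade
#'
#' Rule order (first match wins):
#' 1. PURE and supported monophyly, diagnosable (>= `min_traits`
#'    discontinuous traits) against every shared-pool partner (vacuously
#'    true with none) -> `VALID`.
#' 2. PURE or SUBTHRESHOLD, sharing a pool with a partner against which it
#'    shows fewer than `min_traits` discontinuous traits, and junior to
#'    that partner -> `SYNONYM_CANDIDATE` (the senior member's
#'    diagnosability requirement then ignores this junior).
#' 3. SUBTHRESHOLD with supported monophyly and diagnosable ->
#'    `VALID_BY_OVERRIDE`.
#' 4. ADMIXED with cytonuclear discordance and either non-monophyly or
#'    morphological intermediacy (fewer than `min_traits` discontinuous
#'    traits against at least one parent-candidate taxon) -> `HYBRID`.
#' 5. Otherwise `UNRESOLVED`.
#'
#' @param taxon Taxon id.
#' @param rank `"species"` or `"infraspecific"`.
#' @param mono A `monophyly_result` for the taxon.
#' @param purity A `purity_call` for the taxon.
#' @param diag_partners Named integer vector: discontinuous-trait count
#'   against each shared-pool partner (may be empty).
#' @param diag_parents Named integer vector: discontinuous-trait count
#'   against each parent-candidate taxon (may be empty).
#' @param plastid_discordant Logical or `NA` (unknown).
#' @param junior_to Character vector of partners this taxon is junior to
#'   (already resolved from config seniority).
#' @param config A [delim_config()].
#' @return A list of class `delimitation_record` with `status` and an
#'   ordered `evidence` trail of rule firings.
#' @export
evaluate_taxon <- function(taxon, rank, mono, purity, diag_partners,
                           diag_parents, plastid_discordant, junior_to,
                           config = delim_config()) {
  for (f in c("mono", "purity"))
    assert_that(!is.null(get(f)), "missing required evidence field: %s", f)
  trail <- character(0)
  note <- function(x) trail <<- c(trail, x)
  mono_ok <- isTRUE(mono$passes_thresholds)
  # an undiagnosable partner blocks validity unless that partner is junior
  # to this taxon (a collapsed synonym cannot block its senior)
  failing <- names(diag_partners)[diag_partners < config$min_traits]
  juniors_of_taxon <- setdiff(names(diag_partners), junior_to)
  diagnosable <- all(failing %in% juniors_of_taxon)
  status <- NULL
  if (1 %in% config$rules && purity$class == "PURE" && mono_ok &&
      diagnosable) {
    note("rule1: pure + supported monophyly + diagnosable -> VALID")
    status <- "VALID"
  }
  if (is.null(status) && 2 %in% config$rules &&
      purity$class %in% c("PURE", "SUBTHRESHOLD") &&
      length(junior_to) > 0 && any(diag_partners[junior_to] <
                                     config$min_traits)) {
    note("rule2: shares pool, undiagnosable vs senior -> SYNONYM_CANDIDATE")
    status <- "SYNONYM_CANDIDATE"
  }
  if (is.null(status) && 3 %in% config$rules &&
      purity$class == "SUBTHRESHOLD" && mono_ok && diagnosable) {
    note("rule3: subthreshold override -> VALID_BY_OVERRIDE")
    status <- "VALID_BY_OVERRIDE"
  }
  if (is.null(status) && 4 %in% config$rules && purity$class == "ADMIXED" &&
      isTRUE(plastid_discordant) &&
      (!isTRUE(mono$is_monophyletic) ||
         (length(diag_parents) > 0 &&
            any(diag_parents < config$min_traits)))) {
    note("rule4: admixed + discordant + intermediate/non-mono -> HYBRID")
    status <- "HYBRID"
  }
  if (is.null(status)) {
    note("rule5: no rule fired -> UNRESOLVED")
    status <- "UNRESOLVED"
  }
  structure(list(taxon = taxon, rank = rank, mono = mono, purity = purity,
                 diag_partners = diag_partners, diag_parents = diag_parents,
                 plastid_discordant = plastid_discordant, status = status,
                 evidence = trail),
            class = "delimitation_record")
}

#' @export
print.delimitation_record <- function(x, ...) {
  cat(sprintf("<delimitation_record> %s [%s]: %s (purity %s q*=%.2f)\n",
              x$taxon, x$rank, x$status, x$purity$class, x$purity$q_star))
  invisible(x)
}

## taxon -> unit labels of a trait table, matching either samples or
## populations of the map
taxon_trait_units <- function(traits, M, taxon) {
  rows <- M[M$taxon == taxon, ]
  u <- traits$units
  out <- u[u %in% rows$sample | u %in% rows$population | u %in% rows$taxon]
  unique(out)
}

#' Run the full delimitation cascade
#'
#' Combines ancestry purity, support-thresholded monophyly on the nuclear
#' tree (leaves = population ids), cytonuclear discordance against the
#' plastid clade assignment, and trait diagnosability into one
#' [evaluate_taxon()] verdict per taxon, plus species-rank summary counts.
#'
#' @param Q An [ancestry_matrix()] over samples.
#' @param M A [sample_map()].
#' @param nuclear_tree A [support_tree()] whose leaves are population ids.
#' @param plastid_clades A [clade_map()] giving each population's plastid
#'   clade (for simulated data, the maternal pool label).
#' @param traits A [trait_table()] whose units are sample, population or
#'   taxon ids.
#' @param config A [delim_config()].
#' @param nuclear_clades Optional [clade_map()]; when `NULL`, each
#'   population's nuclear label is its dominant ancestry pool, so
#'   discordance compares maternal against dominant-nuclear ancestry.
#' @return A list of class `delimitation_report`: `records`, `summary`
#'   (valid species, hybrid species, gene pools, synonym pairs, unresolved),
#'   `discordance` and the `config` used.
#' @export
run_delimitation <- function(Q, M, nuclear_tree, plastid_clades, traits,
                             config = delim_config(),
                             nuclear_clades = NULL) {
  taxa <- unique(M$taxon)
  ranks <- M$rank[match(taxa, M$taxon)]
  prof <- taxon_ancestry_profile(Q, M)
  calls <- lapply(taxa, function(t)
    classify_purity(prof[t, ], config$pure_threshold, config$override_floor,
                    config$minor_threshold, taxon = t))
  names(calls) <- taxa

  if (is.null(nuclear_clades)) {
    pops <- unique(M$population)
    dom <- vapply(pops, function(p) {
      sel <- M$population == p
      qbar <- colMeans(Q$q[Q$samples %in% M$sample[sel], , drop = FALSE])
      paste0("G", which.max(qbar))
    }, character(1))
    nuclear_clades <- clade_map(pops, dom)
  }
  disc <- detect_cytonuclear_discordance(nuclear_clades, plastid_clades, M)
  disc_by_taxon <- tapply(disc$populations$discordant,
                          disc$populations$taxon, any)

  pairs <- shared_pool_pairs(calls)
  seniority <- config$seniority
  if (is.null(seniority)) seniority <- taxa
  dominant <- vapply(calls, function(x) x$dominant, numeric(1))
  pure_taxa <- taxa[vapply(calls, function(x) x$class != "ADMIXED",
                           logical(1))]

  records <- list()
  for (i in seq_along(taxa)) {
    t <- taxa[i]
    pops_t <- unique(M$population[M$taxon == t])
    mono <- assess_monophyly(nuclear_tree, pops_t, config$sh_min,
                             config$uf_min, config$waive_singletons)
    partners <- unique(c(pairs$taxon_b[pairs$taxon_a == t],
                         pairs$taxon_a[pairs$taxon_b == t]))
    diag_partners <- vapply(partners, function(o)
      count_diagnostic_traits(traits, taxon_trait_units(traits, M, t),
                              taxon_trait_units(traits, M, o),
                              config$min_traits)$count, numeric(1))
    names(diag_partners) <- partners
    # parent candidates: non-admixed taxa whose dominant pool contributes
    parent_cand <- setdiff(
      pure_taxa[dominant[pure_taxa] %in% calls[[t]]$contributing], t)
    diag_parents <- vapply(parent_cand, function(o)
      count_diagnostic_traits(traits, taxon_trait_units(traits, M, t),
                              taxon_trait_units(traits, M, o),
                              config$min_traits)$count, numeric(1))
    names(diag_parents) <- parent_cand
    junior_to <- partners[match(t, seniority) > match(partners, seniority)]
    junior_to <- junior_to[!is.na(junior_to)]
    records[[t]] <- evaluate_taxon(
      t, ranks[i], mono, calls[[t]], diag_partners, diag_parents,
      plastid_discordant = isTRUE(disc_by_taxon[as.character(t)]),
      junior_to = junior_to, config = config)
  }
  delimitation_report(records, disc, config)
}

delimitation_report <- function(records, discordance, config) {
  status <- vapply(records, function(r) r$status, character(1))
  rank <- vapply(records, function(r) r$rank, character(1))
  sp <- rank == "species"
  dominant <- vapply(records, function(r) r$purity$dominant, numeric(1))
  validish <- status %in% c("VALID", "VALID_BY_OVERRIDE")
  # seniors of synonym pairs keep their pool in the gene-pool tally
  pools <- unique(dominant[validish])
  summary <- list(
    valid_species = sum(validish & sp),
    hybrid_species = sum(status == "HYBRID" & sp),
    synonym_candidates = sum(status == "SYNONYM_CANDIDATE" & sp),
    unresolved_species = sum(status == "UNRESOLVED" & sp),
    gene_pools = length(pools))
  structure(list(records = records, summary = summary,
                 discordance = discordance, config = config),
            class = "delimitation_report")
}

#' @export
print.delimitation_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<delimitation_report> %d valid, %d hybrid, %d synonym",
                     " candidates, %d unresolved species; %d gene pools\n"),
              s$valid_species, s$hybrid_species, s$synonym_candidates,
              s$unresolved_species, s$gene_pools))
  invisible(x)
}

#' Rebuild the tree after removing hybrids and admixed taxa
#'
#' Drops every sample of taxa whose status is HYBRID or whose purity class
#' is ADMIXED (override taxa are SUBTHRESHOLD and stay), then rebuilds the
#' population tree with [bootstrap_supports()] over the retained
#' populations.
#'
#' @param report A `delimitation_report`.
#' @param G The [genotype_matrix()] the analysis used.
#' @param M The [sample_map()].
#' @param n_reps,seed Passed to [bootstrap_supports()].
#' @return A [support_tree()] over the retained populations.
#' @export
rebuild_without_hybrids <- function(report, G, M, n_reps = 100, seed = 1) {
  drop_taxa <- names(report$records)[vapply(report$records, function(r)
    r$status == "HYBRID" || r$purity$class == "ADMIXED", logical(1))]
  keep_samples <- M$sample[!(M$taxon %in% drop_taxa)]
  keep <- G$samples %in% keep_samples
  pops <- unique(M$population[M$sample %in% G$samples[keep]])
  assert_that(length(pops) >= 4,
              "fewer than 4 populations retained (%d)", length(pops))
  Gk <- genotype_matrix(G$dosages[keep, , drop = FALSE], G$samples[keep],
                        G$sites)
  groups <- stats::setNames(M$population[match(Gk$samples, M$sample)],
                            Gk$samples)
  bootstrap_supports(Gk, n_reps = n_reps, seed = seed, groups = groups)
}
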