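## Fixture tables encoding the study's verbal per-taxon evidence ------------
##
## 29 sampled taxa (27 species + 2 infraspecific), their K=9 gene-pool
## compositions, K=19 assignments, nuclear/plastid backbone clades per
## population, and the post-hybrid-removal clade structure. Magnitudes
## (0.97 pure, 0.72 subthreshold, 0.60 admixed-dominant) are stand-ins
## constrained by the published inequalities (pure > 0.95, the one
## subthreshold case in (0.70, 0.95), admixed dominant < 0.70); all summary
## counts are invariant to any choice respecting those bounds.

fixture_taxa <- function() {
  tx <- function(taxon, rank, series, dominant, minors, class) {
    data.frame(taxon = taxon, rank = rank, series = series,
               dominant = dominant, minors = I(list(minors)),
               class = class, stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    # taxa of a single gene pool (near-exclusive ancestry)
    tx("C_conspicuus", "species", "C", 1, integer(0), "pure"),
    tx("C_sherriffii", "species", "C", 1, integer(0), "pure"),
    tx("C_microphyllus", "species", "M", 1, integer(0), "pure"),
    tx("C_rockii", "species", "B", 2, integer(0), "pure"),
    tx("C_sp1", "species", "B", 2, integer(0), "pure"),
    tx("C_salicifolius", "species", "S", 3, integer(0), "pure"),
    tx("C_glaucophyllus", "species", "P", 4, integer(0), "pure"),
    tx("C_dammeri", "species", "R", 4, integer(0), "pure"),
    tx("C_dammeri_songmingensis", "infraspecific", "R", 4, integer(0),
       "pure"),
    tx("C_fulvidus", "species", "P", 5, 6L, "subthreshold"),
    tx("C_serotinus", "species", "P", 6, integer(0), "pure"),
    tx("C_delavayanus", "species", "B", 7, integer(0), "pure"),
    tx("C_brickellii", "species", "P", 8, integer(0), "pure"),
    tx("C_turbinatus", "species", "P", 9, integer(0), "pure"),
    tx("C_coriaceus", "species", "P", 9, integer(0), "pure"),
    # admixed taxa and their named contributing pools
    tx("C_marginatus", "species", "M", 2, c(1L, 3L, 6L), "admixed"),
    tx("C_buxifolius_vellaeus", "infraspecific", "B", 2, c(1L, 7L),
       "admixed"),
    tx("C_insolitus", "species", "B", 2, c(1L, 6L), "admixed"),
    tx("C_sp2", "species", "S", 6, c(3L, 9L), "admixed"),
    tx("C_morrisonensis", "species", "R", 3, c(1L, 4L), "admixed"),
    tx("C_cochleatus", "species", "R", 1, c(3L, 4L), "admixed"),
    tx("C_meiophyllus", "species", "P", 4, 6L, "admixed"),
    tx("C_buxifolius", "species", "B", 6, 7L, "admixed"),
    tx("C_lidjiangensis", "species", "B", 6, 7L, "admixed"),
    tx("C_argenteus", "species", "B", 4, 7L, "admixed"),
    tx("C_sp3", "species", "M", 8, c(3L, 7L), "admixed"),
    tx("C_sp4", "species", "P", 8, c(4L, 3L), "admixed"),
    tx("C_pannosus", "species", "P", 8, 7L, "admixed"),
    tx("C_lacteus", "species", "P", 9, c(7L, 3L, 4L), "admixed")))
}

## populations: id, taxon, nuclear backbone clade (full tree), plastid clade
fixture_populations <- function() {
  p <- function(taxon, n, nuclear, plastid) {
    data.frame(population = sprintf("%s_p%d", taxon, seq_len(n)),
               taxon = taxon, nuclear = nuclear,
               plastid = rep_len(plastid, n), stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    # nuclear clade NA: 8 populations, 5 with discordant plastid placement
    p("C_conspicuus", 1, "NA", "PC"),
    p("C_sherriffii", 1, "NA", "PA"),
    p("C_microphyllus", 1, "NA", "PA"),
    p("C_rockii", 1, "NA", "PC"),
    p("C_sp1", 1, "NA", "PC"),
    p("C_insolitus", 1, "NA", "PC"),
    p("C_buxifolius_vellaeus", 1, "NA", "PA"),
    p("C_marginatus", 1, "NA", "PB"),
    # nuclear clade NB: 17 populations, 9 discordant (2 in PA, 7 in PC)
    p("C_buxifolius", 2, "NB", "PC"),
    p("C_lidjiangensis", 1, "NB", "PC"),
    p("C_argenteus", 1, "NB", "PC"),
    p("C_serotinus", 1, "NB", "PC"),
    p("C_sp2", 2, "NB", "PC"),
    p("C_cochleatus", 1, "NB", "PA"),
    p("C_dammeri", 1, "NB", "PA"),
    p("C_glaucophyllus", 2, "NB", "PB"),
    p("C_meiophyllus", 2, "NB", "PB"),
    p("C_dammeri_songmingensis", 1, "NB", "PB"),
    p("C_morrisonensis", 2, "NB", "PB"),
    p("C_salicifolius", 1, "NB", "PB"),
    # nuclear clade NC: 18 populations, 4 discordant (in PB)
    p("C_sp4", 1, "NC", "PB"),
    p("C_sp3", 1, "NC", "PB"),
    p("C_brickellii", 1, "NC", "PB"),
    p("C_pannosus", 2, "NC", c("PB", "PC")),
    p("C_turbinatus", 2, "NC", "PC"),
    p("C_coriaceus", 2, "NC", "PC"),
    p("C_lacteus", 5, "NC", "PC"),
    p("C_fulvidus", 2, "NC", "PC"),
    p("C_delavayanus", 2, "NC", "PC")))
}

## K=19 assignment: dominant pool per taxon, admixed flag, per-pool novelty.
## Pools 1-5 are the five shared pairs; 6-12 are the novel split-off pools;
## 13-19 continue K=9 pools or hold the remaining singletons.
fixture_k19 <- function() {
  a <- function(taxon, pool, admixed = FALSE, minors = integer(0)) {
    data.frame(taxon = taxon, pool = pool, admixed = admixed,
               minors = I(list(minors)), stringsAsFactors = FALSE)
  }
  assignments <- do.call(rbind, list(
    a("C_conspicuus", 1), a("C_sherriffii", 1),
    a("C_dammeri", 2), a("C_dammeri_songmingensis", 2),
    a("C_morrisonensis", 3), a("C_cochleatus", 3),
    a("C_buxifolius", 4), a("C_lidjiangensis", 4),
    a("C_serotinus", 5), a("C_sp2", 5),
    a("C_microphyllus", 6), a("C_rockii", 7),
    a("C_sp1", 8, admixed = TRUE, minors = c(7L, 1L)),
    a("C_salicifolius", 9), a("C_meiophyllus", 10), a("C_argenteus", 11),
    a("C_coriaceus", 12),
    a("C_glaucophyllus", 13), a("C_fulvidus", 14), a("C_delavayanus", 15),
    a("C_brickellii", 16), a("C_turbinatus", 17),
    a("C_sp3", 18), a("C_sp4", 19),
    a("C_marginatus", 1, admixed = TRUE, minors = c(7L, 3L)),
    a("C_insolitus", 1, admixed = TRUE, minors = c(8L, 7L)),
    a("C_pannosus", 16, admixed = TRUE, minors = 15L),
    a("C_lacteus", 17, admixed = TRUE, minors = c(12L, 15L)),
    a("C_buxifolius_vellaeus", 15, admixed = TRUE, minors = c(7L, 1L))))
  list(assignments = assignments, novel_pools = 6:12)
}

## per-taxon stem supports in the full nuclear tree; the two taxa whose
## populations fail to form exclusive clades are marked non-monophyletic,
## as is the species pair that never separates
fixture_monophyly <- function() {
  taxa <- fixture_taxa()$taxon
  mono <- data.frame(taxon = taxa, monophyletic = TRUE, sh_alrt = 99,
                     ufboot = 100, stringsAsFactors = FALSE)
  mono[mono$taxon == "C_fulvidus", c("sh_alrt", "ufboot")] <- c(100, 100)
  mono$monophyletic[mono$taxon %in%
                      c("C_pannosus", "C_buxifolius",
                        "C_lidjiangensis")] <- FALSE
  mono$sh_alrt[!mono$monophyletic] <- NA
  mono$ufboot[!mono$monophyletic] <- NA
  mono
}

## rebuilt (hybrid-free) backbone clades: three clades over the pure taxa
fixture_rebuilt_clades <- function() {
  c(C_conspicuus = "NA", C_sherriffii = "NA", C_microphyllus = "NA",
    C_salicifolius = "NB", C_glaucophyllus = "NB", C_dammeri = "NB",
    C_dammeri_songmingensis = "NB",
    C_brickellii = "NC", C_turbinatus = "NC", C_coriaceus = "NC",
    C_rockii = "NC", C_sp1 = "NC", C_delavayanus = "NC",
    C_serotinus = "NC", C_fulvidus = "NC")
}

profile_from_spec <- function(dominant, minors, share, K) {
  q <- numeric(K)
  if (length(minors) > 0) {
    q[minors] <- (1 - share) * 0.85 / length(minors)
    rest <- setdiff(seq_len(K), c(dominant, minors))
    q[rest] <- (1 - share) * 0.15 / length(rest)
  } else {
    rest <- setdiff(seq_len(K), dominant)
    q[rest] <- (1 - share) / length(rest)
  }
  q[dominant] <- share
  q / sum(q)
}

#' Machine fixture of the study's published per-taxon evidence
#'
#' Encodes the 29 sampled taxa (27 species plus two infraspecific taxa) and
#' 43 populations: K=9 ancestry profiles built from each taxon's described
#' pool composition, the K=19 assignment table (five shared pools, seven
#' novel split-off pools, five still-admixed species), nuclear and plastid
#' backbone-clade labels per population, per-taxon stem supports, the
#' hybrid-free rebuilt clade structure over the 20 retained populations,
#' and a minimal diagnosability trait table. Ancestry magnitudes are
#' stand-ins constrained by the published bounds; `jitter` perturbs them
#' uniformly within those bounds to check that downstream counts do not
#' depend on the choice.
#'
#' @param jitter Half-width of a uniform perturbation of the dominant
#'   shares (default 0; values are clamped to the published bounds).
#' @param seed Seed for the jitter draw.
#' @return A list with `q9` (ancestry profiles as an [ancestry_matrix()]
#'   over one representative sample per population), `taxa`, `map`,
#'   `nuclear_clades`, `plastid_clades`, `rebuilt_clades` (over retained
#'   populations), `retained_populations`, `k19`, `monophyly` and `traits`.
#' @export
paper_fixture <- function(jitter = 0, seed = 1) {
  taxa <- fixture_taxa()
  pops <- fixture_populations()
  set.seed(seed)
  share_of <- c(pure = 0.97, subthreshold = 0.72, admixed = 0.60)
  lo <- c(pure = 0.9501, subthreshold = 0.7001, admixed = 0.50)
  hi <- c(pure = 0.999, subthreshold = 0.9499, admixed = 0.6999)
  shares <- share_of[taxa$class] +
    stats::runif(nrow(taxa), -jitter, jitter)
  shares <- pmin(pmax(shares, lo[taxa$class]), hi[taxa$class])
  prof9 <- t(vapply(seq_len(nrow(taxa)), function(i)
    profile_from_spec(taxa$dominant[i], taxa$minors[[i]], shares[i], 9),
    numeric(9)))
  rownames(prof9) <- taxa$taxon

  # one representative accession per population
  q_rows <- prof9[pops$taxon, , drop = FALSE]
  samples <- pops$population
  q9 <- ancestry_matrix(q_rows, samples, meta = list(K = 9, seed = seed))
  map <- sample_map(samples, pops$population, pops$taxon,
                    rank = taxa$rank[match(pops$taxon, taxa$taxon)],
                    series = taxa$series[match(pops$taxon, taxa$taxon)])

  nuclear_clades <- clade_map(pops$population, pops$nuclear)
  plastid_clades <- clade_map(pops$population, pops$plastid)

  # hybrid-free rebuild: one retained population per pure-taxon population
  rebuilt <- fixture_rebuilt_clades()
  retained <- pops$population[pops$taxon %in% names(rebuilt)]
  rebuilt_clades <- clade_map(retained,
                              unname(rebuilt[pops$taxon[match(
                                retained, pops$population)]]))

  # K=19 profiles from the assignment table, same magnitude conventions
  k19 <- fixture_k19()
  sh19 <- ifelse(k19$assignments$admixed, share_of["admixed"],
                 share_of["pure"]) +
    stats::runif(nrow(k19$assignments), -jitter, jitter)
  cls19 <- ifelse(k19$assignments$admixed, "admixed", "pure")
  sh19 <- pmin(pmax(sh19, lo[cls19]), hi[cls19])
  prof19 <- t(vapply(seq_len(nrow(k19$assignments)), function(i)
    profile_from_spec(k19$assignments$pool[i],
                      k19$assignments$minors[[i]], sh19[i], 19),
    numeric(19)))
  rownames(prof19) <- k19$assignments$taxon

  # minimal diagnosability layer: two qualitative traits, one state pair
  # per taxon; the described indistinguishable pairs share states
  n_tax <- nrow(taxa)
  state <- seq_len(n_tax)
  names(state) <- taxa$taxon
  state["C_lidjiangensis"] <- state["C_buxifolius"]
  state["C_dammeri_songmingensis"] <- state["C_dammeri"]
  tvals <- cbind(indumentum = unname(state), leaf_apex = unname(state))
  rownames(tvals) <- taxa$taxon
  traits <- trait_table(tvals, taxa$taxon,
                        kinds = c("qualitative", "qualitative"))

  list(q9 = q9, taxa = taxa, map = map, profiles9 = prof9,
       nuclear_clades = nuclear_clades, plastid_clades = plastid_clades,
       rebuilt_clades = rebuilt_clades, retained_populations = retained,
       k19 = list(profiles = prof19, assignments = k19$assignments,
                  novel_pools = k19$novel_pools),
       monophyly = fixture_monophyly(), traits = traits)
}

#' Summary counts from the paper fixture
#'
#' Runs the package's classifiers over a [paper_fixture()] and returns the
#' headline counts: species-rank taxa in a single gene pool (including the
#' subthreshold-override case, which must additionally show supported
#' monophyly and diagnosability), admixed species, distinct gene pools among
#' the single-pool taxa, cytonuclear-discordant populations and species,
#' persistent discordances after hybrid removal, and the K=19 shared-pair /
#' still-admixed / novel-singleton-pool counts.
#'
#' @param fx A [paper_fixture()].
#' @param config A [delim_config()].
#' @return A named list of counts.
#' @export
fixture_summary <- function(fx, config = delim_config()) {
  taxa <- fx$taxa
  prof <- fx$profiles9
  calls <- lapply(taxa$taxon, function(t)
    classify_purity(prof[t, ], config$pure_threshold, config$override_floor,
                    config$minor_threshold, taxon = t))
  names(calls) <- taxa$taxon
  cls <- vapply(calls, function(x) x$class, character(1))
  mono <- fx$monophyly
  mono_pass <- !is.na(mono$sh_alrt) & !is.na(mono$ufboot) &
    mono$monophyletic & mono$sh_alrt >= config$sh_min &
    mono$ufboot >= config$uf_min
  names(mono_pass) <- mono$taxon

  # the override path: subthreshold + supported monophyly + diagnosable
  # against every shared-pool partner (vacuous with none)
  pairs9 <- shared_pool_pairs(calls)
  partners_of <- function(t)
    unique(c(pairs9$taxon_b[pairs9$taxon_a == t],
             pairs9$taxon_a[pairs9$taxon_b == t]))
  diagnosable <- vapply(taxa$taxon, function(t) {
    ps <- partners_of(t)
    if (length(ps) == 0) return(TRUE)
    all(vapply(ps, function(o)
      count_diagnostic_traits(fx$traits, t, o,
                              config$min_traits)$diagnosable, logical(1)))
  }, logical(1))
  single_pool <- cls == "PURE" |
    (cls == "SUBTHRESHOLD" & mono_pass[taxa$taxon] & diagnosable)
  sp <- taxa$rank == "species"

  disc <- detect_cytonuclear_discordance(fx$nuclear_clades,
                                         fx$plastid_clades, fx$map)
  keep <- fx$retained_populations
  disc_rebuilt <- detect_cytonuclear_discordance(
    fx$rebuilt_clades,
    fx$plastid_clades[fx$plastid_clades$population %in% keep, ],
    fx$map)

  k19 <- fx$k19
  calls19 <- lapply(k19$assignments$taxon, function(t)
    classify_purity(k19$profiles[t, ], config$pure_threshold,
                    config$override_floor, config$minor_threshold,
                    taxon = t))
  pairs19 <- shared_pool_pairs(calls19)
  dom19 <- vapply(calls19, function(x) x$dominant, numeric(1))
  holders <- table(dom19)
  novel_singletons <- sum(k19$novel_pools %in%
                            as.integer(names(holders)[holders == 1]))
  rank19 <- taxa$rank[match(k19$assignments$taxon, taxa$taxon)]
  adm19 <- vapply(calls19, function(x) x$class == "ADMIXED", logical(1))

  pools <- unique(vapply(calls[single_pool], function(x) x$dominant,
                         numeric(1)))
  list(
    pure_species = sum(single_pool & sp),
    admixed_species = sum(cls == "ADMIXED" & sp),
    gene_pools = length(pools),
    discordant_populations = disc$n_discordant_populations,
    discordant_species = disc$n_discordant_species,
    persistent_discordances = disc_rebuilt$n_discordant_species,
    k19_shared_pairs = nrow(pairs19),
    k19_still_admixed = sum(adm19 & rank19 == "species"),
    k19_novel_pools = novel_singletons)
}
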