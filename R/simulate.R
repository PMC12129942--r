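#' Specify a synthetic delimitation scenario
#'
#' Describes K ancestral gene pools with drift-divergent allele frequencies
#' (Balding-Nichols construction, divergence parameter `F`), taxa that are
#' pure (one pool) or admixed (arbitrary ancestry vectors), per-population
#' maternal pools with optional plastid-capture overrides, and a trait
#' layer with specified between-taxon effects and within-taxon noise.
#'
#' @param K Number of ancestral pools.
#' @param F Divergence parameter in (0, 1) (plays the role of Fst between
#'   each pool and the ancestral frequency pool).
#' @param taxa Data frame with columns `taxon`, `rank`, `n_pops`,
#'   `samples_per_pop`, and a `q` list-column of true ancestry vectors
#'   (length K, summing to 1). Build with [scenario_taxa()].
#' @param sites Number of biallelic sites.
#' @param trait_means Matrix (taxa x quantitative traits) of per-taxon
#'   trait means; rownames must match `taxa$taxon`.
#' @param trait_sd Within-taxon standard deviation (recycled per trait).
#' @param qual_states Matrix (taxa x qualitative traits) of integer states.
#' @param maternal_pool Named integer vector: taxon -> maternal pool index
#'   (defaults to each taxon's dominant pool). Plastid capture is planted
#'   by pointing a taxon at a different pool.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A list of class `scenario`.
#' @export
scenario <- function(K, F, taxa, sites = 2000, trait_means = NULL,
                     trait_sd = 1, qual_states = NULL, maternal_pool = NULL,
                     seed = 1) {
  assert_that(F > 0 && F < 1, "F must be in (0, 1)")
  assert_that(all(c("taxon", "rank", "n_pops", "samples_per_pop") %in%
                    names(taxa)), "taxa must be a scenario_taxa frame")
  assert_that(all(taxa$n_pops >= 1) && all(taxa$samples_per_pop >= 1),
              "nonpositive population/sample counts")
  for (q in taxa$q) {
    assert_that(length(q) == K && abs(sum(q) - 1) <= 1e-8,
                "taxon q vectors must have length K and sum to 1")
  }
  dominant <- vapply(taxa$q, which.max, numeric(1))
  if (is.null(maternal_pool)) {
    maternal_pool <- stats::setNames(dominant, taxa$taxon)
  }
  assert_that(all(maternal_pool >= 1 & maternal_pool <= K),
              "maternal pool override references a nonexistent pool")
  structure(list(K = K, F = F, taxa = taxa, sites = sites,
                 trait_means = trait_means, trait_sd = trait_sd,
                 qual_states = qual_states, maternal_pool = maternal_pool,
                 seed = seed),
            class = "scenario")
}

#' Build the taxa frame for a [scenario()]
#'
#' @param taxon Character taxon ids.
#' @param q List of true ancestry vectors.
#' @param n_pops,samples_per_pop Integers, recycled.
#' @param rank Character, recycled (default `"species"`).
#' @return A data frame with a `q` list-column.
#' @export
scenario_taxa <- function(taxon, q, n_pops = 2, samples_per_pop = 6,
                          rank = "species") {
  out <- data.frame(taxon = taxon,
                    rank = rep_len(rank, length(taxon)),
                    n_pops = rep_len(n_pops, length(taxon)),
                    samples_per_pop = rep_len(samples_per_pop,
                                              length(taxon)),
                    stringsAsFactors = FALSE)
  out$q <- q
  out
}

#' A standard pure-pools-plus-hybrids scenario
#'
#' Convenience builder used across the test suite and the analysis
#' scripts: one pure taxon per pool, plus `n_hybrids` admixed taxa mixing
#' two consecutive pools 55:45, with plastid capture planted so each
#' hybrid's maternal pool is its minor parent. Quantitative trait means
#' separate pure taxa by `effect` within-taxon SDs on every trait, hybrids
#' sitting midway; hybrids inherit the qualitative states of their major
#' parent.
#'
#' @param n_pools Number of gene pools (pure taxa).
#' @param n_hybrids Number of planted hybrid taxa (0-3).
#' @param F Divergence parameter.
#' @param sites Number of sites.
#' @param n_pops,samples_per_pop Per-taxon sampling design.
#' @param effect Between-taxon trait effect in within-taxon SDs.
#' @param seed Integer seed.
#' @return A [scenario()].
#' @export
standard_scenario <- function(n_pools = 3, n_hybrids = 1, F = 0.2,
                              sites = 2000, n_pops = 2, samples_per_pop = 6,
                              effect = 4, seed = 1) {
  pure_names <- paste0("taxon_P", seq_len(n_pools))
  hyb_names <- if (n_hybrids > 0) paste0("taxon_H", seq_len(n_hybrids))
  else character(0)
  qs <- c(lapply(seq_len(n_pools), function(k) {
    q <- rep(0, n_pools)
    q[k] <- 1
    q
  }),
  lapply(seq_len(n_hybrids), function(h) {
    a <- ((h - 1) %% n_pools) + 1
    b <- (h %% n_pools) + 1
    q <- rep(0, n_pools)
    q[a] <- 0.55
    q[b] <- 0.45
    q
  }))
  taxa <- scenario_taxa(c(pure_names, hyb_names), qs, n_pops = n_pops,
                        samples_per_pop = samples_per_pop)
  n_taxa <- nrow(taxa)
  # two quantitative traits separated by `effect` SDs between pure taxa;
  # hybrids midway between their parents
  tm <- matrix(0, n_taxa, 2,
               dimnames = list(taxa$taxon, c("leaf_length", "leaf_width")))
  for (i in seq_len(n_pools)) tm[i, ] <- effect * i
  if (n_hybrids > 0) {
    for (h in seq_len(n_hybrids)) {
      a <- ((h - 1) %% n_pools) + 1
      b <- (h %% n_pools) + 1
      tm[n_pools + h, ] <- effect * (a + b) / 2
    }
  }
  qs_states <- matrix(0L, n_taxa, 2,
                      dimnames = list(taxa$taxon,
                                      c("indumentum", "petal_color")))
  for (i in seq_len(n_pools)) qs_states[i, ] <- i
  if (n_hybrids > 0) {
    for (h in seq_len(n_hybrids)) {
      a <- ((h - 1) %% n_pools) + 1
      qs_states[n_pools + h, ] <- a  # major parent's states
    }
  }
  # plastid capture: hybrid maternal pool = minor parent
  maternal <- stats::setNames(vapply(qs, which.max, numeric(1)), taxa$taxon)
  if (n_hybrids > 0) {
    for (h in seq_len(n_hybrids)) {
      maternal[n_pools + h] <- (h %% n_pools) + 1
    }
  }
  scenario(K = n_pools, F = F, taxa = taxa, sites = sites,
           trait_means = tm, trait_sd = 1, qual_states = qs_states,
           maternal_pool = maternal, seed = seed)
}

#' Simulate genotypes, map, traits and plastid labels from a scenario
#'
#' Pool allele frequencies follow the Balding-Nichols construction:
#' ancestral `p0 ~ Uniform(0.05, 0.95)` per site, pool frequency
#' `p ~ Beta(p0 (1-F)/F, (1-p0)(1-F)/F)`. Genotypes are
#' `Binomial(2, sum_k q_ik p_kj)`. Quantitative traits are
#' `Normal(taxon mean, SD)` per specimen; qualitative states are fixed per
#' taxon. The plastid layer is emitted as a [clade_map()] of maternal-pool
#' labels (`"G<k>"`), so capture events planted in the scenario are
#' directly discordant with dominant nuclear ancestry.
#'
#' @param S A [scenario()].
#' @return A list with `genotypes`, `map`, `traits` (units = samples),
#'   `plastid` ([clade_map()] over populations), `truth` (per-taxon true Q,
#'   status and maternal pool; per-sample true Q) and `pool_freqs`.
#' @export
simulate_scenario <- function(S) {
  set.seed(S$seed)
  K <- S$K
  J <- S$sites
  p0 <- stats::runif(J, 0.05, 0.95)
  shape_scale <- (1 - S$F) / S$F
  P <- matrix(0, K, J)
  for (k in seq_len(K)) {
    P[k, ] <- stats::rbeta(J, p0 * shape_scale, (1 - p0) * shape_scale)
  }
  P <- pmin(pmax(P, 1e-4), 1 - 1e-4)

  samples <- character(0)
  pops <- character(0)
  taxa_of <- character(0)
  rank_of <- character(0)
  qrows <- list()
  pop_taxon <- character(0)
  pop_ids <- character(0)
  for (i in seq_len(nrow(S$taxa))) {
    t <- S$taxa$taxon[i]
    for (pp in seq_len(S$taxa$n_pops[i])) {
      pid <- sprintf("%s_pop%d", t, pp)
      pop_ids <- c(pop_ids, pid)
      pop_taxon <- c(pop_taxon, t)
      for (s in seq_len(S$taxa$samples_per_pop[i])) {
        samples <- c(samples, sprintf("%s_s%d", pid, s))
        pops <- c(pops, pid)
        taxa_of <- c(taxa_of, t)
        rank_of <- c(rank_of, S$taxa$rank[i])
        qrows[[length(qrows) + 1]] <- S$taxa$q[[i]]
      }
    }
  }
  Qtrue <- do.call(rbind, qrows)
  n <- length(samples)
  Fmat <- Qtrue %*% P
  dos <- matrix(stats::rbinom(n * J, 2, as.vector(Fmat)), n, J)
  sites <- data.frame(chrom = "chr1", pos = seq_len(J),
                      ref = "A", alt = "T", stringsAsFactors = FALSE)
  G <- genotype_matrix(dos, samples, sites)
  M <- sample_map(samples, pops, taxa_of, rank = rank_of)

  # traits per specimen
  traits <- NULL
  if (!is.null(S$trait_means)) {
    tm <- S$trait_means[taxa_of, , drop = FALSE]
    sd_vec <- rep_len(S$trait_sd, ncol(tm))
    quant <- tm + matrix(stats::rnorm(n * ncol(tm)), n) %*% diag(sd_vec,
                                                                 ncol(tm))
    vals <- quant
    kinds <- rep("quantitative", ncol(tm))
    if (!is.null(S$qual_states)) {
      qual <- S$qual_states[taxa_of, , drop = FALSE]
      vals <- cbind(quant, qual)
      kinds <- c(kinds, rep("qualitative", ncol(qual)))
    }
    colnames(vals) <- c(colnames(S$trait_means), colnames(S$qual_states))
    traits <- trait_table(vals, samples, kinds)
  }

  maternal <- S$maternal_pool[pop_taxon]
  plastid <- clade_map(pop_ids, paste0("G", maternal))

  status <- ifelse(vapply(S$taxa$q, max, numeric(1)) >= 0.95, "pure",
                   "admixed")
  truth <- list(
    taxa = data.frame(taxon = S$taxa$taxon, rank = S$taxa$rank,
                      status = status,
                      dominant_pool = vapply(S$taxa$q, which.max,
                                             numeric(1)),
                      maternal_pool = unname(S$maternal_pool[S$taxa$taxon]),
                      stringsAsFactors = FALSE),
    sample_q = Qtrue)
  list(genotypes = G, map = M, traits = traits, plastid = plastid,
       truth = truth, pool_freqs = P)
}
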