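#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ ([ape::nj()]) with negative branch lengths clamped to zero.
#' Supports are absent; use [bootstrap_supports()] to annotate them.
#'
#' @param D Symmetric distance matrix with unit labels (or `dist`).
#' @return A [support_tree()] with absent supports.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  assert_that(all(is.finite(D)), "non-finite distances")
  assert_that(nrow(D) >= 3, "need at least 3 units")
  phy <- ape::nj(stats::as.dist(D))
  phy$edge.length[phy$edge.length < 0] <- 0
  support_tree(phy)
}

## allele-sharing distance between rows of a dosage matrix: mean |g_i - g_j|/2
## over pairwise non-missing sites
dosage_dist <- function(d) {
  n <- nrow(d)
  D <- matrix(0, n, n, dimnames = list(rownames(d), rownames(d)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(d[i, ]) & !is.na(d[j, ])
      D[i, j] <- D[j, i] <- if (any(ok))
        mean(abs(d[i, ok] - d[j, ok])) / 2 else 0.5
    }
  }
  D
}

#' Site-resampled bootstrap supports for a distance + NJ tree
#'
#' Builds the point tree by NJ on allele-sharing distances, then resamples
#' sites with replacement `n_reps` times, rebuilds the tree, and annotates
#' every internal bipartition of the point tree with the percentage of
#' replicates recovering it. Both support slots (SH-aLRT, UFboot) receive
#' the bootstrap percentage — a documented convention for synthetic trees,
#' where no likelihood-based SH-aLRT exists.
#'
#' @param G A [genotype_matrix()] with at least 4 samples (or groups).
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer RNG seed (fixed seed gives bit-identical supports).
#' @param groups Optional named character vector mapping sample id to a
#'   group (e.g. population); dosages are averaged within groups and the
#'   tree is built over groups.
#' @return A [support_tree()].
#' @export
bootstrap_supports <- function(G, n_reps = 100, seed = 1, groups = NULL) {
  assert_that(n_reps >= 1, "n_reps must be >= 1")
  d <- G$dosages
  if (!is.null(groups)) {
    assert_that(all(G$samples %in% names(groups)),
                "groups must cover all samples")
    glev <- unique(unname(groups[G$samples]))
    d <- t(vapply(glev, function(g)
      colMeans(d[groups[G$samples] == g, , drop = FALSE], na.rm = TRUE),
      numeric(ncol(d))))
    rownames(d) <- glev
  } else {
    rownames(d) <- G$samples
  }
  d[is.nan(d)] <- NA
  assert_that(nrow(d) >= 4, "need at least 4 samples/groups")
  point <- nj_tree(dosage_dist(d))
  phy <- point$phy
  labels <- phy$tip.label
  sets <- clade_tip_sets(phy)
  ntip <- length(labels)
  keys <- vapply(seq_along(sets), function(i) {
    # map node clade (indices into phy tips) to a canonical bipartition key
    bipartition_key(sets[[i]], labels)
  }, character(1))
  counts <- stats::setNames(rep(0, length(keys)), NULL)
  set.seed(seed)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(ncol(d), replace = TRUE)
    rep_phy <- ape::nj(stats::as.dist(dosage_dist(d[, cols, drop = FALSE])))
    rep_sets <- clade_tip_sets(rep_phy)
    # replicate tip order may differ: map indices through labels
    rel <- match(rep_phy$tip.label, labels)
    rep_keys <- vapply(rep_sets, function(s)
      bipartition_key(sort(rel[s]), labels), character(1))
    counts <- counts + (keys %in% rep_keys)
  }
  pct <- 100 * counts / n_reps
  # the root "clade" is the full tip set, not a real bipartition
  full <- vapply(sets, function(s) length(s) == ntip, logical(1))
  pct[full] <- NA_real_
  support_tree(phy, sh_alrt = pct, ufboot = pct)
}

#' Assess monophyly of a leaf set with support thresholds
#'
#' Bipartition (unrooted) semantics: the target set is monophyletic iff it
#' or its complement equals one side of some bipartition of the tree. Stem
#' supports are read from that bipartition's edge; the result passes the
#' thresholds iff it is monophyletic and both supports are present and meet
#' their minima (absent support fails closed). A singleton target is
#' trivially monophyletic with no stem supports; it passes only when
#' `waive_singletons = TRUE` (the default, since single-population taxa
#' cannot carry stem support).
#'
#' @param st A [support_tree()].
#' @param leaves Character target leaf set.
#' @param sh_min Minimum SH-aLRT percent (default 80).
#' @param uf_min Minimum UFboot percent (default 95).
#' @param waive_singletons Pass singleton (and full-set) targets without
#'   support evidence (default TRUE).
#' @return A list of class `monophyly_result`: `leaves`,
#'   `is_monophyletic`, `sh_alrt`, `ufboot`, `passes_thresholds`.
#' @export
assess_monophyly <- function(st, leaves, sh_min = 80, uf_min = 95,
                             waive_singletons = TRUE) {
  phy <- st$phy
  tips <- phy$tip.label
  unknown <- setdiff(leaves, tips)
  assert_that(length(unknown) == 0, "unknown leaf: %s",
              paste(unknown, collapse = ", "))
  target <- sort(match(unique(leaves), tips))
  ntip <- length(tips)
  res <- function(mono, sh = NA_real_, uf = NA_real_, passes) {
    structure(list(leaves = tips[target], is_monophyletic = mono,
                   sh_alrt = sh, ufboot = uf, passes_thresholds = passes),
              class = "monophyly_result")
  }
  if (length(target) <= 1 || length(target) == ntip)
    return(res(TRUE, passes = waive_singletons))
  sets <- clade_tip_sets(phy)
  comp <- setdiff(seq_len(ntip), target)
  hit <- NA_integer_
  for (i in seq_along(sets)) {
    s <- sets[[i]]
    if (length(s) == ntip) next  # root: not a bipartition
    if (identical(s, target) || identical(s, comp)) {
      # prefer a labeled node when the bipartition is represented twice
      # (both children of a binary root)
      if (is.na(hit) || !is.na(st$sh_alrt[i]) || !is.na(st$ufboot[i]))
        hit <- i
    }
  }
  if (is.na(hit)) return(res(FALSE, passes = FALSE))
  sh <- st$sh_alrt[hit]
  uf <- st$ufboot[hit]
  passes <- !is.na(sh) && !is.na(uf) && sh >= sh_min && uf >= uf_min
  res(TRUE, sh, uf, passes)
}

#' @export
print.monophyly_result <- function(x, ...) {
  cat(sprintf("<monophyly> {%s}: %s (SH-aLRT %s, UFboot %s) %s\n",
              paste(x$leaves, collapse = ","),
              if (x$is_monophyletic) "monophyletic" else "not monophyletic",
              format(x$sh_alrt), format(x$ufboot),
              if (x$passes_thresholds) "PASS" else "fail"))
  invisible(x)
}

#' Assign backbone clades from exemplar leaves
#'
#' Each backbone clade is the smallest bipartition side containing all
#' exemplars of its label and no exemplar of another label; every leaf
#' falling in exactly one backbone clade gets that label, leaves outside
#' all clades are unassigned, and a leaf inside several (possible with
#' complementary-overlapping sides) is assigned to the smallest.
#'
#' @param st A [support_tree()].
#' @param seeds Named list: label -> character vector of exemplar leaves.
#'   Exemplar sets must be disjoint.
#' @return A [clade_map()] over the tree's leaves.
#' @export
assign_backbone_clades <- function(st, seeds) {
  phy <- st$phy
  tips <- phy$tip.label
  ntip <- length(tips)
  all_ex <- unlist(seeds)
  assert_that(!anyDuplicated(all_ex), "exemplar sets are not disjoint")
  assert_that(all(all_ex %in% tips), "unknown exemplar leaf: %s",
              paste(setdiff(all_ex, tips), collapse = ", "))
  sets <- clade_tip_sets(phy)
  # candidate sides: every clade and its complement, plus single leaves
  sides <- c(lapply(seq_len(ntip), identity),
             sets[vapply(sets, length, 1L) < ntip],
             lapply(sets[vapply(sets, length, 1L) < ntip],
                    function(s) setdiff(seq_len(ntip), s)))
  chosen <- list()
  for (lab in names(seeds)) {
    ex <- match(seeds[[lab]], tips)
    others <- match(setdiff(all_ex, seeds[[lab]]), tips)
    ok <- vapply(sides, function(s)
      all(ex %in% s) && !any(others %in% s), logical(1))
    if (!any(ok))
      stopf("exemplars of %s are not separable from other labels", lab)
    cand <- sides[ok]
    chosen[[lab]] <- cand[[which.min(vapply(cand, length, 1L))]]
  }
  assign <- rep(NA_character_, ntip)
  size <- rep(Inf, ntip)
  for (lab in names(chosen)) {
    s <- chosen[[lab]]
    better <- size[s] > length(s)
    assign[s][better] <- lab
    size[s][better] <- length(s)
  }
  clade_map(tips, assign)
}

#' Detect cytonuclear discordance between clade assignments
#'
#' Finds the nuclear-to-plastid clade-label correspondence maximizing the
#' number of concordant populations (optimal assignment on the label
#' confusion matrix), then flags every population whose plastid clade
#' differs from the image of its nuclear clade. A species is discordant
#' iff at least one of its populations is.
#'
#' @param nuclear,plastid [clade_map()] objects over the same populations
#'   (populations unassigned in either are excluded).
#' @param M A [sample_map()] providing population -> taxon.
#' @return A list of class `discordance_report`: `correspondence` (named
#'   character vector nuclear -> plastid), `populations` (per-population
#'   flags), `n_discordant_populations`, `n_discordant_species`,
#'   `discordant_species`.
#' @export
detect_cytonuclear_discordance <- function(nuclear, plastid, M) {
  tab <- merge(stats::setNames(nuclear, c("population", "nuclear")),
               stats::setNames(plastid, c("population", "plastid")),
               by = "population")
  tab <- tab[!is.na(tab$nuclear) & !is.na(tab$plastid), ]
  assert_that(nrow(tab) > 0, "no populations shared by the two clade maps")
  nl <- sort(unique(tab$nuclear))
  pl <- sort(unique(tab$plastid))
  conf <- table(factor(tab$nuclear, nl), factor(tab$plastid, pl))
  m <- max(length(nl), length(pl))
  cost <- matrix(0, m, m)
  cost[seq_along(nl), seq_along(pl)] <- -conf
  assign_col <- solve_assignment(cost)
  image <- rep(NA_character_, length(nl))
  for (i in seq_along(nl)) {
    j <- assign_col[i]
    if (j <= length(pl)) image[i] <- pl[j]
  }
  names(image) <- nl
  tab$discordant <- tab$plastid != unname(image[tab$nuclear])
  pop2tax <- unique(M[, c("population", "taxon")])
  tab$taxon <- pop2tax$taxon[match(tab$population, pop2tax$population)]
  disc_sp <- sort(unique(tab$taxon[tab$discordant & !is.na(tab$taxon)]))
  structure(list(correspondence = image, populations = tab,
                 n_discordant_populations = sum(tab$discordant),
                 n_discordant_species = length(disc_sp),
                 discordant_species = disc_sp),
            class = "discordance_report")
}

#' @export
print.discordance_report <- function(x, ...) {
  cat(sprintf("<discordance_report> %d discordant populations, %d species\n",
              x$n_discordant_populations, x$n_discordant_species))
  cat("correspondence:",
      paste(names(x$correspondence), x$correspondence, sep = "->",
            collapse = ", "), "\n")
  invisible(x)
}
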