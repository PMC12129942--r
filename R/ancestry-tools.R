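#' Align cluster labels between two ancestry matrices
#'
#' Model-based clustering is label-switching invariant; this finds the
#' permutation of `other`'s columns that maximizes the summed Pearson
#' correlation of matched column pairs (optimal assignment). When `other`
#' has more columns than `reference`, the unmatched columns keep their
#' original order after the matched ones.
#'
#' @param reference,other [ancestry_matrix()] objects over the same samples.
#' @return An integer permutation `perm` of `other`'s columns such that
#'   `other$q[, perm]` is aligned to `reference`.
#' @export
align_cluster_labels <- function(reference, other) {
  assert_that(identical(reference$samples, other$samples),
              "sample mismatch between ancestry matrices")
  kr <- reference$K
  ko <- other$K
  assert_that(ko >= kr, "other must have at least as many clusters")
  corr <- matrix(0, kr, ko)
  for (a in seq_len(kr)) {
    for (b in seq_len(ko)) {
      x <- reference$q[, a]
      y <- other$q[, b]
      corr[a, b] <- if (stats::sd(x) == 0 || stats::sd(y) == 0) 0 else
        stats::cor(x, y)
    }
  }
  # pad to square: virtual reference rows with 0 gain take the leftovers
  cost <- matrix(0, ko, ko)
  cost[seq_len(kr), ] <- -corr
  assign_col <- solve_assignment(cost)
  matched <- assign_col[seq_len(kr)]
  c(matched, setdiff(seq_len(ko), matched))
}

#' Per-taxon mean ancestry profiles
#'
#' Unweighted mean of member-sample ancestry vectors per taxon (or per
#' population then taxon when `by_population = TRUE`). Profiles sum to 1.
#' Taxa with zero samples in `Q` are excluded with a warning.
#'
#' @param Q An [ancestry_matrix()].
#' @param M A [sample_map()] covering all samples of `Q`.
#' @param by_population Average populations first, then taxa (default
#'   FALSE: plain mean over samples).
#' @return A matrix (taxa x K) of mean ancestry fractions.
#' @export
taxon_ancestry_profile <- function(Q, M, by_population = FALSE) {
  assert_that(all(Q$samples %in% M$sample), "samples missing from map")
  m <- M[match(Q$samples, M$sample), ]
  taxa <- unique(M$taxon)
  missing_taxa <- setdiff(taxa, m$taxon)
  if (length(missing_taxa) > 0)
    warnf("taxa with no samples excluded: %s",
          paste(missing_taxa, collapse = ", "))
  taxa <- intersect(taxa, m$taxon)
  prof <- matrix(0, length(taxa), Q$K, dimnames = list(taxa, NULL))
  for (t in taxa) {
    sel <- m$taxon == t
    if (by_population) {
      pops <- unique(m$population[sel])
      pop_means <- t(vapply(pops, function(p)
        colMeans(Q$q[sel & m$population == p, , drop = FALSE]),
        numeric(Q$K)))
      prof[t, ] <- colMeans(pop_means)
    } else {
      prof[t, ] <- colMeans(Q$q[sel, , drop = FALSE])
    }
  }
  prof
}

#' Classify a taxon's gene-pool purity
#'
#' The dominant pool is the one with maximal mean ancestry `q*`. The class
#' is `PURE` when `q* >= pure_threshold`, `SUBTHRESHOLD` when
#' `override_floor <= q* < pure_threshold` (the window in which strong
#' phylogenetic and morphological evidence may still validate the taxon),
#' and `ADMIXED` otherwise. Contributing pools are those with mean ancestry
#' at least `minor_threshold`, sorted by decreasing share.
#'
#' @param profile Numeric ancestry profile summing to 1.
#' @param pure_threshold Purity threshold (default 0.95).
#' @param override_floor Lower edge of the override window (default 0.70).
#' @param minor_threshold Floor for a pool to count as contributing
#'   (default 0.05).
#' @param taxon Optional taxon id carried through to the call.
#' @return An object of class `purity_call`: taxon, dominant pool index,
#'   `q_star`, class, and contributing pool indices.
#' @export
classify_purity <- function(profile, pure_threshold = 0.95,
                            override_floor = 0.70, minor_threshold = 0.05,
                            taxon = NA_character_) {
  assert_that(abs(sum(profile) - 1) <= 1e-6, "profile must sum to 1")
  q_star <- max(profile)
  dominant <- which.max(profile)
  class <- if (q_star >= pure_threshold) "PURE"
  else if (q_star >= override_floor) "SUBTHRESHOLD"
  else "ADMIXED"
  contributing <- order(profile, decreasing = TRUE)
  contributing <- contributing[profile[contributing] >= minor_threshold]
  structure(list(taxon = taxon, dominant = dominant, q_star = q_star,
                 class = class, contributing = contributing,
                 profile = profile),
            class = "purity_call")
}

#' @export
print.purity_call <- function(x, ...) {
  cat(sprintf("<purity_call> %s: %s (q* = %.3f, pool %d)\n",
              x$taxon, x$class, x$q_star, x$dominant))
  invisible(x)
}

#' Pairs of taxa sharing a dominant gene pool
#'
#' Unordered pairs of non-admixed taxa whose purity calls name the same
#' dominant pool; a group of m taxa sharing a pool yields choose(m, 2)
#' pairs.
#'
#' @param calls A list of [classify_purity()] results from one K run.
#' @return A data frame with columns `taxon_a`, `taxon_b`, `pool`.
#' @export
shared_pool_pairs <- function(calls) {
  keep <- vapply(calls, function(x) x$class != "ADMIXED", logical(1))
  calls <- calls[keep]
  pools <- vapply(calls, function(x) x$dominant, numeric(1))
  taxa <- vapply(calls, function(x) x$taxon, character(1))
  out <- list()
  for (p in unique(pools)) {
    members <- sort(taxa[pools == p])
    if (length(members) < 2) next
    cmb <- utils::combn(members, 2)
    out[[length(out) + 1]] <- data.frame(taxon_a = cmb[1, ],
                                         taxon_b = cmb[2, ], pool = p)
  }
  if (length(out) == 0)
    return(data.frame(taxon_a = character(0), taxon_b = character(0),
                      pool = numeric(0)))
  do.call(rbind, out)
}
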