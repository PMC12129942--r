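#' Gower distance for mixed trait tables
#'
#' Pairwise Gower dissimilarity over quantitative and qualitative traits.
#' A quantitative trait contributes `|x_i - x_j| / range` (range taken over
#' all units; a constant trait contributes 0); a qualitative trait
#' contributes 0 on state match, 1 on mismatch. The distance is the mean
#' contribution over traits observed in both units (pairwise deletion with
#' renormalization). A pair of units sharing no observed trait is an error.
#'
#' @param T A [trait_table()].
#' @return A symmetric matrix in `[0, 1]` with zero diagonal and unit labels
#'   as dimnames.
#' @export
gower_matrix <- function(T) {
  v <- T$values
  n <- nrow(v)
  assert_that(n >= 2, "need at least 2 units")
  seen <- colSums(!is.na(v))
  assert_that(all(seen >= 1), "trait %s has no observed values",
              colnames(v)[which(seen < 1)[1]])
  quant <- T$kinds == "quantitative"
  rng <- apply(v, 2, function(x) diff(range(x, na.rm = TRUE)))
  D <- matrix(0, n, n, dimnames = list(T$units, T$units))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- !is.na(v[i, ]) & !is.na(v[j, ])
      if (!any(shared))
        stopf("units %s and %s share no observed traits",
              T$units[i], T$units[j])
      contrib <- numeric(sum(shared))
      k <- 0
      for (t in which(shared)) {
        k <- k + 1
        if (quant[t]) {
          contrib[k] <- if (rng[t] > 0) abs(v[i, t] - v[j, t]) / rng[t] else 0
        } else {
          contrib[k] <- as.numeric(v[i, t] != v[j, t])
        }
      }
      D[i, j] <- D[j, i] <- mean(contrib)
    }
  }
  D
}

#' Average-linkage (UPGMA) clustering of a distance matrix
#'
#' Agglomerative clustering with size-weighted average linkage. Returned
#' merge heights follow the ultrametric-tree convention: a pair at distance
#' `d` merges at height `d/2`, so cophenetic distances on the tree equal the
#' linkage distances.
#'
#' @param D Symmetric distance matrix (or `dist`).
#' @return An `hclust` object with heights on the `d/2` scale.
#' @export
upgma_cluster <- function(D) {
  dd <- stats::as.dist(D)
  assert_that(all(is.finite(dd)) && all(dd >= 0), "invalid distance matrix")
  hc <- stats::hclust(dd, method = "average")
  hc$height <- hc$height / 2
  hc$method <- "upgma"
  hc
}

#' Export a UPGMA dendrogram as Newick with heights
#' @param hc An `hclust` from [upgma_cluster()].
#' @return A Newick string with branch lengths.
#' @export
upgma_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}

#' PCA of an integer-coded trait table
#'
#' Eigen-decomposition of the trait correlation matrix: all traits
#' (qualitative ones as their integer codes, the coding convention of the
#' source data) are centered and scaled to unit variance. Constant traits
#' are excluded with a warning. Missing values are mean-imputed before
#' scaling. The contribution of a trait to a component is its squared
#' loading as a percentage (columns sum to 100).
#'
#' @param T A [trait_table()].
#' @param coding Only `"integer_coded"` is implemented.
#' @return A list with `scores`, `varfrac` (variance fractions per PC) and
#'   `contributions` (traits x PCs, percent).
#' @export
trait_pca <- function(T, coding = "integer_coded") {
  assert_that(identical(coding, "integer_coded"),
              "only integer_coded PCA is implemented")
  v <- T$values
  for (t in seq_len(ncol(v))) {
    if (anyNA(v[, t])) v[is.na(v[, t]), t] <- mean(v[, t], na.rm = TRUE)
  }
  sds <- apply(v, 2, stats::sd)
  if (any(sds == 0)) {
    warnf("excluding constant trait(s): %s",
          paste(colnames(v)[sds == 0], collapse = ", "))
    v <- v[, sds > 0, drop = FALSE]
  }
  assert_that(ncol(v) >= 1, "no variable traits left")
  pc <- stats::prcomp(v, center = TRUE, scale. = TRUE)
  varfrac <- pc$sdev^2 / sum(pc$sdev^2)
  contrib <- 100 * sweep(pc$rotation^2, 2, colSums(pc$rotation^2), "/")
  list(scores = pc$x, varfrac = varfrac, contributions = contrib)
}

#' Count discontinuous (diagnostic) traits between two taxa
#'
#' A quantitative trait is discontinuous iff the observed `[min, max]`
#' intervals of the two taxa are disjoint (optionally requiring a gap of at
#' least `gap_fraction` of the trait's overall range); a qualitative trait
#' is discontinuous iff the observed state sets are disjoint. Traits
#' observed in only one taxon are excluded from the count. Two taxa are
#' "diagnosable" when at least `min_traits` traits are discontinuous.
#'
#' @param T A [trait_table()].
#' @param units_a,units_b Unit labels of the two taxa.
#' @param min_traits Diagnosability threshold (default 2).
#' @param gap_fraction Minimum gap between quantitative intervals as a
#'   fraction of the trait range (default 0 = strict disjointness).
#' @return A list with `count`, `diagnosable`, `verdicts` (per-trait data
#'   frame) and `excluded` (traits unobserved in one taxon).
#' @export
count_diagnostic_traits <- function(T, units_a, units_b, min_traits = 2,
                                    gap_fraction = 0) {
  assert_that(all(units_a %in% T$units) && all(units_b %in% T$units),
              "unknown unit labels")
  assert_that(length(intersect(units_a, units_b)) == 0,
              "taxa share units")
  va <- T$values[units_a, , drop = FALSE]
  vb <- T$values[units_b, , drop = FALSE]
  rng <- apply(T$values, 2, function(x)
    diff(range(x, na.rm = TRUE)))
  traits <- colnames(T$values)
  verdict <- rep(NA, length(traits))
  for (k in seq_along(traits)) {
    xa <- va[, k][!is.na(va[, k])]
    xb <- vb[, k][!is.na(vb[, k])]
    if (length(xa) == 0 || length(xb) == 0) next  # excluded
    if (T$kinds[k] == "quantitative") {
      gap <- max(min(xb) - max(xa), min(xa) - max(xb))
      verdict[k] <- gap > gap_fraction * rng[k] ||
        (gap_fraction == 0 && gap > 0)
    } else {
      verdict[k] <- length(intersect(xa, xb)) == 0
    }
  }
  excluded <- traits[is.na(verdict)]
  count <- sum(verdict, na.rm = TRUE)
  list(count = count, diagnosable = count >= min_traits,
       verdicts = data.frame(trait = traits, discontinuous = verdict),
       excluded = excluded)
}
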