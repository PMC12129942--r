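#' Site filtering on missingness, MAC and MAF
#'
#' Reproduces post-VCF SNP filtering: a site survives iff its missing-data
#' fraction is `<= max_missing`, its minor allele count is `>= min_mac` and
#' its minor allele frequency is `>= min_maf` (all boundaries inclusive).
#' Allele counts are taken over non-missing diploid genotypes; the minor
#' allele is the less frequent allele at that site. Sites with all genotypes
#' missing are removed and counted, not an error.
#'
#' @param G A [genotype_matrix()] of biallelic sites.
#' @param max_missing Maximum per-site missing fraction (default 0.15).
#' @param min_mac Minimum minor allele count (default 3).
#' @param min_maf Minimum minor allele frequency (default 0.05).
#' @return A list with elements `genotypes` (filtered [genotype_matrix()])
#'   and `report` (stage counts and thresholds).
#' @export
filter_sites <- function(G, max_missing = 0.15, min_mac = 3, min_maf = 0.05) {
  d <- G$dosages
  n <- nrow(d)
  n_obs <- colSums(!is.na(d))
  miss_frac <- 1 - n_obs / n
  alt <- colSums(d, na.rm = TRUE)
  total <- 2 * n_obs
  mac <- pmin(alt, total - alt)
  maf <- ifelse(total > 0, mac / total, 0)
  pass_miss <- n_obs > 0 & miss_frac <= max_missing
  pass_mac <- mac >= min_mac
  pass_maf <- maf >= min_maf
  keep <- pass_miss & pass_mac & pass_maf
  report <- filter_report(
    stages = data.frame(
      stage = c("input", "missingness", "mac", "maf"),
      sites = c(length(keep), sum(pass_miss), sum(pass_miss & pass_mac),
                sum(keep))),
    thresholds = list(max_missing = max_missing, min_mac = min_mac,
                      min_maf = min_maf))
  list(genotypes = subset_sites(G, which(keep)), report = report)
}

filter_report <- function(stages, thresholds) {
  assert_that(all(diff(stages$sites) <= 0),
              "stage counts must be non-increasing")
  structure(list(stages = stages, thresholds = thresholds),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n")
  print(x$stages, row.names = FALSE)
  invisible(x)
}

## r^2 between two dosage vectors on pairwise-complete observations;
## monomorphic (zero-variance) vectors give 0 by convention
dosage_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(0)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)^2
}

## greedy within-window pruning of a logical keep vector; sites are column
## indices into d (samples x sites). While any retained pair has r^2 >
## r2_max, drop the later site of the highest-r^2 pair; when several pairs
## tie for the maximum, the largest later-member index is dropped.
prune_window <- function(d, win_idx, keep, r2_max) {
  idx <- win_idx[keep[win_idx]]
  m <- length(idx)
  if (m < 2) return(keep)
  R2 <- matrix(0, m, m)
  for (a in 1:(m - 1)) {
    for (b in (a + 1):m) {
      R2[a, b] <- dosage_r2(d[, idx[a]], d[, idx[b]])
    }
  }
  alive <- rep(TRUE, m)
  repeat {
    cur <- R2
    cur[!alive, ] <- 0
    cur[, !alive] <- 0
    best <- max(cur)
    if (best <= r2_max) break
    tied <- which(cur >= best - 1e-12, arr.ind = TRUE)
    alive[max(tied[, 2])] <- FALSE
  }
  keep[idx[!alive]] <- FALSE
  keep
}

#' Sliding-window LD pruning
#'
#' PLINK-style pruning: windows of `window_sites` SNPs advanced in
#' `step_sites` increments along each chromosome (windows never span
#' chromosomes). Within a window, while any retained pair of sites has
#' squared Pearson correlation of dosages above `r2_max`, the later site of
#' the highest-r^2 pair is dropped (the larger index when several pairs
#' tie). Windows slide over the retained site list and sweeps repeat until
#' no window contains a violating pair, so the output satisfies the window
#' constraint directly. r^2 is composite LD on dosages; a monomorphic site
#' has r^2 = 0 with everything.
#'
#' @param G A [genotype_matrix()] with sites ordered by (chromosome,
#'   position).
#' @param window_sites Window size in SNPs (default 50).
#' @param step_sites Window step in SNPs (default 10).
#' @param r2_max Maximum tolerated r^2 (default 0.1).
#' @return A list with elements `genotypes` and `report`.
#' @export
ld_prune <- function(G, window_sites = 50, step_sites = 10, r2_max = 0.1) {
  assert_that(window_sites >= 2 && step_sites >= 1, "invalid window/step")
  d <- G$dosages
  keep <- rep(TRUE, n_sites(G))
  for (chr in unique(G$sites$chrom)) {
    chr_idx <- which(G$sites$chrom == chr)
    repeat {
      before <- sum(keep[chr_idx])
      alive <- chr_idx[keep[chr_idx]]
      n <- length(alive)
      if (n < 2) break
      for (s in seq(1, n, by = step_sites)) {
        win <- alive[s:min(s + window_sites - 1, n)]
        if (length(win) >= 2) keep <- prune_window(d, win, keep, r2_max)
        if (s + window_sites - 1 >= n) break
      }
      if (sum(keep[chr_idx]) == before) break
    }
  }
  report <- filter_report(
    stages = data.frame(stage = c("input", "ld_prune"),
                        sites = c(length(keep), sum(keep))),
    thresholds = list(window_sites = window_sites, step_sites = step_sites,
                      r2_max = r2_max))
  list(genotypes = subset_sites(G, which(keep)), report = report)
}

#' Genotype principal component analysis
#'
#' Missing dosages are mean-imputed per site; each site is centered at twice
#' its alternate-allele frequency and scaled by `sqrt(2 p (1 - p))`
#' (the standard normalization for dosage PCA). Monomorphic sites carry no
#' information under this scaling and are dropped. Scores are the projections
#' on sample-covariance eigenvectors, ordered by decreasing eigenvalue.
#'
#' @param G A [genotype_matrix()].
#' @param n_components Number of components to return.
#' @return A list with `scores` (samples x components), `varfrac` (variance
#'   fractions, non-increasing, summing to <= 1), and `p` (alt-allele
#'   frequencies used).
#' @export
genotype_pca <- function(G, n_components = 2) {
  assert_that(length(G$samples) >= 2, "need at least 2 samples")
  d <- G$dosages
  p <- colMeans(d, na.rm = TRUE) / 2
  poly <- which(is.finite(p) & p > 0 & p < 1)
  if (length(poly) == 0) stopf("no polymorphism")
  d <- d[, poly, drop = FALSE]
  p <- p[poly]
  X <- sweep(d, 2, 2 * p)
  X[is.na(X)] <- 0  # mean-imputation after centering
  X <- sweep(X, 2, sqrt(2 * p * (1 - p)), "/")
  sv <- svd(X)
  total_var <- sum(sv$d^2)
  if (total_var == 0) stopf("no polymorphism")
  k <- min(n_components, length(sv$d))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)],
                                                      nrow = k)
  rownames(scores) <- G$samples
  colnames(scores) <- paste0("PC", seq_len(k))
  list(scores = scores, varfrac = sv$d[seq_len(k)]^2 / total_var, p = p)
}
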