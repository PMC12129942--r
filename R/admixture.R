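#' Admixture-model ancestry estimation by EM
#'
#' Maximizes the standard admixture log-likelihood for unlinked biallelic
#' dosages: with `q_ik` the ancestry fraction of sample `i` in pool `k` and
#' `p_kj` the alternate-allele frequency of pool `k` at site `j`,
#'
#'   L = sum_ij [ g_ij log f_ij + (2 - g_ij) log(1 - f_ij) ],
#'   f_ij = sum_k q_ik p_kj,
#'
#' by plain EM (multiplicative updates on q and p). Missing dosages are
#' skipped in the likelihood and in all updates. The log-likelihood is
#' non-decreasing across iterations; iteration stops when the increase
#' drops below `tol * (|L| + 1)` or at `max_iter`.
#'
#' Initialization is seeded: q rows from a symmetric Dirichlet(1) draw, p
#' from global allele frequencies with a small uniform perturbation.
#'
#' @param G A [genotype_matrix()] with no all-missing sites.
#' @param K Number of ancestral pools (>= 1, <= number of samples).
#' @param seed Integer RNG seed.
#' @param max_iter Maximum EM iterations (default 2000).
#' @param tol Relative log-likelihood tolerance (default 1e-6).
#' @return A list with `Q` (an [ancestry_matrix()]), `P` (K x sites pool
#'   allele frequencies), and `loglik` (the per-iteration trace).
#' @export
em_admixture <- function(G, K, seed = 1, max_iter = 2000, tol = 1e-6) {
  d <- G$dosages
  n <- nrow(d)
  J <- ncol(d)
  assert_that(K >= 1, "K must be >= 1")
  assert_that(K <= n, "K (%d) exceeds sample count (%d)", K, n)
  assert_that(all(colSums(!is.na(d)) > 0), "all-missing site present")
  pbar <- colMeans(d, na.rm = TRUE) / 2

  if (K == 1) {
    # closed form: everyone fully in the single pool, p = observed freqs
    Q <- ancestry_matrix(matrix(1, n, 1), G$samples,
                         meta = list(seed = seed))
    P <- matrix(pmin(pmax(pbar, 1e-6), 1 - 1e-6), 1, J)
    ll <- admixture_loglik(d, matrix(1, n, 1), P)
    return(list(Q = Q, P = P, loglik = ll))
  }

  obs <- !is.na(d)
  g1 <- d
  g1[!obs] <- 0L
  storage.mode(g1) <- "double"
  g2 <- 2 - d
  g2[!obs] <- 0L
  storage.mode(g2) <- "double"
  denom_q <- 2 * rowSums(obs)

  withr_seed <- function(expr) { set.seed(seed); expr }
  init <- withr_seed({
    q <- matrix(stats::rexp(n * K), n, K)
    q <- q / rowSums(q)
    p <- matrix(rep(pbar, each = K), K, J) +
      matrix(stats::runif(K * J, -0.05, 0.05), K, J)
    list(q = q, p = pmin(pmax(p, 1e-4), 1 - 1e-4))
  })
  q <- init$q
  p <- init$p

  trace <- numeric(0)
  ll_prev <- -Inf
  for (it in seq_len(max_iter)) {
    f <- q %*% p
    f <- pmin(pmax(f, 1e-12), 1 - 1e-12)
    A <- g1 / f          # n x J, zero where missing
    B <- g2 / (1 - f)
    # E-step responsibilities folded into multiplicative M-step updates
    q_new <- q * (A %*% t(p) + B %*% t(1 - p))
    q_new <- q_new / denom_q
    q_new <- q_new / rowSums(q_new)  # guard tiny numeric drift
    num_p <- p * (t(q) %*% A)
    den_p <- num_p + (1 - p) * (t(q) %*% B)
    p_new <- ifelse(den_p > 0, num_p / den_p, p)
    p_new <- pmin(pmax(p_new, 1e-6), 1 - 1e-6)
    q <- q_new
    p <- p_new
    ll <- admixture_loglik(d, q, p)
    if (!is.finite(ll)) stopf("non-finite log-likelihood at iteration %d", it)
    trace <- c(trace, ll)
    if (it > 1 && (ll - ll_prev) < tol * (abs(ll) + 1)) break
    ll_prev <- ll
  }
  Q <- ancestry_matrix(q / rowSums(q), G$samples,
                       meta = list(seed = seed, iterations = length(trace)))
  list(Q = Q, P = p, loglik = trace)
}

admixture_loglik <- function(d, q, p) {
  f <- q %*% p
  f <- pmin(pmax(f, 1e-12), 1 - 1e-12)
  ll_mat <- d * log(f) + (2 - d) * log(1 - f)
  sum(ll_mat[!is.na(d)])
}

#' Choose K by masked cross-validation
#'
#' For each replicate, a random fraction of the non-missing dosages is
#' masked, the admixture model is fitted on the remainder, and the masked
#' entries are predicted as `2 * sum_k q_ik p_kj`. The error is the mean
#' squared deviation between masked dosages and predictions. Returns the
#' error grid and the K minimizing the mean error.
#'
#' @param G A [genotype_matrix()].
#' @param k_grid Integer vector of K values (non-empty).
#' @param replicates Replicates per K (default 3).
#' @param mask_fraction Fraction of non-missing entries to mask, in
#'   (0, 0.5) (default 0.1).
#' @param seed Integer RNG seed.
#' @param max_iter,tol Passed to [em_admixture()] for the masked fits.
#' @return A list with `grid` (data frame of K, replicate, cv_error),
#'   `summary` (mean error per K) and `best_k`.
#' @export
choose_k_cv <- function(G, k_grid, replicates = 3, mask_fraction = 0.1,
                        seed = 1, max_iter = 500, tol = 1e-5) {
  assert_that(length(k_grid) >= 1, "empty K grid")
  assert_that(mask_fraction > 0 && mask_fraction < 0.5,
              "mask_fraction must be in (0, 0.5)")
  d <- G$dosages
  obs_idx <- which(!is.na(d))
  rows <- list()
  for (r in seq_len(replicates)) {
    rep_seed <- stage_seed(seed, paste0("cv_mask_", r))
    set.seed(rep_seed)
    masked <- sample(obs_idx, ceiling(mask_fraction * length(obs_idx)))
    d_train <- d
    d_train[masked] <- NA
    # guard all-missing sites/samples created by masking
    empty_sites <- colSums(!is.na(d_train)) == 0
    if (any(empty_sites)) {
      unmask <- intersect(masked, which(!is.na(d))[col(d)[!is.na(d)] %in%
                                                     which(empty_sites)])
      d_train[unmask] <- d[unmask]
      masked <- setdiff(masked, unmask)
    }
    Gtrain <- G
    Gtrain$dosages <- d_train
    for (K in k_grid) {
      fit <- em_admixture(Gtrain, K,
                          seed = stage_seed(rep_seed, paste0("em_k", K)),
                          max_iter = max_iter, tol = tol)
      pred <- fit$Q$q %*% fit$P * 2
      err <- mean((d[masked] - pred[masked])^2)
      rows[[length(rows) + 1]] <- data.frame(K = K, replicate = r,
                                             cv_error = err)
    }
  }
  grid <- do.call(rbind, rows)
  summary <- stats::aggregate(cv_error ~ K, grid, mean)
  list(grid = grid, summary = summary,
       best_k = summary$K[which.min(summary$cv_error)])
}
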