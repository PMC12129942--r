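test_that("K = 1 has the closed-form solution", {
  g <- random_genotypes(10, 50, miss = 0.1, seed = 2)
  fit <- em_admixture(g, K = 1, seed = 1)
  expect_true(all(fit$Q$q == 1))
  pbar <- colMeans(g$dosages, na.rm = TRUE) / 2
  expect_equal(unname(fit$P[1, ]), unname(pmin(pmax(pbar, 1e-6), 1 - 1e-6)),
               tolerance = 1e-12)
})

test_that("EM log-likelihood is monotone and Q rows stay on the simplex", {
  sim <- simulate_scenario(standard_scenario(n_pools = 2, n_hybrids = 0,
                                             F = 0.2, sites = 300,
                                             samples_per_pop = 5, seed = 4))
  fit <- em_admixture(sim$genotypes, K = 2, seed = 9, max_iter = 300)
  expect_true(all(diff(fit$loglik) >= -1e-6))
  expect_equal(unname(rowSums(fit$Q$q)), rep(1, nrow(fit$Q$q)),
               tolerance = 1e-9)
  expect_true(all(fit$P > 0 & fit$P < 1))
})

test_that("EM recovers pure memberships on a divergent two-pool scenario", {
  sim <- simulate_scenario(standard_scenario(n_pools = 2, n_hybrids = 0,
                                             F = 0.2, sites = 2000,
                                             n_pops = 5,
                                             samples_per_pop = 10,
                                             seed = 6))
  fit <- em_admixture(sim$genotypes, K = 2, seed = 31)
  ref <- ancestry_matrix(sim$truth$sample_q, sim$genotypes$samples)
  perm <- align_cluster_labels(ref, fit$Q)
  rmse <- sqrt(mean((fit$Q$q[, perm] - sim$truth$sample_q)^2))
  expect_lt(rmse, 0.05)
})

test_that("K above the sample count is rejected", {
  g <- random_genotypes(5, 30, miss = 0, seed = 3)
  expect_error(em_admixture(g, K = 6), "exceeds")
})

test_that("masked cross-validation returns its grid and in-range predictions", {
  g <- random_genotypes(20, 200, miss = 0.05, seed = 12)
  cv <- choose_k_cv(g, k_grid = 1, replicates = 2, seed = 5)
  expect_equal(cv$best_k, 1)
  expect_equal(nrow(cv$grid), 2)
  expect_true(all(cv$grid$cv_error >= 0 & cv$grid$cv_error <= 4))
  expect_error(choose_k_cv(g, k_grid = integer(0)), "empty")
  expect_error(choose_k_cv(g, k_grid = 1, mask_fraction = 0.9), "mask")
})

test_that("label alignment inverts swaps and matches exhaustive search", {
  set.seed(19)
  q <- matrix(rexp(30 * 4), 30)
  q <- q / rowSums(q)
  ref <- ancestry_matrix(q, paste0("s", 1:30))
  sw <- c(3, 1, 4, 2)
  other <- ancestry_matrix(q[, sw], ref$samples)
  perm <- align_cluster_labels(ref, other)
  expect_equal(other$q[, perm], ref$q, ignore_attr = TRUE)
  expect_equal(align_cluster_labels(ref, ref), 1:4)

  for (trial in 1:10) {
    q2 <- matrix(rexp(30 * 4), 30)
    q2 <- q2 / rowSums(q2)
    other2 <- ancestry_matrix(q2, ref$samples)
    perm2 <- align_cluster_labels(ref, other2)
    gain <- outer(1:4, 1:4, Vectorize(function(a, b)
      cor(ref$q[, a], other2$q[, b])))
    best <- oracle_best_assignment(gain)
    got <- sum(gain[cbind(1:4, perm2)])
    expect_equal(got, best$value, tolerance = 1e-9)
  }
})

test_that("alignment rejects sample mismatches and handles extra clusters", {
  q <- matrix(0.5, 4, 2)
  ref <- ancestry_matrix(q, paste0("s", 1:4))
  other <- ancestry_matrix(q, paste0("x", 1:4))
  expect_error(align_cluster_labels(ref, other), "mismatch")

  set.seed(3)
  qr <- matrix(rexp(20 * 2), 20)
  qr <- qr / rowSums(qr)
  qo <- cbind(qr[, 2] * 0.9 + 0.05, matrix(rexp(20), 20), qr[, 1])
  qo <- qo / rowSums(qo)
  perm <- align_cluster_labels(ancestry_matrix(qr, paste0("s", 1:20)),
                               ancestry_matrix(qo, paste0("s", 1:20)))
  expect_equal(sort(perm), 1:3)
  expect_equal(perm[1:2], c(3, 1))
})

test_that("taxon profiles are means that are order-invariant", {
  q <- rbind(c(1, 0), c(0.9, 0.1), c(0.2, 0.8))
  Q <- ancestry_matrix(q, c("a1", "a2", "b1"))
  M <- sample_map(c("a1", "a2", "b1"), c("pA", "pA", "pB"),
                  c("taxA", "taxA", "taxB"))
  prof <- taxon_ancestry_profile(Q, M)
  expect_equal(unname(prof["taxA", ]), c(0.95, 0.05))
  expect_equal(unname(prof["taxB", ]), c(0.2, 0.8))
  expect_equal(rowSums(prof), c(taxA = 1, taxB = 1))

  perm <- c(3, 1, 2)
  Q2 <- ancestry_matrix(q[perm, ], c("a1", "a2", "b1")[perm])
  expect_equal(taxon_ancestry_profile(Q2, M), prof)
})

test_that("purity classes follow the threshold windows", {
  expect_equal(classify_purity(c(0.97, 0.02, 0.01))$class, "PURE")
  expect_equal(classify_purity(c(0.97, 0.02, 0.01))$dominant, 1)
  sub <- classify_purity(c(0.18, 0.72, 0.10))
  expect_equal(sub$class, "SUBTHRESHOLD")
  expect_equal(sub$dominant, 2)
  expect_equal(sub$contributing, c(2, 1, 3))
  expect_equal(classify_purity(1)$class, "PURE")
  expect_equal(classify_purity(c(0.6, 0.3, 0.1))$class, "ADMIXED")
  # boundary: exactly at the pure threshold counts as pure
  expect_equal(classify_purity(c(0.95, 0.05))$class, "PURE")
})

test_that("pool-label permutation permutes indices but never the class", {
  set.seed(55)
  for (trial in 1:20) {
    q <- rexp(5)
    q <- q / sum(q)
    perm <- sample(5)
    a <- classify_purity(q)
    b <- classify_purity(q[perm])
    expect_equal(a$class, b$class)
    expect_equal(perm[b$dominant], a$dominant)
  }
})

test_that("shared pools yield all unordered pairs per group", {
  call_of <- function(t, dom, cls = "PURE") {
    structure(list(taxon = t, dominant = dom, q_star = 0.97, class = cls,
                   contributing = dom), class = "purity_call")
  }
  calls <- list(call_of("a", 1), call_of("b", 1), call_of("c", 2))
  expect_equal(nrow(shared_pool_pairs(calls)), 1)
  calls3 <- list(call_of("a", 1), call_of("b", 1), call_of("c", 1))
  expect_equal(nrow(shared_pool_pairs(calls3)), 3)  # C(3,2)
  # admixed taxa never pair
  calls4 <- c(calls, list(call_of("d", 1, cls = "ADMIXED")))
  expect_equal(nrow(shared_pool_pairs(calls4)), 1)
})

test_that("the K=19 fixture reproduces the five published shared pairs", {
  fx <- paper_fixture()
  calls <- lapply(fx$k19$assignments$taxon, function(t)
    classify_purity(fx$k19$profiles[t, ], taxon = t))
  pairs <- shared_pool_pairs(calls)
  expect_equal(nrow(pairs), 5)
  key <- paste(pairs$taxon_a, pairs$taxon_b)
  expect_setequal(key, c("C_conspicuus C_sherriffii",
                         "C_dammeri C_dammeri_songmingensis",
                         "C_cochleatus C_morrisonensis",
                         "C_buxifolius C_lidjiangensis",
                         "C_serotinus C_sp2"))
})
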