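## Independent brute-force oracles used across the suite. These deliberately
## re-derive results by enumeration or direct formula application, never by
## calling the implementation they check.

# all bipartitions of a phylo tree as lists of leaf-label sets (both sides)
oracle_bipartitions <- function(phy) {
  ntip <- length(phy$tip.label)
  sets <- list()
  # descendant tips of every internal node by brute-force path walking
  for (node in (ntip + 1):(ntip + phy$Nnode)) {
    desc <- c()
    for (tip in seq_len(ntip)) {
      cur <- tip
      repeat {
        e <- which(phy$edge[, 2] == cur)
        if (length(e) == 0) break
        cur <- phy$edge[e, 1]
        if (cur == node) { desc <- c(desc, tip); break }
      }
    }
    if (length(desc) > 0 && length(desc) < ntip)
      sets[[length(sets) + 1]] <- sort(phy$tip.label[desc])
  }
  sets
}

# is the label set mono (bipartition sense) on this tree?
oracle_monophyletic <- function(phy, target) {
  tips <- phy$tip.label
  target <- sort(unique(target))
  if (length(target) <= 1 || length(target) == length(tips)) return(TRUE)
  comp <- sort(setdiff(tips, target))
  for (s in oracle_bipartitions(phy)) {
    if (identical(s, target) || identical(s, comp)) return(TRUE)
  }
  FALSE
}

# exhaustive best assignment of rows to columns maximizing sum of gains
oracle_best_assignment <- function(gain) {
  n <- nrow(gain)
  perms <- permutations_of(seq_len(ncol(gain)))
  best <- -Inf
  best_p <- NULL
  for (p in perms) {
    cols <- p[seq_len(n)]
    val <- sum(gain[cbind(seq_len(n), cols)])
    if (val > best + 1e-12) { best <- val; best_p <- cols }
  }
  list(value = best, cols = best_p)
}

permutations_of <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations_of(x[-i])) {
      out[[length(out) + 1]] <- c(x[i], rest)
    }
  }
  out
}

# per-site re-check of the three site filters
oracle_site_pass <- function(dos_col, max_missing = 0.15, min_mac = 3,
                             min_maf = 0.05) {
  n <- length(dos_col)
  obs <- !is.na(dos_col)
  if (!any(obs)) return(FALSE)
  if ((1 - mean(obs)) > max_missing) return(FALSE)
  alt <- sum(dos_col[obs])
  tot <- 2 * sum(obs)
  mac <- min(alt, tot - alt)
  mac >= min_mac && (mac / tot) >= min_maf
}

# quadratic-time greedy LD pruning restricted to the same sliding windows
oracle_ld_prune <- function(d, chrom, window = 50, step = 10, r2_max = 0.1) {
  r2 <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 2 || sd(x[ok]) == 0 || sd(y[ok]) == 0) return(0)
    cor(x[ok], y[ok])^2
  }
  keep <- rep(TRUE, ncol(d))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    repeat {
      changed <- FALSE
      survivors <- idx[keep[idx]]
      n <- length(survivors)
      if (n < 2) break
      for (s in seq(1, n, by = step)) {
        win <- survivors[s:min(s + window - 1, n)]
        repeat {
          alive <- win[keep[win]]
          if (length(alive) < 2) break
          best <- 0
          drop <- NA
          for (a in seq_along(alive)) {
            for (b in seq_along(alive)) {
              if (b <= a) next
              v <- r2(d[, alive[a]], d[, alive[b]])
              if (v > best + 1e-12 ||
                  (abs(v - best) <= 1e-12 && !is.na(drop) &&
                   alive[b] > drop)) {
                best <- v
                drop <- alive[b]
              }
            }
          }
          if (best <= r2_max) break
          keep[drop] <- FALSE
          changed <- TRUE
        }
        if (s + window - 1 >= n) break
      }
      if (!changed) break
    }
  }
  keep
}

# a random phylo tree with unique tip labels and the package kept out of it
random_tree <- function(ntip, labels = paste0("t", seq_len(ntip))) {
  ape::rtree(ntip, tip.label = sample(labels))
}

# random genotype matrix builder for filter tests
random_genotypes <- function(n, J, miss = 0.1, seed = 1) {
  set.seed(seed)
  p <- runif(J, 0.02, 0.5)
  dos <- matrix(rbinom(n * J, 2, rep(p, each = n)), n, J)
  dos[matrix(runif(n * J) < miss, n, J)] <- NA
  cotodelim::genotype_matrix(
    dos, paste0("s", seq_len(n)),
    data.frame(chrom = rep("chr1", J), pos = seq_len(J), ref = "A",
               alt = "T"))
}
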