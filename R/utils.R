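#' @keywords internal
"_PACKAGE"

## internal validation helpers ------------------------------------------------

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stopf(fmt, ...)
  invisible(TRUE)
}

#' Derive a reproducible per-stage seed from a master seed
#'
#' A single pipeline seed fans out to per-stage seeds by stable hashing of the
#' stage name, so each stage is individually reproducible without the stages
#' sharing an RNG stream. The result is always a valid 32-bit R integer.
#'
#' @param seed Master integer seed.
#' @param stage Character stage name (e.g. `"em"`, `"bootstrap"`).
#' @return A single integer seed.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147480009
  as.integer((abs(seed) %% 1000003) * 2039 + h) %% 2147483587L
}

## Hungarian (Jonker-Volgenant style) assignment solver -----------------------
## Minimizes total cost of a square assignment; used for cluster-label
## alignment and nuclear/plastid clade correspondence. Shortest augmenting
## path formulation, O(n^3).

solve_assignment <- function(cost) {
  stopifnot(is.matrix(cost), nrow(cost) == ncol(cost))
  if (any(!is.finite(cost))) stopf("assignment cost matrix must be finite")
  n <- nrow(cost)
  if (n == 0L) return(integer(0))
  # dual potentials and matching, 1-indexed with a virtual 0 column
  u <- numeric(n + 1L)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)      # p[j]: row matched to column j (0 = none)
  way <- integer(n + 1L)
  INF <- sum(abs(cost)) + 1
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L                # columns are offset by 1 (index 1 = virtual)
    minv <- rep(INF, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- INF
      j1 <- 0L
      for (j in 2L:(n + 1L)) {
        if (used[j]) next
        cur <- cost[i0, j - 1L] - u[i0 + 0L] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in 1L:(n + 1L)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  # p[j+1] = row assigned to column j; invert to per-row column
  assign_col <- integer(n)
  for (j in seq_len(n)) assign_col[p[j + 1L]] <- j
  assign_col
}
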