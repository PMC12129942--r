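#' Ancestry-coefficient matrix
#'
#' Per-sample fractional membership in each of K gene pools (the Q matrix of
#' model-based structure inference). Rows sum to 1 within 1e-6.
#'
#' @param q Numeric matrix (samples x K) of ancestry fractions.
#' @param samples Character vector of sample identifiers.
#' @param meta Optional list of run metadata (K, seed, replicate).
#' @return An object of class `ancestry_matrix`.
#' @export
ancestry_matrix <- function(q, samples, meta = list()) {
  q <- as.matrix(q)
  assert_that(nrow(q) == length(samples),
              "samples (%d) must match q rows (%d)", length(samples), nrow(q))
  assert_that(!anyDuplicated(samples), "duplicate sample ids")
  assert_that(all(is.finite(q)) && all(q >= -1e-12) && all(q <= 1 + 1e-12),
              "ancestry fractions must lie in [0, 1]")
  rs <- rowSums(q)
  assert_that(all(abs(rs - 1) <= 1e-6),
              "ancestry rows must sum to 1 (worst |sum-1| = %.3g)",
              max(abs(rs - 1)))
  q <- pmin(pmax(q, 0), 1)
  rownames(q) <- samples
  meta$K <- ncol(q)
  structure(list(samples = as.character(samples), K = ncol(q), q = q,
                 meta = meta),
            class = "ancestry_matrix")
}

#' @export
print.ancestry_matrix <- function(x, ...) {
  cat(sprintf("<ancestry_matrix> %d samples, K = %d\n", length(x$samples), x$K))
  invisible(x)
}

#' Read an ADMIXTURE-style Q file
#'
#' Whitespace-separated fractions, one row per sample, one column per pool.
#' Rows are renormalized only when their sum is within 1e-3 of 1; larger
#' deviations are an error.
#'
#' @param q_path Path to the Q file.
#' @param samples Ordered sample identifiers (sidecar list).
#' @param meta Optional metadata list.
#' @return An [ancestry_matrix()].
#' @export
read_ancestry_matrix <- function(q_path, samples, meta = list()) {
  rows <- strsplit(trimws(readLines(q_path)), "[[:space:]]+")
  rows <- rows[lengths(rows) > 0]
  assert_that(length(rows) == length(samples),
              "Q has %d rows but %d samples given", length(rows),
              length(samples))
  k <- length(rows[[1]])
  assert_that(all(lengths(rows) == k), "ragged rows in Q file")
  q <- matrix(as.numeric(unlist(rows)), ncol = k, byrow = TRUE)
  assert_that(all(is.finite(q)), "non-numeric entries in Q file")
  assert_that(all(q >= 0), "negative ancestry fractions")
  rs <- rowSums(q)
  assert_that(all(abs(rs - 1) <= 1e-3),
              "row %d sums to %.4f (outside 1 +/- 1e-3)",
              which.max(abs(rs - 1)), rs[which.max(abs(rs - 1))])
  ancestry_matrix(q / rs, samples, meta)
}

#' Write an ancestry matrix in ADMIXTURE dialect
#'
#' @param Q An [ancestry_matrix()].
#' @param q_path Output path (fractions only, whitespace separated).
#' @return `q_path`, invisibly.
#' @export
write_ancestry_matrix <- function(Q, q_path) {
  writeLines(apply(format(Q$q, digits = 6, trim = TRUE), 1, paste,
                   collapse = " "), q_path)
  invisible(q_path)
}

#' Sample-to-population-to-taxon map
#'
#' @param sample Character sample ids (unique).
#' @param population Character population ids; each population belongs to
#'   exactly one taxon.
#' @param taxon Character taxon ids.
#' @param rank Taxon rank, `"species"` or `"infraspecific"`.
#' @param series Optional series label.
#' @return A data frame of class `sample_map`.
#' @export
sample_map <- function(sample, population, taxon,
                       rank = rep("species", length(sample)),
                       series = NA_character_) {
  assert_that(!anyDuplicated(sample), "duplicate sample ids in map")
  assert_that(all(rank %in% c("species", "infraspecific")),
              "rank must be species or infraspecific")
  m <- data.frame(sample = sample, population = population, taxon = taxon,
                  rank = rank, series = series, stringsAsFactors = FALSE)
  pt <- unique(m[, c("population", "taxon")])
  assert_that(!anyDuplicated(pt$population),
              "population mapped to more than one taxon")
  class(m) <- c("sample_map", "data.frame")
  m
}

#' Read a sample map from delimited text
#' @param path TSV/CSV with header columns sample, population, taxon, rank
#'   (and optionally series).
#' @param sep Field separator.
#' @return A [sample_map()].
#' @export
read_sample_map <- function(path, sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  sample_map(tab$sample, tab$population, tab$taxon,
             rank = if ("rank" %in% names(tab)) tab$rank else
               rep("species", nrow(tab)),
             series = if ("series" %in% names(tab)) tab$series else
               NA_character_)
}

#' Population-to-backbone-clade assignment
#'
#' @param population Character population ids.
#' @param clade Character clade labels (`NA_character_` = unassigned).
#' @return A data frame of class `clade_map`.
#' @export
clade_map <- function(population, clade) {
  assert_that(!anyDuplicated(population), "duplicate populations in clade map")
  m <- data.frame(population = as.character(population),
                  clade = as.character(clade), stringsAsFactors = FALSE)
  class(m) <- c("clade_map", "data.frame")
  m
}
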