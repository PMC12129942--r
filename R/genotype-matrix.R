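#' Genotype dosage matrix
#'
#' Container for biallelic SNP genotypes coded as alternate-allele dosages
#' (0/1/2, `NA` = missing). Rows are samples, columns are sites; sites carry
#' chromosome, 1-based position and ref/alt allele symbols, and positions are
#' strictly increasing within a chromosome.
#'
#' @param dosages Integer matrix (samples x sites) with values in {0,1,2,NA}.
#' @param samples Character vector of unique sample identifiers.
#' @param sites Data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, samples, sites) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  assert_that(length(samples) == nrow(dosages),
              "samples (%d) must match dosage rows (%d)",
              length(samples), nrow(dosages))
  assert_that(!anyDuplicated(samples), "duplicate sample ids")
  assert_that(is.data.frame(sites) &&
                all(c("chrom", "pos", "ref", "alt") %in% names(sites)),
              "sites must have columns chrom, pos, ref, alt")
  assert_that(nrow(sites) == ncol(dosages),
              "sites (%d) must match dosage columns (%d)",
              nrow(sites), ncol(dosages))
  bad <- dosages[!is.na(dosages)]
  assert_that(all(bad %in% 0:2), "non-missing dosages must be 0, 1 or 2")
  for (chr in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == chr]
    assert_that(all(diff(p) > 0),
                "positions not strictly increasing on chromosome %s", chr)
  }
  rownames(dosages) <- samples
  structure(list(samples = as.character(samples),
                 sites = as.data.frame(sites, stringsAsFactors = FALSE),
                 dosages = dosages),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d sites (%.1f%% missing)\n",
              length(x$samples), nrow(x$sites),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

n_sites <- function(g) nrow(g$sites)

subset_sites <- function(g, keep) {
  genotype_matrix(g$dosages[, keep, drop = FALSE], g$samples,
                  g$sites[keep, , drop = FALSE])
}

#' Read genotypes from a VCF file
#'
#' Reads GT fields of a VCF (v4.x) into a [genotype_matrix()]. Dosage is the
#' count of alternate alleles; `./.` (or `.|.`) becomes missing. Site order
#' follows file order. Only diploid, biallelic records are representable:
#' non-diploid GT strings are an error naming the offending record, and
#' multiallelic records are either rejected or dropped per `multiallelic`.
#'
#' @param path Path to an (uncompressed or gzipped) VCF file.
#' @param multiallelic `"error"` (default) or `"drop"`.
#' @return A [genotype_matrix()].
#' @export
read_genotype_vcf <- function(path, multiallelic = c("error", "drop")) {
  multiallelic <- match.arg(multiallelic)
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fm <- vcfR::getFIX(v)
  if (is.null(dim(fm))) fm <- matrix(fm, nrow = 1,
                                     dimnames = list(NULL, names(fm)))
  fix <- as.data.frame(fm, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    if (multiallelic == "error")
      stopf("multiallelic record at %s:%s", fix$CHROM[which(multi)[1]],
            fix$POS[which(multi)[1]])
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  if (nrow(fix) == 0) {
    samples <- colnames(v@gt)[-1]
    return(genotype_matrix(
      matrix(integer(0), length(samples), 0), samples,
      data.frame(chrom = character(0), pos = integer(0),
                 ref = character(0), alt = character(0))))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  assert_that(!anyDuplicated(samples), "duplicate sample ids in VCF")
  # gt: sites x samples character; strip phasing, count alt alleles
  core <- gsub("\\|", "/", as.vector(gt))
  core[is.na(core)] <- "./."
  known <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L, "./." = NA)
  bad <- !(core %in% names(known))
  if (any(bad)) {
    idx <- arrayInd(which(bad)[1], dim(gt))
    stopf("non-diploid or unsupported GT '%s' at record %s:%s sample %s",
          core[which(bad)[1]], fix$CHROM[idx[1]], fix$POS[idx[1]],
          samples[idx[2]])
  }
  dos <- matrix(unname(known[core]), nrow = nrow(gt))
  sites <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT,
                      stringsAsFactors = FALSE)
  genotype_matrix(t(dos), samples, sites)
}

#' Read genotypes from a dosage table
#'
#' Tab-separated table with columns `chrom`, `pos`, `ref`, `alt` followed by
#' one column per sample holding 0/1/2 dosages (`NA` or empty = missing).
#'
#' @param path Path to the TSV file.
#' @return A [genotype_matrix()].
#' @export
read_dosage_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = c(chrom = "character",
                                          ref = "character",
                                          alt = "character"))
  meta <- c("chrom", "pos", "ref", "alt")
  assert_that(all(meta %in% names(tab)),
              "dosage table must start with chrom, pos, ref, alt columns")
  samples <- setdiff(names(tab), meta)
  dos <- t(as.matrix(tab[, samples, drop = FALSE]))
  genotype_matrix(dos, samples, tab[, meta])
}

#' Write a genotype matrix as a dosage table
#'
#' @param g A [genotype_matrix()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_dosage_table <- function(g, path) {
  tab <- cbind(g$sites, as.data.frame(t(g$dosages), check.names = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
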