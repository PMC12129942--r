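#' Mixed quantitative/qualitative trait table
#'
#' Operational units (populations or taxa) by traits. Quantitative traits are
#' real-valued (finite where present); qualitative traits are integer state
#' codes drawn from a declared state set. Missing values are allowed.
#'
#' @param values Numeric matrix (units x traits); qualitative columns hold
#'   integer codes.
#' @param units Character unit labels.
#' @param kinds Character vector, `"quantitative"` or `"qualitative"`, one
#'   per trait.
#' @param states Optional named list of allowed integer states per
#'   qualitative trait; defaults to the observed states.
#' @param trait_units Optional unit-of-measure strings for quantitative
#'   traits.
#' @return An object of class `trait_table`.
#' @export
trait_table <- function(values, units, kinds, states = NULL,
                        trait_units = NULL) {
  values <- as.matrix(values)
  assert_that(!is.null(colnames(values)), "trait columns must be named")
  traits <- colnames(values)
  assert_that(length(units) == nrow(values), "units must match value rows")
  assert_that(!anyDuplicated(units), "duplicate unit labels")
  assert_that(length(kinds) == length(traits) &&
                all(kinds %in% c("quantitative", "qualitative")),
              "kinds must be quantitative/qualitative, one per trait")
  names(kinds) <- traits
  qn <- traits[kinds == "quantitative"]
  bad <- qn[vapply(qn, function(t) any(is.infinite(values[, t])), logical(1))]
  assert_that(length(bad) == 0, "non-finite quantitative values in trait %s",
              if (length(bad)) bad[1] else "")
  ql <- traits[kinds == "qualitative"]
  if (is.null(states)) {
    states <- lapply(ql, function(t) sort(unique(values[!is.na(values[, t]), t])))
    names(states) <- ql
  }
  for (t in ql) {
    v <- values[, t]
    assert_that(all(is.na(v) | v == floor(v)),
                "qualitative trait %s has non-integer codes", t)
    assert_that(all(is.na(v) | v %in% states[[t]]),
                "qualitative trait %s has values outside its state set", t)
  }
  rownames(values) <- units
  structure(list(units = as.character(units), values = values,
                 kinds = kinds, states = states, trait_units = trait_units),
            class = "trait_table")
}

#' @export
print.trait_table <- function(x, ...) {
  cat(sprintf("<trait_table> %d units x %d traits (%d quantitative, %d qualitative)\n",
              length(x$units), ncol(x$values),
              sum(x$kinds == "quantitative"), sum(x$kinds == "qualitative")))
  invisible(x)
}

#' Read a trait table from delimited text
#'
#' The header row names the traits; the first column holds unit labels.
#' `schema` declares each trait's kind. Empty cells become missing. A
#' qualitative value outside the declared states, or a non-numeric
#' quantitative cell, is an error.
#'
#' @param path Path to the delimited file.
#' @param schema Named character vector mapping trait name to
#'   `"quantitative"`/`"qualitative"`.
#' @param states Optional named list of allowed states (see [trait_table()]).
#' @param sep Field separator (default tab).
#' @return A [trait_table()].
#' @export
read_trait_table <- function(path, schema, states = NULL, sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", na.strings = c("", "NA"))
  units <- tab[[1]]
  tab <- tab[, -1, drop = FALSE]
  assert_that(all(names(tab) %in% names(schema)),
              "schema missing traits: %s",
              paste(setdiff(names(tab), names(schema)), collapse = ", "))
  vals <- matrix(NA_real_, nrow(tab), ncol(tab),
                 dimnames = list(units, names(tab)))
  for (t in names(tab)) {
    raw <- tab[[t]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- !is.na(raw) & is.na(num)
    assert_that(!any(bad), "non-numeric value '%s' in trait %s",
                if (any(bad)) raw[which(bad)[1]] else "", t)
    vals[, t] <- num
  }
  trait_table(vals, units, schema[colnames(vals)], states = states)
}

#' Write a trait table as delimited text
#' @param T A [trait_table()].
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(T, path, sep = "\t") {
  tab <- data.frame(unit = T$units, T$values, check.names = FALSE)
  utils::write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
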