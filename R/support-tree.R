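#' Trees with dual branch-support labels
#'
#' A `support_tree` wraps an [ape::read.tree()] phylogeny whose internal
#' edges may carry a dual support pair: SH-aLRT percent and ultrafast
#' bootstrap percent, written in Newick node labels as `"sh/uf"` (e.g.
#' `99.8/100`). Missing support is distinct from support 0: threshold tests
#' on absent support fail closed.
#'
#' @param phy An `ape::phylo` object.
#' @param sh_alrt,ufboot Numeric vectors of length `phy$Nnode` (one entry per
#'   internal node, `NA` = absent).
#' @return An object of class `support_tree`.
#' @export
support_tree <- function(phy, sh_alrt = rep(NA_real_, phy$Nnode),
                         ufboot = rep(NA_real_, phy$Nnode)) {
  assert_that(inherits(phy, "phylo"), "phy must be an ape phylo tree")
  assert_that(!anyDuplicated(phy$tip.label), "duplicate leaf labels")
  assert_that(length(sh_alrt) == phy$Nnode && length(ufboot) == phy$Nnode,
              "one support pair per internal node required")
  ok <- function(x) all(is.na(x) | (x >= 0 & x <= 100))
  assert_that(ok(sh_alrt) && ok(ufboot), "supports must be percents in [0,100]")
  if (!is.null(phy$edge.length))
    assert_that(all(phy$edge.length >= -1e-12), "negative branch lengths")
  structure(list(phy = phy, sh_alrt = as.numeric(sh_alrt),
                 ufboot = as.numeric(ufboot)),
            class = "support_tree")
}

#' @export
print.support_tree <- function(x, ...) {
  n_sup <- sum(!is.na(x$sh_alrt) | !is.na(x$ufboot))
  cat(sprintf("<support_tree> %d leaves, %d internal nodes (%d with supports)\n",
              length(x$phy$tip.label), x$phy$Nnode, n_sup))
  invisible(x)
}

check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stopf("malformed Newick: unmatched ')' at character %d", i)
    }
  }
  if (depth > 0L)
    stopf("malformed Newick: %d unclosed '(' at character %d", depth,
          length(chars))
  if (!grepl(";\\s*$", text))
    stopf("malformed Newick: missing terminal ';' at character %d",
          length(chars))
  invisible(TRUE)
}

#' Parse a Newick string with support-valued node labels
#'
#' Internal node labels of the form `"a/b"` are read as (SH-aLRT, UFboot) in
#' that order (`label_style = "dual_slash"`). With `label_style = "single"`,
#' a plain numeric label is stored in both support slots, the convention used
#' for bootstrap-only synthetic trees. Unlabeled edges have absent supports.
#'
#' @param newick_text A Newick string.
#' @param label_style `"dual_slash"` or `"single"`.
#' @return A [support_tree()].
#' @export
parse_support_tree <- function(newick_text,
                               label_style = c("dual_slash", "single")) {
  label_style <- match.arg(label_style)
  check_newick_syntax(newick_text)
  phy <- tryCatch(ape::read.tree(text = newick_text),
                  error = function(e) NULL)
  if (is.null(phy) || !inherits(phy, "phylo"))
    stopf("malformed Newick: unparseable at character 1")
  lab <- phy$node.label
  sh <- uf <- rep(NA_real_, phy$Nnode)
  if (!is.null(lab)) {
    for (i in seq_along(lab)) {
      l <- trimws(lab[i])
      if (l == "" || is.na(l)) next
      if (label_style == "dual_slash") {
        if (!grepl("^[0-9.]+/[0-9.]+$", l))
          stopf("node label '%s' at internal node %d does not match 'sh/uf'",
                l, i)
        parts <- as.numeric(strsplit(l, "/")[[1]])
        sh[i] <- parts[1]
        uf[i] <- parts[2]
      } else {
        if (!grepl("^[0-9.]+$", l))
          stopf("node label '%s' at internal node %d is not a number", l, i)
        sh[i] <- uf[i] <- as.numeric(l)
      }
    }
  }
  support_tree(phy, sh, uf)
}

#' Serialize a support tree to Newick
#'
#' Internal nodes with at least one support value get a `"sh/uf"` label
#' (absent halves written as `NA` never occur from this package's builders;
#' both-absent nodes stay unlabeled).
#'
#' @param st A [support_tree()].
#' @param digits Significant digits for support values.
#' @return A Newick string.
#' @export
write_support_tree <- function(st, digits = 6) {
  phy <- st$phy
  lab <- character(phy$Nnode)
  has <- !is.na(st$sh_alrt) | !is.na(st$ufboot)
  fmt <- function(x) ifelse(is.na(x), "NA", format(x, digits = digits,
                                                   trim = TRUE))
  lab[has] <- paste0(fmt(st$sh_alrt[has]), "/", fmt(st$ufboot[has]))
  phy$node.label <- lab
  ape::write.tree(phy)
}

## clade (descendant-tip) sets per internal node ------------------------------
## Returns a list indexed 1..Nnode (internal node number - Ntip) of tip index
## vectors. Postorder accumulation, no recursion.
clade_tip_sets <- function(phy) {
  ntip <- length(phy$tip.label)
  phy <- stats::reorder(phy, "postorder")
  sets <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- i
  for (e in seq_len(nrow(phy$edge))) {
    par <- phy$edge[e, 1]
    child <- phy$edge[e, 2]
    sets[[par]] <- c(sets[[par]], sets[[child]])
  }
  lapply(sets[(ntip + 1):(ntip + phy$Nnode)], sort)
}

## canonical key of the bipartition induced by a tip-index side: the side not
## containing tip 1, as a sorted label string
bipartition_key <- function(side_idx, tip_labels) {
  all_idx <- seq_along(tip_labels)
  if (1 %in% side_idx) side_idx <- setdiff(all_idx, side_idx)
  paste(sort(tip_labels[side_idx]), collapse = "\r")
}
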