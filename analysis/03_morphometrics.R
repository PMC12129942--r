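#!/usr/bin/env Rscript
## Mixed-trait morphometrics on the scenario specimens: Gower distances
## over population trait means, UPGMA clustering, trait PCA, and
## diagnosability counts between every taxon pair.

suppressPackageStartupMessages(library(cotodelim))

traits <- read_trait_table(
  "results/scenario_traits.tsv",
  c(leaf_length = "quantitative", leaf_width = "quantitative",
    indumentum = "qualitative", petal_color = "qualitative"))
map <- read_sample_map("results/scenario_map.tsv")

## population-mean table for clustering (specimen table stays for
## diagnosability, which needs observed ranges)
pops <- unique(map$population)
pop_vals <- t(vapply(pops, function(p) {
  rows <- map$sample[map$population == p]
  colMeans(traits$values[rows, , drop = FALSE], na.rm = TRUE)
}, numeric(ncol(traits$values))))
pop_traits <- trait_table(pop_vals, pops, traits$kinds)

D <- gower_matrix(pop_traits)
hc <- upgma_cluster(D)
writeLines(upgma_newick(hc), "results/morph_upgma.nwk")

pc <- trait_pca(traits)
write.table(data.frame(trait = rownames(pc$contributions),
                       round(pc$contributions[, 1:2], 2)),
            "results/trait_pca_contributions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

taxa <- unique(map$taxon)
rows <- list()
for (a in seq_along(taxa)) {
  for (b in seq_along(taxa)) {
    if (b <= a) next
    ua <- map$sample[map$taxon == taxa[a]]
    ub <- map$sample[map$taxon == taxa[b]]
    d <- count_diagnostic_traits(traits, ua, ub)
    rows[[length(rows) + 1]] <- data.frame(
      taxon_a = taxa[a], taxon_b = taxa[b], discontinuous = d$count,
      diagnosable = d$diagnosable)
  }
}
diag_tab <- do.call(rbind, rows)
write.table(diag_tab, "results/diagnosability.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf("trait PCA: PC1 %.1f%%, PC2 %.1f%% of variance",
                100 * pc$varfrac[1], 100 * pc$varfrac[2]))
message(sprintf("%d of %d taxon pairs diagnosable (>= 2 discontinuous traits)",
                sum(diag_tab$diagnosable), nrow(diag_tab)))
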