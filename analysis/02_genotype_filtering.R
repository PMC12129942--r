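#!/usr/bin/env Rscript
## Site filtering (missingness <= 15%, MAC >= 3, MAF >= 5%), sliding-window
## LD pruning (50-SNP windows, 10-SNP steps, r^2 > 0.1 dropped) and
## genotype PCA on the simulated scenario.

suppressPackageStartupMessages(library(cotodelim))

G <- read_dosage_table("results/scenario_genotypes.tsv")
filt <- filter_sites(G)
pruned <- ld_prune(filt$genotypes)

report <- rbind(filt$report$stages, pruned$report$stages[-1, ])
write.table(report, "results/filter_report.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_dosage_table(pruned$genotypes, "results/scenario_genotypes_pruned.tsv")

pc <- genotype_pca(pruned$genotypes, 4)
scores <- data.frame(sample = rownames(pc$scores), pc$scores)
write.table(scores, "results/genotype_pca_scores.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message("filter stages:")
print(report, row.names = FALSE)
message(sprintf("PC1/PC2 variance fractions: %.1f%% / %.1f%%",
                100 * pc$varfrac[1], 100 * pc$varfrac[2]))
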