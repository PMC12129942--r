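#!/usr/bin/env Rscript
## Generate the reference synthetic scenario used by the downstream
## analysis steps: four gene pools at divergence F = 0.2, one pure taxon
## per pool plus two planted hybrids (55:45 mixtures with captured
## plastids), two populations of six accessions per taxon, 2000 unlinked
## biallelic sites, and a trait layer separating pure taxa by 4 SD.

suppressPackageStartupMessages(library(cotodelim))

seed <- 2026
S <- standard_scenario(n_pools = 4, n_hybrids = 2, F = 0.2, sites = 2000,
                       n_pops = 2, samples_per_pop = 6, effect = 4,
                       seed = seed)
sim <- simulate_scenario(S)

dir.create("results", showWarnings = FALSE)
write_dosage_table(sim$genotypes, "results/scenario_genotypes.tsv")
write.table(sim$map, "results/scenario_map.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_trait_table(sim$traits, "results/scenario_traits.tsv")
write.table(sim$plastid, "results/scenario_plastid.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sim$truth$taxa, "results/scenario_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf("scenario: %d samples, %d populations, %d taxa (%d hybrid)",
                length(sim$genotypes$samples),
                length(unique(sim$map$population)),
                nrow(sim$truth$taxa),
                sum(sim$truth$taxa$status == "admixed")))
message("inputs written under results/")
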