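#!/usr/bin/env Rscript
# Stage 1: generate the study-structured synthetic dataset.
#
# The generator emulates the curated venom-expression dataset the analysis
# was designed for: 52 snake species on a 60-My crown phylogeny, 10 core
# toxin families with phylogenetically heritable (lambda 0.8 / 0.5) latent
# abundances, 15 low-prevalence decoy families, structural zeros from a
# detection-limit rule, and sequencing-technology batch labels. Everything
# downstream (02-05) runs from the files written here.

suppressPackageStartupMessages(library(phylovenom))
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

scenario <- venom_scenario(seed = 20240601)
sim <- simulate_venom_dataset(scenario)

write_phylogeny(sim$tree, "results/data/tree.nwk")
write_toxin_table(sim$table, "results/data/abundance.tsv")
jsonlite::write_json(list(lambda = as.list(scenario$lambda),
                          mu = as.list(scenario$mu),
                          n_tips = scenario$n_tips,
                          height = scenario$height,
                          seed = scenario$seed),
                     "results/data/truth.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

val <- validate_inputs(sim$tree, sim$table)
cat(sprintf("dataset: %d species x %d components; %d components above 50%% prevalence\n",
            nrow(sim$table$values), ncol(sim$table$values),
            sum(val$prevalence >= 0.5)))
cat("wrote results/data/{tree.nwk, abundance.tsv, truth.json}\n")
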