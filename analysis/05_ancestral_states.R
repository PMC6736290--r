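#!/usr/bin/env Rscript
# Stage 5: ancestral toxin abundances and the root venom.
#
# Per-component maximum-likelihood reconstruction under Brownian motion
# (contrasts algorithm), each toxin family reconstructed independently. A
# family is called present in the ancestral venom only when its root 95% CI
# excludes zero from below.

suppressPackageStartupMessages(library(phylovenom))
dir.create("results/asr", recursive = TRUE, showWarnings = FALSE)

tree <- read_phylogeny("results/data/tree.nwk")
filtered <- read_toxin_table("results/pglmm/filtered_table.tsv")

asr <- ml_ancestral_states_all(tree, filtered)
calls <- root_presence_call(asr)

write_asr_tsv(asr, "results/asr/ancestral_states.tsv")
jsonlite::write_json(as.list(calls), "results/asr/root_presence.json",
                     auto_unbox = TRUE, pretty = TRUE)

for (comp in names(asr)) {
  r <- asr[[comp]]$root
  cat(sprintf("%-6s root %6.2f%% [%6.2f, %6.2f]  %s\n", comp, r$estimate,
              r$lower, r$upper,
              if (calls[[comp]]) "PRESENT at root" else "not called"))
}
cat("components called present at the root:",
    paste(names(calls)[calls], collapse = ", "), "\n")
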