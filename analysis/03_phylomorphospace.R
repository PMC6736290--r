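#!/usr/bin/env Rscript
# Stage 3: the venom phylomorphospace.
#
# Eigen-analysis of the posterior-mean PCOV defines the axes of greatest
# phylogenetically heritable variation; species are projected into that
# space. The leading two axes carry the convergence analysis in stage 4.

suppressPackageStartupMessages(library(phylovenom))
dir.create("results/pca", recursive = TRUE, showWarnings = FALSE)

Gtab <- read.table("results/pglmm/pcov_mean_G.tsv", header = TRUE, sep = "\t",
                   check.names = FALSE)
G <- as.matrix(Gtab[-1]); rownames(G) <- Gtab[[1]]
Ytab <- read.table("results/pglmm/scaled_responses.tsv", header = TRUE,
                   sep = "\t", check.names = FALSE)
Y <- as.matrix(Ytab[-1]); rownames(Y) <- Ytab[[1]]

pca <- species_scores(Y, pcov_pca(G))
write_pca_tsv(pca, "results/pca/pca")

vf <- 100 * pca$variance_fractions
cat(sprintf("PC1 %.1f%%, PC2 %.1f%%; first two axes jointly %.1f%%\n",
            vf[1], vf[2], vf[1] + vf[2]))
lead <- apply(abs(pca$loadings[, 1:2]), 2, function(l)
  paste(names(sort(l, decreasing = TRUE))[1:2], collapse = "+"))
cat("dominant loadings: PC1 =", lead[1], "; PC2 =", lead[2], "\n")
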