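#!/usr/bin/env Rscript
# Stage 1 — simulate the study.
#
# Generates the self-contained synthetic two-group splicing study (toy
# genome, annotation, junction counts for 5 + 5 samples, strain VCF,
# motif set, expression matrices, ground truth) under results/bundle/.
# All later stages read from that bundle, so the whole analysis runs
# without any external data. Usage: Rscript analysis/01_simulate.R [seed]

library(psikit)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 1L

cfg <- simulation_config(seed = seed)
bundle <- generate_study(cfg, "results/bundle")

cat(sprintf("seed %d: %d events in %d genes, %d planted SNPs, %d motifs\n",
            seed, nrow(bundle$events),
            length(unique(bundle$events$gene_id)),
            nrow(bundle$snps), length(bundle$motifs)))
cat("bundle written to results/bundle/ (truth tables under truth/)\n")
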