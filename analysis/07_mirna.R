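#!/usr/bin/env Rscript
# Stage 7 — miRNA regulators of the splicing factor.
#
# Identifies miRNAs differentially expressed between the groups (Welch
# test on log2(x+1), BH-adjusted) and keeps those elevated in group 1
# with a canonical 7mer-or-better seed site in the splicing factor's
# 3'UTR. Usage: Rscript analysis/07_mirna.R

library(psikit)
suppressPackageStartupMessages(library(Biostrings))

groups <- read.delim("results/bundle/samples.tsv")
mex <- read_expression("results/bundle/mirna_expression.tsv", groups)
seqs <- as.character(readDNAStringSet("results/bundle/mirnas.fa"))
utr <- as.character(readDNAStringSet("results/bundle/utr.fa"))[[1]]

diff_mir <- differential_mirnas(mex)
readr::write_tsv(diff_mir, "results/tables/mirna_differential.tsv")
cat(sprintf("%d / %d miRNAs differential (BH < 0.05)\n",
            sum(diff_mir$significant), nrow(diff_mir)))

cand <- candidate_regulators(diff_mir, seqs, utr, required_direction = 1)
cat("candidate silencers of the splicing factor (up in group 1, seed site in UTR):\n")
print(cand)
readr::write_tsv(cand, "results/tables/mirna_candidates.tsv")
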