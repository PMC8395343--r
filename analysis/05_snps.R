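#!/usr/bin/env Rscript
# Stage 5 — SNPs around alternative exons.
#
# Classifies strain SNPs into positional categories relative to each
# alternative segment (intronic up/downstream 15-500 nt, splice-site
# adjacent within 15 nt, exon interior), normalizes densities per kb,
# tests local density against the genome-wide baseline (2x2 chi-square),
# flags genes with splice-site SNPs on significant events, and counts
# destroyed CpG sites. Usage: Rscript analysis/05_snps.R

library(psikit)
suppressPackageStartupMessages(library(Biostrings))

genome <- readDNAStringSet("results/bundle/genome.fa")
names(genome) <- sub("\\s.*$", "", names(genome))
snps <- read_vcf("results/bundle/snps.vcf")
events <- read.delim("results/tables/events_quantified.tsv")

cnt <- t(vapply(seq_len(nrow(events)), function(i)
  per_event_snp_counts(snps, events[i, ]), numeric(6)))
snp_table <- cbind(events[, c("event_id", "gene_id")], as.data.frame(cnt))
readr::write_tsv(snp_table, "results/tables/snp_counts.tsv")
cat("per-event SNP counts (events with any SNP):\n")
print(snp_table[snp_table$n_total > 0, ])

win_len <- sum(2 * 500 + events$seg_end0 - events$seg_start0)
enr <- enrichment_chi2(sum(snp_table$n_total), win_len,
                       nrow(snps), sum(width(genome)))
cat(sprintf("density near events %.3f/kb vs global %.3f/kb: chi2 = %.2f, p = %.3g\n",
            enr$density_near, enr$density_global, enr$chi2, enr$p))

ss_genes <- flag_splice_site_snp_genes(snps, events)
cat(sprintf("%d genes with splice-site SNPs on significant events: %s\n",
            length(ss_genes), paste(ss_genes, collapse = ", ")))
readr::write_tsv(data.frame(gene_id = ss_genes),
                 "results/tables/splice_site_snp_genes.tsv")

cpg <- cpg_loss_per_gene(snps, events, genome)
cat("destroyed CpG sites per gene:\n"); print(cpg)
readr::write_tsv(cpg, "results/tables/cpg_loss.tsv")
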