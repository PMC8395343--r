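#!/usr/bin/env Rscript
# Stage 8 — gene-level expression statistics and external gene overlap.
#
# Welch tests per gene with log2 fold changes, a row-scaled matrix of the
# significant genes for heatmap display, and the overlap of alternatively
# spliced genes with an external (GWAS-style) gene list through the
# ortholog map. Usage: Rscript analysis/08_diffexp.R

library(psikit)

groups <- read.delim("results/bundle/samples.tsv")
gex <- read_expression("results/bundle/gene_expression.tsv", groups)
events <- read.delim("results/tables/events_quantified.tsv")

de <- differential_expression(gex)
readr::write_tsv(de, "results/tables/gene_differential.tsv")
cat(sprintf("%d / %d genes differential (BH < 0.05)\n",
            sum(de$significant), nrow(de)))

sig_ids <- de$feature_id[de$significant]
if (length(sig_ids) > 0) {
  hm <- scale_heatmap_matrix(gex, sig_ids)
  readr::write_tsv(cbind(feature_id = rownames(hm), as.data.frame(hm)),
                   "results/tables/heatmap_matrix.tsv")
}

spliced <- unique(events$gene_id[!is.na(events$significant) &
                                   events$significant])
overlap <- intersect_gene_lists(
  spliced,
  read_gene_list("results/bundle/gwas_genes.txt"),
  read_ortholog_map("results/bundle/ortholog_map.tsv"))
cat(sprintf("%d alternatively spliced genes overlap the external list\n",
            nrow(overlap)))
print(overlap)
readr::write_tsv(overlap, "results/tables/external_gene_overlap.tsv")
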