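#!/usr/bin/env Rscript
# Stage 2 — PSI quantification and event filtering.
#
# Estimates per-group PSI from pooled junction counts, the between-group
# delta PSI, and a Monte-Carlo Beta posterior probability per event, then
# applies the significance filter (|dPSI| > 0.1, probability > 0.9) and
# the strong/moderate category labels. Event topology (CE / IR / alt 5'ss
# / alt 3'ss) is classified against the annotation.
# Usage: Rscript analysis/02_quantify.R [seed]

library(psikit)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 1L

ann <- read_annotation("results/bundle/annotation.gtf")
counts <- read_junction_counts("results/bundle/junctions.tsv")
groups <- read.delim("results/bundle/samples.tsv")
coords <- read.delim("results/bundle/events.tsv")

quant <- quantify_events(counts, groups, seed = seed)
events <- merge(coords, quant, by = "event_id")
events$type <- vapply(seq_len(nrow(events)), function(i)
  classify_event_type(events[i, ], ann), character(1))

dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
readr::write_tsv(events, "results/tables/events_quantified.tsv")

sig <- events[!is.na(events$significant) & events$significant, ]
cat(sprintf("%d / %d events pass the filter (|dPSI| > 0.1, P > 0.9)\n",
            nrow(sig), nrow(events)))
print(table(sig$type))
print(table(sig$category))
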