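#' Localize an event to 5'UTR / CDS / 3'UTR
#'
#' The alternative segment is intersected with the CDS span of the
#' longest CDS-bearing transcript of its gene. Segments overlapping both
#' UTR and CDS are called CDS; genes without any annotated CDS give `NA`.
#' UTR sidedness (5' vs 3') follows transcript orientation.
#'
#' @param event list/one-row data frame with `gene_id`, `seg_start0`,
#'   `seg_end0`.
#' @param ann a [genome_annotation()].
#' @return `"5UTR"`, `"CDS"`, `"3UTR"` or `NA_character_`.
#' @export
map_event_region <- function(event, ann) {
  gene <- event$gene_id
  txs <- ann$transcripts$transcript_id[ann$transcripts$gene_id == gene]
  if (length(txs) == 0) {
    warning("gene not in annotation: ", gene, call. = FALSE)
    return(NA_character_)
  }
  cds <- ann$cds[ann$cds$transcript_id %in% txs, , drop = FALSE]
  if (nrow(cds) == 0) return(NA_character_)  # non-coding gene
  len <- cds$cds_end0 - cds$cds_start0
  top <- cds[which.max(len), ]
  s <- event$seg_start0; e <- event$seg_end0
  strand <- gene_strand(ann, gene)
  if (e > top$cds_start0 && s < top$cds_end0) return("CDS")
  genomic_left <- e <= top$cds_start0
  if (strand == "+") {
    if (genomic_left) "5UTR" else "3UTR"
  } else {
    if (genomic_left) "3UTR" else "5UTR"
  }
}

#' Reading-frame consequence of skipping one exon
#'
#' Skipping preserves the reading frame iff the exon length is a
#' multiple of 3.
#'
#' @param exon_length exon length in nucleotides (>= 1).
#' @return `"preserved"` or `"shift"`.
#' @export
frame_consequence <- function(exon_length) {
  stopifnot(all(exon_length >= 1))
  ifelse(exon_length %% 3 == 0, "preserved", "shift")
}

#' Group frameshifting exons that can rescue the frame if co-skipped
#'
#' Within a gene, frameshifting cassette exons changing in the same
#' direction (same delta-PSI sign) whose summed lengths are a multiple of
#' 3 can restore the reading frame when skipped together. Grouping is
#' greedy, smallest groups first: mod-3 residue-1 exons are paired with
#' residue-2 exons in genomic order; leftovers of one residue class are
#' grouped in consecutive triples. Each event joins at most one group;
#' exons whose own length is a multiple of 3 are never grouped.
#'
#' @param events data frame with `event_id`, `gene_id`, `seg_start0`,
#'   `length`, `delta_psi` — typically the CDS cassette-exon events.
#' @return data frame `event_id`, `rescue_group_id` (empty if none).
#' @export
find_rescue_groups <- function(events) {
  out <- data.frame(event_id = character(), rescue_group_id = character())
  if (nrow(events) == 0) return(out)
  cand <- events[events$length %% 3 != 0 & !is.na(events$delta_psi) &
                   events$delta_psi != 0, , drop = FALSE]
  if (nrow(cand) == 0) return(out)
  cand$sign <- ifelse(cand$delta_psi > 0, "up", "down")
  gid <- 0L
  groups <- list()
  for (key in unique(paste(cand$gene_id, cand$sign))) {
    sub <- cand[paste(cand$gene_id, cand$sign) == key, , drop = FALSE]
    sub <- sub[order(sub$seg_start0), , drop = FALSE]
    r1 <- sub$event_id[sub$length %% 3 == 1]
    r2 <- sub$event_id[sub$length %% 3 == 2]
    npair <- min(length(r1), length(r2))
    for (i in seq_len(npair)) {
      gid <- gid + 1L
      groups[[gid]] <- c(r1[i], r2[i])
    }
    for (rest in list(r1[seq_len(length(r1)) > npair],
                      r2[seq_len(length(r2)) > npair])) {
      while (length(rest) >= 3) {
        gid <- gid + 1L
        groups[[gid]] <- rest[1:3]
        rest <- rest[-(1:3)]
      }
    }
  }
  if (length(groups) == 0) return(out)
  do.call(rbind, lapply(seq_along(groups), function(i) {
    data.frame(event_id = groups[[i]],
               rescue_group_id = sprintf("rescue_%03d", i))
  }))
}

#' Expected frameshift rate under random exon skipping
#'
#' The null model for the observed frameshift fraction: among all
#' internal (non-first, non-last) exons lying fully inside a CDS,
#' the fraction whose length is not a multiple of 3. Exons are
#' deduplicated by genomic coordinates.
#'
#' @param ann a [genome_annotation()].
#' @return fraction in `[0,1]`.
#' @export
random_skipping_null <- function(ann) {
  ex <- internal_cds_exons(ann)
  if (nrow(ex) == 0) stop("annotation has no internal CDS exons")
  mean((ex$end0 - ex$start0) %% 3 != 0)
}

# internal exons fully inside their transcript's CDS span, deduplicated
internal_cds_exons <- function(ann) {
  res <- lapply(unique(ann$exons$transcript_id), function(tx) {
    e <- ann$exons[ann$exons$transcript_id == tx, , drop = FALSE]
    e <- e[order(e$start0), , drop = FALSE]
    if (nrow(e) < 3) return(NULL)
    e <- e[-c(1, nrow(e)), , drop = FALSE]
    cds <- ann$cds[ann$cds$transcript_id == tx, , drop = FALSE]
    if (nrow(cds) == 0) return(NULL)
    chrom <- gene_chrom(ann, ann$transcripts$gene_id[
      match(tx, ann$transcripts$transcript_id)])
    keep <- e$start0 >= cds$cds_start0[1] & e$end0 <= cds$cds_end0[1]
    if (!any(keep)) return(NULL)
    data.frame(chrom = chrom, start0 = e$start0[keep], end0 = e$end0[keep])
  })
  ex <- do.call(rbind, res)
  if (is.null(ex)) return(data.frame(chrom = character(), start0 = integer(),
                                     end0 = integer()))
  unique(ex)
}

#' Exact two-sided binomial test of the observed frameshift count
#'
#' Two-sided exact binomial p-value (minimum-likelihood convention, as in
#' [stats::binom.test()]) of seeing `n_shift` frameshifting events among
#' `n_total` under a null frameshift probability `p_null`.
#'
#' @param n_shift,n_total observed counts.
#' @param p_null null frameshift probability in (0,1), e.g. from
#'   [random_skipping_null()].
#' @return p-value.
#' @export
frameshift_enrichment_test <- function(n_shift, n_total, p_null) {
  stopifnot(n_shift >= 0, n_shift <= n_total, n_total >= 1)
  if (p_null <= 0 || p_null >= 1) stop("p_null must be in (0,1)")
  stats::binom.test(n_shift, n_total, p_null)$p.value
}

#' Frame-consequence summary table
#'
#' Tabulates preserved / shift / rescue counts and their percentages of
#' the total, rounded to whole percent.
#'
#' @param n_preserved,n_shift,n_rescue event counts; rescue events are
#'   frameshifting exons sitting in a multi-exon rescue group, counted
#'   separately from plain shifts.
#' @return data frame `class`, `n`, `percent`.
#' @export
frame_summary <- function(n_preserved, n_shift, n_rescue) {
  total <- n_preserved + n_shift + n_rescue
  if (total == 0) stop("no events to summarize")
  data.frame(
    class = c("preserved", "shift", "rescue"),
    n = c(n_preserved, n_shift, n_rescue),
    percent = round(100 * c(n_preserved, n_shift, n_rescue) / total)
  )
}

#' Full consequence annotation for a set of events
#'
#' Maps each event to 5'UTR/CDS/3'UTR, computes the frame consequence of
#' CDS cassette exons, finds multi-exon rescue groups, and attaches
#' everything to the event table. Frame is `NA` outside CDS cassette
#' exons.
#'
#' @param events data frame with `event_id`, `gene_id`, `type`,
#'   `seg_start0`, `seg_end0`, `delta_psi`.
#' @param ann a [genome_annotation()].
#' @return the event table with `region`, `frame`, `rescue_group_id`
#'   columns added; rescue-group members have `frame == "rescue-group"`.
#' @export
annotate_consequences <- function(events, ann) {
  events$length <- events$seg_end0 - events$seg_start0
  events$region <- vapply(seq_len(nrow(events)), function(i)
    map_event_region(events[i, ], ann), character(1))
  events$frame <- NA_character_
  idx <- which(events$type == "CE" & events$region == "CDS")
  events$frame[idx] <- frame_consequence(events$length[idx])
  shifts <- events[idx, , drop = FALSE]
  shifts <- shifts[shifts$frame == "shift", , drop = FALSE]
  rg <- find_rescue_groups(shifts)
  events$rescue_group_id <- rg$rescue_group_id[
    match(events$event_id, rg$event_id)]
  events$frame[!is.na(events$rescue_group_id)] <- "rescue-group"
  events
}
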