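#' RBP motif model
#'
#' A motif is a named set of degenerate IUPAC k-mers (5-8 nt) together
#' with the regions it is scanned in. Motif identifiers are labels only;
#' definitions are supplied by the user (see [read_motifs()]).
#'
#' @param name motif name (e.g. an RBP symbol).
#' @param patterns character vector of IUPAC k-mers.
#' @param regions subset of `upstream_intron`, `exon`, `downstream_intron`.
#' @return a `motif_model` list.
#' @export
motif_model <- function(name, patterns,
                        regions = c("upstream_intron", "exon",
                                    "downstream_intron")) {
  patterns <- toupper(patterns)
  if (length(patterns) == 0) stop("motif needs at least one pattern")
  bad <- grepl("[^ACGTRYSWKMBDHVN]", patterns)
  if (any(bad)) stop("non-IUPAC pattern: ", patterns[bad][1])
  stopifnot(all(regions %in% c("upstream_intron", "exon",
                               "downstream_intron")))
  structure(list(name = name, patterns = patterns, regions = regions),
            class = "motif_model")
}

#' Scan a sequence for motif matches
#'
#' Reports every offset at which any of the motif's IUPAC patterns
#' matches, overlapping matches included. The sequence must be in sense
#' orientation; `N` in the sequence matches only an `N` in the pattern.
#'
#' @param sequence character scalar over `A,C,G,T,N`.
#' @param motif a [motif_model()].
#' @return data frame `offset0` (0-based from the region's 5' end),
#'   `match` (the matched subsequence), `pattern`.
#' @export
scan_motif <- function(sequence, motif) {
  sequence <- toupper(sequence)
  bad <- regexpr("[^ACGTN]", sequence)
  if (bad > 0) {
    stop(sprintf("non-ACGTN base '%s' at position %d",
                 substr(sequence, bad, bad), bad))
  }
  empty <- data.frame(offset0 = integer(), match = character(),
                      pattern = character())
  if (!nzchar(sequence)) return(empty)
  subj <- Biostrings::DNAString(sequence)
  hits <- lapply(motif$patterns, function(p) {
    if (nchar(p) > nchar(sequence)) return(NULL)
    m <- Biostrings::matchPattern(Biostrings::DNAString(p), subj,
                                  fixed = "subject")
    if (length(m) == 0) return(NULL)
    data.frame(offset0 = Biostrings::start(m) - 1L,
               match = as.character(m), pattern = p)
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) return(empty)
  out <- out[order(out$offset0, out$pattern), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sense-orientation sequence of an event region
#'
#' Extracts the exon, upstream intron or downstream intron of an
#' alternative segment, reading 5' to 3' in transcript orientation
#' (upstream = genomic left on `+`, genomic right on `-`).
#'
#' @param genome named `DNAStringSet`.
#' @param event list/row with `chrom`, `strand`, `seg_start0`, `seg_end0`.
#' @param region `"upstream_intron"`, `"exon"` or `"downstream_intron"`.
#' @param flank_nt intron flank length (default 250).
#' @return character scalar (possibly clipped at contig ends).
#' @export
event_region_sequence <- function(genome, event, region, flank_nt = 250) {
  iv <- region_interval0(event, region, length(genome[[event$chrom]]),
                         flank_nt)
  get_sequence(genome, event$chrom, iv[1], iv[2], event$strand)
}

# genomic forward-strand interval of a region (used for SNP overlap)
event_region_interval <- function(genome, event, region, flank_nt = 250) {
  region_interval0(event, region, length(genome[[event$chrom]]), flank_nt)
}

# forward-strand interval of an event region given only the contig length
region_interval0 <- function(event, region, chrom_len, flank_nt = 250) {
  left_is_upstream <- event$strand == "+"
  switch(region,
    exon = c(event$seg_start0, event$seg_end0),
    upstream_intron = if (left_is_upstream) {
      c(max(0, event$seg_start0 - flank_nt), event$seg_start0)
    } else {
      c(event$seg_end0, min(chrom_len, event$seg_end0 + flank_nt))
    },
    downstream_intron = if (left_is_upstream) {
      c(event$seg_end0, min(chrom_len, event$seg_end0 + flank_nt))
    } else {
      c(max(0, event$seg_start0 - flank_nt), event$seg_start0)
    },
    stop("unknown region: ", region)
  )
}

#' Regional motif enrichment between two event sets
#'
#' Presence/absence of at least one motif hit per event in the stated
#' region, compared between a foreground and a background event set with
#' Fisher's exact test. The log2 enrichment is
#' `log2(fg hit fraction / bg hit fraction)`; a zero fraction on either
#' side is capped at +/- `cap`.
#'
#' @param genome named `DNAStringSet`.
#' @param motif a [motif_model()].
#' @param fg_events,bg_events event tables (`chrom`, `strand`,
#'   `seg_start0`, `seg_end0`).
#' @param region region to scan.
#' @param flank_nt intron flank (default 250).
#' @param cap absolute cap for infinite log2 enrichment (default 20).
#' @return list `log2_enrichment`, `p`, `fg_hits`, `fg_n`, `bg_hits`,
#'   `bg_n`.
#' @export
regional_enrichment <- function(genome, motif, fg_events, bg_events,
                                region, flank_nt = 250, cap = 20) {
  stopifnot(nrow(fg_events) > 0, nrow(bg_events) > 0)
  has_hit <- function(events) {
    vapply(seq_len(nrow(events)), function(i) {
      seq <- event_region_sequence(genome, events[i, ], region, flank_nt)
      nrow(scan_motif(seq, motif)) > 0
    }, logical(1))
  }
  fg <- has_hit(fg_events); bg <- has_hit(bg_events)
  tab <- matrix(c(sum(fg), sum(!fg), sum(bg), sum(!bg)), nrow = 2)
  p <- stats::fisher.test(tab)$p.value
  ff <- mean(fg); bf <- mean(bg)
  l2 <- if (ff == 0 && bf == 0) 0
  else if (bf == 0) cap
  else if (ff == 0) -cap
  else log2(ff / bf)
  list(log2_enrichment = l2, p = p, fg_hits = sum(fg), fg_n = length(fg),
       bg_hits = sum(bg), bg_n = length(bg))
}

#' Motif x region enrichment table with BH adjustment
#'
#' Runs [regional_enrichment()] for every motif over its declared
#' regions and adjusts p-values (Benjamini-Hochberg) across all
#' (motif, region) pairs.
#'
#' @param genome named `DNAStringSet`.
#' @param motifs list of [motif_model()]s.
#' @param fg_events,bg_events event tables.
#' @param flank_nt intron flank.
#' @return data frame `motif`, `region`, `log2_enrichment`, `p`, `p_adj`.
#' @export
motif_enrichment_table <- function(genome, motifs, fg_events, bg_events,
                                   flank_nt = 250) {
  rows <- list()
  for (m in motifs) {
    for (r in m$regions) {
      e <- regional_enrichment(genome, m, fg_events, bg_events, r, flank_nt)
      rows[[length(rows) + 1]] <- data.frame(
        motif = m$name, region = r,
        log2_enrichment = e$log2_enrichment, p = e$p,
        fg_hits = e$fg_hits, fg_n = e$fg_n,
        bg_hits = e$bg_hits, bg_n = e$bg_n
      )
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Effect of a SNP on motif matching
#'
#' Classifies a SNP as disrupting, creating or not affecting a motif in a
#' genomic window. The window is padded by `k - 1` on both sides so
#' matches overlapping the window edge are seen. `disrupt`: some match
#' covers the SNP with the REF allele but none does with ALT; `create`:
#' the reverse; `none` otherwise.
#'
#' @param genome named `DNAStringSet`.
#' @param chrom,pos0 SNP location (0-based, forward strand).
#' @param ref,alt alleles (forward strand).
#' @param motif a [motif_model()].
#' @param window_start0,window_end0 scanned window (forward strand).
#' @param strand orientation in which the motif is matched.
#' @return `"disrupt"`, `"create"` or `"none"`.
#' @export
snp_motif_effect <- function(genome, chrom, pos0, ref, alt, motif,
                             window_start0, window_end0, strand = "+") {
  if (pos0 < window_start0 || pos0 >= window_end0) {
    stop("SNP not inside the scanned window")
  }
  kmax <- max(nchar(motif$patterns))
  L <- length(genome[[chrom]])
  ws <- max(0, window_start0 - (kmax - 1))
  we <- min(L, window_end0 + (kmax - 1))
  fwd <- get_sequence(genome, chrom, ws, we, "+")
  rel <- pos0 - ws + 1  # 1-based position of the SNP in fwd
  if (substr(fwd, rel, rel) != ref) {
    stop(sprintf("REF allele mismatch at %s:%d (genome %s, VCF %s)",
                 chrom, pos0 + 1, substr(fwd, rel, rel), ref))
  }
  alt_fwd <- fwd
  substr(alt_fwd, rel, rel) <- alt
  orient <- function(s) if (strand == "-") revcomp(s) else s
  n <- nchar(fwd)
  snp_sense0 <- if (strand == "-") n - rel else rel - 1  # 0-based, sense
  covers <- function(hits) {
    if (nrow(hits) == 0) return(FALSE)
    k <- nchar(hits$pattern)
    any(hits$offset0 <= snp_sense0 & snp_sense0 < hits$offset0 + k)
  }
  ref_cov <- covers(scan_motif(orient(fwd), motif))
  alt_cov <- covers(scan_motif(orient(alt_fwd), motif))
  if (ref_cov && !alt_cov) "disrupt"
  else if (!ref_cov && alt_cov) "create"
  else "none"
}

#' Events whose motif landscape is changed by SNPs
#'
#' For every (event, SNP, motif) combination where the SNP falls in one
#' of the motif's scanned regions of the event, calls
#' [snp_motif_effect()] and reports per-event effects plus the
#' deduplicated count of events with at least one disrupt/create call.
#'
#' @param genome named `DNAStringSet`.
#' @param events event table (`event_id`, `chrom`, `strand`,
#'   `seg_start0`, `seg_end0`).
#' @param snps SNP data frame (`chrom`, `pos0` or `pos`, `ref`, `alt`).
#' @param motifs list of [motif_model()]s.
#' @param flank_nt intron flank (default 250).
#' @return list `n_affected_events`, `effects` (data frame `event_id`,
#'   `motif`, `region`, `chrom`, `pos`, `effect`).
#' @export
count_affected_events <- function(genome, events, snps, motifs,
                                  flank_nt = 250) {
  eff <- data.frame(event_id = character(), motif = character(),
                    region = character(), chrom = character(),
                    pos = integer(), effect = character())
  if (nrow(snps) == 0 || nrow(events) == 0) {
    return(list(n_affected_events = 0L, effects = eff))
  }
  if (!"pos0" %in% names(snps)) snps$pos0 <- snps$pos - 1L
  rows <- list()
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    sub <- snps[snps$chrom == ev$chrom, , drop = FALSE]
    if (nrow(sub) == 0) next
    for (m in motifs) {
      for (r in m$regions) {
        iv <- event_region_interval(genome, ev, r, flank_nt)
        inside <- which(sub$pos0 >= iv[1] & sub$pos0 < iv[2])
        for (j in inside) {
          e <- snp_motif_effect(genome, ev$chrom, sub$pos0[j], sub$ref[j],
                                sub$alt[j], m, iv[1], iv[2], ev$strand)
          if (e != "none") {
            rows[[length(rows) + 1]] <- data.frame(
              event_id = ev$event_id, motif = m$name, region = r,
              chrom = ev$chrom, pos = sub$pos0[j] + 1L, effect = e
            )
          }
        }
      }
    }
  }
  if (length(rows) > 0) eff <- do.call(rbind, rows)
  list(n_affected_events = length(unique(eff$event_id)), effects = eff)
}
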