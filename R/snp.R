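#' Positional class of a SNP relative to an alternative exon
#'
#' Windows follow the standard splice-regulatory annotation: positions
#' within `ss_window` (default 15) nt of a splice site — on either the
#' intronic or the exonic side — are splice-site adjacent; intronic
#' positions between `ss_window` and `intron_window` (default 500) nt
#' from the exon edge are intronic; exon-interior positions more than
#' `ss_exon_window` nt from both edges are exonic; everything further
#' away is `outside`. Upstream/downstream and acceptor (3'ss) / donor
#' (5'ss) are in transcript orientation: on the minus strand the genomic
#' left/right roles flip.
#'
#' @param pos0 0-based SNP position (forward strand).
#' @param exon_start0,exon_end0 the alternative exon, 0-based half-open.
#' @param strand `"+"` or `"-"`.
#' @param chrom,exon_chrom optional chromosome names; when both given and
#'   different, the class is `outside`.
#' @param ss_window intronic splice-site window in nt (default 15).
#' @param ss_exon_window exonic-side splice-site window (default 15).
#' @param intron_window outer intronic window in nt (default 500).
#' @return list `category` (one of `intronic_upstream`, `ss3_adjacent`,
#'   `exonic`, `ss5_adjacent`, `intronic_downstream`, `outside`) and
#'   `distance` (nt to the nearest exon edge; first base on either side
#'   of the edge is distance 1; 0 for `outside` on another chromosome).
#' @export
classify_snp_position <- function(pos0, exon_start0, exon_end0, strand,
                                  chrom = NULL, exon_chrom = NULL,
                                  ss_window = 15, ss_exon_window = 15,
                                  intron_window = 500) {
  if (!is.null(chrom) && !is.null(exon_chrom) && chrom != exon_chrom) {
    return(list(category = "outside", distance = NA_real_))
  }
  stopifnot(strand %in% c("+", "-"))
  # acceptor (3'ss) is the genomic-left edge on +, right edge on -
  if (pos0 >= exon_start0 && pos0 < exon_end0) {
    d_left <- pos0 - exon_start0 + 1  # 1 = first exonic base
    d_right <- exon_end0 - pos0
    d <- min(d_left, d_right)
    near_left <- d_left <= d_right
    if (d <= ss_exon_window) {
      acceptor_side <- if (strand == "+") near_left else !near_left
      return(list(category = if (acceptor_side) "ss3_adjacent"
                  else "ss5_adjacent", distance = d))
    }
    return(list(category = "exonic", distance = d))
  }
  left <- pos0 < exon_start0
  d <- if (left) exon_start0 - pos0 else pos0 - exon_end0 + 1
  if (d > intron_window) return(list(category = "outside", distance = d))
  upstream <- if (strand == "+") left else !left  # transcript orientation
  if (d <= ss_window) {
    # intronic side of the acceptor (upstream intron) or donor (downstream)
    return(list(category = if (upstream) "ss3_adjacent" else "ss5_adjacent",
                distance = d))
  }
  list(category = if (upstream) "intronic_upstream"
       else "intronic_downstream", distance = d)
}

#' Per-event SNP counts by positional category
#'
#' @param snps data frame with `chrom`, `pos0` (or `pos`, 1-based).
#' @param event list/row with `chrom`, `seg_start0`, `seg_end0`, `strand`.
#' @param ... window parameters passed to [classify_snp_position()].
#' @return named integer vector `(n_intronic_up, n_ss3, n_exonic, n_ss5,
#'   n_intronic_down, n_total)`; the total is the sum of the five
#'   categories (SNPs classified `outside` are not counted).
#' @export
per_event_snp_counts <- function(snps, event, ...) {
  if (!"pos0" %in% names(snps)) snps$pos0 <- snps$pos - 1L
  cats <- vapply(seq_len(nrow(snps)), function(i) {
    classify_snp_position(snps$pos0[i], event$seg_start0, event$seg_end0,
                          event$strand, chrom = snps$chrom[i],
                          exon_chrom = event$chrom, ...)$category
  }, character(1))
  n <- c(
    n_intronic_up = sum(cats == "intronic_upstream"),
    n_ss3 = sum(cats == "ss3_adjacent"),
    n_exonic = sum(cats == "exonic"),
    n_ss5 = sum(cats == "ss5_adjacent"),
    n_intronic_down = sum(cats == "intronic_downstream")
  )
  c(n, n_total = sum(n))
}

#' SNP density per 1000 nt
#'
#' @param n_snps SNP count in the region.
#' @param region_length_nt region length (>= 1).
#' @return SNPs per kilobase.
#' @export
snp_density_per_kb <- function(n_snps, region_length_nt) {
  if (any(region_length_nt < 1)) stop("region length must be >= 1")
  n_snps / region_length_nt * 1000
}

#' Chi-square enrichment of SNP density in a region vs. a baseline
#'
#' 2x2 chi-square (SNP vs non-SNP positions x near-exon vs global) with
#' 1 df and no continuity correction, comparing the local SNP density
#' around alternative exons with a genome-wide baseline.
#'
#' @param n_near,len_near_nt SNP count and total length of the local
#'   regions.
#' @param n_global,len_global_nt baseline SNP count and genome length.
#' @return list `chi2`, `p`, `density_near`, `density_global` (per kb).
#' @export
enrichment_chi2 <- function(n_near, len_near_nt, n_global, len_global_nt) {
  stopifnot(n_near >= 0, n_global >= 0, len_near_nt > 0, len_global_nt > 0,
            n_near <= len_near_nt, n_global <= len_global_nt)
  tab <- matrix(c(n_near, len_near_nt - n_near,
                  n_global, len_global_nt - n_global), nrow = 2)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 1)) {
    warning("expected cell count < 1: chi-square approximation is poor",
            call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ht$statistic), p = ht$p.value,
       density_near = snp_density_per_kb(n_near, len_near_nt),
       density_global = snp_density_per_kb(n_global, len_global_nt))
}

#' Genes with splice-site-adjacent SNPs on significant events
#'
#' @param snps SNP data frame (`chrom`, `pos0` or `pos`).
#' @param events event table with `event_id`, `gene_id`, `chrom`,
#'   `strand`, `seg_start0`, `seg_end0`, `significant`.
#' @param ... window parameters passed to [classify_snp_position()].
#' @return character vector of gene ids having at least one
#'   splice-site-adjacent SNP on a significant event.
#' @export
flag_splice_site_snp_genes <- function(snps, events, ...) {
  if (nrow(snps) == 0 || nrow(events) == 0) return(character(0))
  if (!"pos0" %in% names(snps)) snps$pos0 <- snps$pos - 1L
  sig <- events[!is.na(events$significant) & events$significant, ,
                drop = FALSE]
  flagged <- character(0)
  for (i in seq_len(nrow(sig))) {
    ev <- sig[i, ]
    sub <- snps[snps$chrom == ev$chrom, , drop = FALSE]
    for (j in seq_len(nrow(sub))) {
      cl <- classify_snp_position(sub$pos0[j], ev$seg_start0, ev$seg_end0,
                                  ev$strand, ...)
      if (cl$category %in% c("ss3_adjacent", "ss5_adjacent")) {
        flagged <- c(flagged, ev$gene_id)
        break
      }
    }
  }
  sort(unique(flagged))
}

#' Count CpG dinucleotides destroyed by SNPs
#'
#' A SNP destroys a CpG site when the reference context on the genome
#' forward strand is CpG (C at the SNP position followed by G, or G at
#' the SNP position preceded by C) and substituting the ALT allele yields
#' a non-CpG dinucleotide. CpG is strand-symmetric, so the forward strand
#' suffices. SNPs at contig edges where the context is truncated are not
#' called and are counted in `n_no_context`.
#'
#' @param snps data frame with `chrom`, `pos0` (or `pos`), `ref`, `alt`.
#' @param genome named `DNAStringSet`.
#' @return list `calls` (logical per SNP: CpG destroyed), `n_no_context`.
#' @export
count_cpg_loss <- function(snps, genome) {
  if (!"pos0" %in% names(snps)) snps$pos0 <- snps$pos - 1L
  n_trunc <- 0L
  calls <- vapply(seq_len(nrow(snps)), function(i) {
    chrom <- snps$chrom[i]; p <- snps$pos0[i]
    L <- length(genome[[chrom]])
    if (p <= 0 || p >= L - 1) {
      n_trunc <<- n_trunc + 1L
      return(FALSE)
    }
    ctx <- get_sequence(genome, chrom, p - 1L, p + 2L, "+")
    ref <- substr(ctx, 2, 2)
    if (ref != snps$ref[i]) {
      stop(sprintf("reference mismatch at %s:%d (genome %s, VCF %s)",
                   chrom, p + 1L, ref, snps$ref[i]))
    }
    before <- substr(ctx, 1, 1); after <- substr(ctx, 3, 3)
    is_cpg <- (ref == "C" && after == "G") || (ref == "G" && before == "C")
    if (!is_cpg) return(FALSE)
    alt <- snps$alt[i]
    still_cpg <- (alt == "C" && after == "G") || (alt == "G" && before == "C")
    !still_cpg
  }, logical(1))
  if (n_trunc > 0) {
    message(n_trunc, " SNP(s) at contig edges skipped (no context)")
  }
  list(calls = calls, n_no_context = n_trunc)
}

#' Per-gene counts of destroyed CpG sites within event windows
#'
#' @param snps SNP data frame.
#' @param events event table (`gene_id`, `chrom`, `strand`, `seg_start0`,
#'   `seg_end0`).
#' @param genome named `DNAStringSet`.
#' @param ... window parameters passed to [classify_snp_position()].
#' @return data frame `gene_id`, `n_cpg_lost` (genes with >= 1 loss).
#' @export
cpg_loss_per_gene <- function(snps, events, genome, ...) {
  if (nrow(snps) == 0 || nrow(events) == 0) {
    return(data.frame(gene_id = character(), n_cpg_lost = integer()))
  }
  if (!"pos0" %in% names(snps)) snps$pos0 <- snps$pos - 1L
  loss <- count_cpg_loss(snps, genome)$calls
  counts <- list()
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    sub <- which(snps$chrom == ev$chrom & loss)
    for (j in sub) {
      cl <- classify_snp_position(snps$pos0[j], ev$seg_start0,
                                  ev$seg_end0, ev$strand, ...)
      if (cl$category != "outside") {
        key <- paste(ev$gene_id, snps$chrom[j], snps$pos0[j])
        counts[[key]] <- ev$gene_id
      }
    }
  }
  if (length(counts) == 0) {
    return(data.frame(gene_id = character(), n_cpg_lost = integer()))
  }
  tab <- table(unlist(counts, use.names = FALSE))
  data.frame(gene_id = names(tab), n_cpg_lost = as.integer(tab),
             row.names = NULL)
}
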