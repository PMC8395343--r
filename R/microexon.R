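#' Detect microexons in an annotation
#'
#' Microexons are internal exons of 3-30 nt. Internal means neither the
#' first nor the last exon of its transcript; exons are deduplicated by
#' genomic coordinates, so the output does not depend on transcript order
#' in the input.
#'
#' @param ann a [genome_annotation()].
#' @param min_length,max_length inclusive length bounds (defaults 3, 30).
#' @return data frame `chrom`, `start0`, `end0`, `length`, `gene_id`.
#' @export
detect_microexons <- function(ann, min_length = 3, max_length = 30) {
  res <- lapply(unique(ann$exons$transcript_id), function(tx) {
    e <- ann$exons[ann$exons$transcript_id == tx, , drop = FALSE]
    e <- e[order(e$start0), , drop = FALSE]
    if (nrow(e) < 3) return(NULL)
    e <- e[-c(1, nrow(e)), , drop = FALSE]
    g <- ann$transcripts$gene_id[match(tx, ann$transcripts$transcript_id)]
    data.frame(chrom = gene_chrom(ann, g), start0 = e$start0,
               end0 = e$end0, gene_id = g)
  })
  ex <- do.call(rbind, res)
  if (is.null(ex)) {
    return(data.frame(chrom = character(), start0 = integer(),
                      end0 = integer(), length = integer(),
                      gene_id = character()))
  }
  ex <- unique(ex)
  ex$length <- ex$end0 - ex$start0
  ex <- ex[ex$length >= min_length & ex$length <= max_length, , drop = FALSE]
  ex <- ex[order(ex$chrom, ex$start0), c("chrom", "start0", "end0",
                                         "length", "gene_id")]
  rownames(ex) <- NULL
  ex
}

#' Summarize inclusion of a curated target-exon list
#'
#' Given quantified events and a list of target exon coordinates (e.g.
#' curated splicing-factor target microexons), reports group-level mean
#' PSI over the targets and flags events preferentially skipped in one
#' group (significant events whose delta PSI points toward exclusion in
#' that group).
#'
#' @param events quantified events with `event_id`, `chrom`, `seg_start0`,
#'   `seg_end0`, `psi_g1`, `psi_g2`, `delta_psi`, `significant`.
#' @param targets data frame `chrom`, `start0`, `end0`.
#' @return list with `mean_psi` (named numeric: `g1`, `g2`), `events`
#'   (the matched target events with a `skipped_in` column: `"group1"`,
#'   `"group2"` or `NA`).
#' @export
summarize_target_inclusion <- function(events, targets) {
  key <- function(c, s, e) paste(c, s, e, sep = ":")
  hit <- key(events$chrom, events$seg_start0, events$seg_end0) %in%
    key(targets$chrom, targets$start0, targets$end0)
  sub <- events[hit, , drop = FALSE]
  if (nrow(sub) == 0) {
    warning("no quantified events match the target list", call. = FALSE)
    return(list(mean_psi = c(g1 = NA_real_, g2 = NA_real_),
                events = sub))
  }
  sub$skipped_in <- ifelse(
    !is.na(sub$significant) & sub$significant,
    ifelse(sub$delta_psi < 0, "group1", "group2"),
    NA_character_
  )
  list(
    mean_psi = c(g1 = mean(sub$psi_g1, na.rm = TRUE),
                 g2 = mean(sub$psi_g2, na.rm = TRUE)),
    events = sub
  )
}

#' Correlation between splicing-factor expression and target inclusion
#'
#' Spearman rank correlation between per-sample expression of a splicing
#' factor and the per-sample mean PSI of its target exons, with a
#' seeded permutation p-value (two-sided, permuting the PSI vector).
#'
#' @param factor_expression numeric vector, one value per sample.
#' @param psi numeric vector of matching per-sample mean target PSI.
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed.
#' @return list `rho`, `p`, `n_perm`; `rho` is `NA` (flagged) when either
#'   vector is constant.
#' @export
expression_inclusion_correlation <- function(factor_expression, psi,
                                             n_perm = 10000, seed = 1) {
  stopifnot(length(factor_expression) == length(psi))
  if (length(psi) < 4) stop("at least 4 paired samples required")
  if (stats::sd(factor_expression) == 0 || stats::sd(psi) == 0) {
    warning("constant input vector: correlation undefined", call. = FALSE)
    return(list(rho = NA_real_, p = NA_real_, n_perm = 0L))
  }
  rho <- stats::cor(factor_expression, psi, method = "spearman")
  old <- local_seed(seed)
  on.exit(old())
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    r <- stats::cor(factor_expression, sample(psi), method = "spearman")
    if (abs(r) >= abs(rho) - 1e-12) exceed <- exceed + 1L
  }
  list(rho = rho, p = (exceed + 1) / (n_perm + 1), n_perm = n_perm)
}

#' Per-sample PSI values for a set of events
#'
#' Per-sample (not pooled) PSI, used for sample-level summaries such as
#' the expression-inclusion correlation.
#'
#' @param counts long-format junction counts.
#' @param event_ids events to include (default: all).
#' @return data frame `sample`, `mean_psi` (mean over events with
#'   defined per-sample PSI).
#' @export
per_sample_mean_psi <- function(counts, event_ids = NULL) {
  if (!is.null(event_ids)) {
    counts <- counts[counts$event_id %in% event_ids, , drop = FALSE]
  }
  counts$psi <- ifelse(counts$inc + counts$exc > 0,
                       counts$inc / (counts$inc + counts$exc), NA_real_)
  agg <- stats::aggregate(psi ~ sample, counts, mean, na.rm = TRUE,
                          na.action = stats::na.pass)
  names(agg) <- c("sample", "mean_psi")
  agg
}
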