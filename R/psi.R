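#' Pooled PSI estimate for one group of samples
#'
#' Percent spliced in (PSI) is estimated by pooling junction counts across
#' the samples of a group: `PSI = sum(inc) / (sum(inc) + sum(exc))`.
#' Pooling (rather than averaging per-sample ratios) keeps the estimate
#' stable at low per-sample depth.
#'
#' @param inc,exc non-negative integer vectors of per-sample inclusion and
#'   exclusion junction counts.
#' @return PSI in `[0,1]`, or `NA` when all counts are zero (the event is
#'   unquantifiable in this group).
#' @export
estimate_psi <- function(inc, exc) {
  stopifnot(length(inc) == length(exc), all(inc >= 0), all(exc >= 0))
  tot <- sum(inc) + sum(exc)
  if (tot == 0) return(NA_real_)
  sum(inc) / tot
}

#' Between-group PSI difference
#'
#' @param psi_g1,psi_g2 group PSI estimates.
#' @param digits rounding used for reporting (3 decimals, matching the
#'   precision at which PSI tables are usually printed).
#' @return `psi_g1 - psi_g2`, rounded.
#' @export
delta_psi <- function(psi_g1, psi_g2, digits = 3) {
  round(psi_g1 - psi_g2, digits)
}

#' Monte-Carlo posterior probability of a directional PSI change
#'
#' Each group's PSI gets an independent Beta posterior under a Jeffreys
#' prior, `Beta(sum(inc) + 1/2, sum(exc) + 1/2)` on pooled counts. The
#' probability is the fraction of posterior draws in which the group
#' difference exceeds `threshold` in the direction of the point estimate
#' (draws for a zero point estimate are scored against a positive
#' difference, which by symmetry gives ~0.5).
#'
#' @param inc1,exc1,inc2,exc2 per-sample counts for groups 1 and 2.
#' @param n_draws number of posterior draws (>= 1000).
#' @param seed RNG seed; the draw is reproducible given the seed.
#' @param threshold minimal |difference| a draw must exceed to count
#'   (default 0, i.e. P(sign agreement)).
#' @return probability in `[0,1]`, or `NA` if either group is
#'   unquantifiable.
#' @export
dpsi_probability <- function(inc1, exc1, inc2, exc2, n_draws = 10000,
                             seed = 1, threshold = 0) {
  stopifnot(n_draws >= 1000)
  p1 <- estimate_psi(inc1, exc1)
  p2 <- estimate_psi(inc2, exc2)
  if (is.na(p1) || is.na(p2)) return(NA_real_)
  point <- p1 - p2
  old <- local_seed(seed)
  on.exit(old())
  d <- stats::rbeta(n_draws, sum(inc1) + 0.5, sum(exc1) + 0.5) -
    stats::rbeta(n_draws, sum(inc2) + 0.5, sum(exc2) + 0.5)
  if (point >= 0) mean(d > threshold) else mean(d < -threshold)
}

# run code under a local RNG state
local_seed <- function(seed) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
}

#' Significance filter and effect-size category for one event
#'
#' An event is significant when `|dpsi| > dpsi_cutoff` and
#' `probability > prob_cutoff` (defaults 0.1 and 0.9). Significant events
#' are labelled `strong`/`moderate` `inclusion`/`exclusion`; the
#' strong/moderate boundary sits at `|dpsi| >= strong_cutoff` (default
#' 0.5). Non-significant events get category `"none"`.
#'
#' @param dpsi PSI difference (group1 - group2).
#' @param probability posterior probability from [dpsi_probability()].
#' @param dpsi_cutoff,prob_cutoff,strong_cutoff filter thresholds.
#' @return list with `significant` (logical) and `category` (character).
#' @export
classify_event <- function(dpsi, probability, dpsi_cutoff = 0.1,
                           prob_cutoff = 0.9, strong_cutoff = 0.5) {
  if (is.na(dpsi) || is.na(probability)) {
    return(list(significant = NA, category = NA_character_))
  }
  sig <- abs(dpsi) > dpsi_cutoff && probability > prob_cutoff
  cat <- if (!sig) {
    "none"
  } else {
    paste(if (abs(dpsi) >= strong_cutoff) "strong" else "moderate",
          if (dpsi > 0) "inclusion" else "exclusion")
  }
  list(significant = sig, category = cat)
}

#' Classify the topology of an alternative-splicing event
#'
#' Compares the event's alternative segment against the transcripts of its
#' gene:
#' * `CE` (cassette exon): the segment is a whole exon of one isoform and
#'   absent from another isoform that shares the flanking exons;
#' * `IR` (intron retention): the segment is a whole intron of one isoform
#'   and fully contained in an exon of another;
#' * `alt5ss`/`alt3ss`: two isoforms share one exon boundary but differ at
#'   the donor (5'ss) or acceptor (3'ss) side; the segment is the
#'   extension. Donor/acceptor are in transcript orientation.
#'
#' @param event list or one-row data frame with `gene_id`, `seg_start0`,
#'   `seg_end0`.
#' @param ann a [genome_annotation()].
#' @return one of `"CE"`, `"IR"`, `"alt5ss"`, `"alt3ss"`, or `NA` if the
#'   topology cannot be resolved.
#' @export
classify_event_type <- function(event, ann) {
  gene <- event$gene_id
  txs <- ann$transcripts$transcript_id[ann$transcripts$gene_id == gene]
  if (length(txs) == 0) {
    warning("gene not in annotation: ", gene, call. = FALSE)
    return(NA_character_)
  }
  strand <- gene_strand(ann, gene)
  s <- event$seg_start0
  e <- event$seg_end0
  exons_of <- function(tx) {
    x <- ann$exons[ann$exons$transcript_id == tx, , drop = FALSE]
    x[order(x$start0), , drop = FALSE]
  }
  ex_list <- lapply(txs, exons_of)
  names(ex_list) <- txs

  has_exact_exon <- vapply(ex_list, function(x)
    any(x$start0 == s & x$end0 == e), logical(1))
  # CE: exact internal exon in one isoform, absent in another
  for (tx in txs[has_exact_exon]) {
    x <- ex_list[[tx]]
    i <- which(x$start0 == s & x$end0 == e)
    if (i == 1 || i == nrow(x)) next  # terminal exon, not a cassette
    for (other in setdiff(txs, tx)) {
      y <- ex_list[[other]]
      covers <- any(y$end0 <= s) && any(y$start0 >= e)
      absent <- !any(y$start0 < e & y$end0 > s)
      if (covers && absent) return("CE")
    }
  }
  # IR: segment is an intron of one isoform, inside an exon of another
  for (tx in txs) {
    x <- ex_list[[tx]]
    if (nrow(x) < 2) next
    introns <- cbind(x$end0[-nrow(x)], x$start0[-1])
    if (any(introns[, 1] == s & introns[, 2] == e)) {
      for (other in setdiff(txs, tx)) {
        y <- ex_list[[other]]
        if (any(y$start0 < s & y$end0 > e)) return("IR")
      }
    }
  }
  # alt 5'/3' splice sites: segment spans the difference between two exon
  # boundaries; same start + different end, or same end + different start
  for (tx in txs) {
    x <- ex_list[[tx]]
    for (other in setdiff(txs, tx)) {
      y <- ex_list[[other]]
      for (i in seq_len(nrow(x))) {
        same_start <- which(y$start0 == x$start0[i] & y$end0 != x$end0[i])
        for (j in same_start) {
          lo <- min(x$end0[i], y$end0[j]); hi <- max(x$end0[i], y$end0[j])
          if (lo == s && hi == e) {
            # boundary varies at genomic right edge
            return(if (strand == "+") "alt5ss" else "alt3ss")
          }
        }
        same_end <- which(y$end0 == x$end0[i] & y$start0 != x$start0[i])
        for (j in same_end) {
          lo <- min(x$start0[i], y$start0[j]); hi <- max(x$start0[i], y$start0[j])
          if (lo == s && hi == e) {
            return(if (strand == "+") "alt3ss" else "alt5ss")
          }
        }
      }
    }
  }
  warning("unresolvable topology for event in gene ", gene, call. = FALSE)
  NA_character_
}

#' Quantify a table of splicing events
#'
#' Runs the full event-level quantification: pooled per-group PSI, delta
#' PSI, Monte-Carlo posterior probability, significance filter and
#' category, for every event in a long-format junction-count table.
#' Events with all-zero counts in a group are marked unquantifiable
#' (`NA` PSI) and never significant.
#'
#' @param counts long-format counts (`event_id`, `sample`, `inc`, `exc`).
#' @param groups named vector mapping samples to exactly two group labels;
#'   group 1 is the first level in sorted order unless `group_levels` is
#'   given.
#' @param group_levels optional length-2 character vector fixing which
#'   group is "group 1".
#' @param n_draws,seed passed to [dpsi_probability()]; each event draws
#'   from an event-specific substream derived from `seed`.
#' @param dpsi_cutoff,prob_cutoff,strong_cutoff passed to
#'   [classify_event()].
#' @param prob_threshold passed as `threshold` to [dpsi_probability()].
#' @return data frame with one row per event: `event_id`, `psi_g1`,
#'   `psi_g2`, `delta_psi`, `probability`, `significant`, `category`.
#' @export
quantify_events <- function(counts, groups, group_levels = NULL,
                            n_draws = 10000, seed = 1,
                            dpsi_cutoff = 0.1, prob_cutoff = 0.9,
                            strong_cutoff = 0.5, prob_threshold = 0) {
  if (is.data.frame(groups)) {
    groups <- stats::setNames(as.character(groups$group),
                              as.character(groups$sample))
  }
  lv <- if (is.null(group_levels)) sort(unique(groups)) else group_levels
  stopifnot(length(lv) == 2)
  counts$group <- unname(groups[counts$sample])
  if (any(is.na(counts$group))) stop("samples without group assignment")
  events <- unique(counts$event_id)
  res <- lapply(seq_along(events), function(k) {
    ev <- events[k]
    sub <- counts[counts$event_id == ev, , drop = FALSE]
    g1 <- sub[sub$group == lv[1], ]
    g2 <- sub[sub$group == lv[2], ]
    p1 <- estimate_psi(g1$inc, g1$exc)
    p2 <- estimate_psi(g2$inc, g2$exc)
    dp <- if (is.na(p1) || is.na(p2)) NA_real_ else delta_psi(p1, p2)
    pr <- dpsi_probability(g1$inc, g1$exc, g2$inc, g2$exc,
                           n_draws = n_draws, seed = seed + k,
                           threshold = prob_threshold)
    cl <- classify_event(dp, pr, dpsi_cutoff, prob_cutoff, strong_cutoff)
    data.frame(event_id = ev,
               psi_g1 = round(p1, 3), psi_g2 = round(p2, 3),
               delta_psi = dp, probability = pr,
               significant = cl$significant, category = cl$category)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
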