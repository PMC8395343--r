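#' Find canonical miRNA seed-match sites in a 3'UTR
#'
#' Canonical seed classes: a `6mer` site matches the reverse complement
#' of miRNA positions 2-7; `7mer-m8` extends the match to position 8;
#' `7mer-A1` is a 6mer with an `A` in the UTR opposite miRNA position 1
#' (i.e. immediately 3' of the seed match); `8mer` has both. Each matched
#' locus is reported once with its highest-priority class
#' (8mer > 7mer-m8 > 7mer-A1 > 6mer).
#'
#' @param mirna_sequence mature miRNA, 5' to 3', RNA or DNA alphabet
#'   (>= 8 nt, unambiguous seed).
#' @param utr_sequence 3'UTR sequence, 5' to 3' (DNA alphabet; U
#'   accepted).
#' @return data frame `offset0` (0-based start of the seed-matched
#'   region, including the m8 base when present), `site_type`.
#' @export
find_seed_sites <- function(mirna_sequence, utr_sequence) {
  m <- chartr("Uu", "Tt", toupper(mirna_sequence))
  m <- toupper(m)
  utr <- toupper(chartr("Uu", "Tt", utr_sequence))
  if (nchar(m) < 8) stop("miRNA must be at least 8 nt")
  seed <- substr(m, 2, 8)
  if (grepl("[^ACGT]", seed)) stop("ambiguous base in miRNA seed region")
  site6 <- revcomp(substr(m, 2, 7))   # matches miRNA 2-7
  comp8 <- revcomp(substr(m, 8, 8))   # UTR base opposite position 8
  hits <- integer(0)
  start <- 1
  repeat {
    i <- regexpr(site6, substr(utr, start, nchar(utr)), fixed = TRUE)
    if (i < 1) break
    hits <- c(hits, start + i - 1)    # 1-based start of 6mer match
    start <- start + i
  }
  if (length(hits) == 0) {
    return(data.frame(offset0 = integer(), site_type = character()))
  }
  out <- lapply(hits, function(i) {
    m8 <- i > 1 && substr(utr, i - 1, i - 1) == comp8
    a1 <- substr(utr, i + 6, i + 6) == "A"
    type <- if (m8 && a1) "8mer" else if (m8) "7mer-m8"
            else if (a1) "7mer-A1" else "6mer"
    data.frame(offset0 = (if (m8) i - 2L else i - 1L), site_type = type)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# total priority order over site classes
seed_site_priority <- function(type) {
  match(type, c("8mer", "7mer-m8", "7mer-A1", "6mer"))
}

#' Differentially expressed miRNAs between two groups
#'
#' Welch's t-test per miRNA on `log2(x + 1)`-transformed expression,
#' Benjamini-Hochberg adjusted. Direction is the sign of the group1 -
#' group2 mean difference on the log scale. All-zero miRNAs are skipped.
#'
#' @param expr an [expression_matrix()] of miRNAs x samples.
#' @param alpha significance level on the adjusted p (default 0.05).
#' @param group_levels optional length-2 vector fixing group 1.
#' @return data frame `mirna`, `log2fc`, `t`, `p`, `p_adj`, `direction`
#'   (+1/-1), `significant`.
#' @export
differential_mirnas <- function(expr, alpha = 0.05, group_levels = NULL) {
  lv <- if (is.null(group_levels)) sort(unique(expr$groups)) else group_levels
  g1 <- expr$groups == lv[1]
  g2 <- expr$groups == lv[2]
  stopifnot(sum(g1) >= 3, sum(g2) >= 3)
  keep <- rowSums(expr$values) > 0
  if (any(!keep)) message(sum(!keep), " all-zero miRNA(s) skipped")
  v <- log2(expr$values[keep, , drop = FALSE] + 1)
  rows <- lapply(rownames(v), function(id) {
    w <- welch_test(v[id, g1], v[id, g2])
    data.frame(mirna = id,
               log2fc = mean(v[id, g1]) - mean(v[id, g2]),
               t = w$t, p = w$p)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$direction <- ifelse(out$log2fc >= 0, 1L, -1L)
  out$significant <- out$p_adj < alpha
  rownames(out) <- NULL
  out
}

#' Candidate miRNA regulators of a gene
#'
#' miRNAs that are significantly differential in the required direction
#' and have at least one seed site of the required class (default 7mer
#' or better) in the gene's 3'UTR, ranked by site-class priority then
#' adjusted p-value.
#'
#' @param diff_mirnas output of [differential_mirnas()].
#' @param mirna_sequences named character vector of mature miRNA
#'   sequences.
#' @param utr_sequence the gene's 3'UTR.
#' @param required_direction `+1` (up in group 1) or `-1`.
#' @param min_site minimal site class (default `"7mer-m8"`; `"7mer-A1"`
#'   admits both 7mer classes).
#' @return data frame `mirna`, `best_site`, `offset0`, `log2fc`, `p_adj`,
#'   ranked.
#' @export
candidate_regulators <- function(diff_mirnas, mirna_sequences,
                                 utr_sequence, required_direction = 1,
                                 min_site = "7mer-A1") {
  max_rank <- seed_site_priority(min_site)
  sel <- diff_mirnas[diff_mirnas$significant &
                       diff_mirnas$direction == required_direction, ,
                     drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(sel))) {
    id <- sel$mirna[i]
    if (!id %in% names(mirna_sequences)) next
    sites <- find_seed_sites(mirna_sequences[[id]], utr_sequence)
    if (nrow(sites) == 0) next
    pr <- seed_site_priority(sites$site_type)
    best <- which.min(pr)
    if (pr[best] > max_rank) next
    rows[[length(rows) + 1]] <- data.frame(
      mirna = id, best_site = sites$site_type[best],
      offset0 = sites$offset0[best], log2fc = sel$log2fc[i],
      p_adj = sel$p_adj[i]
    )
  }
  if (length(rows) == 0) {
    return(data.frame(mirna = character(), best_site = character(),
                      offset0 = integer(), log2fc = numeric(),
                      p_adj = numeric()))
  }
  out <- do.call(rbind, rows)
  out <- out[order(seed_site_priority(out$best_site), out$p_adj), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
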