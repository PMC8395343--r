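#' Welch's unequal-variance two-sample t-test
#'
#' Thin wrapper around [stats::t.test()] (Welch-Satterthwaite degrees of
#' freedom, two-sided) with explicit conventions for degenerate input:
#' both groups constant with equal means gives `t = 0, p = 1`; both
#' constant with different means gives `p = 0` with `degenerate = TRUE`.
#'
#' @param x,y numeric vectors (>= 2 finite values each).
#' @return list `t`, `df`, `p`, `degenerate`.
#' @export
welch_test <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, df = NA_real_, p = 1, degenerate = TRUE))
    }
    return(list(t = sign(mean(x) - mean(y)) * Inf, df = NA_real_, p = 0,
                degenerate = TRUE))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, degenerate = FALSE)
}

#' Log2 fold change of two group means
#'
#' @param mean_g1,mean_g2 non-negative group means.
#' @param pseudocount added to both means before the ratio (default 1).
#' @return `log2((mean_g1 + pc) / (mean_g2 + pc))`.
#' @export
log2fc <- function(mean_g1, mean_g2, pseudocount = 1) {
  stopifnot(all(mean_g1 >= 0), all(mean_g2 >= 0), pseudocount > 0)
  log2((mean_g1 + pseudocount) / (mean_g2 + pseudocount))
}

#' Row-scaled expression matrix for heatmap display
#'
#' Per selected feature: `log2(x + 1)`, then center to mean 0 and scale
#' to unit variance across samples. Constant rows become all zeros and
#' are listed in the `"constant_features"` attribute.
#'
#' @param expr an [expression_matrix()].
#' @param features feature ids to include (all must exist).
#' @return numeric matrix, features x samples, with attribute
#'   `constant_features`.
#' @export
scale_heatmap_matrix <- function(expr, features) {
  stopifnot(length(features) > 0)
  missing <- setdiff(features, rownames(expr$values))
  if (length(missing) > 0) {
    stop("unknown feature id(s): ", paste(missing, collapse = ", "))
  }
  v <- log2(expr$values[features, , drop = FALSE] + 1)
  const <- apply(v, 1, stats::sd) == 0
  scaled <- t(apply(v, 1, function(r) {
    if (stats::sd(r) == 0) rep(0, length(r)) else (r - mean(r)) / stats::sd(r)
  }))
  dimnames(scaled) <- dimnames(v)
  attr(scaled, "constant_features") <- rownames(v)[const]
  scaled
}

#' Differential expression over an expression matrix
#'
#' Welch test per feature on `log2(x + 1)` values plus log2 fold change
#' of raw group means (pseudocount 1), BH-adjusted.
#'
#' @param expr an [expression_matrix()].
#' @param alpha significance level on adjusted p (default 0.05).
#' @param group_levels optional length-2 vector fixing group 1.
#' @return data frame `feature_id`, `log2fc`, `t`, `p`, `p_adj`,
#'   `significant`.
#' @export
differential_expression <- function(expr, alpha = 0.05,
                                    group_levels = NULL) {
  lv <- if (is.null(group_levels)) sort(unique(expr$groups)) else group_levels
  g1 <- expr$groups == lv[1]
  g2 <- expr$groups == lv[2]
  v <- log2(expr$values + 1)
  rows <- lapply(rownames(v), function(id) {
    w <- welch_test(v[id, g1], v[id, g2])
    data.frame(feature_id = id,
               log2fc = log2fc(mean(expr$values[id, g1]),
                               mean(expr$values[id, g2])),
               t = w$t, p = w$p)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < alpha
  rownames(out) <- NULL
  out
}

#' Intersect a native gene list with an external (e.g. GWAS) list
#'
#' Maps external symbols to native symbols through an ortholog map and
#' intersects with the supplied native genes. Symbol comparison is
#' case-insensitive. External symbols mapping to several native genes
#' are kept and flagged ambiguous.
#'
#' @param native_genes character vector of native gene symbols (e.g.
#'   alternatively spliced genes).
#' @param external_genes character vector of external symbols.
#' @param ortholog_map data frame `external_symbol`, `native_symbol`.
#' @return data frame `native_symbol`, `external_symbol`, `ambiguous`,
#'   deduplicated.
#' @export
intersect_gene_lists <- function(native_genes, external_genes,
                                 ortholog_map) {
  empty <- data.frame(native_symbol = character(),
                      external_symbol = character(), ambiguous = logical())
  if (nrow(ortholog_map) == 0) {
    warning("empty ortholog map: empty intersection", call. = FALSE)
    return(empty)
  }
  map <- ortholog_map[toupper(ortholog_map$external_symbol) %in%
                        toupper(external_genes), , drop = FALSE]
  if (nrow(map) == 0) return(empty)
  amb <- toupper(map$external_symbol) %in%
    toupper(map$external_symbol)[duplicated(toupper(map$external_symbol))]
  hit <- toupper(map$native_symbol) %in% toupper(native_genes)
  out <- data.frame(native_symbol = map$native_symbol[hit],
                    external_symbol = map$external_symbol[hit],
                    ambiguous = amb[hit])
  out <- unique(out)
  rownames(out) <- NULL
  out
}
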