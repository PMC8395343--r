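# Fixtures and independent oracles shared across the test files. The
# oracles are deliberately naive re-derivations (enumeration, regex,
# textbook formulas) kept separate from the implementation paths they
# check.

# --- tiny annotation builders ----------------------------------------------

# one gene, one or two transcripts, explicit exon coordinates
toy_annotation <- function(exons_by_tx, strand = "+", cds = NULL,
                           chrom = "chrT", gene_id = "g1") {
  txs <- names(exons_by_tx)
  genome_annotation(
    genes = data.frame(gene_id = gene_id, symbol = toupper(gene_id),
                       chrom = chrom, strand = strand),
    transcripts = data.frame(transcript_id = txs, gene_id = gene_id),
    exons = do.call(rbind, lapply(txs, function(tx) {
      m <- exons_by_tx[[tx]]
      data.frame(transcript_id = tx, start0 = m[, 1], end0 = m[, 2])
    })),
    cds = if (is.null(cds)) NULL else
      data.frame(transcript_id = txs, cds_start0 = cds[1], cds_end0 = cds[2])
  )
}

# annotation with one single-transcript gene per requested internal-exon
# length; terminal exons have length 150 (a multiple of 3)
lengths_annotation <- function(lengths, cds = TRUE) {
  genes <- sprintf("L%04d", seq_along(lengths))
  exons <- do.call(rbind, lapply(seq_along(lengths), function(i) {
    l <- lengths[i]
    data.frame(transcript_id = paste0(genes[i], "_t"),
               start0 = c(0, 400, 400 + l + 400),
               end0 = c(150, 400 + l, 400 + l + 400 + 150))
  }))
  genome_annotation(
    genes = data.frame(gene_id = genes, symbol = genes,
                       chrom = paste0("chr", genes), strand = "+"),
    transcripts = data.frame(transcript_id = paste0(genes, "_t"),
                             gene_id = genes),
    exons = exons,
    cds = if (cds) data.frame(transcript_id = paste0(genes, "_t"),
                              cds_start0 = 10,
                              cds_end0 = 400 + lengths + 400 + 140)
    else NULL
  )
}

random_genome <- function(chrom, n, seed = 1) {
  withr::with_seed(seed, {
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
               collapse = "")
  })
  g <- Biostrings::DNAStringSet(s)
  names(g) <- chrom
  g
}

# --- independent oracles ----------------------------------------------------

# P(X > Y) for X ~ Beta(a1,b1), Y ~ Beta(a2,b2) by numerical integration
beta_diff_prob_oracle <- function(a1, b1, a2, b2) {
  stats::integrate(function(y) {
    stats::dbeta(y, a2, b2) * stats::pbeta(y, a1, b1, lower.tail = FALSE)
  }, 0, 1, rel.tol = 1e-10)$value
}

# two-sided exact binomial by full enumeration (minimum-likelihood rule)
binom_two_sided_oracle <- function(k, n, p) {
  d <- stats::dbinom(0:n, n, p)
  sum(d[d <= d[k + 1] * (1 + 1e-7)])
}

# 2x2 chi-square from the textbook formula (no continuity correction)
chi2_oracle <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# Welch t and p from the textbook formulas
welch_oracle <- function(x, y) {
  v1 <- stats::var(x) / length(x)
  v2 <- stats::var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# IUPAC k-mer to regular expression, for the brute-force motif oracle
iupac_regex <- function(pattern) {
  map <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
           S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
           D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGTN]")
  paste(map[strsplit(pattern, "")[[1]]], collapse = "")
}

# all match offsets (0-based) of a set of IUPAC patterns via regex
regex_scan_oracle <- function(sequence, patterns) {
  hits <- lapply(patterns, function(p) {
    k <- nchar(p)
    if (k > nchar(sequence)) return(integer(0))
    starts <- seq_len(nchar(sequence) - k + 1)
    windows <- substring(sequence, starts, starts + k - 1)
    starts[grepl(paste0("^", iupac_regex(p), "$"), windows)] - 1L
  })
  sort(unique(unlist(hits)))
}

# exhaustive permutations of 1..n (n <= 7)
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1)
  out <- list()
  for (p in sub) {
    for (i in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(p, n, after = i)
    }
  }
  out
}
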