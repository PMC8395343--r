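test_that("positional classification follows the window definitions", {
  # exon [1000, 1100) on the plus strand
  cl <- function(p, strand = "+") {
    classify_snp_position(p, 1000, 1100, strand)$category
  }
  expect_equal(cl(990), "ss3_adjacent")           # 10 nt into upstream intron
  expect_equal(cl(900), "intronic_upstream")      # 100 nt upstream
  expect_equal(cl(1100 + 99), "intronic_downstream")
  expect_equal(cl(1104), "ss5_adjacent")          # 5 nt into downstream intron
  expect_equal(cl(1050), "exonic")                # exon interior
  expect_equal(cl(1005), "ss3_adjacent")          # exonic side of acceptor
  expect_equal(cl(1095), "ss5_adjacent")          # exonic side of donor
  expect_equal(cl(400), "outside")                # beyond 500 nt
  expect_equal(cl(1100 + 500), "outside")         # d = 501

  # boundary positions
  expect_equal(cl(1000 - 15), "ss3_adjacent")     # d = 15
  expect_equal(cl(1000 - 16), "intronic_upstream")
  expect_equal(cl(1000 - 500), "intronic_upstream")

  # minus strand: upstream/downstream and acceptor/donor flip
  expect_equal(cl(990, "-"), "ss5_adjacent")
  expect_equal(cl(900, "-"), "intronic_downstream")
  expect_equal(cl(1104, "-"), "ss3_adjacent")
  expect_equal(cl(1100 + 99, "-"), "intronic_upstream")

  # different chromosome
  expect_equal(classify_snp_position(1050, 1000, 1100, "+",
                                     chrom = "chrA",
                                     exon_chrom = "chrB")$category,
               "outside")
})

test_that("per-event SNP counts total the five categories", {
  ev <- list(event_id = "e", chrom = "c", strand = "+",
             seg_start0 = 1000, seg_end0 = 1100)
  # plant the five printed category patterns of two published example
  # rows and check the total recomputes
  mk <- function(n_up, n_ss3, n_ex, n_ss5, n_down) {
    pos <- c(
      if (n_up > 0) 1000 - 100 - seq_len(n_up) else integer(0),
      if (n_ss3 > 0) 1000 - seq_len(n_ss3) else integer(0),
      if (n_ex > 0) 1040 + seq_len(n_ex) else integer(0),
      if (n_ss5 > 0) 1100 + seq_len(n_ss5) - 1 else integer(0),
      if (n_down > 0) 1100 + 100 + seq_len(n_down) else integer(0)
    )
    data.frame(chrom = rep("c", length(pos)), pos0 = pos)
  }
  n <- per_event_snp_counts(mk(11, 2, 0, 1, 5), ev)
  expect_equal(unname(n), c(11, 2, 0, 1, 5, 19))
  n <- per_event_snp_counts(mk(6, 3, 3, 1, 14), ev)
  expect_equal(unname(n), c(6, 3, 3, 1, 14, 27))
  n <- per_event_snp_counts(mk(0, 0, 0, 0, 0), ev)
  expect_equal(unname(n), rep(0, 6))
})

test_that("SNP density normalizes per kilobase and scales linearly", {
  expect_equal(snp_density_per_kb(3, 600), 5)
  expect_equal(snp_density_per_kb(0, 100), 0)
  expect_equal(snp_density_per_kb(1, 1000), 1)
  expect_equal(snp_density_per_kb(4 * 7, 500), 4 * snp_density_per_kb(7, 500))
  expect_error(snp_density_per_kb(1, 0), "length")
})

test_that("2x2 chi-square matches the hand formula and is monotone in counts", {
  e <- enrichment_chi2(200, 1e5, 1000, 1e6)
  expect_equal(e$chi2,
               chi2_oracle(200, 1e5 - 200, 1000, 1e6 - 1000),
               tolerance = 1e-9)

  # equal densities: no signal
  e0 <- enrichment_chi2(100, 1e5, 1000, 1e6)
  expect_equal(e0$chi2, 0, tolerance = 1e-9)
  expect_equal(e0$p, 1)

  # doubling counts and lengths fixes the density ratio, grows chi2
  e2 <- enrichment_chi2(400, 2e5, 2000, 2e6)
  expect_gt(e2$chi2, e$chi2)

  # random tables vs the hand formula
  withr::with_seed(3, {
    for (i in 1:25) {
      a <- sample(1:500, 1); la <- a + sample(1000:50000, 1)
      b <- sample(1:500, 1); lb <- b + sample(1000:50000, 1)
      expect_equal(enrichment_chi2(a, la, b, lb)$chi2,
                   chi2_oracle(a, la - a, b, lb - b), tolerance = 1e-9)
    }
  })
})

test_that("splice-site SNP genes are flagged only on significant events", {
  events <- data.frame(
    event_id = c("e1", "e2"), gene_id = c("gA", "gB"), chrom = "c",
    strand = "+", seg_start0 = c(1000, 5000), seg_end0 = c(1100, 5100),
    significant = c(TRUE, TRUE)
  )
  # donor +3 SNP on e1; deep intronic SNP near e2
  snps <- data.frame(chrom = "c", pos0 = c(1102, 5200))
  expect_equal(flag_splice_site_snp_genes(snps, events), "gA")
  # non-significant event is never flagged
  events$significant <- c(FALSE, FALSE)
  expect_equal(flag_splice_site_snp_genes(snps, events), character(0))
  expect_equal(flag_splice_site_snp_genes(snps[0, , drop = FALSE], events),
               character(0))
})

test_that("CpG-loss calls require a reference CpG destroyed by the ALT allele", {
  g <- Biostrings::DNAStringSet("TTACGTTCGTACAT")
  #                              123456789
  names(g) <- "c"
  snp <- function(pos0, ref, alt) {
    data.frame(chrom = "c", pos0 = pos0, ref = ref, alt = alt)
  }
  # A[C]G, C>T destroys the CpG
  expect_true(count_cpg_loss(snp(3, "C", "T"), g)$calls)
  # T[C]G from the C side, C[G]T from the G side
  expect_true(count_cpg_loss(snp(7, "C", "T"), g)$calls)
  expect_true(count_cpg_loss(snp(8, "G", "A"), g)$calls)
  # A[C]A context: no CpG to destroy
  expect_false(count_cpg_loss(snp(11, "C", "T"), g)$calls)
  # a substitution that leaves a CpG in place is not a loss: C[C>G]G
  g2 <- Biostrings::DNAStringSet("TCCGT")
  names(g2) <- "c"
  expect_false(count_cpg_loss(snp(2, "C", "G"), g2)$calls)
  # contig edge: no call, counted
  r <- count_cpg_loss(snp(0, "T", "A"), g)
  expect_false(r$calls)
  expect_equal(r$n_no_context, 1L)
  # reference mismatch is an input inconsistency
  expect_error(count_cpg_loss(snp(3, "G", "T"), g), "mismatch")
})

test_that("planted SNP categories and CpG losses are recovered exactly", {
  sn <- demo_bundle$snps
  ev <- demo_bundle$events
  pos <- sn[sn$purpose == "positional", ]
  got <- vapply(seq_len(nrow(pos)), function(i) {
    e <- ev[ev$event_id == pos$event_id[i], ]
    classify_snp_position(pos$pos0[i], e$seg_start0, e$seg_end0,
                          e$strand)$category
  }, character(1))
  expect_identical(got, pos$category)

  cpg <- cpg_loss_per_gene(sn, ev, demo_bundle$genome)
  planted <- table(sn$event_id[sn$purpose == "cpg_loss"])
  planted_genes <- ev$gene_id[match(names(planted), ev$event_id)]
  expect_setequal(cpg$gene_id, planted_genes)
  expect_equal(cpg$n_cpg_lost[match(planted_genes, cpg$gene_id)],
               as.integer(planted))
})
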