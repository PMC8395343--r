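test_that("motif scanning finds direct and IUPAC-degenerate matches", {
  m <- motif_model("m", "GGACGGA")
  h <- scan_motif("AAGGACGGAA", m)
  expect_equal(h$offset0, 2)
  expect_equal(h$match, "GGACGGA")

  m2 <- motif_model("m2", "GGNGGA")
  h2 <- scan_motif("TTGGAGGATT", m2)
  expect_equal(h2$offset0, 2)

  expect_equal(nrow(scan_motif("ACG", motif_model("m", "GGACGGA"))), 0)
  expect_error(scan_motif("ACGXGT", m), "position 4")
})

test_that("overlapping matches are all reported", {
  m <- motif_model("m", "AAA")
  expect_equal(scan_motif("AAAAA", m)$offset0, c(0, 1, 2))
})

test_that("motif scanner agrees with a regex brute-force oracle", {
  motifs <- list(
    motif_model("a", c("GGAGGAM", "RGAAGA")),
    motif_model("b", "CCYCCY"),
    motif_model("c", "WSNKM")
  )
  withr::with_seed(11, {
    for (i in 1:10) {
      s <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
                 collapse = "")
      for (m in motifs) {
        got <- sort(unique(scan_motif(s, m)$offset0))
        expect_identical(got, regex_scan_oracle(s, m$patterns))
      }
    }
  })
})

test_that("event region sequences read 5' to 3' in transcript orientation", {
  g <- Biostrings::DNAStringSet(paste(rep("ACGT", 100), collapse = ""))
  names(g) <- "c"
  ev_p <- list(chrom = "c", strand = "+", seg_start0 = 200, seg_end0 = 210)
  ev_m <- list(chrom = "c", strand = "-", seg_start0 = 200, seg_end0 = 210)
  expect_equal(event_region_sequence(g, ev_p, "exon", 50),
               get_sequence(g, "c", 200, 210, "+"))
  # upstream intron of a minus-strand event is genomic right
  up_m <- event_region_sequence(g, ev_m, "upstream_intron", 50)
  expect_equal(up_m, get_sequence(g, "c", 210, 260, "-"))
  expect_equal(nchar(up_m), 50)
})

test_that("regional enrichment separates planted foreground from background", {
  # 50 fg events with the motif planted, 50 bg events mostly without
  n <- 50
  motif <- motif_model("m", "GGACGGA", "exon")
  mk_events <- function(prefix, n, with_motif) {
    chars <- lapply(seq_len(n), function(i) {
      withr::with_seed(1000 + i + 31 * with_motif, {
        s <- sample(c("A", "T"), 60, replace = TRUE)  # no G/C background
      })
      if (with_motif) s[20:26] <- strsplit("GGACGGA", "")[[1]]
      paste(s, collapse = "")
    })
    g <- Biostrings::DNAStringSet(unlist(chars))
    names(g) <- paste0(prefix, seq_len(n))
    ev <- data.frame(event_id = names(g), chrom = names(g), strand = "+",
                     seg_start0 = 0, seg_end0 = 60)
    list(genome = g, events = ev)
  }
  fg <- mk_events("fg", n, TRUE)
  bg <- mk_events("bg", n, FALSE)
  # move 10% of fg to no-motif and 10% of bg to motif
  swap <- mk_events("fgswap", 5, FALSE)
  fg$genome[1:5] <- swap$genome
  swap2 <- mk_events("bgswap", 5, TRUE)
  bg$genome[1:5] <- swap2$genome
  genome <- c(fg$genome, bg$genome)
  r <- regional_enrichment(genome, motif, fg$events, bg$events, "exon")
  expect_gt(r$log2_enrichment, 0)
  expect_lt(r$p, 0.01)
  expect_equal(r$fg_hits, 45)
  expect_equal(r$bg_hits, 5)

  # Fisher p agrees with the hypergeometric enumeration oracle
  oracle <- sum(dhyper(0:5, 50, 50, 50)) + sum(dhyper(45:50, 50, 50, 50))
  expect_equal(r$p, oracle, tolerance = 1e-9)

  # label swap flips the enrichment sign, keeps p
  r_sw <- regional_enrichment(genome, motif, bg$events, fg$events, "exon")
  expect_equal(r_sw$log2_enrichment, -r$log2_enrichment)
  expect_equal(r_sw$p, r$p)

  # identical sets: zero enrichment
  r_id <- regional_enrichment(genome, motif, fg$events, fg$events, "exon")
  expect_equal(r_id$log2_enrichment, 0)

  # empty fg fraction is capped, not infinite
  r_cap <- regional_enrichment(genome, motif, bg$events[6:50, ],
                               fg$events, "exon")
  expect_equal(r_cap$log2_enrichment, -20)
})

test_that("SNP motif effects distinguish disrupt, create and none", {
  motif <- motif_model("m", "GGAGGAM")
  base <- paste(rep("T", 40), collapse = "")
  mk <- function(core) {
    s <- paste0(substr(base, 1, 15), core,
                paste(rep("T", 40 - 15 - nchar(core)), collapse = ""))
    g <- Biostrings::DNAStringSet(s)
    names(g) <- "c"
    g
  }
  # intact match; G>A inside it breaks every pattern
  g <- mk("GGAGGAC")
  expect_equal(snp_motif_effect(g, "c", 18, "G", "A", motif, 10, 30), "disrupt")
  # broken match completed by the ALT allele
  g2 <- mk("GGAGGTC")
  expect_equal(snp_motif_effect(g2, "c", 20, "T", "A", motif, 10, 30), "create")
  # SNP outside any possible footprint
  expect_equal(snp_motif_effect(g, "c", 28, "T", "A", motif, 10, 30), "none")
  # allele/reference inconsistency is an error
  expect_error(snp_motif_effect(g, "c", 18, "C", "A", motif, 10, 30),
               "mismatch")
  # identical alleles can never change matching
  expect_equal(snp_motif_effect(g, "c", 18, "G", "G", motif, 10, 30), "none")
})

test_that("minus-strand motif effects are matched in sense orientation", {
  # sense GGAGGAC on the minus strand appears as GTCCTCC forward
  core <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString("GGAGGAC")))
  s <- paste0(strrep("T", 15), core, strrep("T", 18))
  g <- Biostrings::DNAStringSet(s)
  names(g) <- "c"
  motif <- motif_model("m", "GGAGGAM")
  # sense position 4 (a G) is forward position 15 + (7 - 4) = 18
  expect_equal(snp_motif_effect(g, "c", 18, "C", "T", motif, 10, 30,
                                strand = "-"), "disrupt")
})

test_that("planted motif effects in the demo bundle are recovered exactly", {
  aff <- count_affected_events(demo_bundle$genome, demo_bundle$events,
                               demo_bundle$snps, demo_bundle$motifs)
  truth <- demo_bundle$truth$motifs
  expect_equal(aff$n_affected_events, length(unique(truth$event_id)))
  got <- aff$effects[order(aff$effects$event_id), ]
  tr <- truth[order(truth$event_id), ]
  expect_equal(got$event_id, tr$event_id)
  expect_equal(got$effect, tr$effect)
  expect_equal(got$motif, tr$motif)

  # no SNPs: no affected events; duplicate SNPs in one event count once
  none <- count_affected_events(demo_bundle$genome, demo_bundle$events,
                                demo_bundle$snps[0, ], demo_bundle$motifs)
  expect_equal(none$n_affected_events, 0L)
})
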