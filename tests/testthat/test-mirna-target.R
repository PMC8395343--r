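test_that("seed-site classes follow the canonical definitions", {
  mir <- "UGGAAUGUAAAGAAGUAUGUAU"  # positions 2-8: GGAAUGU
  seed6_rc <- "CATTCC"             # revcomp of positions 2-7 (DNA)
  m8_rc <- "A"                     # revcomp of position 8 (U)

  # 8mer: revcomp(2-8) + A opposite position 1
  utr <- paste0("TTTT", m8_rc, seed6_rc, "A", "TTTT")
  s <- find_seed_sites(mir, utr)
  expect_equal(s$site_type, "8mer")
  expect_equal(s$offset0, 4)

  # 7mer-m8: match 2-8, no A
  utr <- paste0("TTTT", m8_rc, seed6_rc, "G", "TTTT")
  expect_equal(find_seed_sites(mir, utr)$site_type, "7mer-m8")

  # 7mer-A1: match 2-7 plus A, wrong m8 base
  utr <- paste0("TTTT", "G", seed6_rc, "A", "TTTT")
  expect_equal(find_seed_sites(mir, utr)$site_type, "7mer-A1")

  # 6mer only
  utr <- paste0("TTTT", "G", seed6_rc, "G", "TTTT")
  s <- find_seed_sites(mir, utr)
  expect_equal(s$site_type, "6mer")
  expect_equal(s$offset0, 5)

  # no complementarity
  expect_equal(nrow(find_seed_sites(mir, "TTTTTTTTTTTT")), 0)
  expect_error(find_seed_sites("UGNAAUGUAAAG", "TTTT"), "ambiguous")
  expect_error(find_seed_sites("UGGAA", "TTTT"), "at least 8")
})

test_that("seed matching agrees with brute-force substring search", {
  withr::with_seed(17, {
    for (i in 1:20) {
      mir <- paste(sample(c("A", "C", "G", "U"), 22, replace = TRUE),
                   collapse = "")
      utr <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                   collapse = "")
      got <- find_seed_sites(mir, utr)
      # oracle: locate the 6mer site by regex, then classify by context
      m <- chartr("U", "T", mir)
      site6 <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(substr(m, 2, 7))))
      comp8 <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(substr(m, 8, 8))))
      starts <- gregexpr(site6, utr, fixed = TRUE)[[1]]
      starts <- starts[starts > 0]
      types <- offs <- c()
      for (st in starts) {
        m8 <- st > 1 && substr(utr, st - 1, st - 1) == comp8
        a1 <- substr(utr, st + 6, st + 6) == "A"
        types <- c(types, if (m8 && a1) "8mer" else if (m8) "7mer-m8"
                   else if (a1) "7mer-A1" else "6mer")
        offs <- c(offs, if (m8) st - 2L else st - 1L)
      }
      expect_equal(got$offset0, as.integer(offs))
      expect_equal(got$site_type, as.character(types))
    }
  })
})

test_that("every matched locus receives exactly one site class", {
  withr::with_seed(23, {
    mir <- "UAGCUUAUCAGACUGAUGUUGA"
    utr <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                 collapse = "")
  })
  s <- find_seed_sites(mir, utr)
  expect_true(all(s$site_type %in% c("8mer", "7mer-m8", "7mer-A1", "6mer")))
  expect_false(any(duplicated(s$offset0)))
})

test_that("differential miRNA calls respect effect, direction and alpha", {
  d <- differential_mirnas(demo_bundle$mirna_expr)
  tr <- demo_bundle$truth$mirna
  planted_up <- tr$mirna[tr$log2fc > 0]
  expect_true(all(d$significant[d$mirna %in% planted_up]))
  expect_true(all(d$direction[d$mirna %in% planted_up] == 1))
  expect_true(all(d$direction[d$mirna == "mir_down"] == -1))

  # identical groups: never significant
  vals <- matrix(rep(c(5, 6, 7, 8, 9), each = 2), nrow = 1,
                 dimnames = list("m1", paste0("s", 1:10)))
  ex <- expression_matrix(vals, stats::setNames(
    rep(c("a", "b"), 5), paste0("s", 1:10)))
  d0 <- differential_mirnas(ex)
  expect_false(any(d0$significant))

  # alpha = 0 admits nothing
  d_none <- differential_mirnas(demo_bundle$mirna_expr, alpha = 0)
  expect_false(any(d_none$significant))
})

test_that("candidate regulators are the planted miRNAs, exactly", {
  d <- differential_mirnas(demo_bundle$mirna_expr)
  cand <- candidate_regulators(d, demo_bundle$mirna_seqs,
                               demo_bundle$utr, required_direction = 1)
  expect_setequal(cand$mirna, c("mir_up_a", "mir_up_b"))
  # the 8mer-site miRNA ranks first
  expect_equal(cand$mirna[1], "mir_up_a")
  expect_equal(cand$best_site[1], "8mer")
  # the elevated miRNA with only a 6mer site is excluded
  expect_false("mir_up_6mer" %in% cand$mirna)
  # the wrong-direction miRNA is excluded even though significant
  expect_false("mir_down" %in% cand$mirna)
})
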