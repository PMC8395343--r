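test_that("events localize to 5'UTR / CDS / 3'UTR in transcript orientation", {
  exons <- list(t1 = rbind(c(0, 100), c(200, 300), c(400, 500)))
  ann_p <- toy_annotation(exons, strand = "+", cds = c(350 + 60, 490))
  ev <- list(gene_id = "g1", seg_start0 = 200, seg_end0 = 300)
  expect_equal(map_event_region(ev, ann_p), "5UTR")

  ann_p2 <- toy_annotation(exons, strand = "+", cds = c(10, 90))
  expect_equal(map_event_region(ev, ann_p2), "3UTR")

  # same geometry, minus strand: sides flip
  ann_m <- toy_annotation(exons, strand = "-", cds = c(410, 490))
  expect_equal(map_event_region(ev, ann_m), "3UTR")

  ann_cds <- toy_annotation(exons, strand = "+", cds = c(10, 490))
  expect_equal(map_event_region(ev, ann_cds), "CDS")
  # overlap of CDS and UTR counts as CDS
  ann_ov <- toy_annotation(exons, strand = "+", cds = c(250, 490))
  expect_equal(map_event_region(ev, ann_ov), "CDS")

  ann_nc <- toy_annotation(exons, strand = "+")
  expect_true(is.na(map_event_region(ev, ann_nc)))
})

test_that("frame consequence is length mod 3", {
  expect_equal(frame_consequence(24), "preserved")
  expect_equal(frame_consequence(25), "shift")
  # two co-skipped exons with lengths 1 and 2 mod 3 jointly preserve
  expect_equal((97 + 98) %% 3, 0)
  expect_equal(frame_consequence(97 + 98), "preserved")
})

test_that("rescue grouping pairs complementary residues in the same direction", {
  ev <- function(id, gene, start, len, dpsi) {
    data.frame(event_id = id, gene_id = gene, seg_start0 = start,
               length = len, delta_psi = dpsi)
  }
  # lengths {7, 5}: residues 1 + 2 -> one pair
  g <- find_rescue_groups(rbind(ev("a", "g", 100, 7, 0.5),
                                ev("b", "g", 500, 5, 0.4)))
  expect_equal(nrow(g), 2)
  expect_equal(length(unique(g$rescue_group_id)), 1)

  # opposite delta-PSI signs: no group
  g <- find_rescue_groups(rbind(ev("a", "g", 100, 7, 0.5),
                                ev("b", "g", 500, 5, -0.4)))
  expect_equal(nrow(g), 0)

  # {4,4,4}: all residue 1; only the full triple sums to 0 mod 3
  # (brute force over subsets: 4+4=8, 4 alone -> not multiples of 3)
  g <- find_rescue_groups(rbind(ev("a", "g", 100, 4, 0.5),
                                ev("b", "g", 500, 4, 0.4),
                                ev("c", "g", 900, 4, 0.3)))
  expect_equal(sort(g$event_id), c("a", "b", "c"))
  expect_equal(length(unique(g$rescue_group_id)), 1)

  # frame-preserving exons are never grouped
  g <- find_rescue_groups(rbind(ev("a", "g", 100, 9, 0.5),
                                ev("b", "g", 500, 5, 0.4),
                                ev("c", "g", 900, 7, 0.3)))
  expect_false("a" %in% g$event_id)

  # different genes never mix
  g <- find_rescue_groups(rbind(ev("a", "g1", 100, 7, 0.5),
                                ev("b", "g2", 500, 5, 0.4)))
  expect_equal(nrow(g), 0)
})

test_that("random-skipping null counts internal CDS exon frames", {
  # every internal exon a multiple of 3
  ann <- lengths_annotation(c(30, 60, 90, 300))
  expect_equal(random_skipping_null(ann), 0)

  # uniform lengths 30..329: exactly 200 of 300 are not multiples of 3
  lens <- 30:329
  ann <- lengths_annotation(lens)
  expect_equal(random_skipping_null(ann),
               mean(lens %% 3 != 0))
  expect_lt(abs(random_skipping_null(ann) - 2 / 3), 0.02)

  # no internal CDS exons -> error
  ann_nc <- lengths_annotation(c(90, 91), cds = FALSE)
  expect_error(random_skipping_null(ann_nc), "internal CDS")
})

test_that("exact binomial test matches enumeration and published counts", {
  # mode of the distribution gives p = 1
  expect_equal(frameshift_enrichment_test(5, 10, 0.5), 1.0)

  # frameshift count well below a 0.66 null is overwhelmingly significant
  expect_lt(frameshift_enrichment_test(109, 259, 0.66), 1e-8)

  # full agreement with enumeration for n <= 25
  for (n in c(5, 10, 17, 25)) {
    for (k in unique(c(0, 1, n %/% 3, n %/% 2, n))) {
      for (p in c(0.25, 0.5, 0.66)) {
        expect_equal(frameshift_enrichment_test(k, n, p),
                     binom_two_sided_oracle(k, n, p), tolerance = 1e-12)
      }
    }
  }
  expect_error(frameshift_enrichment_test(1, 10, 0), "p_null")
})

test_that("frame summary yields whole-percent shares", {
  fs <- frame_summary(150, 109, 14)
  expect_equal(fs$percent, c(55, 40, 5))
  expect_equal(sum(fs$n), 273)
})

test_that("consequence annotation partitions CDS cassette exons", {
  events <- demo_bundle$events
  events$delta_psi <- events$psi_g1 - events$psi_g2  # planted direction
  cons <- annotate_consequences(events, demo_bundle$annotation)
  ce_cds <- cons[cons$type == "CE" & cons$region == "CDS" &
                   !is.na(cons$region), ]
  expect_true(all(!is.na(ce_cds$frame)))
  expect_true(all(is.na(cons$frame[cons$type != "CE"])))
  # preserved + shift + rescue partitions the defined-frame events
  expect_equal(sum(ce_cds$frame %in% c("preserved", "shift", "rescue-group")),
               nrow(ce_cds))
  # rescue members have non-multiple-of-3 lengths
  resc <- ce_cds[ce_cds$frame == "rescue-group", ]
  expect_true(all(resc$length %% 3 != 0))
  expect_equal(sort(resc$event_id), c("rg1a", "rg1b", "rg2a", "rg2b"))
})
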