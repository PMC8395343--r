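test_that("pooled PSI follows the count-ratio definition", {
  expect_equal(estimate_psi(c(10, 5), c(0, 0)), 1.0)
  expect_equal(estimate_psi(c(30, 30), c(10, 10)), 0.75)
  expect_true(is.na(estimate_psi(0, 0)))
})

test_that("delta PSI reproduces printed group differences", {
  # desk-scale recomputation from published group PSI pairs
  expect_equal(delta_psi(0.613, 0.103), 0.510)
  expect_equal(delta_psi(0.562, 0.863), -0.301)
  expect_equal(delta_psi(0.42, 0.42), 0)
})

test_that("posterior probability is calibrated, extreme when counts separate, and deterministic", {
  # identical counts: symmetry gives 0.5 within 3 Monte-Carlo SEs
  p_same <- dpsi_probability(c(50, 50), c(50, 50), c(50, 50), c(50, 50),
                             n_draws = 10000, seed = 11)
  expect_lt(abs(p_same - 0.5), 3 * sqrt(0.25 / 10000))

  # complete separation at depth 200 x 5
  p_sep <- dpsi_probability(rep(200, 5), rep(0, 5), rep(0, 5), rep(200, 5),
                            n_draws = 10000, seed = 12)
  expect_gt(p_sep, 0.999)

  expect_identical(
    dpsi_probability(c(30, 40), c(10, 15), c(20, 25), c(30, 20), seed = 13),
    dpsi_probability(c(30, 40), c(10, 15), c(20, 25), c(30, 20), seed = 13)
  )
  expect_true(is.na(dpsi_probability(0, 0, c(5), c(5))))
})

test_that("posterior probability matches numerically integrated Beta-difference probability", {
  cases <- list(
    list(i1 = c(80, 70), e1 = c(20, 30), i2 = c(40, 50), e2 = c(60, 50)),
    list(i1 = c(150, 160), e1 = c(50, 40), i2 = c(120, 110), e2 = c(80, 90)),
    list(i1 = c(30), e1 = c(70), i2 = c(55), e2 = c(45)),
    list(i1 = c(500), e1 = c(500), i2 = c(450), e2 = c(550))
  )
  for (cs in cases) {
    a1 <- sum(cs$i1) + 0.5; b1 <- sum(cs$e1) + 0.5
    a2 <- sum(cs$i2) + 0.5; b2 <- sum(cs$e2) + 0.5
    point <- sum(cs$i1) / (sum(cs$i1) + sum(cs$e1)) -
      sum(cs$i2) / (sum(cs$i2) + sum(cs$e2))
    oracle <- beta_diff_prob_oracle(a1, b1, a2, b2)
    if (point < 0) oracle <- 1 - oracle
    got <- dpsi_probability(cs$i1, cs$e1, cs$i2, cs$e2,
                            n_draws = 200000, seed = 21)
    expect_lt(abs(got - oracle), 0.01)
  }
})

test_that("probability is monotone in the separation of inclusion fractions", {
  tot <- 200
  incs <- seq(100, 180, by = 20)  # group 1 inclusion rises, group 2 mirrors
  probs <- vapply(incs, function(i) {
    dpsi_probability(i, tot - i, tot - i, i, n_draws = 50000, seed = 31)
  }, numeric(1))
  expect_true(all(diff(probs) >= 0))
})

test_that("significance filter and categories follow the dPSI/probability thresholds", {
  # published example rows
  a <- classify_event(0.510, 0.995)
  expect_true(a$significant)
  expect_equal(a$category, "strong inclusion")
  b <- classify_event(-0.301, 0.909)
  expect_true(b$significant)
  expect_equal(b$category, "moderate exclusion")
  c <- classify_event(-0.410, 0.95)
  expect_equal(c$category, "moderate exclusion")
  # boundary behaviour
  expect_false(classify_event(0.05, 0.99)$significant)
  expect_false(classify_event(0.5, 0.85)$significant)
  expect_equal(classify_event(0.1, 0.99)$significant, FALSE)  # strict >
  expect_equal(classify_event(0.5, 0.99)$category, "strong inclusion")
  expect_equal(classify_event(0.499, 0.99)$category, "moderate inclusion")
})

test_that("event topology is classified from isoform structure", {
  # cassette exon: present in tx1, absent in tx2
  ann <- toy_annotation(list(
    t1 = rbind(c(0, 100), c(200, 300), c(400, 500)),
    t2 = rbind(c(0, 100), c(400, 500))
  ))
  ev <- list(gene_id = "g1", seg_start0 = 200, seg_end0 = 300)
  expect_equal(classify_event_type(ev, ann), "CE")

  # intron retention: t2 keeps the intron inside one exon
  ann <- toy_annotation(list(
    t1 = rbind(c(0, 100), c(250, 350)),
    t2 = rbind(c(0, 350))
  ))
  ev <- list(gene_id = "g1", seg_start0 = 100, seg_end0 = 250)
  expect_equal(classify_event_type(ev, ann), "IR")

  # shared acceptor, different donors -> alt 5'ss on the plus strand
  ann <- toy_annotation(list(
    t1 = rbind(c(0, 100), c(200, 300), c(500, 600)),
    t2 = rbind(c(0, 100), c(200, 340), c(500, 600))
  ))
  ev <- list(gene_id = "g1", seg_start0 = 300, seg_end0 = 340)
  expect_equal(classify_event_type(ev, ann), "alt5ss")

  # the same genomic layout on the minus strand is an alt 3'ss
  ann_m <- toy_annotation(list(
    t1 = rbind(c(0, 100), c(200, 300), c(500, 600)),
    t2 = rbind(c(0, 100), c(200, 340), c(500, 600))
  ), strand = "-")
  expect_equal(classify_event_type(ev, ann_m), "alt3ss")

  # unresolvable topology
  ev_bad <- list(gene_id = "g1", seg_start0 = 123, seg_end0 = 177)
  expect_warning(got <- classify_event_type(ev_bad, ann), "unresolvable")
  expect_true(is.na(got))
})

test_that("quantify_events recovers planted PSI and delta on the demo bundle", {
  q <- quantify_events(demo_bundle$counts, demo_bundle$groups,
                       n_draws = 2000, seed = 41)
  m <- merge(q, demo_bundle$truth$events, by = "event_id")
  expect_equal(nrow(m), nrow(demo_bundle$truth$events))
  expect_true(all(abs(m$psi_g1.x - m$psi_g1.y) <= 0.08))
  expect_true(all(abs(m$psi_g2.x - m$psi_g2.y) <= 0.08))
  # strongly separated planted events must come out significant
  strong <- abs(m$psi_g1.y - m$psi_g2.y) >= 0.3
  expect_true(all(m$significant[strong]))
  # null events must not
  null <- m$psi_g1.y == m$psi_g2.y
  expect_true(all(!m$significant[null]))
})
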