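test_that("subtype rules follow the per-subtype adaptations", {
  # M1/M2: single Y2.64-C45.50 metric at 5 A in every condition
  r1 <- make_subtype_rule("M1", "active-apo")
  expect_equal(r1$components, "Y2.64-C45.50")
  expect_equal(r1$combiner, "single")
  expect_equal(r1$threshold_A, 5)
  expect_equal(r1$open_when, ">")
  expect_equal(make_subtype_rule("M2", "inactive-tio")$components,
    "Y2.64-C45.50")

  # M3: minimum of the Y2.64-C45.50 and K7.32-E45.49 distances
  r3 <- make_subtype_rule("M3", "inactive-tio")
  expect_equal(r3$combiner, "min-of")
  expect_setequal(r3$components, c("Y2.64-C45.50", "K7.32-E45.49"))

  # M4: ECL2-range rule only in the inactive-apo condition
  expect_equal(
    make_subtype_rule("M4", "inactive-apo")$components,
    "Y2.64-ECL2"
  )
  expect_equal(
    make_subtype_rule("M4", "active-ach")$components,
    "Y2.64-C45.50"
  )

  expect_error(make_subtype_rule("M5", "active-apo"))
  expect_error(make_subtype_rule("M1", "holo"))
  expect_error(pocket_rule("r", character(0)), "at least one")
  expect_error(pocket_rule("r", c("a", "b"), combiner = "single"), "exactly one")
  expect_error(pocket_rule("r", "a", threshold_A = 0), "positive")
})

test_that("classification applies strict threshold and min-of semantics", {
  t <- c(0, 0.2)
  rule <- make_subtype_rule("M1", "active-apo")
  s <- distance_series("Y2.64-C45.50", t, c(4.9, 5.1))
  st <- classify_states(s, rule)
  expect_equal(st$open, c(FALSE, TRUE))

  # exactly at threshold: closed under the strict comparator,
  # open under the >= dialect
  s5 <- distance_series("Y2.64-C45.50", t, c(5, 5))
  expect_equal(classify_states(s5, rule)$open, c(FALSE, FALSE))
  ge_rule <- make_subtype_rule("M1", "active-apo", open_when = ">=")
  expect_equal(classify_states(s5, ge_rule)$open, c(TRUE, TRUE))

  # M3-style: one component under threshold keeps the pocket closed
  m3 <- make_subtype_rule("M3", "active-apo")
  sa <- distance_series("Y2.64-C45.50", t, c(8, 8))
  sb <- distance_series("K7.32-E45.49", t, c(3, 7))
  expect_equal(classify_states(list(sa, sb), m3)$open, c(FALSE, TRUE))

  # errors name the missing component / mismatched grid
  expect_error(classify_states(list(sa), m3), "K7.32-E45.49")
  sb_shift <- distance_series("K7.32-E45.49", t + 0.1, c(3, 7))
  expect_error(classify_states(list(sa, sb_shift), m3), "time grid")
})

test_that("raising the threshold never increases the open fraction", {
  set.seed(7)
  s <- distance_series("Y2.64-C45.50", (0:499) * 0.2, runif(500, 0, 12))
  fracs <- vapply(seq(1, 11, by = 0.5), function(th) {
    rule <- pocket_rule("r", "Y2.64-C45.50", threshold_A = th)
    mean(classify_states(s, rule)$open)
  }, numeric(1))
  expect_true(all(diff(fracs) <= 0))
})

test_that("open fractions pool by frames, reporting both weightings", {
  mk <- function(n, n_open, rep, cond = "active-apo", sub = "M1") {
    state_series((seq_len(n) - 1) * 0.2,
      c(rep(TRUE, n_open), rep(FALSE, n - n_open)),
      rule = "r", replicate = rep, condition = cond, subtype = sub
    )
  }
  # all open -> 1
  expect_equal(open_fraction(mk(10, 10, "1"))$open_fraction, 1)

  # equal-length replicates: frame weighting equals mean of fractions
  eq <- open_fraction(list(mk(10, 2, "1"), mk(10, 4, "2")), "per-condition")
  expect_equal(eq$open_fraction, 0.3)
  expect_equal(eq$mean_of_fractions, 0.3)

  # unequal lengths: pooled = (10+90)/(100+300), means differ
  uneq <- open_fraction(
    list(mk(100, 10, "1"), mk(300, 90, "2")),
    "per-condition"
  )
  expect_equal(uneq$open_fraction, 0.25)
  expect_equal(uneq$mean_of_fractions, mean(c(0.1, 0.3)))
  expect_equal(uneq$n_frames, 400L)

  # per-subtype pooling sums numerators and denominators over conditions
  sub <- open_fraction(
    list(
      mk(100, 10, "1", "active-apo"), mk(100, 30, "1", "inactive-apo")
    ),
    "per-subtype"
  )
  expect_equal(sub$open_fraction, 40 / 200)
  expect_equal(sub$condition, "pooled")
})

test_that("distance histograms conserve counts in half-open bins", {
  s <- distance_series("d", c(0, 0.2, 0.4), c(1.0, 1.0, 3.0),
    condition = "active-apo", subtype = "M1"
  )
  h <- distance_histogram(s, bin_width_A = 2, range = c(0, 4))
  expect_equal(h$count, c(2, 1))
  expect_equal(h$bin_lo, c(0, 2))
  expect_equal(sum(h$count), 3)

  # additivity: pooled histogram equals the sum of per-replicate histograms
  set.seed(3)
  r1 <- distance_series("d", (0:99) * 0.2, runif(100, 0, 10),
    replicate = "1", condition = "c", subtype = "M1"
  )
  r2 <- distance_series("d", (0:149) * 0.2, runif(150, 0, 10),
    replicate = "2", condition = "c", subtype = "M1"
  )
  pooled <- distance_histogram(list(r1, r2), 0.5, range = c(0, 10))
  h1 <- distance_histogram(r1, 0.5, range = c(0, 10))
  h2 <- distance_histogram(r2, 0.5, range = c(0, 10))
  expect_equal(pooled$count, h1$count + h2$count)
  expect_equal(sum(pooled$count), 250)

  # a value exactly on the top data edge still lands in a bin
  s_edge <- distance_series("d", c(0, 0.2), c(1, 4))
  h_edge <- distance_histogram(s_edge, bin_width_A = 2)
  expect_equal(sum(h_edge$count), 2)

  expect_error(distance_histogram(list()), "no distance series")
  expect_error(distance_histogram(s, -1), "positive")
  expect_error(distance_histogram(s, 2, range = c(0, 2)), "outside")
})

test_that("classification operates on raw distances, not smoothed ones", {
  # spiky trace: one 10 A opening every 5 frames over a 3 A baseline.
  # Raw classification is 20% open; the 50-ns moving average levels the
  # spikes to ~4.4 A, below threshold everywhere
  t <- (0:499) * 0.2
  v <- rep(c(10, 3, 3, 3, 3), 100)
  s <- distance_series("Y2.64-C45.50", t, v)
  rule <- make_subtype_rule("M1", "active-apo")
  expect_equal(mean(classify_states(s, rule)$open), 0.2)
  sm <- moving_average(s, 50)
  sm_series <- distance_series("Y2.64-C45.50", t, sm$distance)
  expect_equal(mean(classify_states(sm_series, rule)$open), 0)

  # the pipeline classifies the raw trace: its open fraction is the raw one
  dir_in <- withr::local_tempdir()
  dir_out <- withr::local_tempdir()
  s_lab <- distance_series("Y2.64-C45.50", t, v,
    replicate = "1", condition = "active-apo", subtype = "M1"
  )
  write_distance_table(list(s_lab), file.path(dir_in, "dist_M1.csv"))
  res <- run_pocket_pipeline(dir_in, dir_out)
  expect_equal(res$summaries$by_replicate$open_fraction, 0.2)
})
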