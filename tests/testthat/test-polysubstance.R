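test_that("combination universes enumerate all non-empty subsets", {
  u3 <- combo_universe("collapsed")
  expect_equal(nrow(u3), 7)
  expect_equal(as.integer(table(u3$size)), c(3L, 3L, 1L))
  u5 <- combo_universe("dose")
  expect_equal(nrow(u5), 31)
  expect_false(anyDuplicated(u5$combo) > 0)
})

test_that("window classification uses aligned half-open 60-min bins", {
  # water at ZT 0.2 h and ethanol at ZT 0.8 h: one window, two substances
  ev <- make_events("m1", t_sec = c(0.2, 0.8) * 3600,
                    chamber = c("water", "etoh_5"))
  w <- classify_windows(ev, "collapsed")
  expect_equal(nrow(w), 1)
  expect_equal(w$combo, "water+ethanol")
  expect_equal(w$size, 2L)

  # events at 59 and 61 min land in different windows
  w2 <- classify_windows(
    make_events("m1", t_sec = c(59, 61) * 60, chamber = "water"),
    "collapsed"
  )
  expect_equal(nrow(w2), 2)
  expect_equal(w2$size, c(1L, 1L))
  expect_equal(w2$window, c(0L, 1L))

  # an event exactly on the boundary goes to the later window
  w3 <- classify_windows(make_events("m1", 3600, "water"), "collapsed")
  expect_equal(w3$window, 1L)

  # an only-water window is not polysubstance
  expect_equal(classify_windows(make_events("m1", 10, "water"),
                                "collapsed")$size, 1L)
  # zero-volume events do not create set membership
  w4 <- classify_windows(
    make_events("m1", c(10, 20), c("water", "fent_5"),
                volume_ul = c(5, 0)), "collapsed"
  )
  expect_equal(w4$combo, "water")
})

test_that("window classifier matches a brute-force re-bin", {
  ev <- random_events(200, seed = 42)
  for (mode in c("collapsed", "dose")) {
    got <- classify_windows(ev, mode)[c("tag", "day", "window", "combo",
                                        "size")]
    want <- brute_force_windows(ev, mode) |>
      dplyr::mutate(day = as.integer(day), window = as.integer(window),
                    size = as.integer(size)) |>
      dplyr::arrange(tag, day, window)
    expect_equal(as.data.frame(got), as.data.frame(want), label = mode)
  }
  # window partition: every event is in exactly one window
  w <- classify_windows(ev, "collapsed")
  n_per_window <- vapply(seq_len(nrow(w)), function(i) {
    sum(ev$tag == w$tag[i] &
          ev$t_sec >= ((w$day[i] - 1) * 24 + w$window[i]) * 3600 &
          ev$t_sec < ((w$day[i] - 1) * 24 + w$window[i] + 1) * 3600)
  }, numeric(1))
  expect_equal(sum(n_per_window), nrow(ev))
})

test_that("dose-resolved windows collapse to substance-mode windows", {
  ev <- random_events(300, seed = 9)
  dose <- classify_windows(ev, "dose")
  collapsed <- classify_windows(ev, "collapsed")
  map <- stats::setNames(sip_chambers()$substance, sip_chambers()$chamber)
  re <- vapply(strsplit(dose$combo, "+", fixed = TRUE), function(cs) {
    subs <- unique(unname(map[cs]))
    ord <- match(subs, c("water", "ethanol", "fentanyl"))
    paste(subs[order(ord)], collapse = "+")
  }, character(1))
  expect_equal(re, collapsed$combo)
})

test_that("combination distributions tally windows and stay conformable", {
  w <- tibble::tibble(
    tag = c("a", "a", "b"), day = 1L, window = 0:2,
    mode = "collapsed",
    combo = c("water", "water", "water+ethanol"),
    size = c(1L, 1L, 2L)
  )
  d <- combination_distribution(w)
  expect_equal(nrow(d), 7)
  expect_equal(d$n[d$combo == "water"], 2L)
  expect_equal(d$n[d$combo == "water+ethanol"], 1L)
  expect_equal(sum(d$n), 3L)

  # grouped tallies partition the pooled tally
  groups <- tibble::tibble(tag = c("a", "b"), group = c("g1", "g2"))
  dg <- combination_distribution(w, groups)
  pooled <- dg |> dplyr::group_by(combo) |>
    dplyr::summarise(n = sum(n), .groups = "drop") |>
    dplyr::arrange(combo)
  expect_equal(pooled, dplyr::arrange(d[c("combo", "n")], combo))

  # brute-force recount on a random fixture
  ev <- random_events(200, seed = 7)
  wr <- classify_windows(ev, "collapsed")
  dr <- combination_distribution(wr)
  bf <- table(brute_force_windows(ev, "collapsed")$combo)
  for (cb in names(bf)) {
    expect_equal(dr$n[dr$combo == cb], unname(bf[[cb]]))
  }
  expect_equal(sum(dr$n), nrow(wr))
})

test_that("distribution comparisons are chi-squared on the kept categories", {
  mk <- function(g, combos, ns) {
    u <- combo_universe("collapsed")
    u$group <- g
    u$n <- 0L
    u$n[match(combos, u$combo)] <- ns
    u[c("group", "combo", "size", "n")]
  }
  # identical distributions -> chi-squared 0
  d1 <- mk("g1", c("water", "ethanol"), c(10L, 5L))
  d2 <- mk("g2", c("water", "ethanol"), c(10L, 5L))
  expect_equal(compare_distributions(list(d1, d2), "inner")$statistic, 0)

  # diagonal table -> chi-squared 20 with expected counts of 5
  d3 <- mk("g1", "water", 10L)
  d4 <- mk("g2", "ethanol", 10L)
  r <- compare_distributions(list(d3, d4), "inner")
  expect_equal(r$statistic, 20)
  expect_equal(r$df1, 1)

  # adding an all-zero category changes nothing (it is dropped)
  d5 <- mk("g1", c("water", "ethanol"), c(8L, 3L))
  d6 <- mk("g2", c("water", "ethanol"), c(2L, 9L))
  base <- compare_distributions(list(d5, d6), "inner")
  expect_equal(base$statistic,
               chi_square_test(rbind(c(8, 3), c(2, 9)))$statistic)

  # three-group comparison works (cluster analyses)
  d7 <- mk("g3", c("water", "ethanol"), c(5L, 5L))
  r3 <- compare_distributions(list(d5, d6, d7), "inner")
  expect_equal(r3$df1, 2)

  # outer ring aggregates by set size
  d8 <- mk("g1", c("water", "ethanol", "water+ethanol"), c(4L, 6L, 2L))
  d9 <- mk("g2", c("water", "water+ethanol"), c(5L, 5L))
  ro <- compare_distributions(list(d8, d9), "outer")
  expect_equal(ro$statistic,
               chi_square_test(rbind(c(10, 2), c(5, 5)))$statistic)

  expect_error(compare_distributions(d1, "inner"), "two groups")
})
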