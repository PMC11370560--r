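# balanced long-format fixture for the mixed design
mixed_fixture <- function(n_per_group = c(4, 4), a = 3, seed = 1,
                          effect = 0) {
  withr::with_seed(seed, {
    subj <- sprintf("s%02d", seq_len(sum(n_per_group)))
    grp <- rep(paste0("g", seq_along(n_per_group)), n_per_group)
    df <- tidyr::expand_grid(subject = subj, within = paste0("w", seq_len(a)))
    df$group <- grp[match(df$subject, subj)]
    df$value <- rnorm(nrow(df)) + effect * (df$group == "g1") *
      as.integer(factor(df$within))
    df
  })
}

test_that("pooled t test matches the hand formula", {
  r <- t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(round(r$statistic, 3), -3.674)
  expect_equal(r$df1, 4)
  # antisymmetry
  r2 <- t_test(c(4, 5, 6), c(1, 2, 3))
  expect_equal(r2$statistic, -r$statistic)
  expect_equal(r2$p_value, r$p_value)
  # identical groups
  r3 <- t_test(c(2, 3, 4), c(2, 3, 4))
  expect_equal(r3$statistic, 0)
  expect_equal(r3$p_value, 1)
  expect_error(t_test(1, c(1, 2)), "at least 2")
})

test_that("one-way ANOVA has the right df and reduces to t squared", {
  # cluster-sized groups: df (2, 53)
  vals <- rnorm(56)
  g <- rep(c("a", "b", "c"), c(11, 6, 39))
  r <- oneway_anova(vals, g)
  expect_equal(c(r$df1, r$df2), c(2, 53))

  # two groups: F = t^2
  x <- rnorm(8); y <- rnorm(6) + 1
  f2 <- oneway_anova(c(x, y), rep(c("x", "y"), c(8, 6)))
  t2 <- t_test(x, y)
  expect_equal(f2$statistic, t2$statistic^2, tolerance = 1e-9)
  expect_equal(f2$p_value, t2$p_value, tolerance = 1e-9)

  # equal group means: F = 0
  expect_equal(oneway_anova(c(1, 2, 1, 2), c("a", "a", "b", "b"))$statistic, 0)
  expect_equal(oneway_anova(rep(5, 6), rep(c("a", "b"), 3))$p_value, 1)
})

test_that("mixed RM ANOVA df follow the design identities", {
  cases <- list(
    list(n = c(32, 24), a = 5, df_int = c(4, 216), df_grp = c(1, 54)),
    list(n = c(32, 24), a = 7, df_int = c(6, 324), df_grp = c(1, 54)),
    list(n = c(11, 6, 39), a = 5, df_int = c(8, 212), df_grp = c(2, 53)),
    list(n = c(11, 6, 39), a = 7, df_int = c(12, 318), df_grp = c(2, 53)),
    list(n = c(3, 4), a = 2, df_int = c(1, 5), df_grp = c(1, 5))
  )
  for (cs in cases) {
    fit <- tidy(mixed_rm_anova(mixed_fixture(cs$n, cs$a)))
    expect_equal(unlist(fit[fit$effect == "interaction", c("df1", "df2")]),
                 cs$df_int, ignore_attr = TRUE)
    expect_equal(unlist(fit[fit$effect == "group", c("df1", "df2")]),
                 cs$df_grp, ignore_attr = TRUE)
    expect_equal(unlist(fit[fit$effect == "within", c("df1", "df2")]),
                 c(cs$a - 1, cs$df_int[2]), ignore_attr = TRUE)
  }
})

test_that("mixed RM ANOVA matches a hand cell-means decomposition", {
  # 2 groups x 2 within levels, 8 subjects, integer values
  df <- tibble::tibble(
    subject = rep(sprintf("s%d", 1:8), each = 2),
    group = rep(c("g1", "g2"), each = 8),
    within = rep(c("w1", "w2"), 8),
    value = c(3, 5, 4, 6, 2, 4, 5, 9,   # g1
              7, 6, 8, 5, 6, 6, 9, 8)   # g2
  )
  fit <- mixed_rm_anova(df)

  # brute-force sums of squares from cell/subject/group means
  y <- df$value; grand <- mean(y)
  subj_mean <- tapply(y, df$subject, mean)[df$subject]
  grp_mean <- tapply(y, df$group, mean)[df$group]
  w_mean <- tapply(y, df$within, mean)[df$within]
  cell_mean <- tapply(y, paste(df$group, df$within),
                      mean)[paste(df$group, df$within)]
  ss_total <- sum((y - grand)^2)
  ss_between_subj <- sum((subj_mean - grand)^2)
  ss_group <- sum((grp_mean - grand)^2)
  ss_subj_in_grp <- ss_between_subj - ss_group
  ss_within_factor <- sum((w_mean - grand)^2)
  ss_inter <- sum((cell_mean - grp_mean - w_mean + grand)^2)
  ss_resid <- ss_total - ss_between_subj - ss_within_factor - ss_inter

  f_group <- (ss_group / 1) / (ss_subj_in_grp / 6)
  f_within <- (ss_within_factor / 1) / (ss_resid / 6)
  f_inter <- (ss_inter / 1) / (ss_resid / 6)
  tf <- tidy(fit)
  expect_equal(tf$statistic, c(f_group, f_within, f_inter), tolerance = 1e-9)

  # partition property on a larger random balanced fixture
  big <- mixed_fixture(c(5, 7), a = 4, seed = 9, effect = 0.5)
  bf <- mixed_rm_anova(big)
  expect_equal(sum(tidy(bf)$df1) + attr(bf, "df_subject") +
                 attr(bf, "df_resid"),
               nrow(big) - 1)

  # constant data: all F zero
  const <- mixed_fixture(c(3, 3), a = 3)
  const$value <- 2
  expect_equal(tidy(mixed_rm_anova(const))$statistic, rep(0, 3))

  # unbalanced data rejected with the offending subject named
  bad <- mixed_fixture(c(3, 3), a = 3)[-1, ]
  expect_error(mixed_rm_anova(bad), "s01")
})

test_that("Bonferroni post hoc adjusts by the family size and caps at 1", {
  fit <- mixed_rm_anova(mixed_fixture(c(6, 6), a = 4, effect = 1))
  ph <- posthoc_bonferroni(fit, "between")
  expect_equal(nrow(ph), 4) # one group pair at each of 4 within levels
  expect_equal(ph$p_adj, pmin(1, ph$p_value * 4))
  expect_true(all(ph$df == attr(fit, "df_subject")))
  ph2 <- posthoc_bonferroni(fit, "within")
  expect_equal(nrow(ph2), 2 * choose(4, 2))
  expect_true(all(ph2$df == attr(fit, "df_resid")))
  # m = 1 leaves p unchanged
  fit2 <- mixed_rm_anova(mixed_fixture(c(4, 4), a = 2))
  ph3 <- posthoc_bonferroni(fit2, "within")
  expect_equal(ph3$p_adj, pmin(1, 2 * ph3$p_value)) # 2 groups x 1 pair
})

test_that("BH adjustment reproduces the step-up computation", {
  expect_equal(bh_adjust(c(0.01, 0.03, 0.04)), c(0.03, 0.04, 0.04))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  p <- c(0.001, 0.2, 0.04, 0.9)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_equal(order(adj), order(p)) # monotone in ranks
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("chi-squared test handles margins, permutation and scaling", {
  t1 <- chi_square_test(rbind(c(10, 0), c(0, 10)))
  expect_equal(t1$statistic, 20)
  expect_equal(t1$df1, 1)

  tab <- rbind(c(7, 4), c(1, 5), c(24, 15))
  a <- chi_square_test(tab)
  b <- chi_square_test(tab[c(3, 1, 2), c(2, 1)])
  expect_equal(a$statistic, b$statistic)
  # duplicating counts c-fold scales the statistic by c
  c3 <- chi_square_test(tab * 3)
  expect_equal(c3$statistic, 3 * a$statistic)
  # all-zero rows/columns are dropped before testing
  padded <- rbind(cbind(tab, 0), 0)
  expect_equal(chi_square_test(padded)$statistic, a$statistic)
  expect_error(chi_square_test(rbind(c(1, 0), c(2, 0))), "degenerate")
  expect_error(chi_square_test(rbind(c(-1, 2), c(3, 1))), "nonnegative")
})

test_that("group summaries report mean and SEM, dropping NA", {
  gs <- group_summary(c(1, 2, 3, 10, NA), c("a", "a", "a", "b", "b"))
  expect_equal(gs$mean[gs$group == "a"], 2)
  expect_equal(gs$sem[gs$group == "a"], sd(1:3) / sqrt(3))
  expect_equal(gs$n[gs$group == "b"], 1)
})
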