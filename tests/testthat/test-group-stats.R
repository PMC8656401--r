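test_that("one-way ANOVA reproduces textbook sums of squares", {
  # groups (1,2,3), (2,3,4), (3,4,5): SSB = 6, SSW = 6, F = 3 on df (2, 6)
  d <- data.frame(
    g = rep(c("a", "b", "c"), each = 3),
    y = c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  )
  gc <- compare_groups(d, y, g)
  gl <- glance(gc)
  expect_equal(gl$statistic, 3)
  expect_equal(gl$df_between, 2)
  expect_equal(gl$df_within, 6)
  expect_equal(gl$p.value, stats::pf(3, 2, 6, lower.tail = FALSE))

  # three identical groups: F = 0, p = 1
  d0 <- data.frame(g = rep(c("a", "b", "c"), each = 3), y = rep(c(1, 2, 3), 3))
  gl0 <- glance(compare_groups(d0, y, g))
  expect_equal(gl0$statistic, 0)
  expect_equal(gl0$p.value, 1)

  # location invariance
  d_shift <- transform(d, y = y + 100)
  expect_equal(glance(compare_groups(d_shift, y, g))$statistic, gl$statistic)
})

test_that("pairwise layer applies the Bonferroni correction and star flags", {
  set.seed(81)
  d <- data.frame(
    g = rep(c("a", "b", "c"), each = 20),
    y = c(rnorm(20), rnorm(20), rnorm(20, 3))
  )
  gc <- compare_groups(d, y, g)
  pw <- tidy(gc)
  expect_equal(nrow(pw), 3)
  expect_equal(pw$p.adjusted, pmin(1, pw$p.value * 3))
  expect_true(all(pw$sig_0.005 <= pw$sig_0.01 & pw$sig_0.01 <= pw$sig_0.05))
  ab <- pw$p.adjusted[pw$group1 == "a" & pw$group2 == "b"]
  ac <- pw$p.adjusted[pw$group1 == "a" & pw$group2 == "c"]
  expect_gt(ab, 0.05)
  expect_lt(ac, 0.005)
  # Kruskal-Wallis agrees in direction on the well-separated effect
  expect_lt(gc$kruskal$p.value, 0.05)
})

test_that("degenerate comparisons are flagged or refused", {
  d_const <- data.frame(g = rep(c("a", "b"), each = 3), y = rep(1, 6))
  gc <- compare_groups(d_const, y, g)
  expect_true(is.na(glance(gc)$statistic))
  expect_match(gc$anova$note, "zero variance")
  expect_error(compare_groups(data.frame(g = "a", y = 1), y, g), "two groups")
})

test_that("chi-squared test matches hand-computed tables", {
  expect_equal(chi_squared_test(matrix(c(10, 10, 10, 10), 2))$statistic, 0)
  expect_equal(chi_squared_test(matrix(c(10, 10, 10, 10), 2))$p.value, 1)
  r <- chi_squared_test(matrix(c(20, 0, 0, 20), 2))
  expect_equal(r$statistic, 40)
  expect_equal(r$df, 1)
  # proportional rows are independent
  expect_equal(chi_squared_test(matrix(c(10, 20, 30, 60), 2))$statistic, 0)
  expect_error(chi_squared_test(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)), "marginal")
  expect_error(chi_squared_test(matrix(c(1.5, 2, 3, 4), 2)), "integer")
})

test_that("two-way ANOVA detects planted factors and validates the design", {
  set.seed(82)
  d <- expand.grid(g = c("a", "b", "c"), s = c("s1", "s2"), rep = 1:10)
  d$y <- 2 * (d$g == "b") + 1.5 * (d$s == "s2") + rnorm(nrow(d))
  a <- two_way_anova(d, y, g, s)
  expect_setequal(a$term, c("g", "s", "g:s", "Residuals"))
  expect_lt(a$p.value[a$term == "g"], 0.01)
  expect_lt(a$p.value[a$term == "s"], 0.01)
  # permuting site labels within group destroys the site effect
  d_perm <- d
  set.seed(83)
  for (g in unique(d$g)) {
    idx <- which(d$g == g)
    d_perm$s[idx] <- sample(d_perm$s[idx])
  }
  a_perm <- two_way_anova(d_perm, y, g, s)
  expect_gt(a_perm$p.value[a_perm$term == "s"], 0.05)
  # single-level and empty-cell designs are refused
  expect_error(two_way_anova(subset(d, s == "s1"), y, g, s), "two levels")
  expect_error(two_way_anova(subset(d, !(g == "a" & s == "s1")), y, g, s), "empty design cell")
})

test_that("two-way ANOVA interaction p-values are calibrated under an additive null", {
  set.seed(84)
  ps <- replicate(60, {
    d <- expand.grid(g = c("a", "b"), s = c("s1", "s2"), rep = 1:8)
    d$y <- 1 * (d$g == "b") + 0.5 * (d$s == "s2") + rnorm(nrow(d))
    a <- two_way_anova(d, y, g, s)
    a$p.value[a$term == "g:s"]
  })
  expect_lt(mean(ps < 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / 60) + 0.05)
  expect_gt(mean(ps < 0.5), 0.3)
})

test_that("symptom regression recovers exact and planted linear effects", {
  # exact: y = 2 f(A1) + 1
  d <- data.frame(f_major1 = seq(0.1, 0.9, length.out = 10))
  d$f_major2 <- 1 - d$f_major1
  d$bdi <- 2 * d$f_major1 + 1
  fit <- symptom_regression(d, "bdi", "f_major1")
  td <- suppressWarnings(tidy(fit)) # summary.lm warns on an exact fit
  expect_equal(td$estimate[td$term == "f_major1"], 2, tolerance = 1e-10)
  expect_equal(suppressWarnings(glance(fit))$r.squared, 1, tolerance = 1e-10)

  # planted slope with noise recovered within 3 SEs
  set.seed(85)
  d2 <- data.frame(f_major1 = runif(60, 0.2, 0.8))
  d2$bdi <- 10 + 2 * d2$f_major1 + rnorm(60, 0, 0.3)
  td2 <- tidy(symptom_regression(d2, "bdi", "f_major1"))
  row <- td2[td2$term == "f_major1", ]
  expect_lt(abs(row$estimate - 2), 3 * row$std.error)

  # rank-deficient designs are refused with the collinear column named
  d3 <- d2
  d3$dup <- 2 * d3$f_major1
  expect_error(symptom_regression(d3, "bdi", c("f_major1", "dup")), "collinear")
  expect_error(symptom_regression(d2[1:2, ], "bdi", "f_major1"), "observations")
  expect_error(symptom_regression(d2, "bdi", "missing_col"), "not in data")
})

test_that("regression p-values are calibrated when the response is independent", {
  set.seed(86)
  ps <- replicate(80, {
    d <- data.frame(f_major1 = runif(30), y = rnorm(30))
    tidy(symptom_regression(d, "y", "f_major1"))$p.value[2]
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})
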