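test_that("group summaries report exact mean and SEM", {
  tab <- group_table(rep("a", 3), 1, 1:3, c(1, 2, 3))
  s <- summarize_groups(tab)
  expect_equal(s$mean, 2)
  expect_equal(s$sem, 1 / sqrt(3))
  s2 <- summarize_groups(group_table(rep("a", 3), 1, 1:3, c(5, 5, 5)))
  expect_equal(s2$sem, 0)
  expect_warning(
    s3 <- summarize_groups(group_table("a", 1, 1, 7)), "n < 2")
  expect_equal(s3$mean, 7)
  expect_true(is.na(s3$sem))
})

test_that("undefined values are dropped from group tables with a message", {
  expect_message(
    tab <- group_table(c("a", "a", "b"), c(1, 1, 2), 1:3, c(0.5, NA, 0.7)),
    "dropping 1")
  expect_equal(nrow(tab), 2L)
})

test_that("two identical groups give t = 0, p = 1", {
  tab <- group_table(rep(c("a", "b"), each = 4), rep(1, 8), 1:8,
                     rep(c(1, 2, 3, 4), 2))
  cmp <- compare_groups(tab)
  expect_equal(cmp$method, "t")
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p_value, 1)
})

test_that("one-way ANOVA F matches an explicit sum-of-squares oracle", {
  values <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5))
  tab <- group_table(rep(names(values), lengths(values)), 1,
                     1:9, unlist(values))
  cmp <- compare_groups(tab)
  # oracle: between/within decomposition computed from first principles
  grand <- mean(unlist(values))
  ssb <- sum(lengths(values) * (vapply(values, mean, 1) - grand)^2)
  ssw <- sum(unlist(lapply(values, function(v) (v - mean(v))^2)))
  F_oracle <- (ssb / 2) / (ssw / 6)
  expect_equal(cmp$statistic, F_oracle)
  expect_equal(cmp$p_value, pf(F_oracle, 2, 6, lower.tail = FALSE))
  expect_equal(nrow(cmp$tukey), 3L)
  expect_true(all(cmp$tukey$p_adj >= 0 & cmp$tukey$p_adj <= 1))
})

test_that("two-group ANOVA and t-test agree (F = t^2)", {
  set.seed(91)
  tab <- group_table(rep(c("a", "b"), each = 6), 1, 1:12,
                     c(rnorm(6), rnorm(6, 1)))
  tt <- compare_groups(tab)
  df <- as.data.frame(tab); df$group <- factor(df$group)
  av <- summary(aov(value ~ group, df))[[1]]
  expect_equal(tt$statistic^2, av[["F value"]][1], tolerance = 1e-10)
  expect_equal(tt$p_value, av[["Pr(>F)"]][1], tolerance = 1e-10)
})

test_that("comparisons refuse degenerate designs", {
  expect_error(compare_groups(group_table(rep("a", 4), 1, 1:4, 1:4)),
               "2 groups")
  expect_error(compare_groups(group_table(c("a", "a", "b"), 1, 1:3,
                                          c(1, 2, 3))),
               "at least 2 observations")
})

test_that("per-animal averaging collapses cells before testing", {
  tab <- group_table(rep(c("a", "b"), each = 4),
                     c(1, 1, 2, 2, 3, 3, 4, 4), 1:8,
                     c(0, 1, 2, 3, 4, 5, 6, 7))
  cmp <- compare_groups(tab, per_animal = TRUE)
  # animal means: a = (0.5, 2.5), b = (4.5, 6.5)
  expect_equal(cmp$summary$n, c(2L, 2L))
  expect_equal(cmp$summary$mean, c(1.5, 5.5))
})

test_that("synthetic SI tables have the requested structure and means", {
  set.seed(15)
  tab <- simulate_si_table(c(g1 = 0.3, g2 = 0.8), n_per_group = 200)
  s <- summarize_groups(tab)
  expect_equal(s$n, c(200L, 200L))
  expect_lt(abs(s$mean[1] - 0.3), 0.05)
  expect_lt(abs(s$mean[2] - 0.8), 0.05)
  expect_true(all(tab$value >= 0 & tab$value <= 1))
})

test_that("reports are written completely and deterministically", {
  set.seed(8)
  tab <- simulate_si_table(c(a = 0.4, b = 0.8), n_per_group = 6)
  cmp <- compare_groups(tab)
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  on.exit(unlink(c(d1, d2), recursive = TRUE), add = TRUE)
  build_report(list(stability_index = tab), list(stability_index = cmp), d1,
               config = list(alpha = 0.05), seed = 8)
  build_report(list(stability_index = tab), list(stability_index = cmp), d2,
               config = list(alpha = 0.05), seed = 8)
  expect_true(file.exists(file.path(d1, "stability_index.csv")))
  expect_true(file.exists(file.path(d1, "comparisons.csv")))
  expect_true(file.exists(file.path(d1, "run_metadata.json")))
  expect_identical(readLines(file.path(d1, "stability_index.csv")),
                   readLines(file.path(d2, "stability_index.csv")))
  expect_warning(build_report(list(), list(), d1), "metadata only")
})
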