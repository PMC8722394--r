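make_table <- function(values, condition = "wt", stage = "bean",
                       embryos = 5L) {
  n <- length(values)
  data.frame(embryo_id = if (n) sprintf("e%d", rep_len(seq_len(embryos), n))
             else character(0),
             cell_id = sprintf("%s_c%02d", rep_len(condition, n),
                               seq_len(n)),
             condition = rep_len(condition, n),
             stage = rep_len(stage, n),
             fraction_percent = values, mode = rep_len("standard", n),
             stringsAsFactors = FALSE)
}

test_that("identical values give a zero-height box", {
  s <- summarize_condition(make_table(rep(61.3, 25)))
  expect_equal(s$mean, 61.3)
  expect_equal(s$median, 61.3)
  expect_equal(s$stdev, 0)
  expect_equal(s$q1, s$q3)
  expect_equal(s$n_cells, 25L)
  expect_equal(s$n_embryos, 5L)
})

test_that("summaries match a sort-based quantile oracle", {
  s <- summarize_condition(make_table(c(10, 20, 30, 40, 50)))
  expect_equal(s$median, 30)
  # type-7 linear interpolation: h = (n-1)p + 1
  expect_equal(s$q1, 20)
  expect_equal(s$q3, 40)
  expect_equal(s$mean, 30)
  expect_equal(s$stdev, sd(c(10, 20, 30, 40, 50)))
  expect_equal(s$whisker_low, 10)
  expect_equal(s$whisker_high, 50)
  smm <- summarize_condition(make_table(c(10, 20, 30, 40, 150)),
                             whiskers = "minmax")
  expect_equal(smm$whisker_high, 150)
  st <- summarize_condition(make_table(c(10, 20, 30, 40, 150)))
  expect_lt(st$whisker_high, 150)  # 1.5 IQR whisker excludes the outlier
})

test_that("groups below two cells are rejected", {
  expect_error(summarize_condition(make_table(50)), ">= 2 cells")
  expect_error(summarize_condition(make_table(numeric(0))), "empty group")
  expect_error(summarize_condition(make_table(rep(50, 5)), condition = "zz"),
               "empty group")
})

test_that("Welch t matches an independent closed-form computation", {
  a <- c(1, 2, 3, 4, 5); b <- c(2, 3, 4, 5, 6)
  res <- t_test(a, b, tails = 2)
  # closed-form Welch: t = (ma - mb) / sqrt(va/na + vb/nb),
  # df by Welch-Satterthwaite
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t_oracle <- (mean(a) - mean(b)) / sqrt(va + vb)
  df_oracle <- (va + vb)^2 /
    (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p_oracle <- 2 * pt(-abs(t_oracle), df_oracle)
  expect_lt(abs(res$t - t_oracle) / abs(t_oracle), 1e-10)
  expect_lt(abs(res$df - df_oracle) / df_oracle, 1e-10)
  expect_lt(abs(res$p - p_oracle) / p_oracle, 1e-10)
})

test_that("heteroscedastic groups also match the Welch oracle", {
  set.seed(2)
  a <- rnorm(12, 60, 15); b <- rnorm(25, 30, 5)
  res <- t_test(a, b, tails = 2)
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t_oracle <- (mean(a) - mean(b)) / sqrt(va + vb)
  df_oracle <- (va + vb)^2 /
    (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  expect_lt(abs(res$t - t_oracle), 1e-10 * abs(t_oracle))
  expect_lt(abs(res$df - df_oracle), 1e-10 * df_oracle)
  expect_lt(abs(res$p - 2 * pt(-abs(t_oracle), df_oracle)), 1e-12)
})

test_that("identical samples give t = 0, p = 1", {
  a <- c(10, 20, 30)
  res <- t_test(a, a, tails = 2)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
})

test_that("one-tailed p is half the two-tailed p in the tested direction", {
  a <- c(5, 6, 7, 8); b <- c(1, 2, 3, 4)
  two <- t_test(a, b, tails = 2)
  one <- t_test(a, b, tails = 1, direction = "greater")
  expect_equal(one$p, two$p / 2)
  wrong_way <- t_test(a, b, tails = 1, direction = "less")
  expect_equal(wrong_way$p, 1 - two$p / 2)
})

test_that("degenerate zero-variance groups follow the stated conventions", {
  expect_message(res <- t_test(rep(5, 3), rep(5, 4)), "t = 0, p = 1")
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_message(res2 <- t_test(rep(9, 3), rep(5, 4)), "p = 0")
  expect_equal(res2$p, 0)
  expect_error(t_test(c(1), c(2, 3)), ">= 2")
})

test_that("Student mode reproduces the pooled-variance test", {
  a <- c(1, 2, 3, 4, 5); b <- c(2, 4, 6, 8, 9)
  res <- t_test(a, b, var_equal = TRUE)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(res$t, unname(ref$statistic))
  expect_equal(res$df, unname(ref$parameter))
})

test_that("significance stars follow the legend thresholds exactly", {
  expect_identical(significance_stars(0.0003), "***")
  expect_identical(significance_stars(0.02), "*")
  expect_identical(significance_stars(0.009), "**")
  expect_identical(significance_stars(0.05), "n.s.")   # strict boundary
  expect_identical(significance_stars(0.01), "*")
  expect_identical(significance_stars(0.001), "**")
  expect_identical(significance_stars(c(1, 0, 0.049999)),
                   c("n.s.", "***", "*"))
  expect_error(significance_stars(1.2), "\\[0, 1\\]")
  expect_error(significance_stars(-0.1), "\\[0, 1\\]")
  expect_error(significance_stars(NA_real_), "\\[0, 1\\]")
})

test_that("box plots carry summaries identical to summarize_condition", {
  set.seed(5)
  tab <- rbind(make_table(rnorm(25, 75, 8), condition = "full-length"),
               make_table(rnorm(25, 30, 8), condition = "jac-1"))
  file <- file.path(tempdir(), "box.png")
  gg <- render_boxplot(tab,
                       comparisons = list(list(a = "full-length", b = "jac-1",
                                               tails = 1,
                                               direction = "greater")),
                       file = file)
  summ <- attr(gg, "summary")
  expect_equal(summ[summ$condition == "full-length", ],
               summarize_condition(tab, condition = "full-length"),
               ignore_attr = TRUE)
  tests <- attr(gg, "tests")
  expect_identical(tests$stars,
                   significance_stars(tests$p))
  expect_true(file.exists(file))
  csv <- read.csv(file.path(tempdir(), "box_summary.csv"))
  expect_equal(csv$mean, summ$mean)
  unlink(c(file, file.path(tempdir(), c("box_summary.csv", "box_tests.csv"))))
})

test_that("box plot comparisons validate their condition names", {
  tab <- make_table(rnorm(10, 50, 5), condition = "wt")
  expect_error(render_boxplot(tab, comparisons = list(list(a = "wt",
                                                           b = "mut"))),
               "unknown condition")
  gg <- render_boxplot(tab)  # single condition, no stars
  expect_null(attr(gg, "tests"))
})
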