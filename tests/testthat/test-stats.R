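test_that("Welch t-test matches the closed form and its degenerate case", {
  r <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  x <- c(1, 2, 3); y <- x + 10
  r <- two_sample_t(x, y)
  # hand-computed Welch statistic
  se <- sqrt(var(x) / 3 + var(y) / 3)
  t_hand <- (mean(x) - mean(y)) / se
  df_hand <- se^4 / ((var(x) / 3)^2 / 2 + (var(y) / 3)^2 / 2)
  expect_equal(r$t, t_hand)
  expect_equal(r$df, df_hand)
  expect_equal(r$p, 2 * pt(t_hand, df_hand))
})

test_that("t-test holds its nominal type-I error under the null", {
  set.seed(1234)
  rej <- mean(replicate(1000, two_sample_t(rnorm(15), rnorm(15))$p < 0.05))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("Pearson chi-square matches the closed form without correction", {
  r <- chi_square_2x2(10, 10, 10, 10)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  # diagnostic-yield style table: 20/48 vs 24/57 positive
  a <- 20; b <- 28; c <- 24; d <- 33
  n <- a + b + c + d
  hand <- n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  r <- chi_square_2x2(a, b, c, d)
  expect_equal(r$statistic, hand)
  expect_equal(r$df, 1)
  expect_equal(r$p, pchisq(hand, 1, lower.tail = FALSE))
})

test_that("degenerate 2x2 tables are rejected", {
  expect_error(chi_square_2x2(0, 0, 5, 7), "degenerate table")
  expect_error(chi_square_2x2(5, 0, 7, 0), "degenerate table")
})

make_anova_data <- function(n1, n2, k = 4, seed = 1, fun = NULL) {
  set.seed(seed)
  if (is.null(fun)) fun <- function(g, s, q) runif(1)
  rows <- list()
  for (g in 1:2) for (s in seq_len(c(n1, n2)[g])) for (q in seq_len(k))
    rows[[length(rows) + 1]] <- data.frame(
      subject = sprintf("g%ds%d", g, s), group = paste0("G", g),
      quartile = q, value = fun(g, s, q))
  do.call(rbind, rows)
}

test_that("mixed ANOVA reproduces the brute-force decomposition on a toy table", {
  base <- c(0.1, 0.2, 0.3, 0.4)
  d <- make_anova_data(2, 2, fun = function(g, s, q)
    base[q] + (g - 1) * 0.1 + 0.01 * s * q)
  fit <- mixed_anova(d)
  ss <- brute_mixed_ss(d)
  tab <- fit$table
  expect_equal(tab$ss[tab$effect == "group"], unname(ss$group))
  expect_equal(tab$ss[tab$effect == "subjects_within"], unname(ss$subjects_within))
  expect_equal(tab$ss[tab$effect == "quartile"], unname(ss$quartile))
  expect_equal(tab$ss[tab$effect == "group_by_quartile"], unname(ss$interaction))
  expect_equal(tab$ss[tab$effect == "residual"], unname(ss$residual))
  expect_equal(fit$ss_total, unname(ss$total))
})

test_that("mixed ANOVA degrees of freedom follow the split-plot layout", {
  d <- make_anova_data(5, 7, seed = 3)
  fit <- mixed_anova(d)
  df <- setNames(fit$table$df, fit$table$effect)
  expect_equal(unname(df["group"]), 1)
  expect_equal(unname(df["subjects_within"]), 5 + 7 - 2)
  expect_equal(unname(df["quartile"]), 3)
  expect_equal(unname(df["group_by_quartile"]), 3)
  expect_equal(unname(df["residual"]), 3 * (5 + 7 - 2))
})

test_that("sums of squares are conserved on random data sets", {
  for (seed in 1:100) {
    set.seed(seed)
    d <- make_anova_data(sample(3:8, 1), sample(3:8, 1), seed = seed)
    fit <- mixed_anova(d)
    expect_lt(abs(fit$ss_total - sum(fit$table$ss)) /
                max(fit$ss_total, 1e-12), 1e-8)
  }
})

test_that("the group test is the between-subject ANOVA on subject means", {
  d <- make_anova_data(6, 9, seed = 11)
  fit <- mixed_anova(d)
  means <- aggregate(value ~ subject + group, d, mean)
  one <- anova(lm(value ~ group, means))
  k <- 4
  expect_equal(fit$table$ss[1], k * one["group", "Sum Sq"])
  expect_equal(fit$table$ss[2], k * one["Residuals", "Sum Sq"])
  expect_equal(fit$table$F[1], one["group", "F value"])
  expect_equal(fit$table$p[1], one["group", "Pr(>F)"])
})

test_that("constant responses yield a null decomposition", {
  d <- make_anova_data(3, 3, fun = function(g, s, q) 0.5)
  fit <- mixed_anova(d)
  expect_lt(fit$ss_total, 1e-20)
  expect_true(all(fit$table$ss < 1e-20))
})

test_that("input validation rejects malformed designs", {
  d <- make_anova_data(3, 3)
  expect_error(mixed_anova(d[-1, ]), "missing cells")
  d2 <- make_anova_data(1, 3)
  expect_error(mixed_anova(d2), "at least 2 subjects")
})

test_that("Greenhouse-Geisser epsilon is bounded and lowers significance", {
  d <- make_anova_data(8, 8, seed = 21, fun = function(g, s, q)
    q * 0.1 + rnorm(1, 0, 0.05 * q))
  fit <- mixed_anova(d, gg = TRUE)
  expect_gte(fit$gg_epsilon, 1 / 3)
  expect_lte(fit$gg_epsilon, 1)
  i <- which(fit$table$effect == "quartile")
  expect_gte(fit$p_quartile_gg, fit$table$p[i])
})
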