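random_mixed_table <- function(n1, n2, effect = 0) {
  n <- n1 + n2
  ids <- sprintf("s%02d", seq_len(n))
  grp <- rep(c("g1", "g2"), c(n1, n2))
  subj <- rnorm(n, sd = 1.2)
  d <- data.frame(
    participant_id = rep(ids, each = 2L),
    group = rep(grp, each = 2L),
    within = rep(c("a", "b"), times = n),
    stringsAsFactors = FALSE
  )
  d$value <- rnorm(nrow(d)) + subj[rep(seq_len(n), each = 2L)] +
    effect * (d$group == "g2") * (d$within == "b")
  d
}

aov_oracle <- function(d) {
  d$participant_id <- factor(d$participant_id)
  a <- summary(stats::aov(
    value ~ group * within + Error(participant_id / within), data = d))
  c(group = a[[1L]][[1L]]["group", "F value"],
    within = a[[2L]][[1L]]["within", "F value"],
    interaction = a[[2L]][[1L]]["group:within", "F value"])
}

test_that("mixed ANOVA matches the aov error-stratum fit, balanced or not", {
  set.seed(101)
  for (i in 1:20) {
    d <- random_mixed_table(sample(3:12, 1), sample(3:12, 1),
                            effect = runif(1, 0, 1.5))
    fit <- mixed_anova_2x2(d)
    expect_equal(fit$F, unname(aov_oracle(d)), tolerance = 1e-10)
    expect_true(all(fit$pes >= 0 & fit$pes <= 1))
  }
})

test_that("mixed ANOVA reports the study's error degrees of freedom", {
  set.seed(5)
  d <- random_mixed_table(21, 21)
  fit <- mixed_anova_2x2(d)
  expect_equal(fit$df1, rep(1L, 3))
  expect_equal(fit$df2, rep(40L, 3))
})

test_that("a constant within-subject difference gives a zero interaction", {
  d <- random_mixed_table(4, 5)
  # force value(b) = value(a) + 0.75 for every subject, on a grid where the
  # shift is exactly representable so the interaction SS vanishes exactly
  d$value <- sample(0:40, nrow(d), replace = TRUE) / 4
  a_rows <- d$within == "a"
  d$value[!a_rows] <- d$value[a_rows] + 0.75
  fit <- mixed_anova_2x2(d)
  expect_equal(fit$F[fit$effect == "interaction"], 0, tolerance = 1e-20)
  expect_equal(fit$F[fit$effect == "within"] > 0, TRUE)
})

test_that("complementary ratios degrade the between stratum to a null effect", {
  set.seed(9)
  p <- runif(12)
  d <- data.frame(
    participant_id = rep(sprintf("s%02d", 1:12), each = 2L),
    group = rep(rep(c("g1", "g2"), each = 6L), each = 2L),
    within = rep(c("a", "b"), times = 12L),
    value = as.vector(rbind(p, 1 - p))
  )
  fit <- mixed_anova_2x2(d)
  g <- fit[fit$effect == "group", ]
  expect_equal(g$F, 0)
  expect_equal(g$p, 1)
})

test_that("incomplete within pairs raise an error naming the participant", {
  d <- random_mixed_table(3, 3)
  expect_error(mixed_anova_2x2(d[-1L, ]), "s01")
})

test_that("Tukey HSD reproduces the studentized-range calibration", {
  # alternating (0,1)/(1,0) pairs in both groups: all four cell means are
  # exactly 0.5 while the error variance stays positive, so every p is 1
  d <- data.frame(
    participant_id = rep(sprintf("s%02d", 1:8), each = 2L),
    group = rep(c("g1", "g2"), each = 8L),
    within = rep(c("a", "b"), times = 8L),
    value = rep(c(0, 1, 1, 0), times = 4L)
  )
  ths <- tukey_hsd(d)
  expect_true(all(ths$p > 0.999))

  # a difference placed at the published 5% critical value q(4, 40) = 3.79
  # must come out with p = 0.05
  mse <- 0.014
  n <- 21L
  diff <- 3.79 * sqrt(mse / n)
  cells <- matrix(c(0, diff, 0, 0), 2L,
                  dimnames = list(c("g1", "g2"), c("a", "b")))
  fit <- structure(
    data.frame(effect = "group", df1 = 1L, df2 = 40L, F = 1, p = 0.5,
               pes = 0.1),
    cell_means = cells, cell_n = c(g1 = n, g2 = n),
    ms_error_between = mse, ms_error_within = mse,
    class = c("mixed_anova", "data.frame"))
  ths <- tukey_hsd(fit, mse = mse, df = 40L)
  row <- ths[ths$pair == "g1:a vs g2:a", ]
  expect_equal(row$q, 3.79, tolerance = 1e-10)
  expect_equal(row$p, 0.05, tolerance = 2e-3)
  # Cohen's d convention: mean difference over sqrt(MSE)
  expect_equal(abs(row$d), diff / sqrt(mse), tolerance = 1e-10)
  expect_error(tukey_hsd(fit, mse = 0), "non-positive")
})

test_that("one-tailed t reproduces the hand-computed example", {
  tt <- one_tailed_t(c(1, 2, 3), c(2, 3, 4), "less")
  expect_equal(tt$statistic, -1/sqrt(2/3), tolerance = 1e-10)
  expect_equal(tt$d, -1, tolerance = 1e-10)
  expect_equal(tt$df, 4)
  rev <- one_tailed_t(c(1, 2, 3), c(2, 3, 4), "greater")
  expect_equal(tt$p + rev$p, 1, tolerance = 1e-12)

  same <- one_tailed_t(c(1, 2, 3), c(3, 1, 2), "greater")
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 0.5)
  expect_error(one_tailed_t(c(1, 1), c(1, 1)), "zero pooled variance")
})

test_that("FDR adjustment follows the worked step-up example", {
  expect_equal(fdr_bh(0.37), 0.37)
  expect_equal(fdr_bh(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(fdr_bh(rep(1, 5)), rep(1, 5))
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  p <- runif(10)
  expect_true(all(fdr_bh(p) >= p))
})

test_that("outlier screening uses a strict 3-SD rule", {
  expect_warning(fl <- outlier_screen(rep(2, 5)), "zero standard deviation")
  expect_false(any(fl))

  set.seed(1)
  x <- rnorm(99)
  v <- mean(x) + 3.6 * sd(x)
  fl <- outlier_screen(c(x, v))
  expect_true(fl[100L])
  expect_equal(sum(fl), 1L)

  # strictness at the threshold: |1 - mean| = k * sd exactly is not flagged
  vals <- c(0, 0, 1)
  k_star <- abs(1 - mean(vals)) / sd(vals)
  expect_false(any(outlier_screen(vals, k = k_star)))
  expect_true(outlier_screen(vals, k = k_star - 1e-9)[3L])
})

test_that("Dunnett contrasts pool variance across all groups", {
  # zero mean difference
  z <- dunnett_t(c(5, 5, 5), c(1, 2, 1), c(10, 10, 10))
  expect_equal(z$statistic, c(0, 0))
  expect_true(all(z$p > 0.999))
  # with two groups the test is exactly the pooled two-sample t
  set.seed(2)
  x <- rnorm(10); y <- rnorm(12, 1)
  dt2 <- dunnett_t(c(mean(x), mean(y)), c(sd(x), sd(y)), c(10L, 12L))
  tt <- t.test(y, x, var.equal = TRUE)
  expect_equal(dt2$statistic, unname(abs(tt$statistic)), tolerance = 1e-12)
  expect_equal(dt2$p, tt$p.value, tolerance = 1e-12)
  expect_equal(dt2$df, 20)
  expect_error(dunnett_t(c(1, 2), c(1, 1), c(1, 5)), "n >= 2")
})

test_that("2x2 chi-squared handles the continuity correction flag", {
  tab <- matrix(c(10, 13, 11, 8), 2L)
  expect_equal(chi2_2x2(tab, yates = FALSE)$statistic,
               2 * 1.5^2 * (1 / 11.5 + 1 / 9.5), tolerance = 1e-12)
  expect_lt(chi2_2x2(tab, yates = TRUE)$statistic,
            chi2_2x2(tab, yates = FALSE)$statistic)
  same <- matrix(c(7, 7, 9, 9), 2L)
  expect_equal(chi2_2x2(same, yates = FALSE)$statistic, 0)
  expect_error(chi2_2x2(matrix(c(0, 0, 5, 5), 2L, byrow = TRUE)), "margin")
})

test_that("correlations match the rank-formula oracle and handle degeneracy", {
  d <- data.frame(f = c(3, 1, 4, 1.5, 9), s = c(2, 7, 1, 8, 3),
                  same = c(3, 1, 4, 1.5, 9), const = 5)
  res <- correlate_features(d, "f", "same", method = "pearson")
  expect_equal(res$r, 1)

  expect_warning(res0 <- correlate_features(d, "f", "const"), "constant")
  expect_true(is.na(res0$r))

  # Spearman oracle: 1 - 6 sum(d^2) / (n (n^2 - 1)) on untied ranks
  res_s <- suppressWarnings(
    correlate_features(d, "f", "s", method = "spearman"))
  dr <- rank(d$f) - rank(d$s)
  expect_equal(res_s$r, 1 - 6 * sum(dr^2) / (5 * 24), tolerance = 1e-12)
})

test_that("sums of squares decompose additively on random tables", {
  set.seed(77)
  for (i in 1:10) {
    d <- random_mixed_table(sample(3:8, 1), sample(3:8, 1))
    fit <- mixed_anova_2x2(d)
    n <- nrow(d) / 2
    ss_total <- sum((d$value - mean(d$value))^2)
    ss_model <- with(
      list(eb = attr(fit, "ms_error_between") * (n - 2),
           ew = attr(fit, "ms_error_within") * (n - 2)),
      eb + ew + sum(fit$F * c(attr(fit, "ms_error_between"),
                              attr(fit, "ms_error_within"),
                              attr(fit, "ms_error_within"))))
    expect_equal(ss_model, ss_total, tolerance = 1e-8)
  }
})
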