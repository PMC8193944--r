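test_that("summary-statistics ANOVA reproduces the published F values", {
  a1 <- anova2_from_summary(fig_daily_activity())
  expect_equal(a1$F[a1$effect == "age"], 51.02, tolerance = 0.005)
  expect_equal(a1$df2[1], 28)
  a2 <- anova2_from_summary(fig_phase_angle())
  expect_equal(a2$F[a2$effect == "age"], 41.74, tolerance = 0.005)
  a3 <- anova2_from_summary(fig_onset_variability())
  expect_equal(a3$F[a3$effect == "age"], 33.29, tolerance = 0.01)
  # genotype effects are printed too: 0.85, 0.01, 0.93
  expect_equal(a1$F[a1$effect == "genotype"], 0.85, tolerance = 0.01)
  expect_equal(a3$F[a3$effect == "genotype"], 0.93, tolerance = 0.01)
})

test_that("equal cell means give zero F for every effect", {
  gs <- group_summary_2x2(age = c("y", "y", "a", "a"),
                          genotype = c("w", "v", "w", "v"),
                          mean = rep(5, 4), sem = c(1, 2, 1, 2),
                          n = c(4, 6, 8, 10))
  a <- anova2_from_summary(gs)
  expect_equal(a$F, rep(0, 3))
})

test_that("summary ANOVA equals a Type III analysis of the raw data", {
  library(car)
  set.seed(3)
  for (i in 1:8) {
    n <- sample(3:12, 4, replace = TRUE)
    cells <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"))
    raw <- do.call(rbind, lapply(1:4, function(j)
      data.frame(A = cells$A[j], B = cells$B[j],
                 y = rnorm(n[j], mean = rnorm(1, 10, 5), sd = runif(1, 1, 3)))))
    agg <- do.call(rbind, lapply(split(raw, paste(raw$A, raw$B)), function(d)
      data.frame(A = d$A[1], B = d$B[1], mean = mean(d$y),
                 sem = sd(d$y) / sqrt(nrow(d)), n = nrow(d))))
    gs <- group_summary_2x2(agg$A, agg$B, agg$mean, agg$sem, agg$n)
    ours <- anova2_from_summary(gs)
    fit <- lm(y ~ A * B, data = raw,
              contrasts = list(A = contr.sum, B = contr.sum))
    oracle <- car::Anova(fit, type = 3)
    expect_equal(ours$F[ours$effect == "age"], oracle["A", "F value"],
                 tolerance = 1e-8)
    expect_equal(ours$F[ours$effect == "genotype"], oracle["B", "F value"],
                 tolerance = 1e-8)
    expect_equal(ours$F[ours$effect == "interaction"], oracle["A:B", "F value"],
                 tolerance = 1e-8)
  }
})

test_that("F statistics are location- and jointly scale-invariant", {
  gs <- fig_daily_activity()
  shifted <- group_summary_2x2(gs$age, gs$genotype, gs$mean + 1234, gs$sem,
                               gs$n)
  scaled <- group_summary_2x2(gs$age, gs$genotype, gs$mean * 0.001,
                              gs$sem * 0.001, gs$n)
  expect_equal(anova2_from_summary(shifted)$F, anova2_from_summary(gs)$F,
               tolerance = 1e-10)
  expect_equal(anova2_from_summary(scaled)$F, anova2_from_summary(gs)$F,
               tolerance = 1e-10)
})

test_that("balanced designs match the classical aov decomposition", {
  set.seed(9)
  raw <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"),
                     rep = 1:6)
  raw$y <- rnorm(nrow(raw), 10 + 2 * (raw$A == "a2") - (raw$B == "b2"))
  agg <- do.call(rbind, lapply(split(raw, paste(raw$A, raw$B)), function(d)
    data.frame(A = d$A[1], B = d$B[1], mean = mean(d$y),
               sem = sd(d$y) / sqrt(nrow(d)), n = nrow(d))))
  ours <- anova2_from_summary(group_summary_2x2(agg$A, agg$B, agg$mean,
                                                agg$sem, agg$n))
  tab <- summary(aov(y ~ A * B, data = raw))[[1]]
  expect_equal(ours$F, unname(tab[1:3, "F value"]), tolerance = 1e-10)
})

test_that("paired t-test handles regular and degenerate inputs", {
  x <- c(10, 12, 9, 14)
  expect_equal(paired_t(x, x)$t, 0)
  expect_equal(paired_t(x, x)$p, 1)
  d1 <- paired_t(x + 1, x)  # constant nonzero difference
  expect_true(d1$degenerate)
  expect_identical(d1$t, Inf)
  y <- c(11, 11, 10, 12)
  ours <- paired_t(x, y)
  ref <- t.test(x, y, paired = TRUE)
  expect_equal(ours$t, unname(ref$statistic))
  expect_equal(ours$p, ref$p.value)
  expect_equal(ours$df, 3)
  expect_error(paired_t(1:3, 1:4), class = "synphys_invalid_parameter")
})

test_that("paired t power matches the noncentral-t closed form", {
  n <- 10
  ncp <- sqrt(n) * 1  # shift of one SD of the differences
  tcrit <- qt(0.975, n - 1)
  power <- 1 - pt(tcrit, n - 1, ncp) + pt(-tcrit, n - 1, ncp)
  set.seed(18)
  rej <- mean(vapply(1:4000, function(i) {
    d <- rnorm(n, 1, 1)
    paired_t(d, rep(0, n))$p < 0.05
  }, logical(1)))
  expect_lt(abs(rej - power), 0.02)
})

test_that("KS statistic identities", {
  x <- c(1, 2, 3, 4)
  expect_equal(ks_two_sample(x, x)$D, 0)
  expect_equal(ks_two_sample(1:10, 101:110)$D, 1)
  expect_error(ks_two_sample(numeric(0), 1:3),
               class = "synphys_invalid_parameter")
})

test_that("equal-sample KS level equals the exact lattice level, not nominal alpha", {
  # with n = m = 100 the attainable levels near 0.05 are P(D >= 0.19) = 0.0539
  # and P(D >= 0.20) = 0.0364; rejection at p < 0.05 realizes the latter
  level <- psmirnov(0.20 - 1e-9, sizes = c(100, 100), lower.tail = FALSE)
  expect_equal(level, 0.0364, tolerance = 0.01)
  set.seed(27)
  B <- 2500
  rej <- mean(vapply(1:B, function(i)
    ks_two_sample(rexp(100), rexp(100))$p < 0.05, logical(1)))
  expect_lt(abs(rej - level), 3 * sqrt(level * (1 - level) / B))
})
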