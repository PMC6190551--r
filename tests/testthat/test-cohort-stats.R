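test_that("one-way ANOVA matches hand arithmetic and stats::aov", {
  # identical groups
  a0 <- one_way_anova(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_equal(a0$F, 0)
  expect_equal(a0$p, 1)
  # hand-computed fixture: SSB = 4, SSW = 1
  a <- one_way_anova(c(1, 2, 3, 4), c("g1", "g1", "g2", "g2"))
  expect_equal(a$F, 8)
  expect_equal(a$df_between, 1)
  expect_equal(a$df_within, 2)
  expect_equal(a$ss_between, 4)
  expect_equal(a$ss_within, 1)
  # oracle equivalence against the fitted linear model on random fixtures
  set.seed(31)
  for (i in 1:10) {
    y <- rnorm(30)
    g <- factor(sample(letters[1:3], 30, replace = TRUE))
    while (any(tabulate(g) < 2)) g <- factor(sample(letters[1:3], 30, TRUE))
    mine <- one_way_anova(y, g)
    ref <- anova(lm(y ~ g))
    expect_equal(mine$F, ref$`F value`[1], tolerance = 1e-9)
    expect_equal(mine$p, ref$`Pr(>F)`[1], tolerance = 1e-9)
  }
  # degenerate: zero within-variance, unequal means
  d <- one_way_anova(c(1, 1, 2, 2), c("a", "a", "b", "b"))
  expect_true(is.infinite(d$F) && d$p == 0 && d$degenerate)
  expect_error(one_way_anova(1:3, c("a", "a", "b")), "at least 2")
})

test_that("sum-of-squares decomposition and F invariances hold", {
  set.seed(8)
  for (i in 1:10) {
    y <- rnorm(40, sd = runif(1, 0.5, 3))
    g <- factor(sample(c("HC", "MM", "HM"), 40, replace = TRUE))
    while (any(tabulate(g) < 2)) g <- factor(sample(c("HC", "MM", "HM"), 40, TRUE))
    a <- one_way_anova(y, g)
    expect_equal(a$ss_total, sum((y - mean(y))^2), tolerance = 1e-9)
    expect_equal(a$ss_between + a$ss_within, a$ss_total, tolerance = 1e-9)
    # location shift and positive scaling leave F untouched
    expect_equal(one_way_anova(y + 17, g)$F, a$F, tolerance = 1e-9)
    expect_equal(one_way_anova(y * 3.5, g)$F, a$F, tolerance = 1e-9)
  }
})

test_that("Fisher LSD matches hand arithmetic and the pooled t-test", {
  lsd <- fisher_lsd(c(1, 2, 3, 4), c("g1", "g1", "g2", "g2"))
  expect_equal(abs(lsd$t), 2 / sqrt(0.5 * (1 / 2 + 1 / 2)), tolerance = 1e-9)
  expect_equal(abs(lsd$t), 2.828, tolerance = 1e-3)
  # identical means: t = 0, p = 1
  lsd0 <- fisher_lsd(c(1, 2, 1, 2), c("a", "a", "b", "b"))
  expect_equal(lsd0$t, 0)
  expect_equal(lsd0$p, 1)
  # k = 2: identical to the pooled two-sample t-test
  set.seed(12)
  for (i in 1:10) {
    x <- rnorm(12); y <- rnorm(15, 0.5)
    lsd2 <- fisher_lsd(c(x, y), rep(c("a", "b"), c(12, 15)))
    tt <- t.test(x, y, var.equal = TRUE)
    expect_equal(abs(lsd2$t), abs(unname(tt$statistic)), tolerance = 1e-9)
    expect_equal(lsd2$p, tt$p.value, tolerance = 1e-9)
  }
  # k = 3: pairwise p equals a pooled t computed from the 3-group MSE
  set.seed(13)
  y <- rnorm(24)
  g <- rep(c("a", "b", "c"), each = 8)
  a <- one_way_anova(y, g)
  lsd3 <- fisher_lsd(y, g, a)
  for (r in seq_len(nrow(lsd3))) {
    mi <- mean(y[g == lsd3$group_i[r]]); mj <- mean(y[g == lsd3$group_j[r]])
    t_manual <- (mi - mj) / sqrt(a$mse * (1 / 8 + 1 / 8))
    p_manual <- 2 * pt(abs(t_manual), a$df_within, lower.tail = FALSE)
    expect_equal(lsd3$t[r], t_manual, tolerance = 1e-9)
    expect_equal(lsd3$p[r], p_manual, tolerance = 1e-9)
  }
})

test_that("Pearson correlation matches cor.test and handles exact fits", {
  x <- 1:10
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  set.seed(21)
  for (i in 1:10) {
    a <- rnorm(25); b <- 0.3 * a + rnorm(25)
    mine <- pearson_correlation(a, b)
    ref <- cor.test(a, b)
    expect_equal(mine$r, unname(ref$estimate), tolerance = 1e-9)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
    expect_equal(mine$n, 25)
  }
  expect_error(pearson_correlation(rep(1, 5), rnorm(5)), "constant")
  expect_error(pearson_correlation(1:2, 2:3), "at least 3")
})

test_that("multiple regression matches the closed-form oracle and lm", {
  # exact linear response
  X <- cbind(a = rnorm(20), b = rnorm(20))
  y <- 2 + 3 * X[, "a"] - X[, "b"]
  fit <- multiple_regression_overall(y, X)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$p, 0)
  # 10-row fixture against normal equations and lm
  set.seed(5)
  X10 <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("x1", "x2", "x3")))
  y10 <- rnorm(10)
  mine <- multiple_regression_overall(y10, X10)
  beta_oracle <- solve(t(cbind(1, X10)) %*% cbind(1, X10),
                       t(cbind(1, X10)) %*% y10)
  expect_equal(unname(mine$coefficients), c(beta_oracle), tolerance = 1e-9)
  ref <- summary(lm(y10 ~ X10))
  expect_equal(mine$F, unname(ref$fstatistic["value"]), tolerance = 1e-9)
  expect_equal(mine$r_squared, ref$r.squared, tolerance = 1e-9)
  # collinearity names the offending column
  Xc <- cbind(u = rnorm(15), v = 1:15, w = 2 * (1:15))
  expect_error(multiple_regression_overall(rnorm(15), Xc), "w")
  expect_error(multiple_regression_overall(rnorm(3), X10[1:3, ]), "more observations")
})

test_that("ANOVA sample size solves the noncentral-F power equation", {
  # monotonicity: doubling the effect size reduces the required N
  n_small <- anova_sample_size(0.5, k_groups = 3)
  n_large <- anova_sample_size(0.25, k_groups = 3)
  expect_lt(n_small, n_large)
  # brute-force noncentral-F grid search oracle
  f <- 0.40; alpha <- 0.05; power <- 0.80; k <- 3
  oracle <- NA
  for (N in seq(2 * k, 600, by = k)) {
    pw <- pf(qf(1 - alpha, k - 1, N - k), k - 1, N - k, ncp = f^2 * N,
             lower.tail = FALSE)
    if (pw >= power) { oracle <- N; break }
  }
  mine <- anova_sample_size(f, alpha, power, k)
  expect_equal(as.numeric(mine), oracle)
  # the step below the answer must miss the target power
  N_below <- mine - k
  pw_below <- pf(qf(1 - alpha, k - 1, N_below - k), k - 1, N_below - k,
                 ncp = f^2 * N_below, lower.tail = FALSE)
  expect_lt(pw_below, power)
})

test_that("the solved sample size achieves its power in simulation", {
  f <- 0.40; k <- 3
  N <- as.numeric(anova_sample_size(f, 0.05, 0.80, k))
  n_per <- N / k
  # group means with population Cohen's f = 0.40: (-d, 0, d), d = f*sigma/sqrt(2/3)
  d <- f / sqrt(2 / 3)
  set.seed(99)
  reps <- 20000
  draws <- matrix(rnorm(reps * N), reps, N)
  draws[, seq_len(n_per)] <- draws[, seq_len(n_per)] - d
  draws[, 2 * n_per + seq_len(n_per)] <- draws[, 2 * n_per + seq_len(n_per)] + d
  gm <- cbind(rowMeans(draws[, seq_len(n_per)]),
              rowMeans(draws[, n_per + seq_len(n_per)]),
              rowMeans(draws[, 2 * n_per + seq_len(n_per)]))
  grand <- rowMeans(draws)
  ssb <- n_per * rowSums((gm - grand)^2)
  ssw <- rowSums((draws - gm[, rep(1:3, each = n_per)])^2)
  f_stat <- (ssb / (k - 1)) / (ssw / (N - k))
  sim_power <- mean(f_stat > qf(0.95, k - 1, N - k))
  expect_gte(sim_power, 0.80 - 0.02)
})

test_that("the full study analysis reports all endpoints coherently", {
  co <- gen_cohort(cohort_gen_params(seed = 2))
  rep <- run_study_analysis(co)
  expect_s3_class(rep, "study_report")
  expect_true(all(c("pr_ud_i", "dbox_superficial", "venular_speed") %in%
                  names(rep$anova)))
  ps <- vapply(rep$anova, `[[`, numeric(1), "p")
  expect_true(all(ps >= 0 & ps <= 1))
  for (e in names(rep$anova)) {
    expect_equal(rep$anova[[e]]$df_between, 2)
    expect_equal(rep$anova[[e]]$df_within, nrow(co) - 3)
    expect_equal(nrow(rep$pairwise[[e]]), 3)
  }
  expect_equal(nrow(rep$correlations), 12)
  expect_equal(rep$regression$df1, 6)
  # listwise deletion is counted
  co2 <- co; co2$pr_ud_i[3] <- NA
  rep2 <- run_study_analysis(co2)
  expect_equal(unname(rep2$n_dropped["pr_ud_i"]), 1)
  expect_equal(rep2$anova$pr_ud_i$df_within, nrow(co) - 1 - 3)
})

test_that("null velocity endpoints keep the nominal type-I rate across seeds", {
  ps <- unlist(lapply(1:200, function(s) {
    co <- gen_cohort(cohort_gen_params(seed = 5000 + s))
    c(one_way_anova(co$arteriolar_speed, co$group)$p,
      one_way_anova(co$venular_speed, co$group)$p)
  }))
  rate <- mean(ps < 0.05)
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.09)
})
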