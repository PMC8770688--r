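test_that("Welch t and Cohen's d reproduce the reference season comparisons", {
  pos2 <- group_summary("positive", 40, 822.32, 87.0)
  aso2 <- group_summary("asocial", 40, 625.88, 97.4)
  tt <- welch_t(pos2, aso2)
  expect_equal(round(tt$statistic, 2), 9.51)
  # the printed 77.02 comes from unrounded data; rounded summaries give 77.03
  expect_lt(abs(tt$df - 77.02), 0.05)
  expect_lt(tt$p, 0.001)
  expect_equal(round(cohens_d(pos2, aso2), 2), 2.13)

  neg3 <- group_summary("negative", 40, 626.9, 176.4)
  aso3 <- group_summary("asocial", 40, 639.0, 146.8)
  expect_equal(round(welch_t(neg3, aso3)$statistic, 2), -0.33)

  same <- group_summary("a", 40, 500, 80)
  other <- group_summary("b", 25, 500, 120)
  expect_equal(welch_t(same, other)$statistic, 0)
  expect_equal(cohens_d(same, other), 0)
  both_flat <- group_summary("c", 10, 500, 0)
  expect_error(welch_t(both_flat, group_summary("d", 10, 500, 0)),
               "zero variance")
  expect_error(cohens_d(both_flat, group_summary("d", 10, 400, 0)),
               "pooled SD")
})

test_that("summary-based tests agree with R's raw-data tests on random inputs", {
  set.seed(41)
  for (i in 1:1000) {
    n1 <- sample(5:60, 1); n2 <- sample(5:60, 1)
    x <- sample_with_moments(n1, runif(1, 0, 900), runif(1, 1, 150))
    y <- sample_with_moments(n2, runif(1, 0, 900), runif(1, 1, 150))
    g1 <- summarize_group(x); g2 <- summarize_group(y)

    ours <- welch_t(g1, g2)
    ref <- t.test(x, y)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
    # Welch df bounds and group-swap symmetry
    expect_gte(ours$df, min(n1, n2) - 1 - 1e-9)
    expect_lte(ours$df, n1 + n2 - 2 + 1e-9)
    swapped <- welch_t(g2, g1)
    expect_equal(swapped$statistic, -ours$statistic)
    expect_equal(swapped$p, ours$p)

    fv <- f_variance_test(var(x), n1, var(y), n2)
    fref <- var.test(x, y)
    expect_equal(fv$statistic, unname(fref$statistic), tolerance = 1e-10)
    expect_equal(fv$p, fref$p.value, tolerance = 1e-10)

    mu0 <- runif(1, 0, 900)
    ot <- one_sample_t(g1, mu0)
    oref <- t.test(x, mu = mu0)
    expect_equal(ot$statistic, unname(oref$statistic), tolerance = 1e-10)
    expect_equal(ot$p, oref$p.value, tolerance = 1e-10)
  }
})

test_that("the F-test p-value matches numerical integration of the F density", {
  fv <- f_variance_test(0.89 * 4, 40, 4, 40)
  lower_tail <- integrate(function(x) df(x, 39, 39), 0, 0.89,
                          rel.tol = 1e-10)$value
  expect_equal(fv$statistic, 0.89)
  expect_equal(fv$p, 2 * lower_tail, tolerance = 1e-6)
  # the reference p of 0.728 reflects an unrounded F near 0.894; F = 0.89
  # exactly gives 0.718
  expect_lt(abs(fv$p - 0.728), 0.015)
  expect_equal(f_variance_test(4, 40, 8, 40)$statistic, 0.5)
  expect_equal(f_variance_test(4, 40, 8, 40)$df, c(39, 39))
  expect_equal(f_variance_test(6, 12, 6, 30)$statistic, 1)
})

test_that("one-sample t behaves as the formula dictates", {
  g <- group_summary("ratings", 40, 4.7, 1.75)
  tt <- one_sample_t(g, 4)
  expect_equal(round(tt$statistic, 1), 2.5)
  expect_equal(tt$df, 39)
  expect_equal(one_sample_t(g, 4.7)$statistic, 0)
  g2 <- group_summary("ratings", 80, 4.7, 1.75)
  expect_equal(one_sample_t(g2, 4)$statistic, tt$statistic * sqrt(2),
               tolerance = 1e-12)
  expect_error(one_sample_t(group_summary("x", 10, 1, 0), 0), "sd is zero")
})

test_that("Bonferroni threshold is alpha over the number of comparisons", {
  expect_equal(bonferroni_threshold(0.05, 6), 0.05 / 6)
  expect_equal(round(bonferroni_threshold(0.05, 6), 4), 0.0083)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 4), 0.0025)
})

test_that("compare_conditions recovers a built-in condition effect", {
  targets <- tibble::tibble(
    condition = rep(c("asocial", "positive", "negative"), each = 3),
    season = rep(1:3, 3),
    mean = c(rep(600, 3), rep(750, 3), rep(600, 3)),  # +150 for positive
    sd = rep(90, 9))
  d <- generate_fixture(
    fixture_spec(n_per_condition = 40, targets = targets,
                 trials_per_season = 10), seed = 50)
  res <- compare_conditions(d)
  expect_equal(nrow(res), 6)  # 2 social conditions x 3 seasons
  expect_equal(unique(res$alpha_bonferroni), 0.05 / 6)
  pos <- res[res$comparison == "positive vs asocial", ]
  expect_true(all(pos$t > 0))
  expect_true(all(pos$significant))
  neg <- res[res$comparison == "negative vs asocial", ]
  expect_false(any(neg$significant))
})

test_that("identical score distributions produce no significant comparisons", {
  set.seed(51)
  base <- tidyr::expand_grid(agent_id = 1:20, season = 1:2, trial = 1:5)
  base$true_fitness <- rnorm(nrow(base), 500, 50)
  d <- dplyr::bind_rows(
    dplyr::mutate(base, condition = "asocial"),
    dplyr::mutate(base, condition = "positive"))
  res <- compare_conditions(d)
  expect_true(all(abs(res$t) < 1e-8))
  expect_false(any(res$significant))
})

test_that("participant-seasons with missing trials are excluded with a warning", {
  targets <- tibble::tibble(condition = rep(c("asocial", "positive"), each = 1),
                            season = 1, mean = c(500, 500), sd = c(50, 50))
  d <- generate_fixture(
    fixture_spec(n_per_condition = 10, conditions = c("asocial", "positive"),
                 targets = targets, trials_per_season = 6, n_seasons = 1),
    seed = 52)
  d_broken <- d[!(d$agent_id == 1 & d$condition == "asocial" & d$trial > 2), ]
  expect_warning(res <- compare_conditions(d_broken), "missing trials")
  expect_equal(res$n2, 9)  # one asocial participant dropped
  expect_equal(res$n1, 10)
})
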