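#' Group summary (n, mean, SD)
#'
#' Compact sufficient statistics for the two-sample comparisons in the
#' analysis pipeline.
#'
#' @param label Group label.
#' @param n Sample size (>= 2).
#' @param mean Group mean, in score units.
#' @param sd Group standard deviation (>= 0).
#' @return An object of class `group_summary`.
#' @export
group_summary <- function(label, n, mean, sd) {
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  if (sd < 0) stop("sd must be >= 0", call. = FALSE)
  structure(list(label = label, n = as.integer(n),
                 mean = as.numeric(mean), sd = as.numeric(sd)),
            class = "group_summary")
}

#' Summarize a numeric sample as a group summary
#'
#' @param x Numeric vector with at least 2 values.
#' @param label Group label.
#' @return A [group_summary()].
#' @export
summarize_group <- function(x, label = "group") {
  group_summary(label, length(x), mean(x), stats::sd(x))
}

test_result <- function(statistic, df, p, method, effect_size = NA_real_,
                        alpha_used = NA_real_) {
  structure(list(statistic = statistic, df = df, p = p, method = method,
                 effect_size = effect_size, alpha_used = alpha_used),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g",
              x$method, x$statistic, paste(signif(x$df, 6), collapse = ", "),
              x$p))
  if (!is.na(x$effect_size)) cat(sprintf(", d = %.3f", x$effect_size))
  cat("\n")
  invisible(x)
}

#' Welch's two-sample t-test from group summaries
#'
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with Welch–Satterthwaite
#' degrees of freedom and a two-sided p-value. Does not assume equal
#' variances.
#'
#' @param g1,g2 [group_summary()] objects.
#' @return A `test_result` with `statistic`, `df` (fractional), `p`.
#' @examples
#' welch_t(group_summary("positive", 40, 822.32, 87.0),
#'         group_summary("asocial", 40, 625.88, 97.4))
#' @export
welch_t <- function(g1, g2) {
  v1 <- g1$sd^2 / g1$n
  v2 <- g2$sd^2 / g2$n
  if (v1 + v2 == 0) {
    stop("both groups have zero variance: t statistic undefined",
         call. = FALSE)
  }
  t_stat <- (g1$mean - g2$mean) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (g1$n - 1) + v2^2 / (g2$n - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  test_result(t_stat, df, p, "Welch two-sample t-test")
}

#' Cohen's d (pooled-SD form)
#'
#' Standardized mean difference
#' `(m1 - m2) / sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`.
#'
#' @param g1,g2 [group_summary()] objects.
#' @return The effect size, a plain number.
#' @export
cohens_d <- function(g1, g2) {
  pooled <- sqrt(((g1$n - 1) * g1$sd^2 + (g2$n - 1) * g2$sd^2) /
                   (g1$n + g2$n - 2))
  if (pooled == 0) stop("pooled SD is zero: d undefined", call. = FALSE)
  (g1$mean - g2$mean) / pooled
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise alpha.
#' @param m Number of comparisons.
#' @return `alpha / m`.
#' @examples
#' bonferroni_threshold(0.05, 6)  # 0.00833..., two comparisons x three seasons
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  alpha / m
}

#' F-test for equality of two variances
#'
#' `F = var1 / var2` on `(n1 - 1, n2 - 1)` degrees of freedom with a
#' two-sided p-value.
#'
#' @param var1,var2 Sample variances (> 0).
#' @param n1,n2 Sample sizes.
#' @return A `test_result`; `df` is the `(df1, df2)` pair.
#' @export
f_variance_test <- function(var1, n1, var2, n2) {
  if (var1 <= 0 || var2 <= 0) stop("variances must be positive", call. = FALSE)
  f <- var1 / var2
  df1 <- n1 - 1
  df2 <- n2 - 1
  lower <- stats::pf(f, df1, df2)
  p <- 2 * min(lower, 1 - lower)
  test_result(f, c(df1, df2), min(p, 1), "F test of equal variances")
}

#' One-sample t-test from a group summary
#'
#' Tests whether the group mean differs from `mu0`;
#' `t = (mean - mu0) / (sd / sqrt(n))` on `n - 1` degrees of freedom,
#' two-sided.
#'
#' @param g A [group_summary()].
#' @param mu0 Null value, in score units.
#' @return A `test_result`.
#' @export
one_sample_t <- function(g, mu0) {
  if (g$sd == 0) stop("sd is zero: t statistic undefined", call. = FALSE)
  t_stat <- (g$mean - mu0) / (g$sd / sqrt(g$n))
  df <- g$n - 1
  p <- 2 * stats::pt(-abs(t_stat), df)
  test_result(t_stat, df, p, "one-sample t-test")
}

#' Compare social-learning conditions against the asocial baseline
#'
#' Reproduces the season-level analysis: each participant's overall
#' performance in a season is their mean score over that season's
#' trials; for every season, each social condition is compared with the
#' asocial baseline by Welch's t-test with Cohen's d, and the
#' significance threshold is Bonferroni-corrected for the total number
#' of comparisons.
#'
#' Participant-seasons with an incomplete set of trials are excluded
#' with a warning.
#'
#' @param trials Trial-level tibble (schema of [write_trial_csv()]; any
#'   table with `agent_id`, `condition`, `season`, `trial` and the score
#'   column works).
#' @param score Column holding the per-trial score (default
#'   `"true_fitness"`).
#' @param baseline Baseline condition label (default `"asocial"`).
#' @param alpha Family-wise alpha before correction (default 0.05).
#' @return A tibble with one row per (social condition, season):
#'   `comparison`, `season`, `n1`, `n2`, `mean1`, `mean2`, `sd1`, `sd2`,
#'   `t`, `df`, `p`, `d`, `alpha_bonferroni`, `significant`.
#' @export
compare_conditions <- function(trials, score = "true_fitness",
                               baseline = "asocial", alpha = 0.05) {
  stopifnot(score %in% names(trials))
  conds <- unique(trials$condition)
  if (!baseline %in% conds || length(conds) < 2) {
    stop("trials must contain the baseline condition and at least one other",
         call. = FALSE)
  }
  expected_trials <- trials |>
    dplyr::group_by(.data$season) |>
    dplyr::summarise(expected = max(.data$trial), .groups = "drop")
  season_means <- trials |>
    dplyr::group_by(.data$condition, .data$season, .data$agent_id) |>
    dplyr::summarise(mean_score = mean(.data[[score]]),
                     n_trials = dplyr::n(), .groups = "drop") |>
    dplyr::left_join(expected_trials, by = "season")
  incomplete <- season_means |> dplyr::filter(.data$n_trials < .data$expected)
  if (nrow(incomplete) > 0) {
    warning(sprintf("excluding %d participant-season(s) with missing trials",
                    nrow(incomplete)), call. = FALSE)
    season_means <- season_means |>
      dplyr::filter(.data$n_trials >= .data$expected)
  }
  social_conds <- setdiff(conds, baseline)
  seasons <- sort(unique(season_means$season))
  m <- length(social_conds) * length(seasons)
  alpha_b <- bonferroni_threshold(alpha, m)
  rows <- list()
  for (cond in social_conds) {
    for (s in seasons) {
      x1 <- season_means$mean_score[season_means$condition == cond &
                                      season_means$season == s]
      x2 <- season_means$mean_score[season_means$condition == baseline &
                                      season_means$season == s]
      g1 <- summarize_group(x1, cond)
      g2 <- summarize_group(x2, baseline)
      tt <- welch_t(g1, g2)
      rows[[length(rows) + 1]] <- tibble::tibble(
        comparison = paste(cond, "vs", baseline), season = s,
        n1 = g1$n, n2 = g2$n, mean1 = g1$mean, mean2 = g2$mean,
        sd1 = g1$sd, sd2 = g2$sd,
        t = tt$statistic, df = tt$df, p = tt$p, d = cohens_d(g1, g2),
        alpha_bonferroni = alpha_b, significant = tt$p < alpha_b)
    }
  }
  dplyr::bind_rows(rows)
}

#' Reference condition summaries of the virtual arrowhead experiment
#'
#' Season-level performance summaries (mean and SD of participants'
#' season-mean scores, n = 40 per condition) reported for the
#' three-condition virtual arrowhead experiment that this package
#' models. Useful as targets for the synthetic fixture generator and as
#' inputs to the summary-based tests.
#'
#' @return A tibble with columns `condition`, `season`, `mean`, `sd`,
#'   `n`.
#' @export
reference_condition_summaries <- function() {
  tibble::tibble(
    condition = rep(c("positive", "negative", "asocial"), each = 3),
    season = rep(1:3, times = 3),
    mean = c(599.9, 822.32, 796.9,
             613.3, 638.2, 626.9,
             543.4, 625.88, 639.0),
    sd = c(126.2, 87.0, 116.2,
           162.9, 111.3, 176.4,
           120.9, 97.4, 146.8),
    n = 40L
  )
}
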