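# Shared fixtures and independent reference implementations used to
# cross-check the package's algorithms.

# A landscape in which only `length` contributes, so learning is
# effectively one-dimensional. noise_sd = 0 makes scores deterministic.
one_d_landscape <- function(optimum = 57, width = 12, noise_sd = 0) {
  make_landscape(
    season = 1,
    optima = c(length = optimum, width = 50, thickness = 50),
    maxima = c(length = 1000, width = 0, thickness = 0),
    widths = c(length = width, width = 10, thickness = 10),
    noise_sd = noise_sd)
}

random_calibrated_landscape <- function(noise_sd = 0) {
  m <- stats::runif(3)
  m <- m / sum(m) * 1000
  make_landscape(
    season = 1,
    optima = c(length = sample(10:90, 1), width = sample(10:90, 1),
               thickness = sample(10:90, 1)),
    maxima = c(length = m[1], width = m[2], thickness = m[3]),
    widths = c(length = stats::runif(1, 5, 30),
               width = stats::runif(1, 5, 30),
               thickness = stats::runif(1, 5, 30)),
    noise_sd = noise_sd)
}

# Brute-force Win-Stay reference: a direct transcription of the rule for
# a single attribute on a deterministic (noise-free) landscape, kept
# independent of the package's agent code. Returns the attribute value
# after each of n trials.
brute_force_win_stay_1d <- function(start, direction, n_trials, landscape,
                                    step = 5) {
  val <- start
  prev <- NA_real_
  out <- numeric(n_trials)
  for (t in seq_len(n_trials)) {
    val_new <- min(max(val + direction * step, 1), 100)
    # the agent reacts to the displayed score: noise-free here, but still
    # clamped to the printed 1..1000 range
    score <- expected_fitness(arrowhead(val_new, 50, 50), landscape)
    score <- min(max(score, 1), 1000)
    if (!is.na(prev) && score < prev) direction <- -direction
    val <- val_new
    prev <- score
    out[t] <- val
  }
  out
}

# Draw a sample with exactly the requested mean and SD, so t statistics
# computed from raw data equal those computed from the summaries.
sample_with_moments <- function(n, mean, sd) {
  x <- stats::rnorm(n)
  mean + (x - base::mean(x)) / stats::sd(x) * sd
}
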