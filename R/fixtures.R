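#' Specification for synthetic trial-level datasets
#'
#' The fixture generator emulates the trial-level dataset of a
#' three-condition virtual arrowhead experiment, giving the analysis
#' pipeline a download-free test surface. Two modes exist:
#'
#' * `simulate = FALSE` (default): participant season-mean scores are
#'   drawn from per-(condition, season) normal targets, and per-trial
#'   scores scatter around each participant's mean with SD
#'   `trial_sd`, centred so the participant's season mean is exact.
#'   Group summaries of the resulting dataset are then draws from the
#'   stated targets.
#' * `simulate = TRUE`: trial records come from the agent-based engine
#'   ([run_cohort()]) with the condition mapped to its learning
#'   algorithm.
#'
#' @param n_per_condition Participants per condition (default 40).
#' @param conditions Condition labels (default the standard three).
#' @param targets Tibble with columns `condition`, `season`, `mean`,
#'   `sd` covering every condition x season; default
#'   [reference_condition_summaries()]. Ignored when `simulate = TRUE`.
#' @param trial_sd Within-participant per-trial SD around the season
#'   mean, in calories (default 50). Ignored when `simulate = TRUE`.
#' @param trials_per_season,n_seasons Shape of the design (defaults 30
#'   and 3).
#' @param simulate Generate via the simulation engine instead of the
#'   summary targets.
#' @param landscapes Landscapes for `simulate = TRUE`; default
#'   [demo_landscapes()].
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_per_condition = 40,
                         conditions = c("asocial", "positive", "negative"),
                         targets = reference_condition_summaries(),
                         trial_sd = 50,
                         trials_per_season = 30, n_seasons = 3,
                         simulate = FALSE, landscapes = demo_landscapes()) {
  if (n_per_condition < 2) stop("n_per_condition must be >= 2", call. = FALSE)
  structure(list(n_per_condition = as.integer(n_per_condition),
                 conditions = conditions, targets = targets,
                 trial_sd = trial_sd,
                 trials_per_season = as.integer(trials_per_season),
                 n_seasons = as.integer(n_seasons),
                 simulate = simulate, landscapes = landscapes),
            class = "fixture_spec")
}

#' Generate a synthetic trial-level dataset
#'
#' @param spec A [fixture_spec()].
#' @param seed Master seed for all randomness in the fixture.
#' @return A trial-record tibble in the [write_trial_csv()] schema
#'   (`algorithm` column omitted). In target mode scores are synthetic
#'   summaries, not landscape evaluations, and are not clamped to the
#'   displayed-score range.
#' @examples
#' d <- generate_fixture(fixture_spec(n_per_condition = 5), seed = 1)
#' dplyr::count(d, condition)
#' @export
generate_fixture <- function(spec, seed = 1) {
  if (spec$simulate) {
    set.seed(seed)
    cohort_seeds <- sample.int(.Machine$integer.max - 1L,
                               length(spec$conditions))
    out <- lapply(seq_along(spec$conditions), function(i) {
      cfg <- simulation_config(
        condition = spec$conditions[i], n_agents = spec$n_per_condition,
        seed = cohort_seeds[i], landscapes = spec$landscapes,
        trials_per_season = spec$trials_per_season)
      run_cohort(cfg)$trials
    })
    return(dplyr::bind_rows(out))
  }
  needed <- tidyr::expand_grid(condition = spec$conditions,
                               season = seq_len(spec$n_seasons))
  have <- dplyr::semi_join(needed, spec$targets,
                           by = c("condition", "season"))
  if (nrow(have) < nrow(needed)) {
    stop("targets must cover every condition x season", call. = FALSE)
  }
  set.seed(seed)
  nt <- spec$trials_per_season
  np <- spec$n_per_condition
  rows <- lapply(spec$conditions, function(cond) {
    lapply(seq_len(spec$n_seasons), function(s) {
      tg <- spec$targets[spec$targets$condition == cond &
                           spec$targets$season == s, ]
      m <- stats::rnorm(np, tg$mean[1], tg$sd[1])
      e <- matrix(stats::rnorm(np * nt, 0, spec$trial_sd), nrow = nt)
      e <- sweep(e, 2, colMeans(e))   # centred: season mean is exactly m
      scores <- as.vector(sweep(e, 2, m, `+`))
      tibble::tibble(
        agent_id = rep(seq_len(np), each = nt),
        condition = cond, season = s,
        trial = rep(seq_len(nt), times = np),
        length = 50, width = 50, thickness = 50,
        shape = 1L, color = 1L,
        true_fitness = scores,
        perceived_score = scores + stats::rnorm(np * nt, 0, 5),
        social_event = FALSE)
    })
  })
  dplyr::bind_rows(unlist(rows, recursive = FALSE))
}
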