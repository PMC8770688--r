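#' Configuration of a cohort simulation
#'
#' The standard design runs each agent through three seasons of 30
#' trials. The landscape changes between seasons and stays fixed within
#' a season. In the positive and negative conditions, social-learning
#' opportunities arrive once every `social_period` trials in Seasons 2
#' and 3 (on trials `social_phase`, `social_phase + social_period`, ...);
#' Season 1 is always asocial. On a social trial the social update
#' replaces the Win-Stay modification, so every trial changes the design
#' exactly once, mirroring one hunt per trial.
#'
#' @param condition `"asocial"`, `"positive"` (CSI agents observing
#'   better exemplars) or `"negative"` (Reverse agents observing worse
#'   exemplars).
#' @param n_agents Number of independent agents in the cohort.
#' @param seed Master seed; every agent gets an independent substream
#'   derived from it.
#' @param landscapes Named list of `fitness_landscape` objects in season
#'   order, e.g. from [demo_landscapes()] or [read_landscape_config()].
#' @param trials_per_season Trials per season (default 30).
#' @param social_period Trials between social-learning opportunities
#'   (default 3; must be at least 2, since exemplars derive from the
#'   previous trial).
#' @param social_phase First social trial within a social season
#'   (default 2, the earliest trial with a previous score to reference).
#' @param social_seasons Seasons with social opportunities (default 2:3).
#' @param step_size Win-Stay modification size `L_i` (default 5).
#' @param social_params Optional [social_info_params()]; by default
#'   simulation-mode parameters matching `condition` (3 hunters,
#'   magnitude `|N(10, 10^2)|`, 10000 resamples).
#' @param initial_design Optional `arrowhead` shared by all agents; by
#'   default each agent starts from a uniformly random design.
#' @param flip_at_wall Passed to [agent_params()].
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(condition = c("asocial", "positive", "negative"),
                              n_agents = 100, seed = 1,
                              landscapes = demo_landscapes(),
                              trials_per_season = 30,
                              social_period = 3, social_phase = 2,
                              social_seasons = c(2, 3),
                              step_size = 5, social_params = NULL,
                              initial_design = NULL,
                              flip_at_wall = FALSE) {
  condition <- match.arg(condition)
  if (social_period < 2) {
    stop("social_period must be >= 2: social information derives from a previous trial",
         call. = FALSE)
  }
  if (social_phase < 2) {
    stop("social_phase must be >= 2: the first trial has no previous score",
         call. = FALSE)
  }
  if (condition != "asocial" && is.null(social_params)) {
    social_params <- social_info_params(
      condition = condition, mode = "simulation")
  }
  algorithm <- switch(condition, asocial = "asocial",
                      positive = "CSI", negative = "Reverse")
  structure(
    list(condition = condition, algorithm = algorithm,
         n_agents = as.integer(n_agents), seed = as.integer(seed),
         landscapes = landscapes,
         trials_per_season = as.integer(trials_per_season),
         social_period = as.integer(social_period),
         social_phase = as.integer(social_phase),
         social_seasons = as.integer(social_seasons),
         step_size = step_size, social_params = social_params,
         initial_design = initial_design, flip_at_wall = flip_at_wall),
    class = "simulation_config"
  )
}

social_trials <- function(config) {
  seq(config$social_phase, config$trials_per_season, by = config$social_period)
}

random_arrowhead <- function() {
  v <- sample(ATTR_MIN:ATTR_MAX, 3, replace = TRUE)
  arrowhead(v[1], v[2], v[3],
            shape = sample(N_OPTIONS, 1), color = sample(N_OPTIONS, 1))
}

#' Run one agent through all seasons
#'
#' Uses the current state of R's random number stream; [run_cohort()]
#' seeds an independent substream per agent. The agent follows the
#' Win-Stay rule on every trial except scheduled social trials, where
#' the CSI or Reverse update is applied to the previous trial's design
#' using freshly generated exemplar hunters, the new design is scored,
#' and the previous-score memory is refreshed (direction memory is left
#' untouched; only Win-Stay trials update it). At a season boundary the
#' design carries over but the previous-score memory resets, because the
#' landscape changed.
#'
#' @param config A [simulation_config()].
#' @param agent_id Identifier written into the records.
#' @return A tibble of `trials_per_season * n_seasons` trial records
#'   with columns `agent_id`, `condition`, `season`, `trial`, the five
#'   attribute values, `true_fitness`, `perceived_score`,
#'   `social_event`, `algorithm`.
#' @export
run_agent <- function(config, agent_id = 1L) {
  init <- if (is.null(config$initial_design)) random_arrowhead()
          else config$initial_design
  params <- agent_params(step_size = config$step_size,
                         algorithm = config$algorithm,
                         flip_at_wall = config$flip_at_wall)
  state <- init_agent(params, init)
  n_seasons <- length(config$landscapes)
  n_total <- n_seasons * config$trials_per_season
  soc_sched <- social_trials(config)

  season_v <- integer(n_total); trial_v <- integer(n_total)
  attr_m <- matrix(0, n_total, 5,
                   dimnames = list(NULL, c(CONTINUOUS_ATTRS, CATEGORICAL_ATTRS)))
  true_v <- numeric(n_total); perc_v <- numeric(n_total)
  soc_v <- logical(n_total); alg_v <- character(n_total)

  i <- 0L
  for (s in seq_len(n_seasons)) {
    landscape <- config$landscapes[[s]]
    state$prev_score <- NA_real_  # the landscape changed; old score is stale
    for (t in seq_len(config$trials_per_season)) {
      i <- i + 1L
      is_social <- config$condition != "asocial" &&
        landscape$season %in% config$social_seasons && t %in% soc_sched
      if (is_social) {
        reference <- state$design
        hunters <- generate_hunters(reference, state$prev_score, landscape,
                                    config$social_params)
        deltas <- hunter_deltas(hunters)
        design <- if (config$algorithm == "CSI") csi_update(reference, deltas)
                  else reverse_update(reference, deltas)
        score <- perceived_score(design, landscape)
        state$design <- design
        state$prev_score <- score
        true_fit <- expected_fitness(design, landscape)
        alg <- config$algorithm
      } else {
        step <- win_stay_step(state, landscape)
        state <- step$state
        score <- step$record$perceived_score
        true_fit <- step$record$true_fitness
        alg <- "win_stay"
      }
      season_v[i] <- landscape$season; trial_v[i] <- t
      attr_m[i, ] <- c(continuous_values(state$design),
                       state$design$shape, state$design$color)
      true_v[i] <- true_fit; perc_v[i] <- score
      soc_v[i] <- is_social; alg_v[i] <- alg
    }
  }
  tibble::tibble(
    agent_id = agent_id, condition = config$condition,
    season = season_v, trial = trial_v,
    length = attr_m[, "length"], width = attr_m[, "width"],
    thickness = attr_m[, "thickness"],
    shape = as.integer(attr_m[, "shape"]), color = as.integer(attr_m[, "color"]),
    true_fitness = true_v, perceived_score = perc_v,
    social_event = soc_v, algorithm = alg_v
  )
}

#' Run a cohort of agents and summarize trajectories
#'
#' Seeds R's random number generator from the master seed, derives one
#' independent substream seed per agent, and runs each agent with
#' [run_agent()]. The trajectory summary is computed on true fitness,
#' i.e. excluding perception error.
#'
#' @param config A [simulation_config()] with `n_agents >= 2`.
#' @return A list with elements `trials` (row-bound agent records) and
#'   `summary` (see [summarize_trajectories()]).
#' @export
run_cohort <- function(config) {
  if (config$n_agents < 2) stop("n_agents must be >= 2", call. = FALSE)
  set.seed(config$seed)
  agent_seeds <- sample.int(.Machine$integer.max - 1L, config$n_agents)
  trials <- dplyr::bind_rows(lapply(seq_len(config$n_agents), function(a) {
    set.seed(agent_seeds[a])
    run_agent(config, agent_id = a)
  }))
  list(trials = trials, summary = summarize_trajectories(trials))
}

#' Cohort-level trajectory summary
#'
#' Mean, SD, SE and n of true fitness per (condition, season, trial) —
#' the quantities plotted as mean-trajectory and SD-trajectory panels.
#'
#' @param trials Trial-record tibble from [run_agent()], [run_cohort()]
#'   or [read_trial_csv()]; cohorts for several conditions can be
#'   row-bound first.
#' @return A tibble with columns `condition`, `season`, `trial`,
#'   `mean_fitness`, `sd_fitness`, `se_fitness`, `n`.
#' @export
summarize_trajectories <- function(trials) {
  trials |>
    dplyr::group_by(.data$condition, .data$season, .data$trial) |>
    dplyr::summarise(
      mean_fitness = mean(.data$true_fitness),
      sd_fitness = stats::sd(.data$true_fitness),
      se_fitness = stats::sd(.data$true_fitness) / sqrt(dplyr::n()),
      n = dplyr::n(), .groups = "drop")
}

TRIAL_CSV_COLS <- c("agent_id", "condition", "season", "trial",
                    "length", "width", "thickness", "shape", "color",
                    "true_fitness", "perceived_score", "social_event")

#' Write trial records to CSV
#'
#' Fixed-schema interchange format; [read_trial_csv()] round-trips it
#' losslessly.
#'
#' @param trials Trial-record tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trials, path) {
  missing <- setdiff(TRIAL_CSV_COLS, names(trials))
  if (length(missing) > 0) {
    stop("trial table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  utils::write.csv(as.data.frame(trials[TRIAL_CSV_COLS]), path,
                   row.names = FALSE)
  invisible(path)
}

#' Read trial records from CSV
#'
#' @param path CSV file with the schema written by [write_trial_csv()].
#' @return A trial-record tibble.
#' @export
read_trial_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(TRIAL_CSV_COLS, names(df))
  if (length(missing) > 0) {
    stop("trial CSV lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$social_event <- as.logical(df$social_event)
  tibble::as_tibble(df)
}
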