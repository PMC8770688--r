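#' Agent parameters
#'
#' @param step_size Asocial modification size `L_i` in attribute units,
#'   default 5 (the median empirical modification size in virtual
#'   arrowhead experiments).
#' @param algorithm Learning algorithm: `"asocial"` (pure Win-Stay),
#'   `"CSI"` (copy-successful-individuals on positive social
#'   information), or `"Reverse"` (negation of the modifications of
#'   unsuccessful exemplars).
#' @param flip_at_wall When a step is clamped at an attribute bound and
#'   the design does not change, should the direction memory be flipped
#'   anyway? Off by default: the Win-Stay rule as stated only flips on a
#'   score decrease.
#' @return An object of class `agent_params`.
#' @export
agent_params <- function(step_size = 5,
                         algorithm = c("asocial", "CSI", "Reverse"),
                         flip_at_wall = FALSE) {
  algorithm <- match.arg(algorithm)
  if (step_size < 1) stop("step_size must be >= 1", call. = FALSE)
  structure(list(step_size = step_size, algorithm = algorithm,
                 flip_at_wall = flip_at_wall),
            class = "agent_params")
}

#' Initialize a Win-Stay learner
#'
#' The agent's memory holds its current design, the perceived score of
#' the previous trial (unset until the first hunt of a season), and one
#' modification direction (+1 or -1) per continuous attribute, drawn
#' uniformly at random.
#'
#' @param params An [agent_params()] object.
#' @param initial_design The agent's starting `arrowhead`.
#' @return An object of class `agent_state`.
#' @export
init_agent <- function(params, initial_design) {
  validate_arrowhead(initial_design)
  dirs <- sample(c(-1, 1), length(CONTINUOUS_ATTRS), replace = TRUE)
  names(dirs) <- CONTINUOUS_ATTRS
  structure(
    list(params = params, design = initial_design,
         prev_score = NA_real_, directions = dirs),
    class = "agent_state"
  )
}

#' One Win-Stay trial
#'
#' The agent picks one continuous attribute uniformly at random (or from
#' `attributes`), moves it by `step_size` units in the memorized
#' direction (clamped to \[1, 100\]), and goes hunting. If the perceived
#' score did not decrease relative to the previous trial the direction
#' for the focal attribute is kept; if it decreased, the direction is
#' flipped. Exactly one attribute's direction can change per trial. On
#' the first trial of a season there is no previous score, so the score
#' is stored without any flip.
#'
#' @param state An `agent_state`.
#' @param landscape A `fitness_landscape`.
#' @param attributes Candidate attributes to sample the focal attribute
#'   from; defaults to all three continuous attributes. Restricting this
#'   to one attribute yields a 1-D learner, useful for analysing the rule
#'   in isolation.
#' @return A list with elements `state` (updated `agent_state`) and
#'   `record` (list: `focal`, `true_fitness`, `perceived_score`,
#'   `flipped`).
#' @export
win_stay_step <- function(state, landscape, attributes = CONTINUOUS_ATTRS) {
  focal <- if (length(attributes) == 1) attributes else sample(attributes, 1)
  old_val <- state$design[[focal]]
  new_val <- clamp(old_val + state$directions[[focal]] * state$params$step_size,
                   ATTR_MIN, ATTR_MAX)
  design <- state$design
  design[[focal]] <- new_val
  score <- perceived_score(design, landscape)
  flipped <- FALSE
  if (!is.na(state$prev_score) && score < state$prev_score) {
    state$directions[[focal]] <- -state$directions[[focal]]
    flipped <- TRUE
  } else if (state$params$flip_at_wall && new_val == old_val) {
    state$directions[[focal]] <- -state$directions[[focal]]
    flipped <- TRUE
  }
  state$design <- design
  state$prev_score <- score
  list(state = state,
       record = list(focal = focal,
                     true_fitness = expected_fitness(design, landscape),
                     perceived_score = score, flipped = flipped))
}

check_deltas <- function(deltas) {
  if (!setequal(names(deltas), CONTINUOUS_ATTRS) ||
      length(deltas) != length(CONTINUOUS_ATTRS)) {
    stop("deltas must name each of length, width, thickness exactly once",
         call. = FALSE)
  }
  deltas[CONTINUOUS_ATTRS]
}

#' Copy-successful-individuals (CSI) update
#'
#' Adopts all single-attribute modifications shown by the exemplar
#' hunters at once: each hunter moved one attribute, so applying every
#' delta to the reference combines their improvements. On an additive
#' landscape the result's expected fitness is at least that of any
#' single-delta hunter design (unless clamping at an attribute bound
#' binds).
#'
#' @param reference The agent's reference `arrowhead` (previous trial's
#'   design).
#' @param deltas Named numeric vector with one signed delta per
#'   continuous attribute.
#' @return The updated `arrowhead`, clamped to the attribute range.
#' @export
csi_update <- function(reference, deltas) {
  deltas <- check_deltas(deltas)
  set_continuous(reference, continuous_values(reference) + deltas)
}

#' Reverse (negative observational learning) update
#'
#' Moves each attribute in the direction opposite to the modification
#' made by the corresponding unsuccessful hunter: a hunter that worsened
#' attribute `j` by `L_sj` leads the agent to modify `j` by `-L_sj`.
#' Algebraically `reverse_update(x, d) == csi_update(x, -d)`.
#'
#' @inheritParams csi_update
#' @return The updated `arrowhead`, clamped to the attribute range.
#' @export
reverse_update <- function(reference, deltas) {
  csi_update(reference, -check_deltas(deltas))
}
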