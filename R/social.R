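#' Parameters of the social-information ("other hunters") generator
#'
#' Exemplar hunters are single-attribute perturbations of the learner's
#' previous design, constrained to be strictly better (positive
#' condition) or strictly worse (negative condition) than the reference
#' in both true and perceived performance.
#'
#' @param condition `"positive"` or `"negative"`.
#' @param mode `"experiment"` (4 hunters, as shown to participants) or
#'   `"simulation"` (3 hunters, exactly one per continuous attribute).
#' @param n_hunters Number of hunters; defaults to 4 in experiment mode
#'   and 3 in simulation mode.
#' @param magnitude_mean,magnitude_sd Parameters of the normal
#'   distribution whose absolute value gives the modification magnitude,
#'   in attribute units (defaults 10 and 10).
#' @param max_resamples Maximum number of (magnitude, noise) resampling
#'   attempts per hunter before falling back to a copy of the reference
#'   (default 10000).
#' @return An object of class `social_info_params`.
#' @export
social_info_params <- function(condition = c("positive", "negative"),
                               mode = c("experiment", "simulation"),
                               n_hunters = NULL,
                               magnitude_mean = 10, magnitude_sd = 10,
                               max_resamples = 10000) {
  condition <- match.arg(condition)
  mode <- match.arg(mode)
  if (is.null(n_hunters)) n_hunters <- if (mode == "experiment") 4L else 3L
  if (mode == "simulation" && n_hunters != length(CONTINUOUS_ATTRS)) {
    stop("simulation mode uses exactly one hunter per continuous attribute",
         call. = FALSE)
  }
  if (n_hunters < 1 || max_resamples < 1) {
    stop("n_hunters and max_resamples must be >= 1", call. = FALSE)
  }
  structure(list(condition = condition, mode = mode,
                 n_hunters = as.integer(n_hunters),
                 magnitude_mean = magnitude_mean,
                 magnitude_sd = magnitude_sd,
                 max_resamples = as.integer(max_resamples)),
            class = "social_info_params")
}

#' Choose the modification sign that meets a condition's requirement
#'
#' Evaluates the expected fitness of the reference design with the given
#' attribute moved by `+magnitude` and by `-magnitude` (rounded and
#' clamped to the attribute range) and returns the sign that *strictly*
#' increases fitness (positive condition) or strictly reduces it
#' (negative condition). When both signs qualify, the one with the
#' larger change in the required direction is returned; when neither
#' does (e.g. at a one-dimensional optimum in the positive condition),
#' `NA` is returned.
#'
#' @param reference The reference `arrowhead`.
#' @param attribute One continuous attribute name.
#' @param magnitude Positive modification size in attribute units.
#' @param landscape A `fitness_landscape`.
#' @param condition `"positive"` or `"negative"`.
#' @return `+1`, `-1`, or `NA` if no sign qualifies.
#' @export
choose_sign <- function(reference, attribute, magnitude, landscape,
                        condition = c("positive", "negative")) {
  condition <- match.arg(condition)
  stopifnot(magnitude > 0)
  ref_val <- reference[[attribute]]
  base <- expected_fitness(reference, landscape)
  c_ref <- attribute_contribution(landscape, attribute, ref_val)
  cand <- clamp(round(ref_val + c(1, -1) * magnitude), ATTR_MIN, ATTR_MAX)
  dc <- attribute_contribution(landscape, attribute, cand) - c_ref
  dc[cand == ref_val] <- 0  # clamped into no move: cannot qualify strictly
  # qualify on the resulting total fitness: a contribution change too
  # small to alter the total is not strictly better or worse
  fit <- base + dc
  ok <- if (condition == "positive") fit > base else fit < base
  if (!any(ok)) return(NA_real_)
  pick <- if (condition == "positive") which.max(replace(dc, !ok, -Inf))
          else which.min(replace(dc, !ok, Inf))
  c(1, -1)[pick]
}

# Vectorized rejection sampler for one hunter. Draws magnitude and
# perception noise afresh each attempt; accepts the first attempt whose
# modified design beats (positive) or trails (negative) the reference in
# BOTH true and perceived score, strictly. Equality never counts as
# acceptance. Attempts are drawn and evaluated in blocks for speed; the
# first qualifying attempt in draw order is the one returned.
sample_one_hunter <- function(reference, reference_perceived, landscape,
                              attribute, params) {
  ref_val <- reference[[attribute]]
  base_fit <- expected_fitness(reference, landscape)
  c_ref <- attribute_contribution(landscape, attribute, ref_val)
  positive <- params$condition == "positive"
  remaining <- params$max_resamples
  block <- 256L
  while (remaining > 0) {
    b <- min(block, remaining)
    remaining <- remaining - b
    mag <- abs(stats::rnorm(b, params$magnitude_mean, params$magnitude_sd))
    up <- clamp(round(ref_val + mag), ATTR_MIN, ATTR_MAX)
    dn <- clamp(round(ref_val - mag), ATTR_MIN, ATTR_MAX)
    d_up <- attribute_contribution(landscape, attribute, up) - c_ref
    d_dn <- attribute_contribution(landscape, attribute, dn) - c_ref
    d_up[up == ref_val] <- 0
    d_dn[dn == ref_val] <- 0
    take_up <- if (positive) d_up >= d_dn else d_up <= d_dn
    dc <- ifelse(take_up, d_up, d_dn)
    val <- ifelse(take_up, up, dn)
    true_fit <- base_fit + dc
    # qualify on the resulting fitness value: a contribution gain too
    # small to change the total does not count as strictly better
    qual <- if (positive) true_fit > base_fit else true_fit < base_fit
    noise <- stats::rnorm(b, 0, landscape$noise_sd)
    displayed <- clamp(true_fit + noise, landscape$score_floor,
                       landscape$score_ceiling)
    accept <- qual & if (positive) displayed > reference_perceived
                     else displayed < reference_perceived
    hit <- which(accept)
    if (length(hit) > 0) {
      i <- hit[1]
      return(list(value = val[i], delta = val[i] - ref_val,
                  true_fitness = true_fit[i], displayed_score = displayed[i],
                  fallback = FALSE))
    }
  }
  # resampling exhausted: the hunter brings a copy of the reference
  list(value = ref_val, delta = 0,
       true_fitness = base_fit,
       displayed_score = clamp(base_fit + stats::rnorm(1, 0, landscape$noise_sd),
                               landscape$score_floor, landscape$score_ceiling),
       fallback = TRUE)
}

#' Generate exemplar hunters for a social-learning opportunity
#'
#' Each hunter modifies exactly one continuous attribute of the
#' reference design by an absolute magnitude drawn from
#' `|N(magnitude_mean, magnitude_sd^2)|` (rounded to the task's integer
#' grid), with the sign chosen to increase (positive condition) or
#' reduce (negative condition) fitness. Perception noise is then added
#' to the hunter's true fitness; magnitude and noise are resampled up to
#' `max_resamples` times until the hunter strictly beats (positive) or
#' trails (negative) the reference in *both* true and perceived score.
#' If no such combination is found, the hunter is a fallback copy of the
#' reference — typical when the reference sits at the landscape maximum
#' (positive) or minimum (negative).
#'
#' In simulation mode the three hunters cover the attributes
#' `length`, `width`, `thickness` exactly once each; in experiment mode
#' a fourth hunter modifies a uniformly drawn attribute.
#'
#' @param reference The learner's previous design.
#' @param reference_perceived The (noisy) score actually displayed for
#'   the reference on the previous trial.
#' @param landscape A `fitness_landscape`.
#' @param params A [social_info_params()] object.
#' @return A tibble with one row per hunter: `hunter`, `attribute`,
#'   `value`, `delta`, `true_fitness`, `displayed_score`, `fallback`.
#' @export
generate_hunters <- function(reference, reference_perceived, landscape,
                             params) {
  validate_arrowhead(reference)
  attrs <- CONTINUOUS_ATTRS
  if (params$n_hunters > length(attrs)) {
    attrs <- c(attrs, sample(CONTINUOUS_ATTRS,
                             params$n_hunters - length(attrs),
                             replace = TRUE))
  } else if (params$n_hunters < length(attrs)) {
    attrs <- sample(CONTINUOUS_ATTRS, params$n_hunters)
  }
  rows <- lapply(seq_along(attrs), function(i) {
    h <- sample_one_hunter(reference, reference_perceived, landscape,
                           attrs[i], params)
    tibble::tibble(hunter = i, attribute = attrs[i], value = h$value,
                   delta = h$delta, true_fitness = h$true_fitness,
                   displayed_score = h$displayed_score, fallback = h$fallback)
  })
  dplyr::bind_rows(rows)
}

#' Collapse simulation-mode hunters into one delta per attribute
#'
#' @param hunters Tibble returned by [generate_hunters()] in simulation
#'   mode (one hunter per attribute).
#' @return Named numeric vector of signed deltas over
#'   `length`, `width`, `thickness` (0 for fallback hunters).
#' @export
hunter_deltas <- function(hunters) {
  if (anyDuplicated(hunters$attribute) ||
      !setequal(hunters$attribute, CONTINUOUS_ATTRS)) {
    stop("hunters must cover each continuous attribute exactly once",
         call. = FALSE)
  }
  d <- stats::setNames(hunters$delta, hunters$attribute)
  d[CONTINUOUS_ATTRS]
}
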