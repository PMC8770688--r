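#' Gaussian single-attribute contribution
#'
#' Default contribution family: a Gaussian bump
#' `maximum * exp(-(x - optimum)^2 / (2 * width^2))`. It is smooth,
#' unimodal with its peak at `optimum`, and strictly decreasing away from
#' the peak, which is all the task's landscape requires of a
#' single-attribute term. Alternative unimodal families can be plugged
#' into [make_landscape()] through the `contribution` argument.
#'
#' @param x Attribute value(s); vectorized.
#' @param optimum Peak location in attribute units.
#' @param maximum Contribution at the peak, in calories.
#' @param width Width (SD-like scale) of the bump, in attribute units.
#' @return Numeric vector of calorie contributions.
#' @export
gaussian_contribution <- function(x, optimum, maximum, width) {
  maximum * exp(-((x - optimum)^2) / (2 * width^2))
}

#' Build a season's fitness landscape
#'
#' A fitness landscape maps arrowhead designs to expected calorie scores.
#' Contributions are additive and independent across attributes, unimodal
#' per continuous attribute, and calibrated so that the expected score at
#' the joint optimum equals `score_ceiling` (1000 calories by default).
#'
#' @param season Season identifier (1--3 in the standard design).
#' @param optima Named numeric vector: peak location per continuous
#'   attribute (`length`, `width`, `thickness`).
#' @param maxima Named numeric vector: maximum calorie contribution per
#'   continuous attribute. Together with the best categorical options the
#'   maxima must sum to `score_ceiling`; pass `auto_rescale = TRUE` to
#'   rescale proportionally instead of erroring.
#' @param widths Named numeric vector: positive width parameter per
#'   continuous attribute, in attribute units.
#' @param categorical_contributions Optional named list with entries
#'   `shape` and/or `color`, each a numeric vector of 4 calorie values
#'   (one per option). Defaults to all zeros, the simulation setting in
#'   which the two discrete attributes are ignored.
#' @param noise_sd SD of the zero-mean Gaussian perception noise, in
#'   calories (default 5).
#' @param score_floor,score_ceiling Hard bounds of the displayed score
#'   (1 and 1000).
#' @param auto_rescale Rescale contributions so the maxima sum to
#'   `score_ceiling` instead of rejecting an uncalibrated config.
#' @param contribution Single-attribute contribution function with
#'   signature `f(x, optimum, maximum, width)`; must be unimodal with its
#'   maximum `maximum` at `optimum`. Default [gaussian_contribution()].
#'
#' @return An object of class `fitness_landscape`.
#'
#' @examples
#' ls1 <- make_landscape(
#'   season = 1,
#'   optima = c(length = 57, width = 30, thickness = 70),
#'   maxima = c(length = 500, width = 300, thickness = 200),
#'   widths = c(length = 12, width = 12, thickness = 12))
#' expected_fitness(arrowhead(57, 30, 70), ls1)
#'
#' @export
make_landscape <- function(season, optima, maxima, widths,
                           categorical_contributions = NULL,
                           noise_sd = 5, score_floor = 1,
                           score_ceiling = 1000,
                           auto_rescale = FALSE,
                           contribution = gaussian_contribution) {
  optima <- optima[CONTINUOUS_ATTRS]
  maxima <- maxima[CONTINUOUS_ATTRS]
  widths <- widths[CONTINUOUS_ATTRS]
  if (anyNA(optima) || anyNA(maxima) || anyNA(widths)) {
    stop("optima, maxima and widths must each name length, width and thickness",
         call. = FALSE)
  }
  if (any(widths <= 0)) {
    stop("width parameters must be positive (non-unimodal landscape)",
         call. = FALSE)
  }
  if (any(maxima < 0)) stop("maxima must be non-negative", call. = FALSE)
  if (any(optima < ATTR_MIN | optima > ATTR_MAX)) {
    stop("optima must lie in the attribute range [1, 100]", call. = FALSE)
  }
  cat_contrib <- list(shape = rep(0, N_OPTIONS), color = rep(0, N_OPTIONS))
  if (!is.null(categorical_contributions)) {
    for (a in names(categorical_contributions)) {
      if (!a %in% CATEGORICAL_ATTRS) {
        stop(sprintf("unknown categorical attribute '%s'", a), call. = FALSE)
      }
      v <- categorical_contributions[[a]]
      if (length(v) != N_OPTIONS || any(v < 0)) {
        stop(sprintf(
          "categorical contributions for '%s' must be %d non-negative values",
          a, N_OPTIONS), call. = FALSE)
      }
      cat_contrib[[a]] <- as.numeric(v)
    }
  }
  total_max <- sum(maxima) + sum(vapply(cat_contrib, max, numeric(1)))
  if (abs(total_max - score_ceiling) > 1e-6) {
    if (!auto_rescale) {
      stop(sprintf(
        "landscape not calibrated: maximum contributions sum to %g, not %g (set auto_rescale = TRUE to rescale)",
        total_max, score_ceiling), call. = FALSE)
    }
    scale <- score_ceiling / total_max
    maxima <- maxima * scale
    cat_contrib <- lapply(cat_contrib, function(v) v * scale)
  }
  structure(
    list(season = as.integer(season), optima = optima, maxima = maxima,
         widths = widths, categorical_contributions = cat_contrib,
         noise_sd = noise_sd, score_floor = score_floor,
         score_ceiling = score_ceiling, contribution = contribution),
    class = "fitness_landscape"
  )
}

#' @export
print.fitness_landscape <- function(x, ...) {
  cat(sprintf("<fitness_landscape> season %d, noise_sd = %g\n",
              x$season, x$noise_sd))
  for (a in CONTINUOUS_ATTRS) {
    cat(sprintf("  %-9s optimum %3g  max %7.2f  width %g\n",
                a, x$optima[[a]], x$maxima[[a]], x$widths[[a]]))
  }
  invisible(x)
}

#' Contribution of one continuous attribute, vectorized over values
#'
#' @param landscape A `fitness_landscape`.
#' @param attr One of `"length"`, `"width"`, `"thickness"`.
#' @param values Numeric vector of attribute values.
#' @return Calorie contributions.
#' @export
attribute_contribution <- function(landscape, attr, values) {
  stopifnot(attr %in% CONTINUOUS_ATTRS)
  landscape$contribution(values, landscape$optima[[attr]],
                         landscape$maxima[[attr]], landscape$widths[[attr]])
}

#' Expected (noise-free) fitness of a design
#'
#' Sums the per-attribute contributions; deterministic and bounded by the
#' score ceiling. This is the "true fitness" reported in trajectory
#' summaries, excluding perception error.
#'
#' @param design An `arrowhead`.
#' @param landscape A `fitness_landscape`.
#' @return Expected calories, in \[0, `score_ceiling`\].
#' @export
expected_fitness <- function(design, landscape) {
  validate_arrowhead(design)
  cont <- sum(vapply(
    CONTINUOUS_ATTRS,
    function(a) attribute_contribution(landscape, a, design[[a]]),
    numeric(1)))
  catg <- sum(vapply(
    CATEGORICAL_ATTRS,
    function(a) landscape$categorical_contributions[[a]][design[[a]]],
    numeric(1)))
  cont + catg
}

#' Noisy displayed score of a design ("go hunting")
#'
#' Adds one draw of zero-mean Gaussian perception noise to the expected
#' fitness and clamps the result to the printed score range
#' \[`score_floor`, `score_ceiling`\]. Uses R's global random number
#' stream, so `set.seed()` makes draws reproducible.
#'
#' @inheritParams expected_fitness
#' @return Displayed calories in \[`score_floor`, `score_ceiling`\].
#' @export
perceived_score <- function(design, landscape) {
  f <- expected_fitness(design, landscape)
  noise <- if (landscape$noise_sd > 0) stats::rnorm(1, 0, landscape$noise_sd) else 0
  clamp(f + noise, landscape$score_floor, landscape$score_ceiling)
}

#' Read season landscapes from a YAML config
#'
#' The config holds a top-level `seasons:` list; each entry supplies
#' `season`, `optima`, `maxima` and `widths` maps keyed by attribute name,
#' and optionally `categorical_contributions`, `noise_sd` and
#' `auto_rescale`.
#'
#' @param path Path to the YAML file.
#' @param auto_rescale Default rescaling behaviour when an entry does not
#'   set its own.
#' @return Named list of `fitness_landscape` objects, one per season, in
#'   season order.
#' @seealso [demo_landscapes()] for the built-in three-season set.
#' @export
read_landscape_config <- function(path, auto_rescale = FALSE) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seasons)) stop("config must have a 'seasons' list", call. = FALSE)
  out <- lapply(cfg$seasons, function(s) {
    make_landscape(
      season = s$season,
      optima = unlist(s$optima),
      maxima = unlist(s$maxima),
      widths = unlist(s$widths),
      categorical_contributions = s$categorical_contributions,
      noise_sd = if (is.null(s$noise_sd)) 5 else s$noise_sd,
      auto_rescale = if (is.null(s$auto_rescale)) auto_rescale else s$auto_rescale
    )
  })
  out <- out[order(vapply(out, function(l) l$season, integer(1)))]
  names(out) <- paste0("season", vapply(out, function(l) l$season, integer(1)))
  out
}

#' Built-in demo landscapes for the three-season design
#'
#' Three calibrated landscapes with distinct optima per season,
#' attribute importances 500/300/200 calories and width 12 attribute
#' units, perception noise SD 5 and zero categorical contributions (the
#' simulation setting). The width makes the informative region of each
#' attribute a minority of its range, so asocial hill climbers plateau
#' well below the ceiling within a season, as participants in this task
#' typically do. These are illustrative stand-ins: the optima of the
#' original task program are not published, so no numeric equivalence
#' with it is claimed.
#'
#' @param noise_sd Perception noise SD in calories, default 5.
#' @return Named list of three `fitness_landscape` objects.
#' @export
demo_landscapes <- function(noise_sd = 5) {
  spec <- list(
    list(season = 1, optima = c(length = 57, width = 30, thickness = 70)),
    list(season = 2, optima = c(length = 25, width = 72, thickness = 40)),
    list(season = 3, optima = c(length = 80, width = 45, thickness = 15))
  )
  out <- lapply(spec, function(s) {
    make_landscape(
      season = s$season, optima = s$optima,
      maxima = c(length = 500, width = 300, thickness = 200),
      widths = c(length = 12, width = 12, thickness = 12),
      noise_sd = noise_sd)
  })
  names(out) <- paste0("season", 1:3)
  out
}
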