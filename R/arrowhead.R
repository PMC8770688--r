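#' Continuous and categorical attribute names
#'
#' The virtual arrowhead has three continuous attributes (integer-valued,
#' 1--100) and two categorical attributes (four options each).
#'
#' @keywords internal
#' @name attribute-names
NULL

CONTINUOUS_ATTRS <- c("length", "width", "thickness")
CATEGORICAL_ATTRS <- c("shape", "color")
ATTR_MIN <- 1
ATTR_MAX <- 100
N_OPTIONS <- 4

#' Construct a virtual arrowhead design
#'
#' An arrowhead is described by three continuous attributes (`length`,
#' `width`, `thickness`), each a whole number between 1 and 100, and two
#' categorical attributes (`shape`, `color`), each one of four options.
#'
#' @param length,width,thickness Whole numbers in \[1, 100\].
#' @param shape,color Categorical options, integers in \[1, 4\].
#'
#' @return An object of class `arrowhead`: a named list with the five
#'   attribute values.
#'
#' @examples
#' arrowhead(50, 50, 50)
#' arrowhead(10, 90, 33, shape = 2, color = 4)
#'
#' @export
arrowhead <- function(length, width, thickness, shape = 1L, color = 1L) {
  x <- structure(
    list(length = as.numeric(length), width = as.numeric(width),
         thickness = as.numeric(thickness),
         shape = as.integer(shape), color = as.integer(color)),
    class = "arrowhead"
  )
  validate_arrowhead(x)
  x
}

#' @export
print.arrowhead <- function(x, ...) {
  cat(sprintf(
    "<arrowhead> length=%g width=%g thickness=%g shape=%d color=%d\n",
    x$length, x$width, x$thickness, x$shape, x$color))
  invisible(x)
}

#' Validate an arrowhead design
#'
#' Checks the attribute-range invariants and fails naming the offending
#' attribute.
#'
#' @param x An `arrowhead`.
#' @return `x`, invisibly, if valid.
#' @export
validate_arrowhead <- function(x) {
  for (a in CONTINUOUS_ATTRS) {
    v <- x[[a]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) ||
        v < ATTR_MIN || v > ATTR_MAX) {
      stop(sprintf("attribute '%s' must lie in [%d, %d], got %s",
                   a, ATTR_MIN, ATTR_MAX, format(v)), call. = FALSE)
    }
    if (abs(v - round(v)) > 1e-8) {
      stop(sprintf("attribute '%s' must be a whole number, got %s",
                   a, format(v)), call. = FALSE)
    }
  }
  for (a in CATEGORICAL_ATTRS) {
    v <- x[[a]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) ||
        !(v %in% seq_len(N_OPTIONS))) {
      stop(sprintf("attribute '%s' must be one of 1..%d, got %s",
                   a, N_OPTIONS, format(v)), call. = FALSE)
    }
  }
  invisible(x)
}

#' Extract the continuous attribute values of a design
#'
#' @param x An `arrowhead`.
#' @return Named numeric vector `c(length, width, thickness)`.
#' @export
continuous_values <- function(x) {
  vapply(CONTINUOUS_ATTRS, function(a) x[[a]], numeric(1))
}

#' Replace continuous attribute values, clamping to the valid range
#'
#' Values are clamped to \[1, 100\] and rounded to the integer grid the
#' task operates on.
#'
#' @param x An `arrowhead`.
#' @param values Named numeric vector over a subset of
#'   `c("length", "width", "thickness")`.
#' @return A new `arrowhead`.
#' @export
set_continuous <- function(x, values) {
  stopifnot(all(names(values) %in% CONTINUOUS_ATTRS))
  for (a in names(values)) {
    x[[a]] <- clamp(round(values[[a]]), ATTR_MIN, ATTR_MAX)
  }
  x
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
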