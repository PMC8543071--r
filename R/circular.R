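#' Orientation-angle arithmetic on the 180-degree-periodic orientation space
#'
#' Bar orientations are 180-degree periodic: a bar tilted 95 degrees clockwise
#' is physically identical to one tilted 85 degrees anticlockwise. All
#' orientations in this package live in the half-open interval (-90, 90]
#' degrees, with positive values denoting clockwise (rightward) tilt and
#' negative values anticlockwise (leftward) tilt. `wrap_orientation()` maps an
#' arbitrary angle into that canonical interval.
#'
#' @param angle numeric vector of angles in degrees; any finite real value.
#' @return numeric vector in (-90, 90], congruent to `angle` modulo 180.
#' @examples
#' wrap_orientation(c(95, 0, -170))  # -85, 0, 10
#' @export
wrap_orientation <- function(angle) {
  if (!is.numeric(angle) || anyNA(angle) || any(!is.finite(angle)))
    stop_invalid_input("wrap_orientation: angles must be finite numbers")
  angle - 180 * ceiling((angle - 90) / 180)
}

#' Signed angular difference between two orientations
#'
#' `signed_diff(a, b)` is the wrapped difference a - b on the 180-degree
#' period, in (-90, 90]. It is antisymmetric except on the boundary:
#' `signed_diff(a, b) == -signed_diff(b, a)` whenever the magnitude is
#' strictly below 90.
#'
#' @param a,b numeric vectors of angles in degrees (recycled).
#' @return numeric vector in (-90, 90].
#' @examples
#' signed_diff(30, -40)   # 70
#' signed_diff(85, -85)   # -10
#' @export
signed_diff <- function(a, b) {
  wrap_orientation(a - b)
}

#' Absolute angular deviation between two orientations
#'
#' The per-trial kernel of the reproduction error: the absolute wrapped
#' difference between two orientations, bounded by 90 degrees (perpendicular).
#'
#' @param a,b numeric vectors of angles in degrees (recycled).
#' @return numeric vector in \[0, 90\].
#' @examples
#' abs_dev(45, -45)  # 90 (perpendicular)
#' abs_dev(85, -85)  # 10
#' @export
abs_dev <- function(a, b) {
  abs(signed_diff(a, b))
}

#' Doubling transform: orientation degrees to full-circle radians
#'
#' Orientations are 180-degree periodic but circular distributions (von Mises)
#' are defined on the full 360-degree circle. Multiplying by two maps the
#' orientation space onto the full circle so those distributions apply; the
#' inverse halving transform recovers the orientation.
#'
#' @param o numeric vector of orientations in (-90, 90] degrees.
#' @return radians in (-pi, pi]: `o * 2 * pi / 180`.
#' @examples
#' to_full_circle(45)  # pi/2
#' @export
to_full_circle <- function(o) {
  if (!is.numeric(o) || anyNA(o) || any(!is.finite(o)))
    stop_invalid_input("to_full_circle: orientations must be finite numbers")
  if (any(o <= -90 | o > 90))
    stop_invalid_input("to_full_circle: orientations must lie in (-90, 90]")
  o * 2 * pi / 180
}
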