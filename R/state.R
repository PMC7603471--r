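#' Instrument state: position and heading
#'
#' A state couples a position in millimetres with a unit heading direction,
#' i.e. an element of \eqn{R^3 \times S^2}.  Start and goal configurations of
#' a planning problem, as well as the nodes grown by the Bi-RRT, are states.
#'
#' @param position numeric length-3, mm.
#' @param direction numeric length-3; normalised internally, must be nonzero
#'   and within 1e-9 of unit length after normalisation is applied to inputs
#'   that are already close to unit length.
#' @return an object of class `ot_state` with fields `position`, `direction`.
#' @examples
#' ot_state(c(0, 0, 0), c(1, 0, 0))
#' @export
ot_state <- function(position, direction) {
  position <- as.numeric(position)
  direction <- as.numeric(direction)
  stopifnot(length(position) == 3, length(direction) == 3,
            all(is.finite(position)), all(is.finite(direction)))
  n <- sqrt(sum(direction^2))
  if (n < 1e-12) stop("state direction must be a nonzero vector")
  structure(list(position = position, direction = direction / n),
            class = "ot_state")
}

#' @export
print.ot_state <- function(x, ...) {
  cat(sprintf("<ot_state> pos (%.3f, %.3f, %.3f) mm, dir (%.4f, %.4f, %.4f)\n",
              x$position[1], x$position[2], x$position[3],
              x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}

is_ot_state <- function(x) inherits(x, "ot_state")

# --- small vector helpers used throughout the geometry code -----------------

vnorm <- function(v) sqrt(sum(v^2))

vunit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-14) stop("cannot normalise a (near-)zero vector")
  v / n
}

# angle between two vectors, robust near 0 and pi
vangle <- function(a, b) {
  a <- vunit(a); b <- vunit(b)
  2 * asin(pmin(1, vnorm(a - b) / 2))
}
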