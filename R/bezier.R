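# Cubic Bezier primitives and the two-spiral corner construction.
#
# A corner (w_prev, w, w_next) is smoothed by a pair of mirrored cubic Bezier
# "spirals": cubics whose first three control points lie on the corner leg, so
# curvature starts at exactly zero (G2 join with the straight leg), grows
# monotonically, and peaks at the shared join point on the corner bisector.
# Control points are placed along the legs at distances proportional to a
# configuration distance d; since scaling d scales the whole construction
# similarly (curvature ~ 1/d), d is rescaled analytically so the sampled peak
# curvature equals the requested bound.

# spiral placement constants (analytic corner-smoothing construction)
.SPIRAL_C1 <- 7.2364
.SPIRAL_C2 <- 2 * (sqrt(6) - 1) / 5
.SPIRAL_C3 <- (.SPIRAL_C2 + 4) / (.SPIRAL_C1 + 6)

# evaluate a cubic with 4x3 control matrix P at parameter(s) s in [0,1]
bezier_point <- function(P, s) {
  b0 <- (1 - s)^3; b1 <- 3 * s * (1 - s)^2; b2 <- 3 * s^2 * (1 - s); b3 <- s^3
  cbind(b0 %o% P[1, ] + b1 %o% P[2, ] + b2 %o% P[3, ] + b3 %o% P[4, ])[, , drop = TRUE]
}

bezier_d1 <- function(P, s) {
  d0 <- 3 * (1 - s)^2; d1 <- 6 * s * (1 - s); d2 <- 3 * s^2
  d0 %o% (P[2, ] - P[1, ]) + d1 %o% (P[3, ] - P[2, ]) + d2 %o% (P[4, ] - P[3, ])
}

bezier_d2 <- function(P, s) {
  e0 <- 6 * (1 - s); e1 <- 6 * s
  e0 %o% (P[3, ] - 2 * P[2, ] + P[1, ]) + e1 %o% (P[4, ] - 2 * P[3, ] + P[2, ])
}

# curvature of a cubic at parameter(s) s; Inf where the tangent vanishes
bezier_curvature <- function(P, s) {
  d1 <- matrix(bezier_d1(P, s), ncol = 3)
  d2 <- matrix(bezier_d2(P, s), ncol = 3)
  cr <- cbind(d1[, 2] * d2[, 3] - d1[, 3] * d2[, 2],
              d1[, 3] * d2[, 1] - d1[, 1] * d2[, 3],
              d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1])
  num <- sqrt(rowSums(cr^2))
  den <- rowSums(d1^2)^1.5
  k <- ifelse(den < 1e-30, Inf, num / den)
  as.numeric(k)
}

new_spiral_pair <- function(first, second) {
  dimnames(first) <- dimnames(second) <- NULL
  structure(list(control_points_first = first,       # B0..B3
                 control_points_second = second),    # E0..E3 (E3 = B3, join)
            class = "ot_spiral_pair")
}

# place control points for a given configuration distance d
spiral_points_for_d <- function(w, u1, u2, d) {
  gb <- .SPIRAL_C2 * .SPIRAL_C3 * d
  hb <- .SPIRAL_C3 * d
  B0 <- w + d * u1; B1 <- B0 - gb * u1; B2 <- B1 - hb * u1
  E0 <- w + d * u2; E1 <- E0 - gb * u2; E2 <- E1 - hb * u2
  J <- (B2 + E2) / 2  # join on the corner bisector
  list(first = rbind(B0, B1, B2, J), second = rbind(E0, E1, E2, J))
}

#' Smooth a waypoint corner with a curvature-bounded Bezier spiral pair
#'
#' Constructs the pair of mirrored cubic Bezier spirals that replaces the
#' corner formed by the triple `(w_prev, w, w_next)`.  The curve leaves the
#' segment `w_prev--w`, is tangent-continuous with both legs, meets itself on
#' the corner bisector, and its peak sampled curvature equals the requested
#' bound `kappa_max` (so it never exceeds it, up to sampling resolution).
#' A collinear triple yields a degenerate straight piece of zero curvature.
#'
#' @param w_prev,w,w_next three distinct points (mm); the corner angle must
#'   be strictly less than pi (no reversal).
#' @param kappa_max maximum curvature, 1/mm (> 0).
#' @return an `ot_spiral_pair` with fields `control_points_first` (B0..B3)
#'   and `control_points_second` (E0..E3); attribute `d` gives the distance
#'   from the corner to the curve endpoints along each leg.
#' @examples
#' p <- spiral_pair_from_triple(c(0, 0, 0), c(20, 0, 0), c(20, 20, 0), 0.05)
#' max(curvature_at(p, seq(0, 1, length.out = 200)))
#' @export
spiral_pair_from_triple <- function(w_prev, w, w_next, kappa_max) {
  w_prev <- as.numeric(w_prev); w <- as.numeric(w); w_next <- as.numeric(w_next)
  stopifnot(kappa_max > 0)
  leg1 <- vnorm(w - w_prev); leg2 <- vnorm(w_next - w)
  if (leg1 < 1e-12 || leg2 < 1e-12) stop("corner points must be distinct")
  res <- spiral_corner(w_prev, w, w_next, kappa_max = kappa_max)
  if (is.null(res$pair)) {  # collinear: degenerate straight piece
    u1 <- (w_prev - w) / leg1; u2 <- (w_next - w) / leg2
    d <- min(leg1, leg2) / 2
    first <- rbind(w + d * u1, w + (2 / 3) * d * u1, w + (1 / 3) * d * u1, w)
    second <- rbind(w + d * u2, w + (2 / 3) * d * u2, w + (1 / 3) * d * u2, w)
    pair <- new_spiral_pair(first, second)
    attr(pair, "d") <- d
    return(pair)
  }
  if (res$d > min(leg1, leg2) * (1 + 1e-9)) {
    stop(sprintf(paste0("corner infeasible: spiral needs %.3f mm along each leg ",
                        "but legs are %.3f / %.3f mm (kappa_max = %g)"),
                 res$d, leg1, leg2, kappa_max))
  }
  pair <- res$pair
  attr(pair, "d") <- res$d
  pair
}

# Core corner construction.  Returns list(pair, d, gamma) or pair = NULL for a
# (near-)collinear corner.  If d_force is given, builds with that d and does
# not rescale to kappa_max (used by the clamped rebuilds inside the SCO loop).
spiral_corner <- function(w_prev, w, w_next, kappa_max = NULL, d_force = NULL) {
  t1 <- vunit(w - w_prev); t2 <- vunit(w_next - w)
  gamma <- vangle(t1, t2)  # deflection angle
  if (gamma < 1e-6) return(list(pair = NULL, d = 0, gamma = gamma))
  if (gamma > pi - 1e-6) {
    stop("degenerate corner: path reverses direction (angle ~ pi)")
  }
  u1 <- -t1; u2 <- t2
  beta <- gamma / 2
  if (is.null(d_force)) {
    d0 <- ((.SPIRAL_C2 + 4)^2 / (54 * .SPIRAL_C3)) *
      sin(beta) / (kappa_max * cos(beta)^2)
    cp <- spiral_points_for_d(w, u1, u2, d0)
    kpeak <- max(bezier_curvature(cp$first, seq(0, 1, length.out = 101)))
    d <- d0 * kpeak / kappa_max  # curvature scales exactly as 1/d
  } else {
    d <- d_force
  }
  cp <- spiral_points_for_d(w, u1, u2, d)
  list(pair = new_spiral_pair(cp$first, cp$second), d = d, gamma = gamma)
}

#' Evaluate a spiral pair
#'
#' Parameterised over `t` in `[0, 1]`: the first cubic covers `[0, 0.5]`
#' (from B0 to the join), the second covers `[0.5, 1]` (join to E0).
#'
#' @param pair an `ot_spiral_pair`.
#' @param t numeric vector of parameters in `[0, 1]`.
#' @return an `length(t) x 3` matrix of points (a vector for a single `t`).
#' @export
evaluate <- function(pair, t) {
  stopifnot(inherits(pair, "ot_spiral_pair"))
  t <- as.numeric(t)
  if (any(t < 0 | t > 1)) stop("parameter t must lie in [0, 1]")
  P1 <- pair$control_points_first
  P2r <- pair$control_points_second[4:1, ]  # join -> E0
  out <- matrix(NA_real_, length(t), 3)
  lo <- t <= 0.5
  if (any(lo)) out[lo, ] <- matrix(bezier_point(P1, 2 * t[lo]), ncol = 3)
  if (any(!lo)) out[!lo, ] <- matrix(bezier_point(P2r, 2 * t[!lo] - 1), ncol = 3)
  if (length(t) == 1) out <- drop(out)
  out
}

#' Curvature of a spiral pair at parameter t
#'
#' Uses the standard space-curve formula
#' \eqn{\kappa = \|r' \times r''\| / \|r'\|^3}, which is invariant under the
#' internal reparameterisation of the two cubics.  A vanishing tangent (cusp)
#' is reported as `Inf`.
#'
#' @inheritParams evaluate
#' @return numeric vector of curvatures (1/mm), nonnegative (or `Inf`).
#' @export
curvature_at <- function(pair, t) {
  stopifnot(inherits(pair, "ot_spiral_pair"))
  t <- as.numeric(t)
  if (any(t < 0 | t > 1)) stop("parameter t must lie in [0, 1]")
  P1 <- pair$control_points_first
  P2r <- pair$control_points_second[4:1, ]
  out <- numeric(length(t))
  lo <- t <= 0.5
  if (any(lo)) out[lo] <- bezier_curvature(P1, 2 * t[lo])
  if (any(!lo)) out[!lo] <- bezier_curvature(P2r, 2 * t[!lo] - 1)
  out
}

# arc length of one cubic by fixed-order Gauss-Legendre quadrature
gauss_legendre_nodes <- function(n = 24) {
  key <- paste0("gl", n)
  if (!is.null(.otoplan_cache[[key]])) return(.otoplan_cache[[key]])
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  nodes <- list(x = e$values, w = 2 * e$vectors[1, ]^2)
  .otoplan_cache[[key]] <- nodes
  nodes
}

bezier_arclength <- function(P) {
  gl <- gauss_legendre_nodes(24)
  s <- (gl$x + 1) / 2
  d1 <- matrix(bezier_d1(P, s), ncol = 3)
  sum(gl$w / 2 * sqrt(rowSums(d1^2)))
}

pair_arclength <- function(pair) {
  bezier_arclength(pair$control_points_first) +
    bezier_arclength(pair$control_points_second)
}
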