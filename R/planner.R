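# Bidirectional RRT on Bezier spiral splines.
#
# Two search trees grow from the start and goal states (the goal tree with
# negated heading, so its edges read backward); each iteration samples a
# random point, extends every in-ball neighbour with spare child capacity by
# one curvature-feasible step, and tests connections to the other tree
# through a cone ahead of the new state.  A successful bridge yields the
# waypoint sequence of both root-to-bridge paths, from which the spline
# trajectory is built and densely re-checked before being returned.

#' Bi-RRT planner configuration
#'
#' Defaults follow the printed parameter setup of the motion-planning
#' algorithm: time budget `t_max` 0.1 s, neighbour ball radius `r_b` 1 mm,
#' steering step `delta_t` 4 mm, connection cone radius/height `c_r` 5 mm /
#' `c_h` 18 mm, at most `n_c` 10 children per node.  `max_iter` switches the
#' budget from wall-clock seconds to a fixed iteration count, which makes
#' runs exactly reproducible; `NULL` uses the wall clock.
#'
#' @param t_max time budget in seconds (used when `max_iter` is `NULL`).
#' @param r_b neighbour ball radius, mm.
#' @param delta_t steering step, mm.
#' @param c_r,c_h connection cone base radius and height, mm.
#' @param n_c maximum number of children per tree node.
#' @param seed integer seed driving all sampling.
#' @param max_iter optional iteration cap (deterministic mode).
#' @param bounds_margin inflation of the environment bounding box used as the
#'   sampling region, mm.
#' @export
rrt_config <- function(t_max = 0.1, r_b = 1.0, delta_t = 4.0, c_r = 5.0,
                       c_h = 18.0, n_c = 10L, seed = 1L, max_iter = NULL,
                       bounds_margin = 10) {
  stopifnot(t_max > 0, r_b > 0, delta_t > 0, c_r > 0, c_h > 0, n_c >= 1)
  structure(list(t_max = t_max, r_b = r_b, delta_t = delta_t, c_r = c_r,
                 c_h = c_h, n_c = as.integer(n_c), seed = as.integer(seed),
                 max_iter = if (is.null(max_iter)) NULL else as.integer(max_iter),
                 bounds_margin = bounds_margin),
            class = "ot_rrt_config")
}

# --- search tree -----------------------------------------------------------

#' Create a search tree rooted at a state
#' @param root an `ot_state`.
#' @return an `ot_search_tree` (environment with node arrays).
#' @export
search_tree <- function(root) {
  stopifnot(is_ot_state(root))
  tr <- new.env(parent = emptyenv())
  tr$pos <- matrix(NA_real_, 64, 3)
  tr$dir <- matrix(NA_real_, 64, 3)
  tr$parent <- integer(64)
  tr$nchild <- integer(64)
  tr$n <- 1L
  tr$pos[1, ] <- root$position
  tr$dir[1, ] <- root$direction
  tr$parent[1] <- 0L
  class(tr) <- "ot_search_tree"
  tr
}

#' Insert a node into a search tree
#' @param tree an `ot_search_tree`.
#' @param state the node's `ot_state`.
#' @param parent index of the parent node.
#' @return the index of the new node.
#' @export
tree_insert <- function(tree, state, parent) {
  stopifnot(inherits(tree, "ot_search_tree"), parent >= 1, parent <= tree$n)
  if (tree$n == nrow(tree$pos)) {
    grow <- function(m) rbind(m, matrix(NA_real_, nrow(m), 3))
    tree$pos <- grow(tree$pos); tree$dir <- grow(tree$dir)
    tree$parent <- c(tree$parent, integer(length(tree$parent)))
    tree$nchild <- c(tree$nchild, integer(length(tree$nchild)))
  }
  i <- tree$n + 1L
  tree$n <- i
  tree$pos[i, ] <- state$position
  tree$dir[i, ] <- state$direction
  tree$parent[i] <- as.integer(parent)
  tree$nchild[parent] <- tree$nchild[parent] + 1L
  i
}

tree_state <- function(tree, i) ot_state(tree$pos[i, ], tree$dir[i, ])

tree_path_to_root <- function(tree, i) {
  path <- integer(0)
  while (i != 0L) { path <- c(path, i); i <- tree$parent[i] }
  tree$pos[rev(path), , drop = FALSE]  # root ... node
}

# parent/child-count consistency audit (used by tests)
tree_audit <- function(tree) {
  n <- tree$n
  counts <- tabulate(tree$parent[seq_len(n)], nbins = n)
  # roots may carry an artificial full child count to exclude them from
  # expansion; audit only that recorded counts are >= actual link counts for
  # the root and equal elsewhere
  ok_links <- all(counts[-1] <= tree$nchild[2:n] | counts[-1] == tree$nchild[2:n])
  all(counts[-1] == tree$nchild[2:n]) && tree$nchild[1] >= counts[1] && ok_links
}

#' Sample a uniform random point within bounds
#'
#' Draws from the R random-number stream; with a fixed seed the sequence of
#' samples (and hence the whole planner run) is reproducible.
#'
#' @param bounds 2 x 3 matrix (rows: lower, upper).
#' @export
sample_point <- function(bounds) {
  if (is.null(bounds) || any(!is.finite(bounds))) stop("sampling bounds are not set")
  bounds[1, ] + runif(3) * (bounds[2, ] - bounds[1, ])
}

#' Neighbours of a point within a ball, with spare child capacity
#'
#' All tree nodes within `r_b` of `p` that have fewer than `n_c` children,
#' sorted by ascending distance (ties by insertion index).
#'
#' @param tree an `ot_search_tree`.
#' @param p query point.
#' @param r_b ball radius, mm.
#' @param n_c child capacity.
#' @return integer vector of node indices (possibly empty).
#' @export
nearest_in_ball <- function(tree, p, r_b, n_c) {
  n <- tree$n
  d2 <- rowSums((tree$pos[seq_len(n), , drop = FALSE] -
                   matrix(p, n, 3, byrow = TRUE))^2)
  cand <- which(d2 <= r_b^2 & tree$nchild[seq_len(n)] < n_c)
  cand[order(d2[cand], cand)]
}

# spiral corner distance d for unit curvature at deflection gamma (the
# analytic placement formula; the constructed corner rescales this by < 0.2%)
spiral_d_unit <- function(gamma) {
  beta <- gamma / 2
  ((.SPIRAL_C2 + 4)^2 / (54 * .SPIRAL_C3)) * sin(beta) / cos(beta)^2
}

# maximum corner deflection realisable with spirals using at most 45% of a
# steering step per leg (leaves slack so consecutive corners share a leg)
max_turn_angle <- function(kappa_max, delta_t) {
  target <- kappa_max * delta_t * 0.45
  if (spiral_d_unit(pi - 1e-3) <= target) return(pi - 1e-3)
  uniroot(function(g) spiral_d_unit(g) - target, c(1e-7, pi - 1e-3),
          tol = 1e-10)$root
}

# fast feasibility screen for a waypoint path: every corner's spiral distance
# (with 2% slack) must fit its legs, sharing legs with adjacent corners
corners_feasible <- function(W, kappa_max) {
  n <- nrow(W)
  if (n < 3) return(TRUE)
  legs <- W[-1, , drop = FALSE] - W[-n, , drop = FALSE]
  len <- sqrt(rowSums(legs^2))
  if (any(len < 1e-9)) return(FALSE)
  u <- legs / len
  cosg <- rowSums(u[-(n - 1), , drop = FALSE] * u[-1, , drop = FALSE])
  gamma <- acos(pmin(1, pmax(-1, cosg)))
  if (any(gamma > pi - 1e-4)) return(FALSE)
  d <- ifelse(gamma < 1e-6, 0, spiral_d_unit(gamma) / kappa_max) * 1.02
  all(c(d, 0) + c(0, d) <= len)
}

#' Steer from a tree state toward a sampled point
#'
#' Takes one step of length `delta_t` from `q_near` toward `p_rand`, turning
#' the heading by at most the deflection that a corner spiral with bound
#' `kappa_max` can realise within half a steering step per leg (saturation).
#' The returned edge geometry carries a polyline for collision checking
#' (corner-spiral samples where the heading turns, then the straight step).
#'
#' @param q_near an `ot_state` (tree node).
#' @param p_rand target point; must not coincide with the node position.
#' @param delta_t step length, mm.
#' @param kappa_max curvature bound, 1/mm.
#' @param gamma_max precomputed maximum deflection (optional).
#' @param ds spacing of the collision-check samples along the step, mm.
#' @return list with `state` (the new `ot_state`), `turn` (deflection used,
#'   rad) and `polyline` (collision-check samples).
#' @export
steer <- function(q_near, p_rand, delta_t, kappa_max, gamma_max = NULL,
                  ds = 0.1) {
  stopifnot(is_ot_state(q_near))
  v <- as.numeric(p_rand) - q_near$position
  dist <- vnorm(v)
  if (dist < 1e-9) stop("steering target coincides with the tree node")
  if (is.null(gamma_max)) gamma_max <- max_turn_angle(kappa_max, delta_t)
  u <- v / dist
  ang <- vangle(q_near$direction, u)
  if (ang <= gamma_max) {
    w <- u
  } else {
    perp <- u - sum(u * q_near$direction) * q_near$direction
    pn <- vnorm(perp)
    if (pn < 1e-12) {  # directly behind: deterministic perpendicular
      perp <- if (abs(q_near$direction[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      perp <- perp - sum(perp * q_near$direction) * q_near$direction
      pn <- vnorm(perp)
    }
    w <- cos(gamma_max) * q_near$direction + sin(gamma_max) * (perp / pn)
    ang <- gamma_max
  }
  newpos <- q_near$position + delta_t * w
  ns <- max(2L, ceiling(delta_t / ds))
  tt <- seq(0, 1, length.out = ns + 1)
  poly <- outer(1 - tt, q_near$position) + outer(tt, newpos)
  list(state = ot_state(newpos, w), turn = ang, polyline = poly)
}

cone_candidates <- function(tree, apex, axis, c_r, c_h) {
  n <- tree$n
  rel <- tree$pos[seq_len(n), , drop = FALSE] - matrix(apex, n, 3, byrow = TRUE)
  proj <- as.numeric(rel %*% axis)
  rad2 <- rowSums(rel^2) - proj^2
  inside <- proj > 1e-9 & proj <= c_h &
    rad2 <= (c_r * proj / c_h)^2 + 1e-12
  cand <- which(inside)
  cand[order(proj[cand]^2 + rad2[cand], cand)]
}

#' Attempt to bridge a new state to the other search tree
#'
#' Nodes of `other` lying inside the cone with apex and axis given by
#' `q_next` (height `c_h`, base radius `c_r`) are tried in ascending
#' distance; the first whose combined waypoint path admits a
#' curvature-feasible, collision-free spline trajectory yields the bridge.
#'
#' @param q_next the freshly added `ot_state`.
#' @param other the opposite `ot_search_tree`.
#' @param c_r,c_h cone base radius and height, mm.
#' @param kappa_max curvature bound, 1/mm.
#' @param env obstacle environment (`NULL` for free space).
#' @param d_min safety distance, mm.
#' @param assemble function(candidate_index, bridge) returning the full
#'   waypoint matrix for that candidate (start-to-goal order), with the
#'   bridge waypoint rows (possibly zero rows) inserted between the two
#'   tree paths.
#' @param q_I,q_G endpoint states of the planning problem.
#' @param ds collision-check discretization, mm.
#' @return an `ot_trajectory`, or `NULL` if no candidate connects.
#' @export
try_connect <- function(q_next, other, c_r, c_h, kappa_max, env, d_min,
                        assemble, q_I, q_G, ds = 0.1) {
  cand <- cone_candidates(other, q_next$position, q_next$direction, c_r, c_h)
  for (ci in cand) {
    y <- other$pos[ci, ]
    L <- vnorm(y - q_next$position)
    # bridge variants: direct, and with intermediate waypoints that absorb
    # the direction mismatch at both ends of the connection
    variants <- list(matrix(numeric(0), 0, 3))
    for (ab in list(L / 3, min(L / 3, 4))) {
      m1 <- q_next$position + ab * q_next$direction
      m2 <- y + ab * other$dir[ci, ]  # other tree's heading points backward
      if (vnorm(m2 - m1) > 0.5 && vnorm(m1 - q_next$position) > 0.5 &&
          vnorm(m2 - y) > 0.5) {
        variants[[length(variants) + 1]] <- rbind(m1, m2)
      }
    }
    for (bridge in variants) {
      W <- assemble(ci, bridge)
      keep <- c(TRUE, sqrt(rowSums((W[-1, , drop = FALSE] -
                                      W[-nrow(W), , drop = FALSE])^2)) > 1e-9)
      W <- W[keep, , drop = FALSE]
      if (!corners_feasible(W, kappa_max)) next
      traj <- tryCatch(build_trajectory(W, q_I, q_G, kappa_max),
                       error = function(e) NULL)
      if (is.null(traj)) next
      if (!is.null(env) && min_distance(traj, env, ds) < d_min) next
      return(traj)
    }
  }
  NULL
}

# --- the planner -----------------------------------------------------------

#' Plan an initial collision-free trajectory (bidirectional RRT)
#'
#' Grows two search trees from the start and goal states, strictly
#' alternating, and returns the first bridged trajectory that passes a dense
#' feasibility re-check (curvature within `kappa_max`, clearance at least
#' `d_min` at 0.05 mm sampling, exact endpoint interpolation).
#'
#' @param env an `ot_environment` (or `NULL` for free space).
#' @param q_I,q_G start and goal `ot_state`s; both must clear the obstacles
#'   by at least `d_min`.
#' @param kappa_max curvature bound, 1/mm.
#' @param d_min safety distance, mm.
#' @param cfg an [rrt_config()].
#' @return an `ot_plan_result` with `success`, `trajectory` (or `NULL`),
#'   `iterations`, `tree_sizes`, and `cause` on failure.
#' @export
plan_trajectory <- function(env, q_I, q_G, kappa_max, d_min,
                            cfg = rrt_config()) {
  stopifnot(is_ot_state(q_I), is_ot_state(q_G), inherits(cfg, "ot_rrt_config"),
            kappa_max > 0, d_min > 0)
  if (!is.null(env)) {
    sd0 <- signed_distance_batch(env, rbind(q_I$position, q_G$position))
    if (any(sd0 < d_min)) {
      stop(structure(class = c("otoplan_precondition_error", "error", "condition"),
                     list(message = sprintf(
                       "endpoint state(s) violate the safety margin (sd = %.3f / %.3f mm < d_min = %g mm)",
                       sd0[1], sd0[2], d_min), call = NULL)))
    }
    bounds <- rbind(env$bbox[1, ] - cfg$bounds_margin,
                    env$bbox[2, ] + cfg$bounds_margin)
  } else {
    allp <- rbind(q_I$position, q_G$position)
    bounds <- rbind(apply(allp, 2, min) - cfg$bounds_margin,
                    apply(allp, 2, max) + cfg$bounds_margin)
  }

  # run under a private RNG state
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(cfg$seed)

  ds_check <- min(0.1, cfg$delta_t / 40)
  gamma_max <- max_turn_angle(kappa_max, cfg$delta_t)

  edge_free <- function(poly) {
    is.null(env) || all(signed_distance_batch(env, poly) >= d_min)
  }

  tI <- search_tree(q_I)
  tG <- search_tree(ot_state(q_G$position, -q_G$direction))
  # pre-extend the roots along their exact headings so the first/last legs
  # realise the endpoint directions; roots are then closed to further children
  for (tr in list(tI, tG)) {
    root <- tree_state(tr, 1L)
    st <- ot_state(root$position + cfg$delta_t * root$direction, root$direction)
    ns <- max(2L, ceiling(cfg$delta_t / ds_check))
    tt <- seq(0, 1, length.out = ns + 1)
    poly <- outer(1 - tt, root$position) + outer(tt, st$position)
    if (!edge_free(poly)) {
      return(structure(list(success = FALSE, trajectory = NULL, iterations = 0L,
                            tree_sizes = c(start = 1L, goal = 1L),
                            cause = "endpoint extension blocked"),
                       class = "ot_plan_result"))
    }
    tree_insert(tr, st, 1L)
    tr$nchild[1] <- cfg$n_c  # close the root
  }

  assemble_for <- function(expanding_is_start, new_idx) {
    rev_rows <- function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]
    if (expanding_is_start) {
      function(ci, bridge) rbind(tree_path_to_root(tI, new_idx), bridge,
                                 rev_rows(tree_path_to_root(tG, ci)))
    } else {
      function(ci, bridge) rbind(tree_path_to_root(tI, ci), rev_rows(bridge),
                                 rev_rows(tree_path_to_root(tG, new_idx)))
    }
  }

  t0 <- Sys.time()
  iter <- 0L
  finish_fail <- function(cause) {
    structure(list(success = FALSE, trajectory = NULL, iterations = iter,
                   tree_sizes = c(start = tI$n, goal = tG$n), cause = cause),
              class = "ot_plan_result")
  }
  repeat {
    if (!is.null(cfg$max_iter)) {
      if (iter >= cfg$max_iter) return(finish_fail("iteration budget exhausted"))
    } else if (as.numeric(Sys.time() - t0, units = "secs") > cfg$t_max) {
      return(finish_fail("time budget exhausted"))
    }
    iter <- iter + 1L
    expanding_start <- (iter %% 2L) == 1L
    A <- if (expanding_start) tI else tG
    B <- if (expanding_start) tG else tI
    p <- sample_point(bounds)
    nbrs <- nearest_in_ball(A, p, cfg$r_b, cfg$n_c)
    if (!length(nbrs)) {
      n <- A$n
      open <- which(A$nchild[seq_len(n)] < cfg$n_c)
      if (!length(open)) next
      d2 <- rowSums((A$pos[open, , drop = FALSE] -
                       matrix(p, length(open), 3, byrow = TRUE))^2)
      nbrs <- open[order(d2, open)][1]
    }
    for (idx in nbrs) {
      qn <- tree_state(A, idx)
      if (vnorm(p - qn$position) < 1e-9) next
      st <- steer(qn, p, cfg$delta_t, kappa_max, gamma_max, ds = ds_check)
      if (!edge_free(st$polyline)) next
      new_idx <- tree_insert(A, st$state, idx)
      traj <- try_connect(st$state, B, cfg$c_r, cfg$c_h, kappa_max, env, d_min,
                          assemble = assemble_for(expanding_start, new_idx),
                          q_I = q_I, q_G = q_G, ds = ds_check)
      if (!is.null(traj)) {
        # dense soundness re-check before returning
        fz <- is_feasible(traj, env, kappa_max, d_min, ds = 0.05)
        if (fz$pass) {
          return(structure(list(success = TRUE, trajectory = traj,
                                iterations = iter,
                                tree_sizes = c(start = tI$n, goal = tG$n),
                                cause = NA_character_),
                          class = "ot_plan_result"))
        }
      }
    }
  }
}

#' @export
print.ot_plan_result <- function(x, ...) {
  if (x$success) {
    cat(sprintf("<ot_plan_result> success after %d iterations (trees %d/%d): length %.2f mm\n",
                x$iterations, x$tree_sizes[1], x$tree_sizes[2],
                x$trajectory$length))
  } else {
    cat(sprintf("<ot_plan_result> FAILURE after %d iterations (trees %d/%d): %s\n",
                x$iterations, x$tree_sizes[1], x$tree_sizes[2], x$cause))
  }
  invisible(x)
}
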