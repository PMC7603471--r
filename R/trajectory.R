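# Trajectories: waypoint sequences with spiral-smoothed interior corners,
# alternating straight connectors and Bezier spiral pairs.

new_trajectory <- function(waypoints, start, goal, kappa_max, corners, pieces) {
  lens <- vapply(pieces, function(p) p$len, numeric(1))
  kappas <- vapply(pieces, function(p) if (p$type == "pair") p$kappa_peak else 0,
                   numeric(1))
  structure(list(
    waypoints = waypoints, start = start, goal = goal, kappa_max = kappa_max,
    corners = corners, pieces = pieces,
    length = sum(lens), max_curvature = if (length(kappas)) max(kappas) else 0
  ), class = "ot_trajectory")
}

#' @export
print.ot_trajectory <- function(x, ...) {
  cat(sprintf(
    "<ot_trajectory> %d waypoints, %d spline corners, length %.2f mm, max curvature %.4f /mm\n",
    nrow(x$waypoints), sum(!vapply(x$corners, is.null, logical(1))),
    x$length, x$max_curvature))
  invisible(x)
}

#' Build a curvature-bounded trajectory through a waypoint sequence
#'
#' Interior waypoints become corners smoothed by cubic Bezier spiral pairs;
#' the pieces alternate straight connectors and spiral pairs, sharing
#' endpoints and tangents.  The first and last legs must be aligned with the
#' start and goal headings so that both endpoint states are interpolated
#' exactly.  Near-collinear corners (deflection < 1e-6 rad) are emitted as
#' straight pieces.
#'
#' @param waypoints numeric `n x 3` matrix of waypoints (mm), `n >= 2`; the
#'   first/last rows must equal the start/goal positions.
#' @param start,goal `ot_state` endpoint configurations.
#' @param kappa_max curvature bound, 1/mm.
#' @param clamp if `TRUE`, corners whose spirals do not fit on the legs are
#'   built with the largest fitting configuration distance instead of
#'   failing; the resulting trajectory can then exceed `kappa_max` (its
#'   `max_curvature` field reports the realised peak).  Used by the
#'   optimizer, which treats curvature violations as constraints to repair.
#' @return an `ot_trajectory`.
#' @export
build_trajectory <- function(waypoints, start, goal, kappa_max, clamp = FALSE) {
  waypoints <- as.matrix(waypoints)
  storage.mode(waypoints) <- "double"
  dimnames(waypoints) <- NULL
  n <- nrow(waypoints)
  stopifnot(is_ot_state(start), is_ot_state(goal), ncol(waypoints) == 3,
            n >= 2, kappa_max > 0)
  if (vnorm(waypoints[1, ] - start$position) > 1e-9)
    stop("first waypoint must coincide with the start position")
  if (vnorm(waypoints[n, ] - goal$position) > 1e-9)
    stop("last waypoint must coincide with the goal position")
  seg1 <- waypoints[2, ] - waypoints[1, ]
  segN <- waypoints[n, ] - waypoints[n - 1, ]
  if (vangle(seg1, start$direction) > 1e-6)
    stop("first leg is not aligned with the start direction")
  if (vangle(segN, goal$direction) > 1e-6)
    stop("last leg is not aligned with the goal direction")

  leg_len <- sqrt(rowSums((waypoints[-1, , drop = FALSE] -
                             waypoints[-n, , drop = FALSE])^2))
  if (any(leg_len < 1e-12)) stop("consecutive waypoints must be distinct")

  # corner construction at interior waypoints
  corners <- vector("list", n)
  d_req <- numeric(n)
  if (n > 2) {
    for (i in 2:(n - 1)) {
      res <- tryCatch(
        spiral_corner(waypoints[i - 1, ], waypoints[i, ], waypoints[i + 1, ],
                      kappa_max = kappa_max),
        error = function(e) stop(sprintf("corner at waypoint %d: %s", i,
                                         conditionMessage(e)), call. = FALSE))
      if (!is.null(res$pair)) {
        corners[[i]] <- res
        d_req[i] <- res$d
      }
    }
    # leg budgets: corner i and corner i+1 share the leg between them
    scale_i <- rep(1, n)
    for (j in 1:(n - 1)) {
      used <- d_req[j] + d_req[j + 1]
      if (used > leg_len[j] * (1 - 1e-12)) {
        if (!clamp) {
          stop(sprintf(paste0("infeasible corner geometry on leg %d: spirals of ",
                              "waypoints %d/%d need %.3f mm but the leg is %.3f mm ",
                              "(kappa_max = %g)"), j, j, j + 1, used, leg_len[j],
                       kappa_max))
        }
        rho <- leg_len[j] * (1 - 1e-9) / used
        scale_i[j] <- min(scale_i[j], rho)
        scale_i[j + 1] <- min(scale_i[j + 1], rho)
      }
    }
    if (clamp && any(scale_i < 1)) {
      for (i in 2:(n - 1)) {
        if (!is.null(corners[[i]]) && scale_i[i] < 1) {
          corners[[i]] <- spiral_corner(waypoints[i - 1, ], waypoints[i, ],
                                        waypoints[i + 1, ],
                                        d_force = d_req[i] * scale_i[i])
          d_req[i] <- corners[[i]]$d
        }
      }
    }
  }

  # assemble pieces: straight connector, spiral pair, straight connector, ...
  ts <- seq(0, 1, length.out = 101)
  pieces <- list()
  cursor <- waypoints[1, ]
  add_seg <- function(a, b) {
    len <- vnorm(b - a)
    if (len > 1e-12) pieces[[length(pieces) + 1]] <<- list(type = "seg", a = a,
                                                          b = b, len = len)
  }
  if (n > 2) {
    for (i in 2:(n - 1)) {
      cr <- corners[[i]]
      if (is.null(cr)) next
      B0 <- cr$pair$control_points_first[1, ]
      E0 <- cr$pair$control_points_second[1, ]
      add_seg(cursor, B0)
      kp <- max(curvature_at(cr$pair, ts))
      pieces[[length(pieces) + 1]] <- list(type = "pair", pair = cr$pair,
                                           len = pair_arclength(cr$pair),
                                           kappa_peak = kp, corner = i)
      cursor <- E0
    }
  }
  add_seg(cursor, waypoints[n, ])

  traj <- new_trajectory(waypoints, start, goal, kappa_max, corners, pieces)
  if (!clamp && traj$max_curvature > kappa_max * (1 + 1e-3)) {
    stop(sprintf("constructed trajectory exceeds the curvature bound (%.4f > %g)",
                 traj$max_curvature, kappa_max))
  }
  traj
}

#' Total arc length of a trajectory (mm)
#'
#' Sum of connector lengths and spiral-pair arc lengths (Gauss-Legendre
#' quadrature per cubic).  Always at least the straight start--goal distance.
#'
#' @param traj an `ot_trajectory`.
#' @export
trajectory_length <- function(traj) {
  stopifnot(inherits(traj, "ot_trajectory"))
  traj$length
}

#' Maximum sampled curvature along a trajectory (1/mm)
#' @param traj an `ot_trajectory`.
#' @export
max_curvature <- function(traj) {
  stopifnot(inherits(traj, "ot_trajectory"))
  traj$max_curvature
}

#' Discretize a trajectory into an ordered polyline
#'
#' Produces points ordered along the trajectory with consecutive gaps of at
#' most `ds` (refined adaptively on the curved pieces); both endpoints are
#' always included.
#'
#' @param traj an `ot_trajectory`.
#' @param ds maximum chord step, mm (> 0).
#' @return a `m x 3` matrix of points.
#' @export
discretize <- function(traj, ds) {
  stopifnot(inherits(traj, "ot_trajectory"))
  if (!is.numeric(ds) || length(ds) != 1 || !is.finite(ds) || ds <= 0)
    stop("ds must be a positive number")
  out <- list()
  for (p in traj$pieces) {
    if (p$type == "seg") {
      m <- max(1L, ceiling(p$len / ds))
      tt <- seq(0, 1, length.out = m + 1)
      pts <- outer(1 - tt, p$a) + outer(tt, p$b)
    } else {
      m <- max(2L, ceiling(p$len / ds))
      tt <- seq(0, 1, length.out = m + 1)
      pts <- matrix(evaluate(p$pair, tt), ncol = 3)
      for (iter in 1:40) {
        gaps <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                                pts[-nrow(pts), , drop = FALSE])^2))
        bad <- which(gaps > ds)
        if (!length(bad)) break
        mids <- (tt[bad] + tt[bad + 1]) / 2
        tt <- sort(c(tt, mids))
        pts <- matrix(evaluate(p$pair, tt), ncol = 3)
      }
    }
    out[[length(out) + 1]] <- pts
  }
  if (!length(out)) return(rbind(traj$waypoints[1, ]))
  pts <- out[[1]]
  if (length(out) > 1) {
    for (i in 2:length(out)) pts <- rbind(pts, out[[i]][-1, , drop = FALSE])
  }
  dimnames(pts) <- NULL
  pts
}

# curvature peaks per interior waypoint (0 where no spiral), used by the SCO
corner_curvatures <- function(traj) {
  n <- nrow(traj$waypoints)
  k <- numeric(n)
  for (p in traj$pieces) if (p$type == "pair") k[p$corner] <- p$kappa_peak
  k
}

#' Serialize / deserialize trajectories
#'
#' `trajectory_to_json()` writes waypoints, endpoint states, the curvature
#' bound and all spiral control points; `trajectory_from_json()` rebuilds the
#' trajectory from its waypoints (the spline construction is deterministic).
#' `trajectory_to_csv()` writes an `x,y,z` polyline discretized at `ds`.
#'
#' @param traj an `ot_trajectory`.
#' @param path output file; for `trajectory_to_json(path = NULL)` the JSON
#'   string is returned instead.
#' @param ds polyline step for the CSV export, mm.
#' @return `trajectory_from_json()` returns an `ot_trajectory`.
#' @export
trajectory_to_json <- function(traj, path = NULL) {
  stopifnot(inherits(traj, "ot_trajectory"))
  cps <- lapply(seq_along(traj$corners), function(i) {
    cr <- traj$corners[[i]]
    if (is.null(cr)) return(NULL)
    list(waypoint = i,
         first = cr$pair$control_points_first,
         second = cr$pair$control_points_second)
  })
  obj <- list(
    waypoints = traj$waypoints,
    start = list(position = traj$start$position, direction = traj$start$direction),
    goal = list(position = traj$goal$position, direction = traj$goal$direction),
    kappa_max = traj$kappa_max,
    length = traj$length,
    max_curvature = traj$max_curvature,
    control_points = Filter(Negate(is.null), cps)
  )
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' @rdname trajectory_to_json
#' @export
trajectory_from_json <- function(path) {
  obj <- jsonlite::fromJSON(if (file.exists(path)) paste(readLines(path, warn = FALSE),
                                                         collapse = "") else path)
  build_trajectory(matrix(unlist(obj$waypoints), ncol = 3),
                   ot_state(obj$start$position, obj$start$direction),
                   ot_state(obj$goal$position, obj$goal$direction),
                   obj$kappa_max, clamp = TRUE)
}

#' @rdname trajectory_to_json
#' @export
trajectory_to_csv <- function(traj, path, ds = 0.1) {
  pts <- discretize(traj, ds)
  df <- data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
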