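# Obstacle environments: named triangle meshes with exact signed-distance /
# nearest-point / normal queries (positive outside, negative inside).

new_mesh <- function(vertices, faces, name = "mesh") {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  faces <- as.matrix(faces); storage.mode(faces) <- "integer"
  dimnames(vertices) <- dimnames(faces) <- NULL
  structure(list(vertices = vertices, faces = faces, name = name),
            class = "ot_mesh")
}

#' @export
print.ot_mesh <- function(x, ...) {
  cat(sprintf("<ot_mesh> '%s': %d vertices, %d triangles\n",
              x$name, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Clean a triangle mesh
#'
#' Welds duplicate vertices (tolerance `tol` mm), drops degenerate
#' (zero-area) and duplicate-index triangles, and removes unused vertices.
#'
#' @param mesh an `ot_mesh`.
#' @param tol welding tolerance, mm.
#' @export
clean_mesh <- function(mesh, tol = 1e-9) {
  V <- mesh$vertices; F <- mesh$faces
  key <- apply(round(V / tol), 1, paste, collapse = ",")
  first <- !duplicated(key)
  remap <- match(key, key[first])  # new id = position among first occurrences
  F2 <- matrix(remap[F], ncol = 3)
  V2 <- V[first, , drop = FALSE]
  # drop triangles with repeated vertices or ~zero area
  ok <- F2[, 1] != F2[, 2] & F2[, 2] != F2[, 3] & F2[, 1] != F2[, 3]
  F2 <- F2[ok, , drop = FALSE]
  e1 <- V2[F2[, 2], , drop = FALSE] - V2[F2[, 1], , drop = FALSE]
  e2 <- V2[F2[, 3], , drop = FALSE] - V2[F2[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area2 <- sqrt(rowSums(cr^2))
  F2 <- F2[area2 > 1e-14, , drop = FALSE]
  used <- sort(unique(as.vector(F2)))
  V3 <- V2[used, , drop = FALSE]
  F3 <- matrix(match(F2, used), ncol = 3)
  new_mesh(V3, F3, mesh$name)
}

#' Surface area and enclosed volume of a mesh
#' @param mesh an `ot_mesh` (volume assumes a closed, outward-oriented mesh).
#' @return list with `area` (mm^2) and `volume` (mm^3).
#' @export
mesh_area_volume <- function(mesh) {
  mesh_area_volume_cpp(mesh$vertices, mesh$faces)
}

#' Is a mesh watertight (closed, consistently oriented)?
#' @param mesh an `ot_mesh`.
#' @export
is_watertight <- function(mesh) {
  mesh_is_watertight_cpp(mesh$faces, nrow(mesh$vertices))
}

#' Build an obstacle environment from named meshes
#'
#' @param meshes list of `ot_mesh` objects (each with >= 4 vertices); names
#'   are taken from the meshes or from the list names.
#' @param clean clean each mesh on load (weld duplicates, drop degenerate
#'   faces); cleaning never changes signed-distance results.
#' @return an `ot_environment`.
#' @export
environment_from_meshes <- function(meshes, clean = TRUE) {
  if (inherits(meshes, "ot_mesh")) meshes <- list(meshes)
  if (!length(meshes)) stop("environment must contain at least one mesh")
  nms <- names(meshes)
  meshes <- lapply(seq_along(meshes), function(i) {
    m <- meshes[[i]]
    stopifnot(inherits(m, "ot_mesh"))
    if (!is.null(nms) && nzchar(nms[i])) m$name <- nms[i]
    if (clean) m <- clean_mesh(m)
    if (nrow(m$vertices) < 4) stop(sprintf("mesh '%s' has fewer than 4 vertices", m$name))
    m
  })
  allv <- do.call(rbind, lapply(meshes, `[[`, "vertices"))
  env <- structure(list(
    meshes = meshes,
    names = vapply(meshes, `[[`, character(1), "name"),
    bbox = rbind(lo = apply(allv, 2, min), hi = apply(allv, 2, max)),
    ptr = NULL
  ), class = "ot_environment")
  env$ptr <- env_build_cpp(lapply(meshes, function(m)
    list(vertices = m$vertices, faces = m$faces)))
  env
}

#' @export
print.ot_environment <- function(x, ...) {
  cat(sprintf("<ot_environment> %d obstacles: %s\n", length(x$meshes),
              paste(x$names, collapse = ", ")))
  invisible(x)
}

# external pointers do not survive serialisation; rebuild lazily
env_handle <- function(env) {
  stopifnot(inherits(env, "ot_environment"))
  if (is.null(env$ptr) || !env_ptr_valid_cpp(env$ptr)) {
    env$ptr <- env_build_cpp(lapply(env$meshes, function(m)
      list(vertices = m$vertices, faces = m$faces)))
  }
  env$ptr
}

#' Exact signed distance from a point to the nearest obstacle
#'
#' Distance to the closest triangle over all obstacle meshes; the sign is
#' positive outside obstacles (free space) and negative inside, decided by
#' the angle-weighted pseudonormal at the nearest surface feature.
#'
#' @param env an `ot_environment`.
#' @param x query point (length-3, mm).
#' @return an `ot_sdquery`: `sd` (mm), `nearest_point`, `normal` (unit,
#'   outward), `obstacle_name`, and the query `point` itself.
#' @export
signed_distance <- function(env, x) {
  res <- env_query_cpp(env_handle(env), matrix(as.numeric(x), 1, 3))
  structure(list(sd = res$sd[1],
                 nearest_point = as.numeric(res$nearest[1, ]),
                 normal = as.numeric(res$normal[1, ]),
                 obstacle_name = env$names[res$obstacle[1]],
                 point = as.numeric(x)),
            class = "ot_sdquery")
}

# vectorised signed distance (values only)
signed_distance_batch <- function(env, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  env_sd_cpp(env_handle(env), pts)
}

# vectorised full query
signed_distance_query_batch <- function(env, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  env_query_cpp(env_handle(env), pts)
}

#' First-order (linearized) signed distance
#'
#' The signed distance around a query is approximated by its first-order
#' expansion \eqn{sd(x) = sd(x_0) + n(x_0)^T (x - x_0)} with the nearest
#' surface point \eqn{x_0} and outward normal \eqn{n} frozen; equivalently,
#' expanding about the original query point `q$point` where the value is
#' `q$sd`.  Exact at the expansion point; error is second order in the
#' displacement.
#'
#' @param q an `ot_sdquery` from [signed_distance()].
#' @param x point at which to evaluate the expansion.
#' @return approximate signed distance, mm.
#' @export
linearized_sd <- function(q, x) {
  stopifnot(inherits(q, "ot_sdquery"))
  q$sd + sum(q$normal * (as.numeric(x) - q$point))
}

#' Minimal distance from a trajectory to the environment
#'
#' Minimum signed distance over the trajectory discretized at step `ds`;
#' negative if the trajectory enters an obstacle.
#'
#' @param traj an `ot_trajectory`.
#' @param env an `ot_environment`.
#' @param ds discretization step, mm.
#' @export
min_distance <- function(traj, env, ds = 0.1) {
  pts <- discretize(traj, ds)
  min(signed_distance_batch(env, pts))
}

#' Feasibility report for a trajectory
#'
#' Checks the curvature bound, the safety clearance at discretization `ds`,
#' and exact endpoint interpolation (position within 1e-9 mm, direction
#' within 1e-6 rad).
#'
#' @param traj an `ot_trajectory`.
#' @param env an `ot_environment`, or `NULL` for an empty environment (the
#'   clearance check then passes vacuously and `min_distance` is `Inf`).
#' @param kappa_max curvature bound, 1/mm.
#' @param d_min safety distance, mm.
#' @param ds discretization step, mm.
#' @return a list with `max_curvature`, `min_distance`, `endpoints_ok`,
#'   `pass` and `cause` (`NA` when passing).
#' @export
is_feasible <- function(traj, env, kappa_max, d_min, ds = 0.1) {
  stopifnot(inherits(traj, "ot_trajectory"), ds > 0)
  md <- if (is.null(env)) Inf else min_distance(traj, env, ds)
  mk <- traj$max_curvature
  n <- nrow(traj$waypoints)
  ep <- vnorm(traj$waypoints[1, ] - traj$start$position) < 1e-9 &&
    vnorm(traj$waypoints[n, ] - traj$goal$position) < 1e-9 &&
    vangle(traj$waypoints[2, ] - traj$waypoints[1, ], traj$start$direction) < 1e-6 &&
    vangle(traj$waypoints[n, ] - traj$waypoints[n - 1, ], traj$goal$direction) < 1e-6
  pass <- (mk <= kappa_max * (1 + 1e-3)) && (md >= d_min) && ep
  cause <- if (pass) NA_character_
  else if (!ep) "endpoint interpolation"
  else if (mk > kappa_max * (1 + 1e-3)) "curvature bound exceeded"
  else "minimum distance below d_min"
  list(max_curvature = mk, min_distance = md, endpoints_ok = ep,
       pass = pass, cause = cause)
}
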