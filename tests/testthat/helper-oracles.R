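# Independent oracles and fixture builders used across the test files.

# --- brute-force point-to-mesh distance (vectorised over triangles) ---------
# Closest-point-on-triangle distances computed for all triangles at once with
# plain matrix arithmetic; independent of the package's BVH query path.
brute_mesh_distance <- function(mesh, p) {
  V <- mesh$vertices; F <- mesh$faces
  A <- V[F[, 1], , drop = FALSE]
  B <- V[F[, 2], , drop = FALSE]
  C <- V[F[, 3], , drop = FALSE]
  P <- matrix(p, nrow(A), 3, byrow = TRUE)
  ab <- B - A; ac <- C - A; ap <- P - A
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- P - B; d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- P - C; d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  vc <- d1 * d4 - d3 * d2
  vb <- d5 * d2 - d1 * d6
  va <- d3 * d6 - d5 * d4
  # region classification (Ericson), computed as masks
  r1 <- d1 <= 0 & d2 <= 0
  r2 <- !r1 & d3 >= 0 & d4 <= d3
  r3 <- !r1 & !r2 & vc <= 0 & d1 >= 0 & d3 <= 0
  r4 <- !r1 & !r2 & !r3 & d6 >= 0 & d5 <= d6
  r5 <- !r1 & !r2 & !r3 & !r4 & vb <= 0 & d2 >= 0 & d6 <= 0
  r6 <- !r1 & !r2 & !r3 & !r4 & !r5 & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0
  r0 <- !(r1 | r2 | r3 | r4 | r5 | r6)
  X <- A  # region 1: vertex A
  X[r2, ] <- B[r2, , drop = FALSE]
  X[r4, ] <- C[r4, , drop = FALSE]
  if (any(r3)) {
    v <- d1[r3] / (d1[r3] - d3[r3])
    X[r3, ] <- A[r3, , drop = FALSE] + v * ab[r3, , drop = FALSE]
  }
  if (any(r5)) {
    w <- d2[r5] / (d2[r5] - d6[r5])
    X[r5, ] <- A[r5, , drop = FALSE] + w * ac[r5, , drop = FALSE]
  }
  if (any(r6)) {
    w <- (d4[r6] - d3[r6]) / ((d4[r6] - d3[r6]) + (d5[r6] - d6[r6]))
    X[r6, ] <- B[r6, , drop = FALSE] + w * (C[r6, , drop = FALSE] - B[r6, , drop = FALSE])
  }
  if (any(r0)) {
    den <- va[r0] + vb[r0] + vc[r0]
    v <- vb[r0] / den; w <- vc[r0] / den
    X[r0, ] <- A[r0, , drop = FALSE] + v * ab[r0, , drop = FALSE] +
      w * ac[r0, , drop = FALSE]
  }
  min(sqrt(rowSums((P - X)^2)))
}

brute_env_distance <- function(env, p) {
  min(vapply(env$meshes, brute_mesh_distance, numeric(1), p = p))
}

# --- Bernstein-basis cubic evaluation (independent of de Casteljau path) ----
bernstein_point <- function(P, s) {
  out <- 0
  for (k in 0:3) {
    out <- out + choose(3, k) * s^k * (1 - s)^(3 - k) * P[k + 1, ]
  }
  out
}

# finite-difference curvature of a sampled curve function r(t)
fd_curvature <- function(rfun, t, h = 1e-5) {
  d1 <- (rfun(t + h) - rfun(t - h)) / (2 * h)
  d2 <- (rfun(t + h) - 2 * rfun(t) + rfun(t - h)) / h^2
  cr <- c(d1[2] * d2[3] - d1[3] * d2[2],
          d1[3] * d2[1] - d1[1] * d2[3],
          d1[1] * d2[2] - d1[2] * d2[1])
  sqrt(sum(cr^2)) / sum(d1^2)^1.5
}

# --- brute-force 26-connected flood fill (recursive queue in plain R) -------
flood_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  cur <- 0L
  sizes <- integer(0)
  idx_all <- which(mask != 0)
  for (s in idx_all) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    sz <- 0L
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      sz <- sz + 1L
      ijk <- arrayInd(p, d)
      for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
        if (di == 0 && dj == 0 && dk == 0) next
        q <- ijk + c(di, dj, dk)
        if (any(q < 1) || any(q > d)) next
        ql <- q[1] + (q[2] - 1) * d[1] + (q[3] - 1) * d[1] * d[2]
        if (mask[ql] != 0 && lab[ql] == 0L) { lab[ql] <- cur; queue <- c(queue, ql) }
      }
    }
    sizes <- c(sizes, sz)
  }
  list(labels = lab, sizes = sizes)
}

# --- tiny fixtures ----------------------------------------------------------

# digitized ball label volume
ball_volume <- function(centre = c(5, 5, 5), radius = 3,
                        dims = c(40, 40, 20), spacing = c(0.25, 0.25, 0.5)) {
  vol <- array(0L, dims)
  otoplan:::raster_tube_cpp(vol, dims, spacing, c(0, 0, 0), rbind(centre),
                            radius, 1L)
  label_volume(vol, spacing)
}

ball_env <- function(centre = c(5, 5, 5), radius = 3, smooth_iters = 30, ...) {
  environment_from_meshes(list(extract_surface(ball_volume(centre, radius, ...),
                                               1, smooth_iters)))
}

# random feasible waypoint corridor: consecutive legs of length >= leg_min
# and corner deflections small enough for the curvature bound
random_feasible_waypoints <- function(n, kappa_max, leg = 30) {
  gmax <- 0.9 * otoplan:::max_turn_angle(kappa_max, leg)
  W <- matrix(0, n, 3)
  dir <- c(1, 0, 0)
  for (i in 2:n) {
    if (i > 2) {
      ax <- stats::rnorm(3); ax <- ax - sum(ax * dir) * dir
      ax <- ax / sqrt(sum(ax^2))
      ang <- stats::runif(1, 0, gmax)
      dir <- cos(ang) * dir + sin(ang) * ax
    }
    W[i, ] <- W[i - 1, ] + leg * dir
  }
  W
}

traj_from_waypoints <- function(W, kappa_max) {
  n <- nrow(W)
  build_trajectory(W,
                   ot_state(W[1, ], W[2, ] - W[1, ]),
                   ot_state(W[n, ], W[n, ] - W[n - 1, ]),
                   kappa_max)
}
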