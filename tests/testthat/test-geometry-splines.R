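# Bezier spiral corners and spline trajectories.

test_that("spiral pairs respect the curvature bound and corner geometry", {
  ts <- seq(0, 1, length.out = 501)
  # feasible right angle
  p <- spiral_pair_from_triple(c(-40, 0, 0), c(0, 0, 0), c(0, 40, 0), 0.05)
  expect_lte(max(curvature_at(p, ts)), 0.05 * (1 + 1e-3))
  # symmetric about the bisector for equal legs: join on the bisector
  J <- p$control_points_first[4, ]
  expect_equal(J, p$control_points_second[4, ])
  b <- c(-1, 1, 0) / sqrt(2)
  off <- (J - c(0, 0, 0)) - sum(J * b) * b
  expect_lt(sqrt(sum(off^2)), 1e-9)
  # starts/ends on the legs, tangent to them
  expect_equal(p$control_points_first[1, ], c(-attr(p, "d"), 0, 0))
  expect_equal(p$control_points_second[1, ], c(0, attr(p, "d"), 0))
  # curvature is zero at the leg ends (G2 with the straight legs)
  expect_lt(curvature_at(p, 0), 1e-12)
  expect_lt(curvature_at(p, 1), 1e-12)
})

test_that("spiral curvature is monotone along each cubic (spiral property)", {
  set.seed(42)
  for (rep in 1:20) {
    ang <- runif(1, 0.15, 2.4)
    v <- c(cos(ang), sin(ang), runif(1, -0.3, 0.3))
    p <- spiral_pair_from_triple(c(-600, 0, 0), c(0, 0, 0), 600 * v / sqrt(sum(v^2)),
                                 runif(1, 0.02, 0.1))
    k1 <- curvature_at(p, seq(0, 0.5, length.out = 64))
    k2 <- curvature_at(p, seq(0.5, 1, length.out = 64))
    expect_true(all(diff(k1) > -1e-5 * max(k1)))
    expect_true(all(diff(k2) < 1e-5 * max(k2)))
    # curvature continuity at the join (mirror symmetry)
    expect_lt(abs(k1[64] - k2[1]) / k1[64], 1e-3)
  }
})

test_that("degenerate and infeasible corners are handled per contract", {
  ts <- seq(0, 1, length.out = 301)
  pc <- spiral_pair_from_triple(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), 0.05)
  expect_lt(max(curvature_at(pc, ts)), 1e-12)
  expect_error(spiral_pair_from_triple(c(0, 0, 0), c(20, 0, 0), c(20, 20, 0), 0.05),
               "infeasible")
  expect_error(spiral_pair_from_triple(c(0, 0, 0), c(1, 0, 0), c(0, 0, 0), 0.05),
               "revers|distinct")
})

test_that("evaluate matches a Bernstein-expansion oracle and its endpoints", {
  p <- spiral_pair_from_triple(c(-50, 0, 0), c(0, 0, 0), c(30, 40, 0), 0.05)
  expect_equal(evaluate(p, 0), p$control_points_first[1, ])
  expect_equal(evaluate(p, 1), p$control_points_second[1, ])
  for (t in c(0.05, 0.21, 0.4, 0.5, 0.77, 0.93)) {
    got <- evaluate(p, t)
    want <- if (t <= 0.5) bernstein_point(p$control_points_first, 2 * t)
    else bernstein_point(p$control_points_second[4:1, ], 2 * t - 1)
    expect_equal(got, want, tolerance = 1e-12)
  }
  expect_error(evaluate(p, 1.2), "\\[0, 1\\]")
})

test_that("curvature_at matches finite differences and scales with similarity", {
  p <- spiral_pair_from_triple(c(-60, 0, 0), c(0, 0, 0), c(40, 40, 10), 0.04)
  for (t in c(0.1, 0.3, 0.45, 0.6, 0.9)) {
    fd <- fd_curvature(function(s) evaluate(p, s), t)
    expect_equal(curvature_at(p, t), fd, tolerance = 1e-4)
  }
  # doubling all control points halves the curvature
  p2 <- p
  p2$control_points_first <- 2 * p$control_points_first
  p2$control_points_second <- 2 * p$control_points_second
  tt <- c(0.1, 0.5, 0.8)
  expect_equal(curvature_at(p2, tt), curvature_at(p, tt) / 2, tolerance = 1e-12)
})

test_that("build_trajectory smooths every interior corner and interpolates endpoints", {
  # planar zigzag: one spiral pair per interior corner
  x <- seq(0, 8) * 40
  W <- cbind(x, rep(c(0, 6), length.out = 9), 0)
  W[1:2, 2] <- 0; W[8:9, 2] <- c(0, 0)  # aligned first/last legs
  tr <- traj_from_waypoints(W, 0.05)
  n_pairs <- sum(vapply(tr$pieces, function(p) p$type == "pair", logical(1)))
  interior_corners <- sum(vapply(2:(nrow(W) - 1), function(i) {
    otoplan:::vangle(W[i, ] - W[i - 1, ], W[i + 1, ] - W[i, ]) > 1e-6
  }, logical(1)))
  expect_equal(n_pairs, interior_corners)
  expect_lte(max_curvature(tr), 0.05 * (1 + 1e-3))
  # exact endpoint interpolation
  expect_equal(tr$waypoints[1, ], tr$start$position)
  expect_equal(tr$waypoints[9, ], tr$goal$position)
  # misaligned start direction is rejected
  expect_error(build_trajectory(W, ot_state(W[1, ], c(0, 1, 0)),
                                ot_state(W[9, ], c(1, 0, 0)), 0.05),
               "aligned")
})

test_that("junction continuity holds along constructed trajectories", {
  set.seed(7)
  for (rep in 1:5) {
    W <- random_feasible_waypoints(7, 0.05)
    tr <- traj_from_waypoints(W, 0.05)
    pieces <- tr$pieces
    for (i in seq_along(pieces)[-1]) {
      a <- pieces[[i - 1]]; b <- pieces[[i]]
      pa <- if (a$type == "seg") a$b else evaluate(a$pair, 1)
      pb <- if (b$type == "seg") b$a else evaluate(b$pair, 0)
      expect_lt(sqrt(sum((pa - pb)^2)), 1e-9)
      ta <- if (a$type == "seg") (a$b - a$a) else
        (evaluate(a$pair, 1) - evaluate(a$pair, 1 - 1e-7))
      tb <- if (b$type == "seg") (b$b - b$a) else
        (evaluate(b$pair, 1e-7) - evaluate(b$pair, 0))
      expect_lt(otoplan:::vangle(ta, tb), 1e-5)
    }
  }
})

test_that("trajectory construction is rigid-motion equivariant", {
  set.seed(11)
  W <- random_feasible_waypoints(6, 0.05)
  # random rotation (QR of a random matrix) + translation
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  tv <- c(5, -3, 2)
  tr1 <- traj_from_waypoints(W, 0.05)
  tr2 <- traj_from_waypoints(t(Q %*% t(W)) + matrix(tv, 6, 3, byrow = TRUE), 0.05)
  ts <- seq(0, 1, length.out = 33)
  for (i in seq_along(tr1$pieces)) {
    p1 <- tr1$pieces[[i]]; p2 <- tr2$pieces[[i]]
    expect_equal(p1$type, p2$type)
    if (p1$type == "pair") {
      a <- t(Q %*% t(matrix(evaluate(p1$pair, ts), ncol = 3))) +
        matrix(tv, length(ts), 3, byrow = TRUE)
      b <- matrix(evaluate(p2$pair, ts), ncol = 3)
      expect_lt(max(abs(a - b)), 1e-9)
    }
  }
  expect_equal(trajectory_length(tr1), trajectory_length(tr2), tolerance = 1e-9)
})

test_that("discretize respects the step bound, endpoints and length", {
  s <- ot_state(c(0, 0, 0), c(1, 0, 0))
  g <- ot_state(c(10, 0, 0), c(1, 0, 0))
  tr <- build_trajectory(rbind(c(0, 0, 0), c(10, 0, 0)), s, g, 0.05)
  pts <- discretize(tr, 1)
  expect_equal(nrow(pts), 11)
  expect_equal(pts[1, ], c(0, 0, 0))
  expect_equal(pts[11, ], c(10, 0, 0))
  expect_error(discretize(tr, 0), "positive")

  set.seed(3)
  W <- random_feasible_waypoints(6, 0.05)
  tr <- traj_from_waypoints(W, 0.05)
  for (ds in c(1, 0.2)) {
    pts <- discretize(tr, ds)
    gaps <- sqrt(rowSums((pts[-1, ] - pts[-nrow(pts), ])^2))
    expect_lte(max(gaps), ds * (1 + 1e-9))
    expect_equal(pts[1, ], W[1, ])
    expect_equal(pts[nrow(pts), ], W[6, ])
  }
  # polyline length converges to the quadrature length from below
  len <- trajectory_length(tr)
  poly_len <- sum(sqrt(rowSums(diff(discretize(tr, 0.05))^2)))
  expect_lt(abs(poly_len - len) / len, 1e-3)
  expect_gte(len, sqrt(sum((W[6, ] - W[1, ])^2)))
})

test_that("trajectory serialization round-trips", {
  set.seed(5)
  W <- random_feasible_waypoints(5, 0.05)
  tr <- traj_from_waypoints(W, 0.05)
  f <- tempfile(fileext = ".json")
  trajectory_to_json(tr, f)
  tr2 <- trajectory_from_json(f)
  expect_equal(tr2$waypoints, tr$waypoints)
  expect_equal(trajectory_length(tr2), trajectory_length(tr))
  fc <- tempfile(fileext = ".csv")
  trajectory_to_csv(tr, fc, ds = 0.5)
  df <- read.csv(fc)
  expect_equal(unlist(df[1, ], use.names = FALSE), W[1, ])
})
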