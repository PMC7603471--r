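# Sequential convex optimization: printed cost/constraint formulas, the
# convex subproblem, the ADMM solver, and the triple loop.

test_that("cost_length implements the squared-length surrogate exactly", {
  expect_equal(cost_length(rbind(c(0, 0, 0), c(3, 4, 0))), 25)
  expect_equal(cost_length(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))), 2)
  set.seed(2)
  W <- matrix(rnorm(21), ncol = 3)
  brute <- 0
  for (i in 1:(nrow(W) - 1)) for (k in 1:3) brute <- brute + (W[i, k] - W[i + 1, k])^2
  expect_equal(cost_length(W), brute, tolerance = 1e-12)
})

test_that("curvature_smoothing reproduces the printed straightening formulas", {
  W <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  cs <- curvature_smoothing(W, 2)
  expect_equal(cs$targets[1, ], c(0.25, -0.25, 0))
  expect_equal(cs$targets[2, ], c(0.875, 0.125, 0))
  expect_equal(cs$targets[3, ], c(1.25, 0.75, 0))
  expect_equal(cs$g, 0.28125)
  # collinear equally spaced: identity, zero penalty
  cs0 <- curvature_smoothing(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), 2)
  expect_equal(cs0$targets, rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
  expect_equal(cs0$g, 0)
  # rigid-motion invariance of g
  set.seed(5)
  W <- matrix(rnorm(15), ncol = 3)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  W2 <- t(Q %*% t(W)) + matrix(c(1, 2, 3), 5, 3, byrow = TRUE)
  expect_equal(curvature_smoothing(W2, 3)$g, curvature_smoothing(W, 3)$g,
               tolerance = 1e-9)
  expect_error(curvature_smoothing(W, 1), "interior")
  expect_error(curvature_smoothing(W, 5), "interior")
})

test_that("clearance cost terms follow theta - sd, unclamped", {
  ctr <- c(5, 5, 5)
  env <- ball_env(centre = ctr, radius = 3)
  z <- ctr[3] + 5.5
  W <- rbind(c(-3, 5, z), c(1, 5, z), c(5, 5, z), c(9, 5, z), c(13, 5, z))
  tr <- traj_from_waypoints(W, 0.05)
  sd_mid <- signed_distance(env, W[3, ])$sd
  # theta equal to the measured clearance: zero cost term (printed formula)
  cc <- clearance_cost(tr, env, theta = sd_mid)
  expect_equal(unname(cc["3"]), 0, tolerance = 1e-12)
  # theta below clearance: negative, no clamping
  cc2 <- clearance_cost(tr, env, theta = sd_mid / 2)
  expect_equal(unname(cc2["3"]), -sd_mid / 2, tolerance = 1e-12)
  expect_equal(length(cc), 3)  # one term per interior waypoint
})

test_that("convexified model matches true values at the expansion point", {
  ctr <- c(5, 5, 5)
  env <- ball_env(centre = ctr, radius = 3)
  z <- ctr[3] + 5
  set.seed(12)
  W <- cbind(seq(-30, 110, length.out = 8), 5 + c(0, 0, runif(4, -0.5, 0.5), 0, 0), z)
  tr <- traj_from_waypoints(W, 0.05)
  cfg <- sco_config()
  sp <- convexify(tr, env, cfg, state = list(mu = cfg$mu0, s = cfg$s0),
                  d_min = 0.8)
  # equalities: first and last two waypoints fixed
  expect_equal(sp$fixed_waypoints, c(1, 2, 7, 8))
  expect_equal(sp$n_eq, 12)
  mu <- cfg$mu0
  model0 <- otoplan:::subproblem_merit(sp, numeric(length(sp$c0)), mu)
  true0 <- otoplan:::true_merit_fn(tr$waypoints, env, cfg, 0.8, mu, sp$active)
  expect_equal(model0, true0$merit, tolerance = 1e-9)
  # gradient of the quadratic model matches central finite differences of the
  # true cost (length + clearance) at the expansion point
  free <- sp$free_idx
  h <- 1e-5
  g_model <- as.numeric(sp$c0)  # gradient of the cost model at zero
  for (j in seq_along(free)) {
    for (k in 1:3) {
      Wp <- tr$waypoints; Wm <- tr$waypoints
      Wp[free[j], k] <- Wp[free[j], k] + h
      Wm[free[j], k] <- Wm[free[j], k] - h
      f <- function(Wx) {
        cfg$alpha_len * cost_length(Wx) +
          cfg$alpha_obs * sum(cfg$theta -
            otoplan:::signed_distance_batch(env, Wx[2:7, , drop = FALSE]))
      }
      fd <- (f(Wp) - f(Wm)) / (2 * h)
      expect_equal(g_model[(j - 1) * 3 + k], fd, tolerance = 2e-3)
    }
  }
})

test_that("solve_subproblem matches direct minimisation on small QPs", {
  # unconstrained quadratic |x - a|^2 inside and outside the trust box
  mk <- function(a, s) {
    structure(list(H0 = 2 * diag(2), c0 = -2 * a, const0 = sum(a^2),
                   Hk = matrix(0, 2, 2), ck = numeric(2), constk = 0,
                   A = matrix(0, 0, 2), b = numeric(0), hinge_const = 0,
                   s = s, free_idx = 1L, n = 5, fixed_waypoints = integer(0),
                   n_eq = 0, active = integer(0), anchors = NULL),
              class = "ot_convex_subproblem")
  }
  expect_equal(solve_subproblem(mk(c(0.05, -0.08), s = 0.15), 1),
               c(0.05, -0.08), tolerance = 1e-8)
  expect_equal(solve_subproblem(mk(c(0.5, -0.8), s = 0.15), 1),
               c(0.15, -0.15), tolerance = 1e-8)
  # random QPs with hinge terms vs a dense grid oracle (2 variables)
  set.seed(33)
  for (rep in 1:5) {
    M <- matrix(rnorm(4), 2); H <- crossprod(M) + 0.5 * diag(2)
    cc <- rnorm(2); A <- matrix(rnorm(4), 2); b <- rnorm(2, sd = 0.05)
    mu <- runif(1, 0.5, 5); s <- 0.2
    sp <- structure(list(H0 = H, c0 = cc, const0 = 0,
                         Hk = matrix(0, 2, 2), ck = numeric(2), constk = 0,
                         A = A, b = b, hinge_const = 0, s = s,
                         free_idx = 1L, n = 5, fixed_waypoints = integer(0),
                         n_eq = 0, active = integer(0), anchors = NULL),
                    class = "ot_convex_subproblem")
    xs <- seq(-s, s, length.out = 401)
    grid <- as.matrix(expand.grid(xs, xs))
    vals <- 0.5 * rowSums((grid %*% H) * grid) + grid %*% cc +
      mu * (pmax(0, grid %*% A[1, ] + b[1]) + pmax(0, grid %*% A[2, ] + b[2]))
    xstar <- grid[which.min(vals), ]
    got <- solve_subproblem(sp, mu)
    fval <- function(x) 0.5 * sum(x * (H %*% x)) + sum(cc * x) +
      mu * sum(pmax(0, A %*% x + b))
    expect_lte(fval(got), min(vals) + 1e-4)
    expect_lt(max(abs(got - unname(xstar))), 2e-3)
  }
})

test_that("free-space optimization straightens a zigzag and fixes endpoints", {
  x <- seq(0, 60, by = 4)
  W <- cbind(x, 0, 0)
  dimnames(W) <- NULL
  W[seq(4, 14, by = 2), 2] <- 2
  s <- ot_state(W[1, ], c(1, 0, 0)); g <- ot_state(W[nrow(W), ], c(1, 0, 0))
  tr <- build_trajectory(W, s, g, 0.05, clamp = TRUE)
  res <- optimize_trajectory(tr, NULL, 0.05, 0.8, sco_config())
  expect_identical(res$trajectory$waypoints[c(1, 2, nrow(W) - 1, nrow(W)), ],
                   W[c(1, 2, nrow(W) - 1, nrow(W)), ])
  expect_lte(cost_length(res$trajectory$waypoints), cost_length(W))
  expect_lt(trajectory_length(res$trajectory), 60 * 1.02)
  expect_equal(res$report$status, "converged")
})

test_that("accepted SCO steps never increase the merit; violations end below eps_c", {
  an <- generate_anatomy(benchmark_params(seed = 4))
  env <- environment_from_labels(an$volume)
  fid <- an$fiducials[["Access"]]
  pr <- plan_trajectory(env, fid$start, fid$goal, 0.05, 0.8,
                        rrt_config(max_iter = 3000L, seed = 4))
  expect_true(pr$success)
  pre <- min_distance(pr$trajectory, env, 0.1)
  res <- optimize_trajectory(pr$trajectory, env, 0.05, 0.8, sco_config())
  acc <- res$log[res$log$accepted, ]
  expect_true(all(acc$merit_after <= acc$merit_before + 1e-9))
  expect_true(res$report$converged)
  expect_lte(res$report$violation, sco_config()$eps_c)
  expect_identical(res$trajectory$waypoints[1:2, ], pr$trajectory$waypoints[1:2, ])
  nW <- nrow(pr$trajectory$waypoints)
  expect_identical(res$trajectory$waypoints[(nW - 1):nW, ],
                   pr$trajectory$waypoints[(nW - 1):nW, ])
  post <- min_distance(res$trajectory, env, 0.1)
  expect_gte(post, pre - 0.05)  # clearance is maintained or improved
})
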