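# Bidirectional RRT planner.

test_that("sample_point is deterministic under seed and stays within bounds", {
  bounds <- rbind(c(-1, 2, 5), c(3, 4, 9))
  set.seed(123)
  a <- replicate(100, sample_point(bounds))
  set.seed(123)
  b <- replicate(100, sample_point(bounds))
  expect_identical(a, b)
  expect_true(all(a >= bounds[1, ] & a <= bounds[2, ]))
  # per-axis empirical mean within 3 sigma of the box centre
  n <- 4000
  set.seed(99)
  s <- t(replicate(n, sample_point(bounds)))
  centre <- colMeans(bounds)
  width <- bounds[2, ] - bounds[1, ]
  tol <- 3 * width / sqrt(12 * n)
  expect_true(all(abs(colMeans(s) - centre) < tol))
  expect_error(sample_point(NULL), "bounds")
})

test_that("nearest_in_ball filters by radius and capacity, sorted with ties stable", {
  tr <- search_tree(ot_state(c(0, 0, 0), c(1, 0, 0)))
  expect_equal(nearest_in_ball(tr, c(0.5, 0, 0), 1, 10), 1L)
  expect_length(nearest_in_ball(tr, c(5, 0, 0), 1, 10), 0)
  # capacity exclusion
  i2 <- tree_insert(tr, ot_state(c(0.2, 0, 0), c(1, 0, 0)), 1L)
  expect_false(1L %in% nearest_in_ball(tr, c(0, 0, 0), 1, 1))
  expect_true(i2 %in% nearest_in_ball(tr, c(0, 0, 0), 1, 1))
  # brute-force comparison on a 500-node tree
  set.seed(21)
  tr <- search_tree(ot_state(c(0, 0, 0), c(1, 0, 0)))
  for (i in 1:499) {
    tree_insert(tr, ot_state(runif(3, -5, 5), c(1, 0, 0)),
                sample.int(tr$n, 1))
  }
  p <- c(1, -2, 0.5); r_b <- 2.5; n_c <- 3
  got <- nearest_in_ball(tr, p, r_b, n_c)
  n <- tr$n
  d2 <- rowSums((tr$pos[1:n, ] - matrix(p, n, 3, byrow = TRUE))^2)
  want <- which(d2 <= r_b^2 & tr$nchild[1:n] < n_c)
  want <- want[order(d2[want], want)]
  expect_identical(got, want)
})

test_that("steer saturates the turn and keeps the implied corner feasible", {
  q <- ot_state(c(0, 0, 0), c(1, 0, 0))
  st <- steer(q, c(10, 0, 0), 4, 0.05)
  expect_equal(st$state$position, c(4, 0, 0), tolerance = 1e-12)
  expect_equal(st$state$direction, c(1, 0, 0))
  expect_equal(st$turn, 0, tolerance = 1e-12)
  # 200 random targets: step length delta_t, implied corner within kappa_max
  set.seed(31)
  gmax <- otoplan:::max_turn_angle(0.05, 4)
  for (i in 1:200) {
    p <- runif(3, -20, 20)
    if (sqrt(sum(p^2)) < 1e-6) next
    st <- steer(q, p, 4, 0.05)
    expect_equal(sqrt(sum((st$state$position - q$position)^2)), 4,
                 tolerance = 1e-9)
    expect_lte(st$turn, gmax + 1e-12)
    if (st$turn > 1e-6) {
      pair <- spiral_pair_from_triple(q$position - 4 * q$direction, q$position,
                                      st$state$position, 0.05)
      expect_lte(max(curvature_at(pair, seq(0, 1, length.out = 101))),
                 0.05 * (1 + 1e-3))
    }
  }
  expect_error(steer(q, c(0, 0, 0), 4, 0.05), "coincides")
})

test_that("cone membership matches the brute-force half-angle test", {
  set.seed(17)
  apex <- c(1, 2, 3); axis <- c(0, 0, 1)
  tr <- search_tree(ot_state(apex, axis))
  pts <- matrix(runif(900, -6, 10), ncol = 3)
  for (i in seq_len(nrow(pts))) {
    tree_insert(tr, ot_state(pts[i, ], c(1, 0, 0)), 1L)
  }
  c_r <- 5; c_h <- 18
  got <- otoplan:::cone_candidates(tr, apex, axis, c_r, c_h)
  rel <- sweep(rbind(apex, pts), 2, apex)
  proj <- rel %*% axis
  rad <- sqrt(rowSums(rel^2) - proj^2)
  half <- atan(c_r / c_h)
  inside <- proj > 1e-9 & proj <= c_h & atan2(rad, proj) <= half + 1e-12
  expect_setequal(got, which(inside))
  # a node straight behind the apex is never a candidate
  tr2 <- search_tree(ot_state(apex, axis))
  tree_insert(tr2, ot_state(apex - 5 * axis, axis), 1L)
  expect_length(otoplan:::cone_candidates(tr2, apex, axis, c_r, c_h), 0)
})

test_that("free-space planning finds a near-straight bridge deterministically", {
  qI <- ot_state(c(0, 0, 0), c(1, 0, 0))
  qG <- ot_state(c(50, 0, 0), c(1, 0, 0))
  cfg <- rrt_config(max_iter = 2000L, seed = 7)
  pr <- plan_trajectory(NULL, qI, qG, 0.05, 0.8, cfg)
  expect_true(pr$success)
  expect_lt(trajectory_length(pr$trajectory), 50 * 1.05)
  fz <- is_feasible(pr$trajectory, NULL, 0.05, 0.8, 0.05)
  expect_true(fz$pass)
  # identical seed/config: byte-identical serialized trajectory
  pr2 <- plan_trajectory(NULL, qI, qG, 0.05, 0.8, cfg)
  expect_identical(as.character(trajectory_to_json(pr$trajectory)),
                   as.character(trajectory_to_json(pr2$trajectory)))
})

test_that("planner respects obstacles, preconditions and budgets", {
  env <- ball_env(centre = c(5, 5, 5), radius = 3)
  # start inside the safety margin: precondition error, not a timeout
  expect_error(
    plan_trajectory(env, ot_state(c(5, 5, 8.5), c(1, 0, 0)),
                    ot_state(c(25, 5, 5), c(1, 0, 0)), 0.05, 2.0,
                    rrt_config(max_iter = 50L, seed = 1)),
    class = "otoplan_precondition_error")
  # goal sealed inside a voxelized closed box: failure by budget, with stats
  box <- array(0L, c(40, 40, 40))
  box[10:30, 10:30, 10:30] <- 1L
  box[14:26, 14:26, 14:26] <- 0L   # hollow interior
  lvb <- label_volume(box, c(1, 1, 1))
  envb <- environment_from_meshes(list(extract_surface(lvb, 1, smooth_iters = 5)))
  pr <- plan_trajectory(envb, ot_state(c(-8, 20, 20), c(1, 0, 0)),
                        ot_state(c(20, 20, 20), c(1, 0, 0)), 0.05, 0.5,
                        rrt_config(max_iter = 150L, seed = 2))
  expect_false(pr$success)
  expect_match(pr$cause, "budget")
  expect_true(all(pr$tree_sizes >= 1))
})

test_that("planned trajectories on synthetic cases pass dense re-checks; audit holds", {
  an <- generate_anatomy(benchmark_params(seed = 2))
  env <- environment_from_labels(an$volume)
  fid <- an$fiducials[["Access"]]
  pr <- plan_trajectory(env, fid$start, fid$goal, 0.05, 0.8,
                        rrt_config(max_iter = 3000L, seed = 2))
  expect_true(pr$success)
  fz <- is_feasible(pr$trajectory, env, 0.05, 0.8, ds = 0.05)
  expect_true(fz$pass)
  expect_gte(fz$min_distance, 0.8)
})
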