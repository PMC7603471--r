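# Label volumes, surface extraction, and signed-distance queries.

test_that("label volume IO round-trips (MetaImage exactly, NIfTI to float spacing)", {
  set.seed(1)
  arr <- array(sample(0:3, 6 * 5 * 4, replace = TRUE), c(6, 5, 4))
  lv <- label_volume(arr, spacing = c(0.2, 0.2, 0.4), origin = c(1.5, -2, 0.25))
  for (ext in c(".mha", ".mhd", ".nii", ".nii.gz")) {
    f <- tempfile(fileext = ext)
    save_label_volume(lv, f)
    lv2 <- load_label_volume(f)
    expect_identical(lv2$data, lv$data, info = ext)
    tol <- if (grepl("nii", ext)) 1e-6 else 0
    expect_equal(lv2$spacing, lv$spacing, tolerance = tol, info = ext)
    expect_equal(lv2$origin, lv$origin, tolerance = tol, info = ext)
  }
  f <- tempfile(fileext = ".xyz")
  expect_error(save_label_volume(lv, f), "format")
  expect_error(load_label_volume(f), "not found")
})

test_that("largest_component keeps the biggest 26-connected component", {
  arr <- array(0L, c(12, 12, 6))
  arr[2:5, 2:5, 2:3] <- 1L      # 32 voxels
  arr[9:10, 9:10, 2] <- 1L      # 4 voxels
  lv <- label_volume(arr)
  m <- largest_component(lv, 1)
  expect_equal(sum(m), 32)
  expect_true(all(m[2:5, 2:5, 2:3] == 1L))
  # identity on a single component
  arr2 <- array(0L, c(6, 6, 6)); arr2[2:4, 2:4, 2:4] <- 2L
  expect_equal(sum(largest_component(label_volume(arr2), 2)), 27)
  # absent label: empty mask with a warning
  expect_warning(m0 <- largest_component(lv, 7), "absent")
  expect_equal(sum(m0), 0)
})

test_that("largest_component agrees with a brute-force flood fill, ties deterministic", {
  set.seed(9)
  for (rep in 1:5) {
    arr <- array(as.integer(runif(8 * 8 * 8) < 0.25), c(8, 8, 8))
    lv <- label_volume(arr)
    if (!any(arr == 1L)) next
    ours <- largest_component(lv, 1)
    oracle <- flood_components(arr)
    best_size <- max(oracle$sizes)
    winners <- which(oracle$sizes == best_size)
    # deterministic tie-break: the component seeded earliest in scan order
    expect_equal(sum(ours), best_size)
    expect_equal(unname(which(array(ours, dim(arr)) == 1L)),
                 unname(which(oracle$labels == winners[1])))
  }
})

test_that("compute_voi squares the X-Y extent, honours exclusion and clips", {
  arr <- array(0L, c(40, 40, 12))
  arr[6:15, 6:25, 3:10] <- 1L   # 10 x 20 x 8 structure
  lv <- label_volume(arr)
  voi <- compute_voi(lv, pad = 0)
  ext <- voi$index_box[2, ] - voi$index_box[1, ] + 1
  expect_equal(unname(ext[1]), unname(ext[2]))
  expect_equal(unname(ext[2]), 20)
  expect_true(all(voi$index_box[1, ] <= c(6, 6, 3)) &&
                all(voi$index_box[2, ] >= c(15, 25, 10)))
  # excluding a label removes its influence
  arr[30:38, 30:38, 2:11] <- 2L
  lv2 <- label_volume(arr, labels = c(ICA = 2, Coc = 1))
  voi_all <- compute_voi(lv2, pad = 0)
  voi_ex <- compute_voi(lv2, exclude = "ICA", pad = 0)
  expect_gte(voi_all$index_box[2, 1], 38)
  expect_lte(voi_ex$index_box[2, 1], 26)
  # huge padding clips to the grid
  voi_big <- compute_voi(lv, pad = 1000)
  expect_true(all(voi_big$index_box[1, ] >= 1))
  expect_true(all(voi_big$index_box[2, ] <= dim(arr)))
  expect_error(compute_voi(lv, exclude = 1), "no non-excluded")
})

test_that("extract_surface recovers analytic area/volume and scales with spacing", {
  lv <- ball_volume(centre = c(5, 5, 5), radius = 4)
  m <- extract_surface(lv, 1)
  av <- mesh_area_volume(m)
  expect_equal(av$area, 4 * pi * 16, tolerance = 0.05)
  expect_equal(av$volume, 4 / 3 * pi * 64, tolerance = 0.05)
  expect_true(is_watertight(m))
  # vertices near the mask boundary (within one voxel diagonal)
  r <- sqrt(rowSums(sweep(m$vertices, 2, c(5, 5, 5))^2))
  expect_lt(max(abs(r - 4)), sqrt(sum(c(0.25, 0.25, 0.5)^2)))
  # doubling the spacing doubles the coordinates
  lv2 <- label_volume(lv$data, spacing = 2 * lv$spacing)
  m2 <- extract_surface(lv2, 1)
  expect_equal(m2$vertices, 2 * m$vertices, tolerance = 1e-12)
  # too-small structures are rejected
  tiny <- array(0L, c(6, 6, 6)); tiny[3, 3, 3] <- 1L
  expect_error(extract_surface(label_volume(tiny), 1), "too small")
})

test_that("signed_distance matches the brute-force all-triangle oracle", {
  env <- ball_env(radius = 3, smooth_iters = 20)
  expect_lte(nrow(env$meshes[[1]]$faces), 20000)
  set.seed(4)
  pts <- matrix(runif(150, 0, 10), ncol = 3)
  sd <- otoplan:::signed_distance_batch(env, pts)
  for (i in seq_len(nrow(pts))) {
    expect_equal(abs(sd[i]), brute_env_distance(env, pts[i, ]), tolerance = 1e-9)
  }
})

test_that("signed distance sign, nearest point and normal behave on a ball", {
  ctr <- c(5, 5, 5)
  env <- ball_env(centre = ctr, radius = 3)
  q <- signed_distance(env, ctr + c(5, 0, 0))
  expect_equal(q$sd, 2, tolerance = 0.05)
  expect_equal(q$normal, c(1, 0, 0), tolerance = 0.15)
  expect_equal(sqrt(sum((q$nearest_point - q$point)^2)), abs(q$sd),
               tolerance = 1e-9)
  expect_lt(signed_distance(env, ctr)$sd, 0)
  # interior/exterior classification away from the surface
  set.seed(8)
  pts <- matrix(runif(3000, 0, 10), ncol = 3)
  rr <- sqrt(rowSums(sweep(pts, 2, ctr)^2))
  keep <- abs(rr - 3) > 0.5
  sd <- otoplan:::signed_distance_batch(env, pts[keep, ])
  expect_gte(mean((sd < 0) == (rr[keep] < 3)), 0.999)
})

test_that("linearized_sd reproduces the printed expansion and Taylor remainder", {
  ctr <- c(5, 5, 5)
  env <- ball_env(centre = ctr, radius = 3)
  p <- ctr + c(4.2, 0.3, -0.4)
  q <- signed_distance(env, p)
  expect_equal(linearized_sd(q, p), q$sd)  # zero displacement
  # hand-built query on the unit-sphere surface point
  qh <- structure(list(sd = 0, nearest_point = c(1, 0, 0), normal = c(1, 0, 0),
                       obstacle_name = "sphere", point = c(1, 0, 0)),
                  class = "ot_sdquery")
  expect_equal(linearized_sd(qh, c(1.1, 0, 0)), 0.1)
  # second-order remainder under shrinking displacements
  dirv <- c(0.3, -0.8, 0.5); dirv <- dirv / sqrt(sum(dirv^2))
  errs <- vapply(c(0.4, 0.2, 0.1), function(h) {
    x <- p + h * dirv
    abs(linearized_sd(q, x) - signed_distance(env, x)$sd)
  }, numeric(1))
  # quartering the displacement should shrink the error ~16x; allow 6x
  expect_lt(errs[3], errs[1] / 6)
})

test_that("min_distance and is_feasible compose correctly", {
  ctr <- c(5, 5, 5)
  env <- ball_env(centre = ctr, radius = 3)
  # straight segment passing 2 mm above the ball surface
  z <- ctr[3] + 5
  s <- ot_state(c(-5, 5, z), c(1, 0, 0)); g <- ot_state(c(15, 5, z), c(1, 0, 0))
  tr <- build_trajectory(rbind(s$position, g$position), s, g, 0.05)
  md <- min_distance(tr, env, 0.05)
  expect_equal(md, 2, tolerance = 0.05)
  # halving ds never increases the minimum
  expect_lte(min_distance(tr, env, 0.05), min_distance(tr, env, 0.1) + 1e-12)
  # through the obstacle: negative clearance
  s2 <- ot_state(c(-5, 5, 5), c(1, 0, 0)); g2 <- ot_state(c(15, 5, 5), c(1, 0, 0))
  tr2 <- build_trajectory(rbind(s2$position, g2$position), s2, g2, 0.05)
  expect_lt(min_distance(tr2, env, 0.1), 0)
  # feasibility report mirrors the standalone ops
  fz <- is_feasible(tr, env, 0.05, 0.8, ds = 0.1)
  expect_true(fz$pass)
  expect_equal(fz$min_distance, min_distance(tr, env, 0.1))
  expect_equal(fz$max_curvature, max_curvature(tr))
  fz2 <- is_feasible(tr, env, 0.05, 3.5, ds = 0.1)
  expect_false(fz2$pass)
  expect_match(fz2$cause, "distance")
  # empty environment passes vacuously
  expect_true(is_feasible(tr, NULL, 0.05, 0.8)$pass)
})

test_that("mesh IO round-trips STL and PLY", {
  m <- extract_surface(ball_volume(radius = 2.5, dims = c(30, 30, 15)), 1,
                       smooth_iters = 10)
  fs <- tempfile(fileext = ".stl")
  write_mesh(m, fs)
  m2 <- read_mesh(fs)
  expect_equal(mesh_area_volume(m2)$area, mesh_area_volume(m)$area,
               tolerance = 1e-5)
  expect_equal(nrow(m2$faces), nrow(m$faces))
  fp <- tempfile(fileext = ".ply")
  write_mesh(m, fp)
  m3 <- read_mesh(fp)
  expect_equal(m3$vertices, m$vertices, tolerance = 1e-12)
  expect_equal(m3$faces, m$faces)
  expect_error(read_mesh(tempfile(fileext = ".obj")), "not found")
  f <- tempfile(fileext = ".obj"); writeLines("x", f)
  expect_error(read_mesh(f), "format")
})
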